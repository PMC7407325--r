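model	day1_accuracy	day2_accuracy
K-Nearest Neighbors	70	81
Linear SVM	70	77
Decision Tree	82	82
Random Forest	77	78
AdaBoost	69	81
Naive Bayes	74	78
Quadratic Discriminant Analysis	73	75
Logistic Regression	82	82
Neural Net	76	77
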