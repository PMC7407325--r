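feature	selected	day1_rf_importance	day1_svm	day1_logistic	day2_rf_importance	day2_svm	day2_logistic
Angular_R	both	-0.04	0.03	0.08	-0.03	0.01	0.04
Frontal_Inf_Tri_R	both	-0.03	-0.01	-0.02	-0.04	-0.06	-0.2
Frontal_Mid_L	both	-0.04	0.01	0.04	-0.02	0.01	0.06
Frontal_Mid_Orb_R	both	-0.03	0.04	0.18	-0.03	-0.02	-0.08
Frontal_Mid_R	both	-0.03	-0.01	-0.02	-0.03	0	-0.02
Frontal_Sup_Orb_R	both	-0.03	-0.18	-0.59	-0.02	-0.01	-0.1
Frontal_Sup_R	both	-0.03	0.02	0.05	-0.03	0.04	0.16
Insula_R	both	-0.03	0.03	0.13	-0.02	0.07	0.26
Occipital_Mid_L	both	-0.03	-0.03	-0.07	-0.03	-0.02	-0.1
Parietal_Inf_L	both	-0.04	0	-0.01	-0.03	-0.02	-0.06
Parietal_Sup_L	both	-0.03	0.01	0.04	-0.03	-0.02	-0.09
Parietal_Sup_R	both	-0.04	-0.01	-0.02	-0.05	-0.02	-0.06
Postcentral_R	both	-0.03	0.05	0.13	-0.03	0.05	0.21
Precuneus_L	both	-0.03	0.01	0.01	-0.04	-0.04	-0.13
Precuneus_R	both	-0.03	-0.01	-0.05	-0.04	0.01	0.04
Putamen_L	both	-0.03	0.2	0.81	-0.03	-0.02	-0.08
Temporal_Inf_R	both	-0.03	0	0.03	-0.03	0.01	0.07
Cerebellum_Crus2_L	day1	-0.04	0.01	0.02	NA	NA	NA
Cingulum_Mid_L	day1	-0.04	0.05	0.15	NA	NA	NA
Cingulum_Mid_R	day1	-0.04	-0.08	-0.28	NA	NA	NA
Frontal_Inf_Oper_L	day1	-0.04	-0.02	-0.08	NA	NA	NA
Frontal_Inf_Orb_R	day1	-0.04	0	-0.02	NA	NA	NA
Frontal_Mid_Orb_L	day1	-0.04	-0.13	-0.44	NA	NA	NA
Frontal_Sup_L	day1	-0.03	0.02	0.06	NA	NA	NA
Fusiform_R	day1	-0.03	0	-0.04	NA	NA	NA
Occipital_Mid_R	day1	-0.03	-0.08	-0.23	NA	NA	NA
Rolandic_Oper_R	day1	-0.03	0.01	0.14	NA	NA	NA
SupraMarginal_L	day1	-0.03	-0.01	-0.07	NA	NA	NA
Temporal_Mid_R	day1	-0.04	0.01	0	NA	NA	NA
Temporal_Pole_Mid_L	day1	-0.03	0.01	0.11	NA	NA	NA
Cerebellum_6_L	day2	NA	NA	NA	-0.03	0.08	0.32
Cerebellum_8_R	day2	NA	NA	NA	-0.02	0.02	0.12
Cerebellum_9_L	day2	NA	NA	NA	-0.03	0.1	0.35
Cingulum_Ant_L	day2	NA	NA	NA	-0.02	-0.02	-0.03
Frontal_Inf_Oper_R	day2	NA	NA	NA	-0.03	0.02	0
Frontal_Inf_Orb_L	day2	NA	NA	NA	-0.02	0.08	0.3
Frontal_Sup_Medial_R	day2	NA	NA	NA	-0.03	-0.16	-0.59
Fusiform_L	day2	NA	NA	NA	-0.03	-0.04	-0.11
Parietal_Inf_R	day2	NA	NA	NA	-0.03	-0.01	-0.02
Postcentral_L	day2	NA	NA	NA	-0.04	0.06	0.23
Precentral_L	day2	NA	NA	NA	-0.03	-0.02	-0.09
Precentral_R	day2	NA	NA	NA	-0.03	-0.03	-0.08
Rolandic_Oper_L	day2	NA	NA	NA	-0.03	-0.06	-0.23
Supp_Motor_Area_L	day2	NA	NA	NA	-0.05	0.03	0.12
Temporal_Mid_L	day2	NA	NA	NA	-0.03	0.03	0.07
Thalamus_L	day2	NA	NA	NA	-0.04	0.02	0.08
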