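#' Specification of a synthetic two-group fMRI cohort
#'
#' Bundles every knob of the synthetic cohort generator: group sizes, the
#' number of atlas regions, the grid used for voxel maps, the count model for
#' per-region suprathreshold voxel counts, planted group effects, the
#' covariate model (age, sex, BMI per group) and the symptom-coupling model.
#' The defaults emulate the study design the package targets: 38 chronic
#' fatigue syndrome (CFS) and 80 Gulf War illness (GWI) subjects, 117 atlas
#' regions, and demographics matching the reported cohort table.
#'
#' Per-region latent counts are negative binomial (counts of suprathreshold
#' voxels are overdispersed non-negative integers); `dispersion` is the
#' negative-binomial size parameter \eqn{\theta}, so the variance at mean
#' \eqn{\mu} is \eqn{\mu + \mu^2/\theta}. In `effect_regions` the group-B
#' (GWI) mean is raised so that the *pooled* standardized mean difference
#' between groups equals `effect_size` (the group-B variance inflates with
#' its mean, so the shift is solved numerically rather than taken as
#' `effect_size` times the group-A SD).
#'
#' @param n_group_a Number of group-A ("CFS") subjects. Default 38.
#' @param n_group_b Number of group-B ("GWI") subjects. Default 80.
#' @param n_regions Number of atlas regions / features. Default 117.
#' @param grid_shape Integer vector of 3 map dimensions. Default `c(24, 24, 24)`,
#'   a desk-scale grid; configurable up to full MNI resolution.
#' @param baseline_count_mean Per-region baseline mean count (scalar recycled,
#'   or vector of length `n_regions`). Default 15.
#' @param dispersion Negative-binomial size parameter (> 0). Default 8.
#' @param effect_regions Integer ids of regions carrying a planted group
#'   effect. Default none (null cohort).
#' @param effect_size Pooled standardized mean difference planted in each
#'   effect region. Default 0.
#' @param covariate_model Per-group list with `age_mean`, `age_sd`,
#'   `bmi_mean`, `bmi_sd`, `male_prop`; defaults follow the reported
#'   demographics of the two clinical groups.
#' @param symptom_coupling 9 x `n_regions` matrix of linear weights from
#'   z-scored region counts to the nine symptom-severity scores, or `NULL`
#'   for the default (each symptom coupled with weight 0.4 to one planted
#'   effect region, cycled; all-zero when there are no effect regions).
#' @param symptom_noise_sd Gaussian noise SD on the symptom scale. Default 0.5.
#' @param seed Integer seed making all generation deterministic.
#' @return An object of class `cohort_spec` (a named list).
#' @export
#' @examples
#' spec <- cohort_spec(effect_regions = 1:5, effect_size = 1.5, seed = 7)
#' spec$n_group_a + spec$n_group_b
cohort_spec <- function(n_group_a = 38,
                        n_group_b = 80,
                        n_regions = 117,
                        grid_shape = c(24, 24, 24),
                        baseline_count_mean = 15,
                        dispersion = 8,
                        effect_regions = integer(0),
                        effect_size = 0,
                        covariate_model = NULL,
                        symptom_coupling = NULL,
                        symptom_noise_sd = 0.5,
                        seed = 1L) {
  stopifnot(
    is_count_scalar(n_group_a), n_group_a >= 2,
    is_count_scalar(n_group_b), n_group_b >= 2,
    is_count_scalar(n_regions), n_regions >= 1,
    length(grid_shape) == 3, all(grid_shape >= 1),
    all(baseline_count_mean > 0),
    length(dispersion) == 1, dispersion > 0,
    length(effect_size) == 1, is.finite(effect_size)
  )
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 1) || any(effect_regions > n_regions))) {
    stop("`effect_regions` must be region ids in 1..n_regions", call. = FALSE)
  }
  baseline <- rep_len(baseline_count_mean, n_regions)
  if (is.null(covariate_model)) {
    # Demographics of the two clinical groups (means +- SD, male fraction).
    covariate_model <- list(
      a = list(age_mean = 47.74, age_sd = 16.46, bmi_mean = 26.20,
               bmi_sd = 4.52, male_prop = 0.263),
      b = list(age_mean = 46.9, age_sd = 7.8, bmi_mean = 29.6,
               bmi_sd = 5.6, male_prop = 0.738)
    )
  }
  if (is.null(symptom_coupling)) {
    symptom_coupling <- matrix(
      0, nrow = length(SYMPTOM_ITEMS), ncol = n_regions,
      dimnames = list(SYMPTOM_ITEMS, NULL)
    )
    if (length(effect_regions)) {
      for (s in seq_along(SYMPTOM_ITEMS)) {
        r <- effect_regions[((s - 1L) %% length(effect_regions)) + 1L]
        symptom_coupling[s, r] <- 0.4
      }
    }
  }
  stopifnot(
    nrow(symptom_coupling) == length(SYMPTOM_ITEMS),
    ncol(symptom_coupling) == n_regions,
    symptom_noise_sd >= 0
  )
  structure(
    list(
      n_group_a = as.integer(n_group_a),
      n_group_b = as.integer(n_group_b),
      n_regions = as.integer(n_regions),
      grid_shape = as.integer(grid_shape),
      baseline_count_mean = baseline,
      dispersion = dispersion,
      effect_regions = effect_regions,
      effect_size = effect_size,
      covariate_model = covariate_model,
      symptom_coupling = symptom_coupling,
      symptom_noise_sd = symptom_noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

region_name <- function(id) sprintf("region_%03d", id)

#' Generate a synthetic labelled atlas volume
#'
#' Partitions the voxels inside an ellipsoidal "brain" mask into `n_regions`
#' contiguous parcels (discrete Voronoi cells around randomly placed seed
#' voxels), standing in for an anatomical parcellation such as the AAL atlas.
#' Voxels outside the mask carry the background label 0.
#'
#' @param n_regions Number of regions (default 117).
#' @param grid_shape Integer vector of 3 dimensions (default `c(24, 24, 24)`).
#' @param seed Integer seed; the atlas is deterministic given the seed.
#' @param vox_size Isotropic voxel size in mm for the affine (default 8).
#' @return An object of class `atlas_volume`: a list with `labels` (3-D
#'   integer array), `region_table` (tibble: `region_id`, `name`, centre of
#'   mass in world mm, `n_voxels`), and `affine` (4 x 4 voxel-to-world
#'   transform, 0-based voxel indices).
#' @export
#' @examples
#' atlas <- generate_atlas(n_regions = 5, grid_shape = c(8, 8, 8), seed = 1)
#' atlas$region_table
generate_atlas <- function(n_regions = 117,
                           grid_shape = c(24, 24, 24),
                           seed = 1L,
                           vox_size = 8) {
  stopifnot(is_count_scalar(n_regions), n_regions >= 1,
            length(grid_shape) == 3, all(grid_shape >= 1))
  grid_shape <- as.integer(grid_shape)
  if (prod(grid_shape) < n_regions) {
    stop("grid too small: fewer voxels than requested regions", call. = FALSE)
  }
  # Voxel centre coordinates, 0-based, and an ellipsoidal in-brain mask with
  # semi-axes at 45% of each dimension.
  ijk <- as.matrix(expand.grid(
    i = seq_len(grid_shape[1]) - 1L,
    j = seq_len(grid_shape[2]) - 1L,
    k = seq_len(grid_shape[3]) - 1L
  ))
  centre <- (grid_shape - 1) / 2
  semi <- pmax(grid_shape * 0.45, 0.5)
  d2 <- ((ijk[, 1] - centre[1]) / semi[1])^2 +
    ((ijk[, 2] - centre[2]) / semi[2])^2 +
    ((ijk[, 3] - centre[3]) / semi[3])^2
  in_mask <- which(d2 <= 1)
  if (length(in_mask) < n_regions) {
    stop(sprintf(
      "mask holds %d voxels, fewer than the %d requested regions",
      length(in_mask), n_regions
    ), call. = FALSE)
  }
  labels <- with_seed(seed, {
    seeds <- sample(in_mask, n_regions)
    lab <- integer(prod(grid_shape))
    sc <- ijk[seeds, , drop = FALSE]
    # Nearest seed in voxel space; ties go to the lowest region id.
    best_d <- rep(Inf, length(in_mask))
    best_r <- integer(length(in_mask))
    pm <- ijk[in_mask, , drop = FALSE]
    for (r in seq_len(n_regions)) {
      dr <- (pm[, 1] - sc[r, 1])^2 + (pm[, 2] - sc[r, 2])^2 +
        (pm[, 3] - sc[r, 3])^2
      upd <- dr < best_d
      best_d[upd] <- dr[upd]
      best_r[upd] <- r
    }
    lab[in_mask] <- best_r
    array(lab, dim = grid_shape)
  })
  affine <- diag(c(rep(vox_size, 3), 1))
  affine[1:3, 4] <- -centre * vox_size
  com <- vapply(seq_len(n_regions), function(r) {
    v <- ijk[labels == r, , drop = FALSE]
    world <- sweep(v * vox_size, 2, centre * vox_size)
    colMeans(world)
  }, numeric(3))
  region_table <- tibble::tibble(
    region_id = seq_len(n_regions),
    name = region_name(seq_len(n_regions)),
    com_x = com[1, ], com_y = com[2, ], com_z = com[3, ],
    n_voxels = as.integer(tabulate(labels[labels > 0], nbins = n_regions))
  )
  structure(
    list(labels = labels, region_table = region_table, affine = affine),
    class = "atlas_volume"
  )
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf(
    "<atlas_volume> %s grid, %d regions, %d in-mask voxels\n",
    paste(dim(x$labels), collapse = "x"),
    nrow(x$region_table), sum(x$labels > 0)
  ))
  invisible(x)
}

# Group-B mean such that the pooled standardized mean difference against
# mu_a equals d under NB variance mu + mu^2/theta.
nb_shifted_mean <- function(mu_a, theta, d) {
  if (d == 0) {
    return(mu_a)
  }
  v <- function(mu) mu + mu^2 / theta
  f <- function(mu_b) (mu_b - mu_a) / sqrt((v(mu_a) + v(mu_b)) / 2) - d
  upper <- mu_a + abs(d) * sqrt(v(mu_a)) * 10 + 10
  if (d > 0) {
    uniroot(f, c(mu_a, upper), tol = 1e-10)$root
  } else {
    uniroot(f, c(max(mu_a + d * sqrt(v(mu_a)) * 10 - 10, 1e-8), mu_a),
            tol = 1e-10)$root
  }
}

#' Generate a synthetic two-group cohort of activation maps or counts
#'
#' Draws per-subject, per-region latent suprathreshold voxel counts from a
#' negative binomial model, plants a standardized group difference in the
#' spec's effect regions, and attaches demographics drawn from the spec's
#' covariate model. In `"table"` mode the latent counts are returned directly
#' as the feature table; in `"maps"` mode each subject receives a full 3-D
#' t-statistic map in which exactly the latent number of voxels per region is
#' suprathreshold (t drawn uniformly in (3.2, 8)) and every other voxel is
#' subthreshold (t uniform in (-2, 3)), so feature extraction at t > 3.17
#' recovers the latent counts exactly. In `"maps"` mode latent counts are
#' truncated at each region's voxel capacity before planting.
#'
#' @param spec A [cohort_spec()].
#' @param atlas An `atlas_volume`; required in `"maps"` mode (grid must match
#'   `spec$grid_shape`), and used for region capacities. If `NULL`, one is
#'   generated from the spec.
#' @param mode `"table"` (default) or `"maps"`.
#' @return An object of class `synthetic_cohort`: list with `table` (tibble:
#'   `subject_id`, `group`, `day`, `age`, `sex`, `bmi`, nine `sev_*` symptom
#'   scores, then one column per region), `maps` (named list of `stat_map`
#'   objects, `"maps"` mode only), `latent_counts` (subjects x regions integer
#'   matrix), `atlas`, and `spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_group_a = 4, n_group_b = 6, n_regions = 5,
#'                     grid_shape = c(8, 8, 8), seed = 2)
#' coh <- generate_cohort(spec)
#' dim(coh$table)
generate_cohort <- function(spec, atlas = NULL, mode = c("table", "maps")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  if (is.null(atlas)) {
    atlas <- generate_atlas(spec$n_regions, spec$grid_shape, seed = spec$seed)
  }
  stopifnot(inherits(atlas, "atlas_volume"))
  if (nrow(atlas$region_table) != spec$n_regions) {
    stop("atlas region count does not match spec$n_regions", call. = FALSE)
  }
  if (mode == "maps" && !all(dim(atlas$labels) == spec$grid_shape)) {
    stop("in 'maps' mode the atlas grid must match spec$grid_shape",
         call. = FALSE)
  }
  n_a <- spec$n_group_a
  n_b <- spec$n_group_b
  n <- n_a + n_b
  R <- spec$n_regions
  group <- factor(rep(c("CFS", "GWI"), c(n_a, n_b)), levels = c("GWI", "CFS"))
  subject_id <- sprintf("S%03d", seq_len(n))

  mu <- matrix(rep(spec$baseline_count_mean, each = n), n, R)
  for (r in spec$effect_regions) {
    mu[group == "GWI", r] <- nb_shifted_mean(
      spec$baseline_count_mean[r], spec$dispersion, spec$effect_size
    )
  }

  out <- with_seed(spec$seed, {
    counts <- matrix(
      rnbinom(n * R, size = spec$dispersion, mu = as.vector(mu)), n, R
    )
    if (mode == "maps") {
      capacity <- atlas$region_table$n_voxels
      counts <- pmin(counts, matrix(rep(capacity, each = n), n, R))
    }
    cm <- spec$covariate_model
    age <- c(rnorm(n_a, cm$a$age_mean, cm$a$age_sd),
             rnorm(n_b, cm$b$age_mean, cm$b$age_sd))
    bmi <- c(rnorm(n_a, cm$a$bmi_mean, cm$a$bmi_sd),
             rnorm(n_b, cm$b$bmi_mean, cm$b$bmi_sd))
    sex <- factor(
      ifelse(c(rbinom(n_a, 1, cm$a$male_prop),
               rbinom(n_b, 1, cm$b$male_prop)) == 1, "M", "F"),
      levels = c("F", "M")
    )
    maps <- NULL
    if (mode == "maps") {
      region_vox <- split(which(atlas$labels > 0),
                          atlas$labels[atlas$labels > 0])
      nvox <- prod(spec$grid_shape)
      maps <- lapply(seq_len(n), function(s) {
        t_arr <- array(runif(nvox, -2, 3), dim = spec$grid_shape)
        for (r in seq_len(R)) {
          k <- counts[s, r]
          if (k > 0) {
            vox <- region_vox[[as.character(r)]]
            pick <- if (length(vox) == 1) vox else sample(vox, k)
            t_arr[pick] <- runif(k, 3.2, 8)
          }
        }
        stat_map(t_arr, affine = atlas$affine,
                 subject_id = subject_id[s], day = 1L)
      })
      names(maps) <- subject_id
    }
    list(counts = counts, age = age, bmi = bmi, sex = sex, maps = maps)
  })

  counts <- out$counts
  colnames(counts) <- atlas$region_table$name
  storage.mode(counts) <- "integer"
  tab <- tibble::tibble(
    subject_id = subject_id,
    group = group,
    day = 1L,
    age = out$age,
    sex = out$sex,
    bmi = out$bmi
  )
  tab <- dplyr::bind_cols(tab, tibble::as_tibble(counts))
  tab <- set_region_cols(tab, atlas$region_table$name)

  coh <- structure(
    list(table = tab, maps = out$maps, latent_counts = counts,
         atlas = atlas, spec = spec),
    class = "synthetic_cohort"
  )
  sym <- generate_symptoms(coh$table, spec)
  coh$table <- dplyr::bind_cols(
    tab[, c("subject_id", "group", "day", "age", "sex", "bmi")],
    sym[, SYMPTOM_COLS],
    tab[, atlas$region_table$name]
  )
  coh$table <- set_region_cols(coh$table, atlas$region_table$name)
  coh
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d CFS / %d GWI), %d regions%s\n",
    nrow(x$table), sum(x$table$group == "CFS"), sum(x$table$group == "GWI"),
    length(region_cols(x$table)),
    if (is.null(x$maps)) "" else sprintf(", %d t-maps", length(x$maps))
  ))
  invisible(x)
}

#' Generate symptom-severity scores coupled to region counts
#'
#' Produces the nine symptom-severity items (0-4 scale) per subject as a
#' linear combination of z-scored region counts plus Gaussian noise, affinely
#' mapped around the scale midpoint (2) and clipped to \[0, 4\]. With zero
#' coupling and zero noise every score is exactly the midpoint.
#'
#' @param counts A cohort table (with region columns) or a subjects x regions
#'   numeric matrix.
#' @param spec The [cohort_spec()] carrying `symptom_coupling` (9 x regions)
#'   and `symptom_noise_sd`; scores are deterministic given `spec$seed`.
#' @return Tibble with `subject_id` (when available) and nine `sev_*` columns.
#' @export
generate_symptoms <- function(counts, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.data.frame(counts)) {
    ids <- counts[["subject_id"]]
    X <- region_matrix(counts)
  } else {
    ids <- rownames(counts)
    X <- as.matrix(counts)
  }
  W <- spec$symptom_coupling
  if (ncol(W) != ncol(X)) {
    stop("symptom_coupling columns do not match the number of regions",
         call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  Z <- sweep(X, 2, colMeans(X))
  nz <- sds > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sds[nz], "/")
  Z[, !nz] <- 0
  raw <- Z %*% t(W)
  scores <- with_seed(spec$seed + 1L, {
    2 + 0.8 * raw +
      matrix(rnorm(length(raw), 0, spec$symptom_noise_sd), nrow(raw))
  })
  scores <- pmin(pmax(scores, 0), 4)
  colnames(scores) <- SYMPTOM_COLS
  out <- tibble::as_tibble(scores)
  if (!is.null(ids)) {
    out <- dplyr::bind_cols(tibble::tibble(subject_id = ids), out)
  }
  out
}
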