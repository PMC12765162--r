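#' Cohort generator configuration
#'
#' Defaults emulate the demographics and effect-size structure of a
#' 160-participant memory-clinic/healthy-aging sample: age 65.0 +/- 8.3
#' years, 64% female, cognitive staging CN/SCD/MCI = 114/27/19, Fazekas
#' 0/1/2/3 = 60/71/23/6, and amyloid status assigned per stage
#' (CN 12 A+/101 A-/1 NA, SCD 6/19/2, MCI 12/6/1). The per-metric
#' coefficient blocks inject the age, sex, age-by-sex, cognitive-staging,
#' Fazekas and amyloid effects that the cohort analyses are expected to
#' recover; intercepts and residual standard deviations set plausible
#' absolute levels (GM Tex about 400 ms for a 65-year-old CN female with
#' residual sd 40 ms; CBF about 55 mL/100 g/min, sd 12; ATT about 1250 ms,
#' sd 100). ATT coefficients are stored in ms.
#'
#' @param n Number of subjects.
#' @param age_mean,age_sd Age distribution, years.
#' @param female_frac Probability of female sex.
#' @param stage_counts Named integer vector CN/SCD/MCI summing to `n`.
#' @param fazekas_counts Named integer vector `0`..`3` summing to `n`.
#' @param amyloid_by_stage List per stage of counts `c(pos, neg, na)`
#'   summing to the stage count.
#' @param coefficients Named list per metric of the coefficient block:
#'   `intercept`, `age`, `sex` (male), `age_sex`, `scd`, `mci`,
#'   `fazekas1..3`, `amyloid` (A+).
#' @param residual_sd Named numeric vector per metric.
#' @param confounded If TRUE, stage assignment is age-dependent (MCI and
#'   SCD drawn preferentially from older subjects) to exercise covariate
#'   adjustment; default FALSE assigns groups independently of age and
#'   sex.
#' @return An object of class `cohort_gen_config`.
#' @export
cohort_gen_config <- function(
    n = 160L, age_mean = 65.0, age_sd = 8.3, female_frac = 0.64,
    stage_counts = c(CN = 114L, SCD = 27L, MCI = 19L),
    fazekas_counts = c(`0` = 60L, `1` = 71L, `2` = 23L, `3` = 6L),
    amyloid_by_stage = list(CN = c(pos = 12L, neg = 101L, na = 1L),
                            SCD = c(pos = 6L, neg = 19L, na = 2L),
                            MCI = c(pos = 12L, neg = 6L, na = 1L)),
    coefficients = list(
      gm_tex = c(intercept = 550, age = -2.29, sex = -129.0,
                 age_sex = 1.57, scd = -17.4, mci = -31.8,
                 fazekas1 = -6.72, fazekas2 = -16.9, fazekas3 = -7.42,
                 amyloid = 3.29),
      gm_cbf = c(intercept = 118, age = -0.97, sex = -69.1,
                 age_sex = 0.90, scd = -5.60, mci = -18.8,
                 fazekas1 = 1.30, fazekas2 = -7.48, fazekas3 = -2.99,
                 amyloid = 1.32),
      gm_att = c(intercept = 924, age = 5.02, sex = 80.9,
                 age_sex = -0.52, scd = -3, mci = -4,
                 fazekas1 = 24, fazekas2 = 59, fazekas3 = 156,
                 amyloid = 0)),
    residual_sd = c(gm_tex = 40, gm_cbf = 12, gm_att = 100),
    confounded = FALSE) {
  if (sum(stage_counts) != n) stop("stage counts must sum to n")
  if (sum(fazekas_counts) != n) stop("fazekas counts must sum to n")
  for (s in names(stage_counts)) {
    if (sum(amyloid_by_stage[[s]]) != stage_counts[[s]])
      stop("amyloid counts for stage ", s, " must sum to its stage count")
  }
  if (female_frac < 0 || female_frac > 1) stop("female_frac must be in [0,1]")
  if (any(residual_sd <= 0)) stop("residual sd must be > 0")
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 female_frac = female_frac, stage_counts = stage_counts,
                 fazekas_counts = fazekas_counts,
                 amyloid_by_stage = amyloid_by_stage,
                 coefficients = coefficients, residual_sd = residual_sd,
                 confounded = confounded),
            class = "cohort_gen_config")
}

#' Generate a synthetic cohort table
#'
#' Samples demographics and assigns staging, Fazekas and amyloid status by
#' exact counts (shuffled by seed; independent of age and sex unless
#' `confounded`), then builds each metric as the linear predictor of its
#' coefficient block plus Gaussian residual noise. Fully reproducible per
#' seed.
#'
#' @param cfg A [cohort_gen_config()].
#' @param seed Integer seed.
#' @return Data frame with columns subject, age, sex, cohort, cogstage,
#'   fazekas, amyloid and one column per metric (gm_tex ms, gm_cbf
#'   mL/100 g/min, gm_att ms).
#' @export
gen_cohort <- function(cfg = cohort_gen_config(), seed = 1L) {
  set.seed(seed)
  n <- cfg$n
  age <- stats::rnorm(n, cfg$age_mean, cfg$age_sd)
  sex <- ifelse(stats::runif(n) < cfg$female_frac, "female", "male")

  stage_pool <- rep(names(cfg$stage_counts), cfg$stage_counts)
  if (cfg$confounded) {
    # older subjects drawn preferentially into SCD/MCI
    ord <- order(age + stats::rnorm(n, 0, cfg$age_sd / 2))
    stage <- character(n)
    n_mci <- cfg$stage_counts[["MCI"]]; n_scd <- cfg$stage_counts[["SCD"]]
    stage[ord[seq(n, n - n_mci + 1)]] <- "MCI"
    stage[ord[seq(n - n_mci, n - n_mci - n_scd + 1)]] <- "SCD"
    stage[stage == ""] <- "CN"
  } else {
    stage <- sample(stage_pool)
  }
  fazekas <- sample(rep(names(cfg$fazekas_counts), cfg$fazekas_counts))

  amyloid <- character(n)
  for (s in names(cfg$stage_counts)) {
    idx <- which(stage == s)
    cts <- cfg$amyloid_by_stage[[s]]
    lab <- sample(rep(c("A+", "A-", NA_character_), cts))
    amyloid[idx] <- lab
  }

  male <- as.numeric(sex == "male")
  scd <- as.numeric(stage == "SCD"); mci <- as.numeric(stage == "MCI")
  f1 <- as.numeric(fazekas == "1"); f2 <- as.numeric(fazekas == "2")
  f3 <- as.numeric(fazekas == "3")
  apos <- as.numeric(!is.na(amyloid) & amyloid == "A+")

  out <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n)),
    age = age, sex = sex,
    cohort = ifelse(stage == "CN", "LCBC", "DDI"),
    cogstage = stage, fazekas = fazekas, amyloid = amyloid,
    stringsAsFactors = FALSE)

  for (m in names(cfg$coefficients)) {
    b <- cfg$coefficients[[m]]
    mu <- b["intercept"] + b["age"] * age + b["sex"] * male +
      b["age_sex"] * age * male + b["scd"] * scd + b["mci"] * mci +
      b["fazekas1"] * f1 + b["fazekas2"] * f2 + b["fazekas3"] * f3 +
      b["amyloid"] * apos
    out[[m]] <- as.numeric(mu) + stats::rnorm(n, 0, cfg$residual_sd[[m]])
  }
  out
}

#' Digital phantom configuration
#'
#' Layout of a small rectangular-slab phantom: each ROI is a disjoint slab
#' of the grid carrying constant ground-truth kinetics. Default grid
#' 16 x 16 x 4 with the seven named regions (ACA, MCA, posterior,
#' precuneus, frontal, ant_cingulate, post_cingulate) tiled across the
#' grid; remaining in-mask voxels are generic GM.
#'
#' @param dims Grid shape (3 integers).
#' @param rois Data frame with columns name, and the slab bounds x0, x1,
#'   y0, y1, z0, z1 (inclusive voxel indices), plus truth columns cbf,
#'   att_a, t_a, tex. NULL for the default layout.
#' @param baseline Static-tissue signal (relative M0).
#' @param noise_sd Acquisition noise sd (signal-fraction units).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(16L, 16L, 4L), rois = NULL,
                           baseline = 1, noise_sd = 0) {
  dims <- as.integer(dims)
  if (is.null(rois)) {
    # 4 x-columns by 2 y-halves, full z; seven slabs, one cell left as
    # out-of-mask background (scales with the grid; needs dims >= c(4,2,1))
    if (any(dims < c(4L, 2L, 1L)))
      stop("default layout needs a grid of at least 4 x 2 x 1")
    xb <- round(seq(0, dims[1], length.out = 5))
    yb <- round(seq(0, dims[2], length.out = 3))
    cell <- function(i, j) c(x0 = xb[i] + 1, x1 = xb[i + 1],
                             y0 = yb[j] + 1, y1 = yb[j + 1])
    slabs <- rbind(cell(1, 1), cell(2, 1), cell(3, 1), cell(4, 1),
                   cell(1, 2), cell(2, 2), cell(3, 2))
    rois <- data.frame(
      name = c("ACA", "MCA", "posterior", "precuneus", "frontal",
               "ant_cingulate", "post_cingulate"),
      slabs,
      z0 = rep(1, 7), z1 = rep(dims[3], 7),
      cbf = c(65, 60, 55, 50, 58, 52, 48),
      att_a = c(600, 700, 900, 800, 700, 750, 850),
      t_a = c(400, 450, 550, 500, 450, 480, 520),
      tex = c(350, 400, 450, 300, 380, 320, 430))
  }
  if (length(dims) != 3 || any(dims < 1)) stop("dims must be 3 positive ints")
  occupied <- array(FALSE, dim = dims)
  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    if (r$x1 > dims[1] || r$y1 > dims[2] || r$z1 > dims[3])
      stop("slab '", r$name, "' exceeds the grid")
    sl <- occupied[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1]
    if (any(sl)) stop("overlapping slabs at '", r$name, "'")
    occupied[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1] <- TRUE
  }
  structure(list(dims = dims, rois = rois, baseline = baseline,
                 noise_sd = noise_sd),
            class = "phantom_config")
}

#' Generate a digital phantom
#'
#' Paints piecewise-constant ground-truth parameter fields onto the slab
#' layout of a [phantom_config()]; everything outside the union of slabs
#' is outside the gray-matter mask and zero-filled.
#'
#' @param cfg A [phantom_config()].
#' @return List with `truth` (list of 3D arrays cbf, att_a, t_a, tex),
#'   `gm_mask` (logical array), `atlas` (a [roi_atlas()]).
#' @export
gen_phantom <- function(cfg = phantom_config()) {
  dims <- cfg$dims
  zero <- function() array(0, dim = dims)
  truth <- list(cbf = zero(), att_a = zero(), t_a = zero(), tex = zero())
  label_map <- array(0L, dim = dims)
  for (i in seq_len(nrow(cfg$rois))) {
    r <- cfg$rois[i, ]
    ix <- r$x0:r$x1; iy <- r$y0:r$y1; iz <- r$z0:r$z1
    truth$cbf[ix, iy, iz] <- r$cbf
    truth$att_a[ix, iy, iz] <- r$att_a
    truth$t_a[ix, iy, iz] <- r$t_a
    truth$tex[ix, iy, iz] <- r$tex
    label_map[ix, iy, iz] <- i
  }
  gm_mask <- label_map > 0
  atlas <- roi_atlas(label_map,
                     data.frame(label = seq_len(nrow(cfg$rois)),
                                name = cfg$rois$name))
  list(truth = truth, gm_mask = gm_mask, atlas = atlas)
}

#' Simulate the encoded acquisitions of a phantom
#'
#' Runs the forward model over every in-mask voxel of a phantom for the
#' standard protocol set (HAD8 PLD sets A and B, HAD4 multi-echo) and
#' returns the encoded series.
#'
#' @param phantom Output of [gen_phantom()].
#' @param c A [tissue_constants()].
#' @param baseline Static signal level.
#' @param noise_sd Gaussian noise sd; 0 for noiseless.
#' @param seed Seed (required when noise_sd > 0). Each protocol uses a
#'   distinct sub-seed derived from it.
#' @return List of `encoded_series`: `had8a`, `had8b`, `had4`.
#' @export
simulate_phantom_acquisition <- function(phantom, c = tissue_constants(),
                                         baseline = 1, noise_sd = 0,
                                         seed = NULL) {
  dims <- dim(phantom$gm_mask)
  nv <- prod(dims)
  truth_list <- vector("list", nv)
  for (v in seq_len(nv)) {
    if (phantom$gm_mask[v] && phantom$truth$cbf[v] > 0) {
      truth_list[[v]] <- voxel_params(phantom$truth$cbf[v],
                                      phantom$truth$att_a[v],
                                      phantom$truth$t_a[v],
                                      phantom$truth$tex[v])
    } else {
      truth_list[[v]] <- voxel_params(0, 1, 1, 1)
    }
  }
  protos <- list(had8a = protocol_had8("A"), had8b = protocol_had8("B"),
                 had4 = protocol_had4())
  out <- list()
  for (i in seq_along(protos)) {
    sd_i <- if (noise_sd > 0) seed + i else NULL
    out[[names(protos)[i]]] <- encode_series(
      truth_list, protos[[i]], c, baseline = baseline,
      noise_sd = noise_sd, seed = sd_i)
  }
  out
}

#' Generate a synthetic SUVR table
#'
#' Region SUVRs for amyloid-negative subjects around 1.2 and positives
#' around 1.2 + `sep`, with within-subject correlation across regions
#' (shared subject-level random effect) and total per-cell sd 0.05.
#'
#' @param n_neg,n_pos Group sizes (sum >= 10).
#' @param sep Mean separation between groups (>= 0; 0 exercises the
#'   degenerate-mixture path downstream).
#' @param regions Region names (>= 2).
#' @param seed Integer seed.
#' @return List with `suvr` (data frame, subjects x regions) and `truth`
#'   (character vector "A+"/"A-").
#' @export
gen_suvr <- function(n_neg, n_pos, sep = 0.7,
                     regions = c("precuneus", "frontal", "ant_cingulate",
                                 "post_cingulate", "lat_parietal"),
                     seed = 1L) {
  if (n_neg + n_pos < 10) stop("need at least 10 subjects in total")
  if (sep < 0) stop("sep must be >= 0")
  if (length(regions) < 2) stop("need at least 2 regions")
  set.seed(seed)
  n <- n_neg + n_pos
  truth <- c(rep("A-", n_neg), rep("A+", n_pos))
  mu <- 1.2 + ifelse(truth == "A+", sep, 0)
  u <- stats::rnorm(n, 0, 0.03)                  # shared across regions
  e <- matrix(stats::rnorm(n * length(regions), 0, 0.04), n)
  suvr <- sweep(e, 1, mu + u, `+`)
  colnames(suvr) <- regions
  list(suvr = as.data.frame(suvr), truth = truth)
}
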