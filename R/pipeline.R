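#' Pipeline run configuration
#'
#' Bundles everything an end-to-end synthetic run needs: output directory,
#' tissue constants, fit configuration, QC threshold, phantom and cohort
#' settings, and the master seed. Can be loaded from a YAML file with
#' [load_run_config()].
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; every stage derives its sub-seeds from it.
#' @param constants A [tissue_constants()].
#' @param fit_cfg A [fit_config()].
#' @param qc_threshold sCoV pass threshold (default 0.8).
#' @param phantom_dims Grid for the imaging phantom (kept deliberately
#'   small for routine runs; the slab layout scales with it).
#' @param n_img_subjects Number of simulated imaging subjects to push
#'   through encode/decode/fit/QC/ROI.
#' @param img_noise_sd Acquisition noise sd for the imaging subjects.
#' @param cohort_cfg A [cohort_gen_config()].
#' @param log_level "info" or "quiet".
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("asltex_run_"), seed = 1L,
                       constants = tissue_constants(),
                       fit_cfg = fit_config(),
                       qc_threshold = 0.8,
                       phantom_dims = c(8L, 8L, 2L),
                       n_img_subjects = 1L,
                       img_noise_sd = 0,
                       cohort_cfg = cohort_gen_config(),
                       log_level = c("info", "quiet")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 constants = constants, fit_cfg = fit_cfg,
                 qc_threshold = qc_threshold,
                 phantom_dims = as.integer(phantom_dims),
                 n_img_subjects = as.integer(n_img_subjects),
                 img_noise_sd = img_noise_sd,
                 cohort_cfg = cohort_cfg,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror the [run_config()]
#' arguments (scalar settings only; constants and fit bounds as nested
#' maps). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("out_dir", "seed", "qc_threshold", "phantom_dims",
               "n_img_subjects", "img_noise_sd", "constants", "log_level")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  const <- if (!is.null(y$constants)) do.call(tissue_constants, y$constants)
           else tissue_constants()
  args <- y[setdiff(names(y), "constants")]
  args$constants <- const
  do.call(run_config, args)
}

.log <- function(cfg, ...) {
  if (cfg$log_level == "info")
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
}

#' Run the full synthetic pipeline
#'
#' End-to-end run: simulate encoded acquisitions for `n_img_subjects`
#' digital phantoms, decode, fit parameter maps, apply the sCoV quality
#' gate, aggregate ROI metrics for the survivors; then generate the
#' synthetic cohort table and run the statistical battery (age/sex
#' interaction models, Welch test on amyloid status, one-way ANOVA +
#' Tukey on staging and Fazekas, and the staged linear-model ladder with
#' the full-covariate model). All outputs are TSV/NIfTI/JSON files under
#' `cfg$out_dir`; a manifest records seeds, thresholds, exclusions and the
#' files written. Deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @return The manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  const <- cfg$constants

  ## --- imaging arm: phantom -> encode -> decode -> fit -> QC -> ROI ----
  phantom <- gen_phantom(phantom_config(dims = cfg$phantom_dims))
  qc_rows <- list(); roi_rows <- list()
  n_excluded <- 0L
  for (s in seq_len(cfg$n_img_subjects)) {
    sid <- sprintf("sub-%02d", s)
    .log(cfg, "simulating and fitting ", sid)
    acq <- simulate_phantom_acquisition(
      phantom, const, baseline = 1, noise_sd = cfg$img_noise_sd,
      seed = if (cfg$img_noise_sd > 0) cfg$seed * 1000L + s else NULL)
    dec8 <- list(decode_series(acq$had8a, const),
                 decode_series(acq$had8b, const))
    dec4 <- decode_series(acq$had4, const)
    pmap <- fit_volume(dec8, dec4, phantom$gm_mask, const, cfg$fit_cfg)
    prefix <- file.path(cfg$out_dir, sid)
    files <- c(files, write_parameter_map(pmap, prefix))
    qc <- compute_scov(pmap$cbf_map, phantom$gm_mask, cfg$qc_threshold)
    qc_rows[[s]] <- data.frame(subject = sid, scov = qc$scov,
                               pass = qc$pass, threshold = qc$threshold)
    if (!qc$pass) { n_excluded <- n_excluded + 1L; next }
    roi_rows[[s]] <- roi_metrics(pmap, phantom$atlas, phantom$gm_mask, sid)
  }
  qc_tab <- do.call(rbind, qc_rows)
  files <- c(files, write_tsv(qc_tab, file.path(cfg$out_dir, "qc.tsv")))
  roi_tab <- if (length(roi_rows)) do.call(rbind, roi_rows) else
    data.frame(subject = character(0), roi = character(0),
               metric = character(0), value = numeric(0),
               n_voxels = integer(0))
  files <- c(files, write_tsv(roi_tab, file.path(cfg$out_dir,
                                                 "roi_metrics.tsv")))
  if (nrow(roi_tab) == 0)
    .log(cfg, "all imaging subjects excluded by QC; n = 0 downstream")

  ## --- cohort arm: generate table -> stats battery --------------------
  .log(cfg, "generating cohort and running statistics")
  cohort <- gen_cohort(cfg$cohort_cfg, seed = cfg$seed)
  files <- c(files, write_tsv(cohort, file.path(cfg$out_dir, "cohort.tsv")))

  metrics <- names(cfg$cohort_cfg$coefficients)
  stats_rows <- list()
  for (m in metrics) {
    ixn <- staged_lm(cohort, m, "age_sex_interaction")
    stats_rows[[length(stats_rows) + 1]] <-
      cbind(metric = m, model = "age_sex_interaction",
            ixn[, c("term", "estimate", "se", "p")])
    for (pred in c("amyloid", "cogstage", "fazekas")) {
      asx <- staged_lm(cohort, m, "age_sex", predictor = pred)
      stats_rows[[length(stats_rows) + 1]] <-
        cbind(metric = m, model = paste0("age_sex_", pred),
              asx[, c("term", "estimate", "se", "p")])
    }
    full <- staged_lm(cohort, m, "full")
    stats_rows[[length(stats_rows) + 1]] <-
      cbind(metric = m, model = "full",
            full[, c("term", "estimate", "se", "p")])
  }
  stats_tab <- do.call(rbind, stats_rows)
  files <- c(files, write_tsv(stats_tab,
                              file.path(cfg$out_dir, "stats_models.tsv")))

  group_rows <- list()
  for (m in metrics) {
    wt <- welch_t(cohort[[m]], cohort$amyloid)
    group_rows[[length(group_rows) + 1]] <-
      data.frame(metric = m, test = "welch_amyloid", stat = wt$t, p = wt$p)
    for (g in c("cogstage", "fazekas")) {
      av <- anova_tukey(cohort[[m]], cohort[[g]])
      group_rows[[length(group_rows) + 1]] <-
        data.frame(metric = m, test = paste0("anova_", g),
                   stat = av$F, p = av$p)
    }
  }
  group_tab <- do.call(rbind, group_rows)
  files <- c(files, write_tsv(group_tab,
                              file.path(cfg$out_dir, "stats_groups.tsv")))

  ## --- amyloid biomarker arm ------------------------------------------
  sv <- gen_suvr(n_neg = 50, n_pos = 10, sep = 0.7, seed = cfg$seed + 7L)
  calls <- pet_gmm_classify(sv$suvr, seed = cfg$seed)
  calls$truth <- sv$truth
  files <- c(files, write_tsv(calls, file.path(cfg$out_dir,
                                               "amyloid_pet.tsv")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("asltex")),
    seed = cfg$seed,
    qc_threshold = cfg$qc_threshold,
    phantom_dims = cfg$phantom_dims,
    n_img_subjects = cfg$n_img_subjects,
    n_excluded_qc = n_excluded,
    cohort_n = nrow(cohort),
    files = basename(unname(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
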