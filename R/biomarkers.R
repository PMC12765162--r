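#' Amyloid status from PET SUVR via PC1 + two-component Gaussian mixture
#'
#' Replicates the PET pathway for amyloid classification: each region's
#' standardized uptake value ratio (SUVR) column is z-scored, the first
#' principal component (PC1) is extracted from the standardized table, its
#' sign is fixed so that PC1 correlates positively with the per-subject
#' mean SUVR, and a two-component Gaussian mixture (unequal variances) is
#' fitted to the PC1 scores. Subjects assigned by maximum posterior to the
#' component with the higher mean are called amyloid positive (A+).
#'
#' @param suvr Data frame or matrix of SUVR values, subjects in rows,
#'   regions in columns (>= 10 subjects, >= 2 regions, all positive, no
#'   missing values).
#' @param seed Integer seed, recorded in the result. The mixture fit uses
#'   a deterministic EM initialization, so the seed does not alter calls;
#'   it is kept for interface stability and provenance.
#' @return Data frame with one row per subject: `status` ("A+"/"A-"/NA),
#'   `posterior_prob` (probability of the A+ component), `pathway`
#'   ("PET-GMM"), `pc1`.
#' @importFrom mclust Mclust mclustBIC
#' @export
pet_gmm_classify <- function(suvr, seed = 1L) {
  x <- as.matrix(suvr)
  if (nrow(x) < 10) stop("need at least 10 subjects")
  if (ncol(x) < 2) stop("need at least 2 regions")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("SUVR values must be positive and complete")

  # columns with zero variance carry no information; drop them
  keep <- apply(x, 2, stats::sd) > 0
  if (sum(keep) < 2) stop("need at least 2 regions with variation")
  z <- scale(x[, keep, drop = FALSE])
  pc1 <- stats::prcomp(z, center = FALSE, scale. = FALSE)$x[, 1]
  if (stats::cor(pc1, rowMeans(x)) < 0) pc1 <- -pc1

  set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(pc1, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  na_out <- data.frame(status = NA_character_,
                       posterior_prob = NA_real_,
                       pathway = "PET-GMM", pc1 = pc1)
  if (is.null(fit)) {
    warning("Gaussian mixture fit failed; all calls set to NA")
    return(na_out)
  }
  pos_comp <- which.max(fit$parameters$mean)
  hard <- apply(fit$z, 1, which.max)
  if (min(table(factor(hard, levels = 1:2))) < 2) {
    warning("degenerate mixture (a component holds < 2 subjects); ",
            "all calls set to NA")
    return(na_out)
  }
  post_pos <- fit$z[, pos_comp]
  data.frame(status = ifelse(post_pos >= 0.5, "A+", "A-"),
             posterior_prob = post_pos,
             pathway = "PET-GMM", pc1 = pc1)
}

#' Amyloid status from the CSF Ab42/40 ratio
#'
#' Deterministic cutoff rule: amyloid positive when the cerebrospinal
#' fluid amyloid-beta 42/40 ratio is at or below 0.077 (the boundary is
#' inclusive).
#'
#' @param ratio Numeric vector of Ab42/40 ratios; non-positive or missing
#'   values yield NA calls.
#' @param cutoff Positivity cutoff (default 0.077).
#' @return Data frame with `status`, `posterior_prob` (1 for determined
#'   calls, NA otherwise), `pathway` ("CSF-cutoff").
#' @export
csf_classify <- function(ratio, cutoff = 0.077) {
  ok <- is.finite(ratio) & ratio > 0
  status <- ifelse(!ok, NA_character_,
                   ifelse(ratio <= cutoff, "A+", "A-"))
  data.frame(status = status,
             posterior_prob = ifelse(ok, 1.0, NA_real_),
             pathway = "CSF-cutoff")
}
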