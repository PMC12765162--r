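#' Fit configuration
#'
#' Bounds, multistart grid and convergence settings for the voxelwise
#' nonlinear least-squares fit. Defaults: CBF in [0, 300] mL/100 g/min,
#' arterial arrival in [100, 3000] ms, arterial residence in [50, 2000] ms,
#' exchange time in [10, 5000] ms; multistart over total transit times
#' {500, 1000, 1500, 2000} ms crossed with exchange times {100, 400, 1600}
#' ms.
#'
#' @param lower,upper Named numeric vectors with elements `cbf`, `att_a`,
#'   `t_a`, `tex`.
#' @param att_grid Multistart values for total arterial transit time
#'   (split 60/40 between arrival and residence), ms.
#' @param tex_grid Multistart values for the exchange time, ms.
#' @param reltol Convergence tolerance passed to the optimizer.
#' @param seed Integer seed recorded in outputs (the fit itself is
#'   deterministic).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(lower = c(cbf = 0, att_a = 100, t_a = 50, tex = 10),
                       upper = c(cbf = 300, att_a = 3000, t_a = 2000, tex = 5000),
                       att_grid = c(500, 1000, 1500, 2000),
                       tex_grid = c(100, 400, 1600),
                       reltol = 2e-13, seed = 1L) {
  nm <- c("cbf", "att_a", "t_a", "tex")
  stopifnot(all(nm %in% names(lower)), all(nm %in% names(upper)))
  if (any(lower[nm] >= upper[nm])) stop("each lower bound must be < upper")
  structure(list(lower = lower[nm], upper = upper[nm],
                 att_grid = att_grid, tex_grid = tex_grid,
                 reltol = reltol, seed = as.integer(seed)),
            class = "fit_config")
}

# Model prediction stacked in the order the data vector uses:
# HAD8-A dM (PLD increasing), HAD8-B dM, then HAD4 dM by TE within PLD.
.predict_joint <- function(theta, protocols, c) {
  p <- voxel_params(theta[1], theta[2], theta[3], theta[4])
  unlist(lapply(protocols, function(pr) {
    dm <- multi_te_signal(p, c, pr$subboluses, pr$tes)
    # chronological sub-boluses have decreasing PLD; emit increasing PLD
    as.vector(t(dm[rev(seq_len(nrow(dm))), , drop = FALSE]))
  }), use.names = FALSE)
}

#' Fit one voxel from concatenated decoded data
#'
#' Joint bounded nonlinear least squares over the concatenated decoded
#' difference signals of the two single-echo HAD8 measurements and the
#' multi-echo HAD4 measurement (38 samples for the stock protocols).
#' Minimizes the residual sum of squares over (CBF, arterial arrival,
#' arterial residence, exchange time) with `optim(method = "L-BFGS-B")`,
#' multi-started over the configured (transit, exchange) grid. Ties are
#' broken by lowest RSS, then smallest exchange time.
#'
#' @param dm_had8 Numeric vector of difference signals at the HAD8 echo
#'   time, ordered by increasing PLD across both PLD sets (set A then set B
#'   when using [concat_decoded()] output the order is by PLD overall;
#'   pass the matching `protocols`).
#' @param dm_had4 Matrix (PLD x TE) of HAD4 difference signals, PLDs
#'   increasing.
#' @param protocols List of the protocols that produced the data, HAD8
#'   entries first, e.g. `list(protocol_had8("A"), protocol_had8("B"),
#'   protocol_had4())`.
#' @param c A [tissue_constants()].
#' @param cfg A [fit_config()].
#' @return List with `params` ([voxel_params()]), `rss`, `converged`, and
#'   `n_obs`.
#' @export
fit_voxel <- function(dm_had8, dm_had4, protocols,
                      c = tissue_constants(), cfg = fit_config()) {
  had8 <- Filter(function(p) p$had_order == 8, protocols)
  had4 <- Filter(function(p) p$had_order == 4, protocols)
  n8 <- sum(vapply(had8, function(p) length(p$plds), integer(1)))
  if (length(dm_had8) != n8)
    stop("dm_had8 has ", length(dm_had8), " samples; protocols imply ", n8)

  # Observation vector in .predict_joint order: per-protocol blocks of
  # increasing PLD, HAD8 first, then HAD4 rows by TE within PLD.
  y8 <- dm_had8
  y <- c(y8, if (length(had4)) as.vector(t(dm_had4)) else numeric(0))

  if (all(abs(y) < .Machine$double.eps * 10)) {
    return(list(params = voxel_params(0, cfg$lower["att_a"], cfg$lower["t_a"],
                                      cfg$lower["tex"]),
                rss = 0, converged = FALSE, n_obs = length(y)))
  }

  lo <- cfg$lower; hi <- cfg$upper
  # Bounded Levenberg-Marquardt on the residual vector, in scaled
  # coordinates (signals x 1e3, parameters / typical magnitudes) so the
  # finite-difference Jacobian is well conditioned on the flat
  # (t_a, tex) valley of this model.
  sc <- c(50, 500, 500, 500)
  ys <- y * 1e3
  resid_fn <- function(xs) .predict_joint(xs * sc, protocols, c) * 1e3 - ys

  # cbf start from the peak HAD8 signal scale (rough linear calibration)
  cbf0 <- min(max(max(y8) / 6e-5, 5), hi["cbf"] - 1)
  starts <- expand.grid(att = cfg$att_grid, tex = cfg$tex_grid)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    att0 <- starts$att[i]
    th0 <- c(cbf = cbf0,
             att_a = min(max(0.6 * att0, lo["att_a"] + 1), hi["att_a"] - 1),
             t_a = min(max(0.4 * att0, lo["t_a"] + 1), hi["t_a"] - 1),
             tex = min(max(starts$tex[i], lo["tex"] + 1), hi["tex"] - 1))
    fit <- tryCatch(
      minpack.lm::nls.lm(th0 / sc, lower = (lo + 1e-9) / sc,
                         upper = hi / sc, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = cfg$reltol, ptol = 1e-14, maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cand <- list(theta = fit$par * sc, rss = sum(fit$fvec^2) / 1e6,
                 ok = fit$info %in% 1:3)
    if (is.null(best) || cand$rss < best$rss * (1 - 1e-9) - 1e-24 ||
        (abs(cand$rss - best$rss) <= 1e-9 * best$rss + 1e-24 &&
         cand$theta[4] < best$theta[4]))
      best <- cand
    # noiseless data: an exact fit ends the multistart early
    if (best$rss < 1e-17) break
  }
  if (is.null(best)) {
    return(list(params = NULL, rss = Inf, converged = FALSE,
                n_obs = length(y),
                diagnostics = "all multistart optimizations failed"))
  }

  # The chain's observables (vascular sum, extravascular) are invariant
  # under exchanging the capillary residence and exchange times, so every
  # fit has a mirror solution with t_a and tex swapped. Apply the
  # tie-break (equal RSS -> smallest tex) by canonicalizing to the
  # in-bounds labelling with the smaller exchange time.
  th <- best$theta
  swapped <- th[c(1, 2, 4, 3)]
  names(swapped) <- names(th)
  if (swapped[4] < th[4] &&
      swapped[3] >= lo["t_a"] && swapped[3] <= hi["t_a"] &&
      swapped[4] >= lo["tex"] && swapped[4] <= hi["tex"])
    th <- swapped

  list(params = voxel_params(th[1], th[2], th[3], th[4]),
       rss = best$rss, converged = isTRUE(best$ok), n_obs = length(y))
}

#' Fit a whole volume
#'
#' Applies [fit_voxel()] to every voxel inside the gray-matter mask of a
#' decoded HAD8 + HAD4 acquisition pair and assembles parameter maps.
#' Voxels outside the mask are NaN-coded; non-converged voxels are flagged
#' in `converged_mask`, never silently filled.
#'
#' @param decoded8 List of two single-TE `decoded_series` (PLD sets A, B).
#' @param decoded4 Multi-echo `decoded_series` (HAD4).
#' @param gm_mask Logical or 0/1 3D array; voxel count must match the
#'   decoded data's voxel axis (column-major flattening).
#' @param c A [tissue_constants()].
#' @param cfg A [fit_config()].
#' @return An object of class `parameter_map` with `cbf_map`, `att_map`
#'   (arrival + residence), `tex_map`, `rss_map` 3D arrays and
#'   `converged_mask`.
#' @export
fit_volume <- function(decoded8, decoded4, gm_mask,
                       c = tissue_constants(), cfg = fit_config()) {
  mask <- gm_mask > 0
  if (!any(mask)) stop("empty gray-matter mask")
  dims <- dim(mask)
  nv <- prod(dims)
  if (dim(decoded4$dm)[3] != nv)
    stop("decoded data voxel axis does not match mask grid")
  protocols <- c(lapply(decoded8, function(d) d$protocol),
                 list(decoded4$protocol))

  shape <- function() array(NA_real_, dim = dims)
  cbf_map <- shape(); att_map <- shape(); tex_map <- shape(); rss_map <- shape()
  conv <- array(FALSE, dim = dims)

  for (v in which(mask)) {
    dm8 <- unlist(lapply(decoded8, function(d)
      rev(d$dm[, 1, v])))                       # increasing PLD per protocol
    dm4 <- matrix(decoded4$dm[rev(seq_len(dim(decoded4$dm)[1])), , v],
                  nrow = dim(decoded4$dm)[1])   # increasing PLD x TE
    f <- fit_voxel(dm8, dm4, protocols, c, cfg)
    if (!is.null(f$params)) {
      cbf_map[v] <- f$params$cbf
      att_map[v] <- f$params$att
      tex_map[v] <- f$params$tex
    }
    rss_map[v] <- f$rss
    conv[v] <- f$converged
  }
  structure(list(cbf_map = cbf_map, att_map = att_map, tex_map = tex_map,
                 rss_map = rss_map, converged_mask = conv,
                 gm_mask = mask, seed = cfg$seed),
            class = "parameter_map")
}

#' Spatial coefficient of variation QC
#'
#' Computes the spatial coefficient of variation (population standard
#' deviation over mean) of a CBF map within the gray-matter mask, the
#' standard automated quality gate for ASL: maps with sCoV above the
#' threshold (default 0.8) have too little tissue contrast and are
#' excluded.
#'
#' @param cbf_map 3D numeric array (NaN allowed, excluded).
#' @param gm_mask Logical or 0/1 array of the same shape.
#' @param threshold Pass/fail threshold on sCoV (default 0.8).
#' @return List with `scov`, `pass`, `threshold`, and `warning_code`
#'   (`"nonpositive_mean"` when the GM mean is <= 0, else NA).
#' @export
compute_scov <- function(cbf_map, gm_mask, threshold = 0.8) {
  mask <- gm_mask > 0
  if (!any(mask)) stop("empty gray-matter mask")
  x <- cbf_map[mask]
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite CBF values inside the mask")
  m <- mean(x)
  if (m <= 0) {
    warning("non-positive mean CBF inside mask; QC fails")
    return(list(scov = Inf, pass = FALSE, threshold = threshold,
                warning_code = "nonpositive_mean"))
  }
  sd_pop <- sqrt(mean((x - m)^2))
  scov <- sd_pop / m
  list(scov = scov, pass = scov <= threshold, threshold = threshold,
       warning_code = NA_character_)
}
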