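#' Sylvester Hadamard matrix
#'
#' Builds the order-2, -4 or -8 Hadamard matrix by the Sylvester doubling
#' construction. Rows index acquisitions of a time-encoded ASL train,
#' columns 2..N index sub-boluses; an entry of -1 means the sub-bolus is
#' labeled in that acquisition.
#'
#' @param order Matrix order, one of 2, 4, 8.
#' @return An `order` x `order` matrix of +1/-1 with all-ones first row and
#'   column, satisfying `H %*% t(H) == order * I`.
#' @export
build_hadamard <- function(order) {
  if (!order %in% c(2, 4, 8)) stop("unsupported Hadamard order: ", order)
  h <- matrix(1, 1, 1)
  while (nrow(h) < order) h <- rbind(cbind(h, h), cbind(h, -h))
  h
}

#' Time-encoded ASL protocol
#'
#' Describes one Hadamard time-encoded pCASL acquisition: the Hadamard
#' order, the chronological sub-bolus schedule (durations and PLDs), the
#' echo times, TR and number of averages. Sub-boluses are stored in
#' chronological order, so their PLDs are strictly decreasing (the first
#' labeled block has the longest delay to readout).
#'
#' @param name Protocol label, e.g. "HAD8-A".
#' @param had_order Hadamard matrix order (4 or 8); the schedule has
#'   `had_order - 1` sub-boluses.
#' @param plds Numeric vector of post-labeling delays, ms, one per
#'   sub-bolus (any order; sorted decreasing internally).
#' @param sbd Sub-bolus duration, ms (one value, shared).
#' @param tes Numeric vector of echo times, ms, increasing.
#' @param tr Repetition time, ms.
#' @param repeats Number of averages.
#' @return An object of class `asl_protocol`.
#' @export
asl_protocol <- function(name, had_order, plds, sbd, tes,
                         tr = NA_real_, repeats = 1L) {
  if (!had_order %in% c(4, 8)) stop("had_order must be 4 or 8")
  if (length(plds) != had_order - 1)
    stop("need ", had_order - 1, " PLDs for a HAD", had_order, " protocol")
  if (length(tes) == 0 || is.unsorted(tes, strictly = TRUE))
    stop("tes must be non-empty and strictly increasing")
  plds <- sort(plds, decreasing = TRUE)
  subboluses <- lapply(plds, function(pld) sub_bolus(sbd, pld))
  structure(list(name = name, had_order = had_order,
                 subboluses = subboluses, plds = plds, sbd = sbd,
                 tes = tes, tr = tr, repeats = repeats),
            class = "asl_protocol")
}

#' Stock protocols
#'
#' The two single-echo Hadamard-8 measurements (PLD sets A and B, sub-bolus
#' duration 400 ms, TE 13.4 ms) used for CBF/ATT estimation, and the
#' multi-echo Hadamard-4 protocol (PLDs 500/1500/2500 ms, sub-bolus
#' duration 1000 ms, eight echoes 14 to 210 ms in steps of 28 ms) used for
#' water-exchange estimation.
#'
#' @param set For HAD8, PLD set "A" (600..3000 ms) or "B" (800..3200 ms).
#' @return An [asl_protocol()] object.
#' @export
protocol_had8 <- function(set = c("A", "B")) {
  set <- match.arg(set)
  plds <- if (set == "A") seq(600, 3000, by = 400) else seq(800, 3200, by = 400)
  asl_protocol(paste0("HAD8-", set), 8L, plds, sbd = 400,
               tes = 13.4, tr = 4190, repeats = 1L)
}

#' @rdname protocol_had8
#' @export
protocol_had4 <- function() {
  asl_protocol("HAD4", 4L, plds = c(500, 1500, 2500), sbd = 1000,
               tes = seq(14, 210, by = 28), tr = 4670, repeats = 2L)
}

# Label-selection matrix: s[i, k] = 1 when sub-bolus k is labeled in
# acquisition row i (Hadamard entry -1), using columns 2..N chronologically.
.label_select <- function(had_order) {
  h <- build_hadamard(had_order)
  (1 - h[, -1, drop = FALSE]) / 2
}

#' Simulate an encoded acquisition
#'
#' Evaluates the forward model for every sub-bolus of a protocol and
#' composes the Hadamard-encoded acquisition: row i, echo j, voxel v is the
#' static tissue signal `baseline_v * exp(-TE_j / T2t)` minus the summed
#' difference signals of the sub-boluses labeled in row i (labeling
#' subtracts magnetization). Optional i.i.d. Gaussian noise is added per
#' array element.
#'
#' @param truth A single [voxel_params()] object or a list of them (one per
#'   voxel).
#' @param protocol An [asl_protocol()].
#' @param c A [tissue_constants()].
#' @param baseline Numeric vector of per-voxel static signal (relative M0).
#' @param noise_sd Gaussian noise standard deviation (same units as the
#'   signal fractions); 0 for noiseless.
#' @param seed Integer seed; required when `noise_sd > 0`.
#' @return An object of class `encoded_series` with `data` (array
#'   row x TE x voxel), `baseline`, `protocol`, `noise_sd`.
#' @export
encode_series <- function(truth, protocol, c = tissue_constants(),
                          baseline = 1, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (inherits(truth, "voxel_params")) truth <- list(truth)
  nv <- length(truth)
  baseline <- rep_len(baseline, nv)
  if (noise_sd > 0 && is.null(seed))
    stop("seed is required when noise_sd > 0")

  n_row <- protocol$had_order
  tes <- protocol$tes
  sel <- .label_select(n_row)                       # row x sub-bolus
  dat <- array(0, dim = c(n_row, length(tes), nv))
  base_decay <- exp(-tes / c$T2t)
  for (v in seq_len(nv)) {
    dm <- multi_te_signal(truth[[v]], c, protocol$subboluses, tes)
    dat[, , v] <- matrix(baseline[v] * base_decay, n_row, length(tes),
                         byrow = TRUE) - sel %*% dm
  }
  if (noise_sd > 0) {
    set.seed(seed)
    dat <- dat + array(stats::rnorm(length(dat), 0, noise_sd), dim = dim(dat))
  }
  structure(list(data = dat, baseline = baseline, protocol = protocol,
                 noise_sd = noise_sd, seed = seed),
            class = "encoded_series")
}

#' Decode an encoded acquisition
#'
#' Recovers the per-sub-bolus difference signals by exact inversion of the
#' encoding design. For each echo and voxel the acquisition rows satisfy
#' `E = [1 | -S] (b_te, dM_1 .. dM_{N-1})` where S is the 0/1 label
#' selection derived from the Hadamard matrix and `b_te` the static signal
#' at that echo; the design is invertible by Hadamard orthogonality.
#'
#' @param e An `encoded_series` (or a compatible list with `data` and
#'   `protocol`).
#' @param c A [tissue_constants()], used only to refer the recovered static
#'   signal back to TE = 0 via tissue T2.
#' @return An object of class `decoded_series` with `dm` (array
#'   sub-bolus x TE x voxel), `baseline_te` (TE x voxel static signal),
#'   `baseline_hat` (per-voxel static signal at TE = 0), `protocol`.
#' @export
decode_series <- function(e, c = tissue_constants()) {
  protocol <- e$protocol
  n_row <- protocol$had_order
  dat <- e$data
  if (length(dim(dat)) != 3 || dim(dat)[1] != n_row ||
      dim(dat)[2] != length(protocol$tes))
    stop("encoded data shape does not match protocol")
  nv <- dim(dat)[3]
  n_te <- dim(dat)[2]

  design <- cbind(1, -.label_select(n_row))         # N x N, invertible
  dinv <- solve(design)

  flat <- matrix(dat, nrow = n_row)                 # rows x (TE * voxel)
  sol <- dinv %*% flat
  baseline_te <- matrix(sol[1, ], n_te, nv)
  dm <- array(sol[-1, ], dim = c(n_row - 1, n_te, nv))
  baseline_hat <- colMeans(baseline_te * exp(outer(protocol$tes, rep(1, nv)) / c$T2t))
  structure(list(dm = dm, baseline_te = baseline_te,
                 baseline_hat = baseline_hat, protocol = protocol),
            class = "decoded_series")
}

#' Concatenate decoded HAD8 measurements into one PLD series
#'
#' Merges the sub-bolus difference signals of several decoded series
#' acquired at a single shared TE (the two HAD8 PLD sets) into one series
#' ordered by increasing PLD.
#'
#' @param ... `decoded_series` objects with single-TE protocols.
#' @return List with `pld` (sorted increasing), `dm` (PLD x voxel matrix).
#' @export
concat_decoded <- function(...) {
  parts <- list(...)
  plds <- unlist(lapply(parts, function(d) d$protocol$plds))
  dm <- do.call(rbind, lapply(parts, function(d) {
    if (dim(d$dm)[2] != 1) stop("concat_decoded expects single-TE series")
    matrix(d$dm[, 1, ], nrow = dim(d$dm)[1])
  }))
  ord <- order(plds)
  list(pld = plds[ord], dm = dm[ord, , drop = FALSE])
}
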