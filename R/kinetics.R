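#' Tissue and blood relaxation constants
#'
#' Container for the literature-based relaxation values and scaling factors
#' used throughout the forward model and the voxelwise fit. Defaults follow
#' the values commonly used for multi-echo ASL exchange modelling at 3T:
#' T2 of blood 165 ms, T2 of tissue 85 ms, T1 of blood 1650 ms, T1 of
#' tissue 1300 ms.
#'
#' @param T1b Longitudinal relaxation time of arterial blood, ms.
#' @param T1t Longitudinal relaxation time of tissue, ms.
#' @param T2b Transverse relaxation time of blood, ms.
#' @param T2t Transverse relaxation time of tissue, ms.
#' @param alpha Combined labeling and background-suppression efficiency,
#'   dimensionless, in (0, 1]. Default 0.72 (0.85 labeling efficiency times
#'   two background-suppression pulses, about 0.85^2).
#' @param lambda_bp Blood-brain partition coefficient, mL/g. Default 0.9.
#' @return An object of class `tissue_constants`.
#' @export
tissue_constants <- function(T1b = 1650, T1t = 1300, T2b = 165, T2t = 85,
                             alpha = 0.72, lambda_bp = 0.9) {
  vals <- c(T1b = T1b, T1t = T1t, T2b = T2b, T2t = T2t,
            alpha = alpha, lambda_bp = lambda_bp)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all tissue constants must be finite and strictly positive")
  if (alpha > 1) stop("alpha must be in (0, 1]")
  structure(as.list(vals), class = "tissue_constants")
}

#' Voxel kinetic parameters
#'
#' Ground-truth or estimated kinetic parameters of one voxel. The arterial
#' arrival time `att_a` is the delay from the labeling plane to the voxel's
#' arterial compartment; `t_a` is the mean residence time in that arterial
#' compartment, so labeled water reaches the capillary exchange site at
#' `att_a + t_a` on average, which is reported as the arterial transit time
#' (ATT). `tex` is the mean residence time of water in the capillary
#' compartment before it crosses the blood-brain barrier.
#'
#' @param cbf Perfusion, mL/100 g/min. Must be >= 0.
#' @param att_a Arterial arrival time, ms. Must be >= 0.
#' @param t_a Arterial compartment residence time, ms. Must be > 0.
#' @param tex Water exchange time, ms. Must be > 0.
#' @return An object of class `voxel_params` with an `att` field equal to
#'   `att_a + t_a`.
#' @export
voxel_params <- function(cbf, att_a, t_a, tex) {
  if (!is.finite(cbf) || cbf < 0) stop("cbf must be finite and >= 0")
  if (!is.finite(att_a) || att_a < 0) stop("att_a must be finite and >= 0")
  if (!is.finite(t_a) || t_a <= 0) stop("t_a must be finite and > 0")
  if (!is.finite(tex) || tex <= 0) stop("tex must be finite and > 0")
  structure(list(cbf = unname(cbf), att_a = unname(att_a),
                 t_a = unname(t_a), tex = unname(tex),
                 att = unname(att_a + t_a)),
            class = "voxel_params")
}

#' One sub-bolus of a time-encoded labeling train
#'
#' @param duration Label duration tau, ms (> 0).
#' @param pld Post-labeling delay from the end of this sub-bolus to readout,
#'   ms (>= 0).
#' @return An object of class `sub_bolus`.
#' @export
sub_bolus <- function(duration, pld) {
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.finite(pld) || pld < 0) stop("pld must be >= 0")
  structure(list(duration = duration, pld = pld), class = "sub_bolus")
}

# CBF unit conversion lives here and nowhere else:
# mL/100 g/min -> mL/g/ms (i.e. per-ms delivery once divided by lambda).
cbf_per_ms <- function(cbf) cbf / (100 * 60 * 1000)

# E(k) = int_a^b exp(-k (T - s)) ds = (exp(-k (T-b)) - exp(-k (T-a))) / k
# for the boxcar delivery window [a, b] ending before readout time T.
.boxcar_exp <- function(k, T, a, b) {
  (exp(-k * (T - b)) - exp(-k * (T - a))) / k
}

#' Compartment magnetizations for one sub-bolus
#'
#' Solves the three-compartment linear chain (arterial blood -> capillary
#' intravascular water -> extravascular tissue water) for a single labeled
#' sub-bolus and returns the labeled magnetization of each compartment at
#' the readout instant, as fractions of the equilibrium voxel
#' magnetization M0. Delivery into the arterial compartment is a boxcar of
#' height `A = 2 alpha f exp(-att_a / T1b) / lambda_bp` (with `f` the
#' perfusion in per-ms units) lasting the label duration, delayed by
#' `att_a`; the chain decays with rates `1/T1b + 1/t_a` (arterial),
#' `1/T1b + 1/tex` (capillary) and `1/T1t` (extravascular). The solution is
#' the exact piecewise-exponential convolution of the boxcar input with the
#' chain's impulse response.
#'
#' @param p A [voxel_params()] object.
#' @param c A [tissue_constants()] object.
#' @param sb A [sub_bolus()] object (all times in ms).
#' @return A list with `m_art`, `m_iv`, `m_ev` (fractions of M0).
#' @export
compartment_signals <- function(p, c = tissue_constants(), sb) {
  stopifnot(inherits(p, "voxel_params"), inherits(c, "tissue_constants"),
            inherits(sb, "sub_bolus"))
  m <- .compartments_vec(p, c, durations = sb$duration, plds = sb$pld)
  list(m_art = unname(m[1, 1]), m_iv = unname(m[2, 1]),
       m_ev = unname(m[3, 1]))
}

# Vectorized core: one column per sub-bolus. Times from label onset;
# readout at T = duration + pld; delivery active on [att_a, att_a + tau],
# clipped to [0, T].
.compartments_vec <- function(p, c, durations, plds) {
  n <- length(durations)
  out <- matrix(0, nrow = 3, ncol = n,
                dimnames = list(c("m_art", "m_iv", "m_ev"), NULL))
  if (p$cbf == 0) return(out)

  k1 <- 1 / c$T1b + 1 / p$t_a
  k2 <- 1 / c$T1b + 1 / p$tex
  k3 <- 1 / c$T1t
  # Degenerate partial fractions when two chain rates coincide: nudge the
  # capillary rate by a relative epsilon (error O(1e-9), far below fit noise).
  eps <- 1e-9
  if (abs(k1 - k2) < eps * k1) k2 <- k2 * (1 + 1e-7)
  if (abs(k2 - k3) < eps * k2) k2 <- k2 * (1 + 1e-7)
  if (abs(k1 - k3) < eps * k1) k1 <- k1 * (1 + 1e-7)

  A <- 2 * c$alpha * cbf_per_ms(p$cbf) * exp(-p$att_a / c$T1b) / c$lambda_bp

  T_read <- durations + plds
  a <- pmin(pmax(p$att_a, 0), T_read)
  b <- pmin(p$att_a + durations, T_read)
  live <- b > a
  if (!any(live)) return(out)
  Tl <- T_read[live]; al <- a[live]; bl <- b[live]

  E1 <- .boxcar_exp(k1, Tl, al, bl)
  E2 <- .boxcar_exp(k2, Tl, al, bl)
  E3 <- .boxcar_exp(k3, Tl, al, bl)

  c1 <- 1 / ((k2 - k1) * (k3 - k1))
  c2 <- 1 / ((k1 - k2) * (k3 - k2))
  c3 <- 1 / ((k1 - k3) * (k2 - k3))

  m_art <- A * E1
  m_iv  <- A / (p$t_a * (k2 - k1)) * (E1 - E2)
  m_ev  <- A / (p$t_a * p$tex) * (c1 * E1 + c2 * E2 + c3 * E3)

  out[1, live] <- m_art
  out[2, live] <- pmax(m_iv, 0)
  out[3, live] <- pmax(m_ev, 0)
  out
}

#' Multi-echo difference signal for a sub-bolus schedule
#'
#' Applies transverse (T2) decay to the compartment magnetizations of each
#' sub-bolus: arterial and capillary water decay with blood T2, exchanged
#' extravascular water with tissue T2. Entry (k, j) is the difference
#' signal of sub-bolus k at echo time j,
#' `(m_art + m_iv) exp(-TE/T2b) + m_ev exp(-TE/T2t)`.
#'
#' @param p A [voxel_params()] object.
#' @param c A [tissue_constants()] object.
#' @param schedule List of [sub_bolus()] objects.
#' @param tes Numeric vector of echo times, ms (all >= 0).
#' @return Matrix (sub-bolus x TE) of signal fractions of M0.
#' @export
multi_te_signal <- function(p, c = tissue_constants(), schedule, tes) {
  if (length(schedule) == 0) stop("schedule must be non-empty")
  if (length(tes) == 0) stop("tes must be non-empty")
  if (any(tes < 0)) stop("negative TE")
  durations <- vapply(schedule, function(s) s$duration, numeric(1))
  plds <- vapply(schedule, function(s) s$pld, numeric(1))
  m <- .compartments_vec(p, c, durations, plds)
  vasc <- m["m_art", ] + m["m_iv", ]
  tiss <- m["m_ev", ]
  outer(vasc, exp(-tes / c$T2b)) + outer(tiss, exp(-tes / c$T2t))
}

#' Vascular/tissue decomposition of the multi-echo signal
#'
#' Same evaluation as [multi_te_signal()] but keeping the vascular
#' (arterial + capillary, blood T2) and tissue (extravascular, tissue T2)
#' contributions separate, for plotting modeled decay curves.
#'
#' @inheritParams multi_te_signal
#' @return List of two (sub-bolus x TE) matrices, `vascular` and `tissue`.
#' @export
multi_te_components <- function(p, c = tissue_constants(), schedule, tes) {
  if (any(tes < 0)) stop("negative TE")
  durations <- vapply(schedule, function(s) s$duration, numeric(1))
  plds <- vapply(schedule, function(s) s$pld, numeric(1))
  m <- .compartments_vec(p, c, durations, plds)
  list(vascular = outer(m["m_art", ] + m["m_iv", ], exp(-tes / c$T2b)),
       tissue = outer(m["m_ev", ], exp(-tes / c$T2t)))
}
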