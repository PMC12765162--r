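test_that("zero perfusion and no-exchange limits behave physically", {
  cc <- tissue_constants()
  sb <- sub_bolus(1000, 1500)

  z <- compartment_signals(voxel_params(0, 700, 500, 200), cc, sb)
  expect_identical(unlist(z), c(m_art = 0, m_iv = 0, m_ev = 0))

  # label never crosses the barrier when the exchange time diverges
  frozen <- compartment_signals(voxel_params(60, 700, 500, 1e9), cc, sb)
  expect_lt(frozen$m_ev, 1e-6 * (frozen$m_art + frozen$m_iv))
})

test_that("closed form matches the stiff-ODE oracle at the reference voxel", {
  cc <- tissue_constants()
  p <- voxel_params(60, 700, 500, 200)
  sb <- sub_bolus(1000, 1500)
  cf <- unlist(compartment_signals(p, cc, sb))
  # frozen from the deSolve oracle (rtol 1e-12) run before the main build
  expect_equal(unname(cf),
               c(4.625347e-04, 2.943676e-04, 3.6173576e-03),
               tolerance = 1e-6)
  or <- ode_compartments(p, cc, sb)
  expect_lt(max(abs(cf - or) / pmax(abs(or), 1e-12)), 1e-6)
})

test_that("signal is linear in perfusion and monotone in exchange time", {
  cc <- tissue_constants()
  sb <- sub_bolus(400, 1800)
  set.seed(11)
  for (i in 1:5) {
    att_a <- runif(1, 200, 1500); t_a <- runif(1, 100, 1200)
    tex <- runif(1, 50, 2000); cbf <- runif(1, 10, 100)
    s1 <- unlist(compartment_signals(voxel_params(cbf, att_a, t_a, tex), cc, sb))
    s2 <- unlist(compartment_signals(voxel_params(2 * cbf, att_a, t_a, tex), cc, sb))
    expect_equal(s2, 2 * s1, tolerance = 1e-12)
  }
  # m_ev at readout non-increasing in tex, fixed delivery
  texs <- c(50, 100, 200, 400, 800, 1600, 3200)
  mev <- vapply(texs, function(tx)
    compartment_signals(voxel_params(60, 700, 500, tx), cc, sb)$m_ev,
    numeric(1))
  expect_true(all(diff(mev) <= 1e-15))
})

test_that("total label respects the slowest-T1 decay bound", {
  cc <- tissue_constants()
  set.seed(12)
  for (i in 1:10) {
    p <- voxel_params(runif(1, 10, 100), runif(1, 200, 2000),
                      runif(1, 100, 1500), runif(1, 50, 2000))
    sb <- sub_bolus(runif(1, 200, 1500), runif(1, 0, 2500))
    s <- compartment_signals(p, cc, sb)
    T_read <- sb$duration + sb$pld
    a <- min(p$att_a, T_read); b <- min(p$att_a + sb$duration, T_read)
    if (b <= a) next
    A <- 2 * cc$alpha * (p$cbf / 6e6) * exp(-p$att_a / cc$T1b) / cc$lambda_bp
    bound <- A * (b - a) * exp(-(T_read - b) / max(cc$T1b, cc$T1t))
    expect_lte(s$m_art + s$m_iv + s$m_ev, bound * (1 + 1e-12))
  }
})

test_that("multi-echo signal decays by compartment T2", {
  cc <- tissue_constants()
  p <- voxel_params(60, 700, 500, 200)
  sched <- protocol_had4()$subboluses
  tes <- protocol_had4()$tes

  # TE = 0 returns the raw compartment sums
  s0 <- multi_te_signal(p, cc, sched, 0)
  m <- t(vapply(sched, function(sb) unlist(compartment_signals(p, cc, sb)),
                numeric(3)))
  expect_equal(as.vector(s0), unname(rowSums(m)), tolerance = 1e-12)

  # instantaneous exchange + late readout: pure tissue decay slope -1/T2t
  fast <- voxel_params(60, 300, 100, 1e-2)
  sig <- multi_te_signal(fast, cc, list(sub_bolus(400, 2500)), tes)
  slope <- coef(lm(log(as.vector(sig)) ~ tes))[2]
  expect_equal(unname(slope), -1 / cc$T2t, tolerance = 1e-3)

  # decomposition: both components decay monotonically over the 8 echoes
  # and the vascular fraction shrinks as PLD grows
  comp <- multi_te_components(p, cc, sched, tes)
  expect_true(all(apply(comp$vascular, 1, function(r) all(diff(r) < 0))))
  expect_true(all(apply(comp$tissue, 1, function(r) all(diff(r) < 0))))
  vfrac <- comp$vascular[, 1] / (comp$vascular[, 1] + comp$tissue[, 1])
  # rows are chronological, i.e. decreasing PLD -> fraction increases
  expect_true(all(diff(vfrac) > 0))
})

test_that("invalid kinetic inputs are rejected", {
  expect_error(voxel_params(60, 700, -1, 200), "t_a")
  expect_error(voxel_params(60, 700, 500, 0), "tex")
  expect_error(voxel_params(-5, 700, 500, 200), "cbf")
  expect_error(sub_bolus(0, 100), "duration")
  p <- voxel_params(60, 700, 500, 200)
  expect_error(multi_te_signal(p, tissue_constants(), list(sub_bolus(400, 600)),
                               c(14, -5)), "negative TE")
  expect_error(tissue_constants(T2b = -1))
  expect_error(tissue_constants(alpha = 1.5))
})
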