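test_that("Sylvester construction yields orthogonal Hadamard matrices", {
  expect_identical(build_hadamard(2), matrix(c(1, 1, 1, -1), 2, byrow = TRUE))
  h4 <- build_hadamard(4)
  expect_equal(h4 %*% t(h4), 4 * diag(4))
  h8 <- build_hadamard(8)
  # brute force over all 28 distinct column pairs
  for (i in 1:7) for (j in (i + 1):8)
    expect_identical(sum(h8[, i] * h8[, j]), 0)
  expect_true(all(h8[, 1] == 1))
  expect_error(build_hadamard(6), "unsupported")
})

test_that("protocols carry the published timing", {
  pa <- protocol_had8("A"); pb <- protocol_had8("B"); p4 <- protocol_had4()
  expect_equal(sort(pa$plds), seq(600, 3000, by = 400))
  expect_equal(sort(pb$plds), seq(800, 3200, by = 400))
  expect_equal(pa$sbd, 400)
  expect_equal(pa$tes, 13.4)
  expect_equal(p4$plds, c(2500, 1500, 500))
  expect_equal(p4$sbd, 1000)
  expect_equal(p4$tes, seq(14, 210, by = 28))
  # PLDs strictly decreasing chronologically, step = sub-bolus duration
  expect_true(all(diff(pa$plds) == -400))
  expect_true(all(diff(p4$plds) == -1000))
})

test_that("encode/decode is the exact identity on noiseless data", {
  cc <- tissue_constants()
  voxels <- list(voxel_params(60, 700, 500, 200),
                 voxel_params(30, 1200, 300, 800),
                 voxel_params(90, 400, 900, 120))
  for (proto in list(protocol_had8("A"), protocol_had4())) {
    e <- encode_series(voxels, proto, cc, baseline = c(1, 0.9, 1.1))
    d <- decode_series(e, cc)
    for (v in seq_along(voxels)) {
      dm_true <- multi_te_signal(voxels[[v]], cc, proto$subboluses, proto$tes)
      expect_lt(max(abs(d$dm[, , v] - dm_true)), 1e-12)
    }
    expect_equal(d$baseline_hat, c(1, 0.9, 1.1), tolerance = 1e-10)
  }
})

test_that("zero perfusion leaves only the static decay term", {
  cc <- tissue_constants()
  proto <- protocol_had4()
  e <- encode_series(voxel_params(0, 700, 500, 200), proto, cc, baseline = 1)
  for (i in seq_len(proto$had_order))
    expect_equal(e$data[i, , 1], exp(-proto$tes / cc$T2t), tolerance = 1e-14)
  # all-zero input decodes to all zeros
  e$data[] <- 0
  d <- decode_series(e, cc)
  expect_true(all(d$dm == 0) && all(d$baseline_te == 0))
})

test_that("decoded sub-boluses match the forward model at their own PLDs", {
  cc <- tissue_constants()
  p <- voxel_params(55, 800, 400, 300)
  proto <- protocol_had8("A")
  d <- decode_series(encode_series(p, proto, cc), cc)
  for (k in seq_along(proto$plds)) {
    single <- multi_te_signal(p, cc, list(sub_bolus(proto$sbd, proto$plds[k])),
                              proto$tes)
    expect_equal(d$dm[k, , 1], as.vector(single), tolerance = 1e-12)
  }
})

test_that("the two HAD8 measurements concatenate to 14 distinct PLDs", {
  cc <- tissue_constants()
  p <- voxel_params(60, 700, 500, 200)
  d8a <- decode_series(encode_series(p, protocol_had8("A"), cc), cc)
  d8b <- decode_series(encode_series(p, protocol_had8("B"), cc), cc)
  cat14 <- concat_decoded(d8a, d8b)
  expect_equal(cat14$pld, seq(600, 3200, by = 200))
  expect_equal(length(unique(cat14$pld)), 14L)
})

test_that("decoding is linear", {
  cc <- tissue_constants()
  proto <- protocol_had4()
  e1 <- encode_series(voxel_params(40, 600, 400, 250), proto, cc)
  e2 <- encode_series(voxel_params(70, 900, 600, 600), proto, cc)
  mix <- e1; mix$data <- 2.5 * e1$data - 0.7 * e2$data
  d_mix <- decode_series(mix, cc)
  d1 <- decode_series(e1, cc); d2 <- decode_series(e2, cc)
  expect_equal(d_mix$dm, 2.5 * d1$dm - 0.7 * d2$dm, tolerance = 1e-12)
})

test_that("decoded noise follows the 4 sigma^2 / N least-squares law", {
  cc <- tissue_constants()
  p0 <- voxel_params(0, 100, 100, 100)
  proto <- protocol_had8("A")
  sig <- 2e-4
  e <- encode_series(rep(list(p0), 3000), proto, cc, baseline = 0,
                     noise_sd = sig, seed = 9)
  d <- decode_series(e, cc)
  v <- apply(d$dm[, 1, ], 1, var)      # single TE: variance per sub-bolus
  expect_lt(max(abs(v / (4 * sig^2 / proto$had_order) - 1)), 0.10)
  expect_lt(max(abs(rowMeans(d$dm[, 1, ]))), 5 * sig)   # zero-mean
})

test_that("encoding validates its inputs", {
  cc <- tissue_constants()
  expect_error(encode_series(voxel_params(60, 700, 500, 200),
                             protocol_had4(), cc, noise_sd = 1e-4),
               "seed")
  e <- encode_series(voxel_params(60, 700, 500, 200), protocol_had4(), cc)
  e$data <- e$data[1:3, , , drop = FALSE]
  expect_error(decode_series(e, cc), "shape")
})
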