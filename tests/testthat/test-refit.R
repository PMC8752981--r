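test_that("a spectrum drawn from one catalog signature refits to that signature", {
  cat6 <- preset_catalog()
  set.seed(1)
  x <- rmultinom(1L, 200L, cat6["APOBEC.CtoT", ])[, 1L]
  fit <- refit_exposures(x, cat6)
  expect_false(fit$excluded)
  expect_gt(fit$weights["APOBEC.CtoT"], 0.9)
  expect_true(all(fit$weights[names(fit$weights) != "APOBEC.CtoT"] < 0.06))
  expect_lt(fit$residual, 0.05)
  expect_equal(fit$counts, fit$weights * 200)

  # exactly the signature profile itself: weight 1, residual ~ 0
  exact <- refit_exposures(100 * cat6["MMRd.like", ], cat6)
  expect_equal(unname(exact$weights["MMRd.like"]), 1, tolerance = 1e-8)
  expect_lt(exact$residual, 1e-8)
})

test_that("spectra below the mutation threshold are excluded, not fit", {
  cat6 <- preset_catalog()
  x <- counts96(`1` = 49L)
  fit <- refit_exposures(x, cat6)
  expect_true(fit$excluded)
  expect_true(all(is.na(fit$weights)))
  fit50 <- refit_exposures(counts96(`1` = 50L), cat6)
  expect_false(fit50$excluded)
})

test_that("refitting is scale invariant on counts", {
  cat6 <- preset_catalog()
  set.seed(2)
  x <- rmultinom(1L, 500L, 0.5 * cat6["Clock.like", ] + 0.5 * cat6["POLE.like", ])[, 1L]
  f1 <- refit_exposures(x, cat6)
  f2 <- refit_exposures(10L * x, cat6)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-10)
})

test_that("adding a truly present signature never increases the residual", {
  cat6 <- preset_catalog()
  set.seed(3)
  for (i in 1:10) {
    x <- rmultinom(1L, 2000L, 0.6 * cat6["APOBEC.CtoT", ] + 0.4 * cat6["HRD.like", ])[, 1L]
    small <- signature_catalog(unclass(cat6)[c("APOBEC.CtoT", "Clock.like"), ])
    big <- signature_catalog(unclass(cat6)[c("APOBEC.CtoT", "Clock.like", "HRD.like"), ])
    r_small <- refit_exposures(x, small, min_weight = 0)$residual
    r_big <- refit_exposures(x, big, min_weight = 0)$residual
    expect_lte(r_big, r_small + 1e-12)
  }
})

test_that("NNLS matches the exhaustive simplex grid oracle on small subcatalogs", {
  cat6 <- preset_catalog()
  set.seed(11)
  for (i in 1:20) {
    k <- sample(2:3, 1L)
    sub <- signature_catalog(unclass(cat6)[sample(6L, k), , drop = FALSE])
    w_true <- as.vector(featsig:::.rdirichlet(1L, rep(1, k)))
    x <- rmultinom(1L, 1000L, as.vector(w_true %*% unclass(sub)))[, 1L]
    fit <- refit_exposures(x, sub, min_weight = 0)
    oracle <- grid_search_weights(x / sum(x), sub, step = 0.01)
    expect_lt(max(abs(fit$weights - oracle)), 0.02)
  }
})

test_that("exposure_matrix handles mixed-eligibility cohorts deterministically", {
  cat6 <- preset_catalog()
  set.seed(4)
  counts <- rbind(
    t(rmultinom(2L, 400L, cat6["Clock.like", ])),
    t(rmultinom(1L, 30L, cat6["Clock.like", ]))
  )
  counts <- rbind(counts, counts[1L, ]) # identical to row 1
  rownames(counts) <- c("a", "b", "tiny", "a2")
  em <- exposure_matrix(new_spectra(counts), cat6)
  expect_identical(em$sample_id, c("a", "b", "tiny", "a2"))
  expect_true(em$excluded[3L])
  expect_true(all(is.na(em[3L, rownames(cat6)])))
  expect_equal(
    unlist(em[1L, rownames(cat6)]),
    unlist(em[4L, rownames(cat6)])
  )
  em2 <- exposure_matrix(new_spectra(counts), cat6)
  expect_identical(em, em2)
})

test_that("renormalized weights sum to one and counts scale with burden", {
  cat6 <- preset_catalog()
  set.seed(6)
  x <- rmultinom(1L, 800L, 0.7 * cat6["MMRd.like", ] + 0.3 * cat6["HRD.like", ])[, 1L]
  fit <- refit_exposures(x, cat6, renormalize = TRUE)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  expect_equal(sum(fit$counts), 800, tolerance = 1e-6)
  plain <- refit_exposures(x, cat6)
  expect_lte(sum(plain$weights), 1 + 1e-9)
})
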