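test_that("percentile stratification matches the quantile rule on 1..100", {
  v <- stats::setNames(1:100, paste0("s", 1:100))
  g <- stratify_samples(v, mode = "percentile")
  expect_setequal(g$high, paste0("s", 96:100))
  expect_setequal(g$low, paste0("s", 1:5))
})

test_that("median and binary stratification behave as documented", {
  v <- stats::setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  g <- stratify_samples(v, mode = "median")
  expect_setequal(g$high, c("s3", "s4")) # ties at the median go low
  expect_setequal(g$low, c("s1", "s2"))

  flags <- stats::setNames(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), paste0("s", 1:10))
  gb <- stratify_samples(flags, mode = "binary")
  expect_length(gb$high, 3L)
  expect_length(gb$low, 7L)

  expect_error(stratify_samples(stats::setNames(rep(1, 5), paste0("s", 1:5))), "degenerate")
  expect_error(stratify_samples(flags[1], mode = "binary"), "at least 2")
})

test_that("disjoint group profiles give back the two profiles as pos/neg", {
  cat6 <- preset_catalog()
  a <- cat6["APOBEC.CtoG", ] # disjoint support from MMRd.like
  b <- cat6["MMRd.like", ]
  counts <- rbind(
    matrix(round(1000 * a), 3L, 96L, byrow = TRUE),
    matrix(round(1000 * b), 3L, 96L, byrow = TRUE)
  )
  rownames(counts) <- paste0("s", 1:6)
  pair <- suppressWarnings(differential_signature(counts, paste0("s", 1:3), paste0("s", 4:6)))
  expect_equal(unname(pair$pos), unname(as.numeric(a)), tolerance = 1e-6)
  expect_equal(unname(pair$neg), unname(as.numeric(b)), tolerance = 1e-6)
  expect_identical(pair$n_high, 3L)
  expect_identical(pair$n_low, 3L)
})

test_that("pos and neg always have disjoint support and swap under inversion", {
  cohort <- simulate_scenario("apobec", n_samples = 60L, mutations_per_sample = 300L, seed = 8L)
  vals <- stats::setNames(cohort$features$APOBEC3A_expr, cohort$features$sample_id)
  g <- stratify_samples(vals, hi_q = 0.8, lo_q = 0.2)
  pair <- differential_signature(cohort$spectra, g$high, g$low)
  swapped <- differential_signature(cohort$spectra, g$high, g$low, invert = TRUE)
  expect_equal(sum(pair$pos * pair$neg), 0)
  expect_equal(pair$pos, swapped$neg)
  expect_equal(pair$neg, swapped$pos)
  expect_equal(pair$raw_differential, -swapped$raw_differential)
  expect_equal(sum(pair$pos), 1, tolerance = 1e-12)
  expect_equal(sum(pair$neg), 1, tolerance = 1e-12)
})

test_that("identical groups raise an empty-differential error", {
  counts <- matrix(5L, 6L, 96L, dimnames = list(paste0("s", 1:6), NULL))
  expect_error(
    suppressWarnings(differential_signature(counts, paste0("s", 1:3), paste0("s", 4:6))),
    "identical group spectra"
  )
  expect_error(
    differential_signature(counts, paste0("s", 1:3), paste0("s", 3:6)),
    "disjoint"
  )
})

test_that("small groups warn and tiny groups error", {
  counts <- matrix(rpois(96L * 8L, 5), 8L, 96L, dimnames = list(paste0("s", 1:8), NULL))
  expect_warning(
    differential_signature(counts, paste0("s", 1:4), paste0("s", 5:8)),
    "fewer than 10"
  )
  expect_error(
    suppressWarnings(differential_signature(counts, paste0("s", 1:2), paste0("s", 5:8))),
    "min_group"
  )
})

test_that("mean-of-frequencies differential resists a hypermutant; pooled does not", {
  cat6 <- preset_catalog()
  a <- cat6["APOBEC.CtoT", ]
  b <- cat6["Clock.like", ]
  hrd <- cat6["HRD.like", ]
  counts <- rbind(
    round(200 * a), round(200 * a), round(100000 * hrd), # hypermutant in high group
    round(200 * b), round(200 * b), round(200 * b)
  )
  rownames(counts) <- paste0("s", 1:6)
  per_sample <- suppressWarnings(
    differential_signature(counts, paste0("s", 1:3), paste0("s", 4:6))
  )
  pooled <- suppressWarnings(
    differential_signature(counts, paste0("s", 1:3), paste0("s", 4:6), pooled = TRUE)
  )
  expect_gt(cosine_similarity(per_sample$pos, a), 0.85)
  expect_gt(
    cosine_similarity(pooled$pos, hrd),
    cosine_similarity(per_sample$pos, hrd)
  )
})

test_that("signature-pair TSV round-trips", {
  cohort <- simulate_scenario("hrd", n_samples = 60L, mutations_per_sample = 300L, seed = 12L)
  pair <- derive_scenario_signature(cohort, hi_q = 0.8, lo_q = 0.2)
  path <- file.path(tempdir(), "pair.tsv")
  write_signature_pair_tsv(pair, path)
  back <- read_signature_pair_tsv(path, feature_name = pair$feature_name)
  expect_equal(unname(back$pos), unname(pair$pos), tolerance = 1e-12)
  expect_equal(unname(back$neg), unname(pair$neg), tolerance = 1e-12)
  expect_equal(unname(back$raw_differential), unname(pair$raw_differential), tolerance = 1e-12)
})
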