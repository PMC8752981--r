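test_that("make_catalog is seed-reproducible, row-stochastic and dissimilar", {
  c1 <- make_catalog(5L, seed = 19L)
  c2 <- make_catalog(5L, seed = 19L)
  expect_identical(unclass(c1), unclass(c2))
  expect_equal(unname(rowSums(c1)), rep(1, 5L), tolerance = 1e-9)
  s <- similarity_matrix(c1)
  expect_lt(max(s[upper.tri(s)]), 0.8)
  c3 <- make_catalog(5L, seed = 20L)
  expect_false(identical(unclass(c1), unclass(c3)))
})

test_that("simulated cohorts conserve counts and are deterministic per seed", {
  cfg <- scenario_config("apobec", n_samples = 40L, mutations_per_sample = 200L, seed = 5L)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1$spectra$counts, coh2$spectra$counts)
  expect_identical(coh1$features, coh2$features)
  expect_equal(unname(rowSums(coh1$spectra$counts)), unname(coh1$truth$n_mut))
  expect_equal(unname(rowSums(coh1$truth$exposures)), rep(1, 40L), tolerance = 1e-9)
  expect_true(all(coh1$truth$exposures >= 0))

  other_seed <- simulate_cohort(scenario_config("apobec",
    n_samples = 40L,
    mutations_per_sample = 200L, seed = 6L
  ))
  expect_false(identical(coh1$spectra$counts, other_seed$spectra$counts))
})

test_that("log-normal burdens respect the configured floor and cap", {
  cfg <- simulation_config(
    n_samples = 200L, catalog = preset_catalog(),
    mutations_per_sample = list(median = 600, sdlog = 1.1, min = 50, max = 10000),
    seed = 9L
  )
  coh <- simulate_cohort(cfg)
  m <- coh$truth$n_mut
  expect_true(all(m >= 50 & m <= 10000))
  expect_gt(length(unique(m)), 50L)
})

test_that("realized feature-activity correlation tracks the requested coupling", {
  for (rho in c(0.8, -0.8, 0.5)) {
    cfg <- simulation_config(
      n_samples = 400L,
      catalog = preset_catalog(),
      causal_map = data.frame(
        feature = "f", signature = "HRD.like", coupling = rho,
        stringsAsFactors = FALSE
      ),
      mutations_per_sample = 100L,
      seed = 100L + round(10 * rho)
    )
    coh <- simulate_cohort(cfg)
    r <- cor(coh$features$f, coh$truth$activity[, "f"])
    expect_lt(abs(r - rho), 0.1)
  }
})

test_that("binary features have the configured prevalence and direction", {
  coh <- simulate_scenario("pole", n_samples = 400L, mutations_per_sample = 100L, seed = 77L)
  flag <- coh$features$POLE_mutant
  expect_true(all(flag %in% c(0L, 1L)))
  expect_lt(abs(mean(flag) - 0.15), 0.07)
  expect_gt(
    mean(coh$truth$activity[flag == 1L, "pole"]),
    mean(coh$truth$activity[flag == 0L, "pole"])
  )
})

test_that("uncoupled features stay at the permutation chance level; coupled ones exceed it", {
  make_coh <- function(rho, seed) {
    simulate_cohort(simulation_config(
      n_samples = 200L,
      catalog = preset_catalog(),
      causal_map = data.frame(
        feature = "f", signature = "APOBEC.CtoT", coupling = rho,
        stringsAsFactors = FALSE
      ),
      mutations_per_sample = 500L,
      seed = seed
    ))
  }
  # permutation-test statistic: size of the group contrast
  diff_norm <- function(coh, vals) {
    pair <- derive_feature_signature(coh$spectra, vals, hi_q = 0.9, lo_q = 0.1)
    sqrt(sum(pair$raw_differential^2))
  }
  coh0 <- make_coh(0, 55L)
  vals <- stats::setNames(coh0$features$f, coh0$features$sample_id)
  obs <- diff_norm(coh0, vals)
  # permutation oracle: the chance-level distribution of the same statistic
  set.seed(56L)
  null_norm <- replicate(30L, diff_norm(coh0, stats::setNames(sample(vals), names(vals))))
  # an uncoupled feature is exchangeable with its permutations: its contrast
  # sits inside the permutation distribution
  expect_lte(obs, max(null_norm))
  # a strongly coupled feature clears the whole permutation distribution
  coh1 <- make_coh(0.8, 57L)
  obs1 <- diff_norm(coh1, stats::setNames(coh1$features$f, coh1$features$sample_id))
  expect_gt(obs1, max(null_norm))
})

test_that("config validation rejects malformed inputs", {
  cat6 <- preset_catalog()
  expect_error(
    simulation_config(10L, cat6,
      causal_map = data.frame(feature = "f", signature = "NotASig", coupling = 0.5),
      seed = 1L
    ),
    "not in catalog"
  )
  expect_error(
    simulation_config(10L, cat6,
      causal_map = data.frame(feature = "f", signature = "HRD.like", coupling = 1.5),
      seed = 1L
    ),
    "\\[-1, 1\\]"
  )
  expect_error(
    simulation_config(10L, cat6, mutations_per_sample = list(median = 5, sdlog = 1, min = 0), seed = 1L),
    "floor"
  )
  expect_error(simulate_cohort(structure(list(), class = "list")), "sim_config")
})

test_that("MAF round trip reproduces counts exactly and is byte-stable", {
  coh <- simulate_scenario("mlh1", n_samples = 3L, mutations_per_sample = 80L, seed = 14L)
  d <- tempdir()
  p1 <- write_maf(coh$spectra, file.path(d, "rt1.maf"), file.path(d, "rt1.fa"))
  sp <- build_spectra(read_maf(p1$maf), p1$fasta)
  expect_identical(
    sp$counts[rownames(coh$spectra$counts), ],
    coh$spectra$counts
  )
  # byte-identical across repeated writes of the same cohort
  p2 <- write_maf(coh$spectra, file.path(d, "rt2.maf"), file.path(d, "rt2.fa"))
  expect_identical(
    unname(tools::md5sum(p1$maf)), unname(tools::md5sum(p2$maf))
  )
  expect_identical(
    unname(tools::md5sum(p1$fasta)), unname(tools::md5sum(p2$fasta))
  )

  # empty cohort -> header-only MAF
  empty <- write_maf(
    matrix(0L, 1L, 96L, dimnames = list("s0", NULL)),
    file.path(d, "empty.maf"), file.path(d, "empty.fa")
  )
  expect_identical(length(readLines(empty$maf)), 1L)
})
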