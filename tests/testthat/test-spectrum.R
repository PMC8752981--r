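test_that("channel order is canonical and pyrimidine-collapsed", {
  labs <- channel_labels()
  expect_length(labs, 96L)
  expect_identical(labs[1], "A[C>A]A")
  expect_identical(labs[17], "A[C>G]A")
  expect_identical(labs[96], "T[T>G]T")
  expect_false(anyDuplicated(labs) > 0)

  expect_identical(classify_substitution("C", "A", "A", "A"), 1L)
  # purine-strand record collapses to the same channel
  expect_identical(classify_substitution("G", "T", "T", "T"), 1L)
  expect_identical(classify_substitution("T", "G", "T", "T"), 96L)
  # every channel maps to itself through its own parts
  parts <- featsig:::.channel_parts(1:96)
  expect_identical(
    classify_substitution(parts$ref, parts$alt, parts$five, parts$three),
    1:96
  )
  expect_error(classify_substitution("C", "C", "A", "A"), "invalid")
  expect_error(classify_substitution("N", "A", "A", "A"), "invalid")
})

test_that("build_spectra counts SNVs into channels and indels into TMB", {
  ref <- toy_reference("GGACGTTACGTACCA") # ACG at pos 3-5 and 8-10
  mut <- data.frame(
    sample_id = "s1",
    chrom = "chr1",
    pos = c(4L, 9L, 4L, 6L),
    ref = c("C", "C", "C", "T"),
    alt = c("T", "T", "G", "-"),
    stringsAsFactors = FALSE
  )
  # duplicate-record rule keys on (sample, chrom, pos, alt): same pos but
  # different alt is kept
  sp <- build_spectra(mut, ref, min_snv = 50L)
  expect_s3_class(sp, "mutation_spectra")
  expect_identical(sum(sp$counts), 3L)
  expect_identical(unname(sp$counts[1, "A[C>T]G"]), 2L)
  expect_identical(unname(sp$counts[1, "A[C>G]G"]), 1L)
  expect_identical(unname(sp$n_snv["s1"]), 3)
  expect_identical(unname(sp$tmb["s1"]), 4) # 3 SNVs + 1 DEL
  expect_false(sp$eligible["s1"])
})

test_that("mismatching, duplicate and off-reference records are skipped with warnings", {
  ref <- toy_reference("GGACGTTACGTACCA")
  mut <- data.frame(
    sample_id = "s1",
    chrom = c("chr1", "chr1", "chr1", "chrX"),
    pos = c(4L, 4L, 9L, 5L),
    ref = c("C", "C", "G", "A"),
    alt = c("T", "T", "A", "C"),
    stringsAsFactors = FALSE
  )
  expect_warning(
    expect_warning(
      expect_warning(
        sp <- build_spectra(mut, ref),
        "duplicate"
      ),
      "absent from the reference"
    ),
    "mismatch"
  )
  expect_identical(sum(sp$counts), 1L)
  expect_error(
    suppressWarnings(build_spectra(mut[4, ], ref)),
    "no mutation records"
  )
})

test_that("spectra are invariant under strand flip and record permutation", {
  cohort <- simulate_scenario("apobec", n_samples = 20L, mutations_per_sample = 150L, seed = 42L)
  paths <- write_maf(
    cohort$spectra,
    file.path(tempdir(), "strand.maf"), file.path(tempdir(), "strand.fa")
  )
  mut <- read_maf(paths$maf)
  seqs <- featsig:::.as_reference(paths$fasta)
  sp_fwd <- build_spectra(mut, seqs)

  sp_rev <- build_spectra(mirror_mutations(mut, seqs), mirror_reference(seqs))
  expect_identical(
    sp_fwd$counts[rownames(sp_rev$counts), ],
    sp_rev$counts
  )

  perm <- sample(nrow(mut))
  sp_perm <- build_spectra(mut[perm, ], seqs)
  expect_identical(sp_fwd$counts, sp_perm$counts[rownames(sp_fwd$counts), ])
})

test_that("normalize_spectrum returns frequencies proportional to counts", {
  x <- counts96(`6` = 10L)
  f <- normalize_spectrum(x)
  expect_identical(f[6], 1)
  expect_equal(sum(f), 1, tolerance = 1e-12)

  u <- normalize_spectrum(rep(1L, 96L))
  expect_equal(u, rep(1 / 96, 96L))

  set.seed(5)
  m <- matrix(rpois(96L * 4L, 8), nrow = 4L)
  fm <- normalize_spectrum(m)
  expect_equal(rowSums(fm), rep(1, 4L), tolerance = 1e-12)
  expect_equal(fm, m / rowSums(m))
  expect_error(normalize_spectrum(integer(96L)), "all-zero")
})

test_that("spectra TSV round-trips counts and TMB", {
  cohort <- simulate_scenario("pole", n_samples = 10L, mutations_per_sample = 120L, seed = 3L)
  path <- file.path(tempdir(), "spectra.tsv")
  write_spectra_tsv(cohort$spectra, path)
  back <- read_spectra_tsv(path)
  expect_identical(unname(back$counts), unname(cohort$spectra$counts))
  expect_identical(rownames(back$counts), rownames(cohort$spectra$counts))
  expect_equal(back$tmb, cohort$spectra$tmb)
})
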