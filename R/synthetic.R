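# Seeded synthetic cohorts: spectra drawn as multinomial mixtures of catalog
# signatures, with feature variables coupled to the latent activity of
# designated causal signatures. Everything is deterministic given the seed.

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a random sparse signature catalog
#'
#' Draws `k` row-stochastic 96-channel profiles from a sparse symmetric
#' Dirichlet and rejects/redraws rows until every pairwise cosine similarity
#' is below `max_cos`, so the catalog is identifiable. Reproducible per
#' seed.
#'
#' @param k Number of signatures (>= 2).
#' @param sparsity Dirichlet concentration per channel in `(0, 1]`; smaller
#'   means spikier signatures (default 0.1).
#' @param seed Integer seed (required).
#' @param max_cos Maximum allowed pairwise cosine similarity (default 0.8).
#' @param max_tries Redraw budget before giving up.
#' @return A [signature_catalog()] named `SynthSig1..k`.
#' @export
make_catalog <- function(k, sparsity = 0.1, seed, max_cos = 0.8, max_tries = 200L) {
  if (k < 2L) stop("k must be >= 2")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  .with_seed(seed, {
    m <- .rdirichlet(k, rep(sparsity, 96L))
    for (i in seq_len(max_tries)) {
      nm <- m / sqrt(rowSums(m^2))
      s <- nm %*% t(nm)
      diag(s) <- 0
      if (max(s) < max_cos) break
      worst <- which.max(apply(s, 1L, max))
      m[worst, ] <- .rdirichlet(1L, rep(sparsity, 96L))
      if (i == max_tries) stop("make_catalog: could not reach target dissimilarity")
    }
    signature_catalog(m, names = paste0("SynthSig", seq_len(k)), renormalize = TRUE)
  })
}

#' Stylized six-signature reference catalog (synthetic)
#'
#' A fixed, code-built catalog of six synthetic signature shapes echoing
#' well-known processes, used by the scenario presets:
#' \describe{
#'   \item{Clock.like}{C>T at NpCpG sites (spontaneous deamination).}
#'   \item{APOBEC.CtoT}{C>T in TpC contexts (APOBEC-type deamination).}
#'   \item{APOBEC.CtoG}{C>G in TpC contexts (APOBEC-type, REV1 branch).}
#'   \item{MMRd.like}{C>T at GpC plus T>C, a mismatch-repair-deficiency-like
#'     blend.}
#'   \item{POLE.like}{C>A at TpCpT and T>G at TpTpT (proofreading loss).}
#'   \item{HRD.like}{a broad, flat profile spread over the channels unused by
#'     the five focal signatures (double-strand-break-repair-deficiency-like
#'     flatness).}
#' }
#' These are synthetic stand-ins built in code, not the published COSMIC
#' profiles; use [read_cosmic_catalog()] for the real catalog.
#'
#' @return A [signature_catalog()] with 6 rows.
#' @export
preset_catalog <- function() {
  labs <- channel_labels()
  ch <- function(sub, five, three) match(paste0(five, "[", sub, "]", three), labs)
  prof <- matrix(0, nrow = 6L, ncol = 96L)
  rownames(prof) <- c(
    "Clock.like", "APOBEC.CtoT", "APOBEC.CtoG",
    "MMRd.like", "POLE.like", "HRD.like"
  )
  prof["Clock.like", c(ch("C>T", "A", "G"), ch("C>T", "C", "G"), ch("C>T", "G", "G"), ch("C>T", "T", "G"))] <-
    c(0.35, 0.15, 0.15, 0.35)
  prof["APOBEC.CtoT", c(ch("C>T", "T", "A"), ch("C>T", "T", "C"), ch("C>T", "T", "G"), ch("C>T", "T", "T"))] <-
    c(0.40, 0.10, 0.10, 0.40)
  prof["APOBEC.CtoG", c(ch("C>G", "T", "A"), ch("C>G", "T", "C"), ch("C>G", "T", "G"), ch("C>G", "T", "T"))] <-
    c(0.40, 0.10, 0.10, 0.40)
  prof["MMRd.like", c(
    ch("C>T", "G", "A"), ch("C>T", "G", "C"), ch("C>T", "G", "T"),
    ch("T>C", "A", "A"), ch("T>C", "A", "G")
  )] <- c(0.25, 0.20, 0.25, 0.15, 0.15)
  prof["POLE.like", c(ch("C>A", "T", "T"), ch("T>G", "T", "T"), ch("C>A", "T", "A"))] <-
    c(0.45, 0.35, 0.20)
  unused <- colSums(prof) == 0
  prof["HRD.like", unused] <- 1 / sum(unused)
  signature_catalog(prof)
}

#' Simulation configuration for a synthetic cohort
#'
#' Defines the generative model. Each causal process has one log-normal
#' latent activity per sample (`A = exp(sigma * z)`, `z ~ N(0,1)`). The
#' exposure share of a causal signature is linear in the standardized
#' activity — `share = base + slope * (A - E[A]) / sd(A)`, floored at 0 and
#' with the per-sample causal total capped at `max` (the cap binds only in
#' the far activity tail) — and the remaining exposure mass is split over the
#' non-causal signatures by a symmetric Dirichlet draw. Spectra are
#' multinomial draws from the resulting mixture profile, and each feature is
#' a linear function of its latent activity plus Gaussian noise calibrated so
#' the realized feature-activity Pearson correlation is approximately the
#' requested coupling. The linear share keeps the coupling transmitted
#' through spectra to projected signature levels instead of being absorbed
#' by a saturating link.
#'
#' @param n_samples Number of genomes.
#' @param catalog A [signature_catalog()].
#' @param causal_map `data.frame` with columns `feature`, `signature`,
#'   `coupling` (in `[-1, 1]`), and optionally `type` (`"continuous"`,
#'   default, or `"binary"`), `latent` (grouping id; rows sharing a latent
#'   share one activity, default = feature name), `prevalence` (binary
#'   features, default 0.15). May be empty for a null cohort.
#' @param mutations_per_sample Either a single number (fixed burden) or a
#'   list `list(median =, sdlog =, min =, max =)` for a clamped log-normal
#'   burden (default: median 600, sdlog 1.1, clamped to 50..10000, the
#'   realistic burden span of exome cohorts).
#' @param baseline_alpha Dirichlet concentration for splitting the
#'   non-causal exposure mass (default 1 = uniform on the simplex).
#' @param activity_sigma Log-sd of the latent activity (default 0.6).
#' @param causal_share List `list(base, slope, max)` of the linear
#'   activity-to-share map (defaults 0.30, 0.15, 0.85): an average-activity
#'   genome devotes ~30% of its mutations to the causal process, one
#'   activity-sd moves that by 15 points, and the causal total never exceeds
#'   85%.
#' @param seed Integer seed (required).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_samples, catalog, causal_map = NULL,
                              mutations_per_sample = list(median = 600, sdlog = 1.1, min = 50, max = 10000),
                              baseline_alpha = 1, activity_sigma = 0.6,
                              causal_share = list(base = 0.30, slope = 0.15, max = 0.85),
                              seed) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (is.null(causal_map)) {
    causal_map <- data.frame(
      feature = character(0), signature = character(0),
      coupling = numeric(0), stringsAsFactors = FALSE
    )
  }
  causal_map <- as.data.frame(causal_map, stringsAsFactors = FALSE)
  if (nrow(causal_map)) {
    req <- c("feature", "signature", "coupling")
    if (length(setdiff(req, names(causal_map)))) {
      stop("causal_map needs columns feature, signature, coupling")
    }
    if (is.null(causal_map$type)) causal_map$type <- "continuous"
    if (is.null(causal_map$latent)) causal_map$latent <- causal_map$feature
    if (is.null(causal_map$prevalence)) causal_map$prevalence <- 0.15
    if (!all(causal_map$type %in% c("continuous", "binary"))) {
      stop("causal_map$type must be 'continuous' or 'binary'")
    }
    if (any(abs(causal_map$coupling) > 1)) stop("couplings must lie in [-1, 1]")
    bad_sig <- setdiff(causal_map$signature, rownames(catalog))
    if (length(bad_sig)) stop("causal signatures not in catalog: ", paste(bad_sig, collapse = ", "))
    # one generative definition per feature
    per_feat <- causal_map[!duplicated(causal_map$feature), , drop = FALSE]
    if (nrow(per_feat) < length(unique(causal_map$feature))) stop("internal feature dedup error")
  }
  if (is.numeric(mutations_per_sample) && length(mutations_per_sample) == 1L) {
    if (mutations_per_sample < 1) stop("mutations_per_sample must be >= 1")
  } else if (is.list(mutations_per_sample)) {
    mps <- mutations_per_sample
    if (is.null(mps$median) || is.null(mps$sdlog)) {
      stop("mutations_per_sample list needs median and sdlog")
    }
    if (is.null(mps$min)) mps$min <- 1
    if (is.null(mps$max)) mps$max <- Inf
    if (mps$min < 1) stop("mutations_per_sample floor must be >= 1")
    mutations_per_sample <- mps
  } else {
    stop("mutations_per_sample must be a number or a list(median, sdlog, min, max)")
  }
  if (!is.list(causal_share) ||
    !all(c("base", "slope", "max") %in% names(causal_share))) {
    stop("causal_share must be a list(base, slope, max)")
  }
  if (causal_share$max <= 0 || causal_share$max > 1) stop("causal_share$max must be in (0, 1]")
  structure(
    list(
      n_samples = as.integer(n_samples),
      catalog = catalog,
      causal_map = causal_map,
      mutations_per_sample = mutations_per_sample,
      baseline_alpha = baseline_alpha,
      activity_sigma = activity_sigma,
      causal_share = causal_share,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a synthetic cohort of spectra, features and ground truth
#'
#' Draws a cohort under a [simulation_config()]: latent activities, tilted
#' Dirichlet exposures (nonnegative, summing to 1 per sample), multinomial
#' spectra whose per-sample totals equal the drawn mutation burden, and
#' coupled feature columns. Fully deterministic given the config (which
#' includes the seed).
#'
#' @param config A `sim_config`.
#' @return List with elements `spectra` ([new_spectra()]), `features`
#'   (`data.frame` with `sample_id` + one column per feature), and `truth`
#'   (list: `exposures` matrix, `activity` matrix, `latent` z matrix,
#'   `n_mut`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_samples
    catalog <- config$catalog
    k <- nrow(catalog)
    map <- config$causal_map
    ids <- sprintf("S%04d", seq_len(n))

    lat_names <- unique(map$latent)
    z <- matrix(stats::rnorm(n * max(length(lat_names), 1L)),
      nrow = n,
      dimnames = list(ids, if (length(lat_names)) lat_names else "none")
    )
    A <- exp(config$activity_sigma * z)

    if (nrow(map)) {
      # causal share linear in the standardized (analytic moments) activity
      sg <- config$activity_sigma
      mu_A <- exp(sg^2 / 2)
      sd_A <- sqrt(exp(sg^2) - 1) * mu_A
      cs <- config$causal_share
      sig_by_latent <- lapply(
        split(map$signature, map$latent),
        unique
      )[lat_names]
      S <- vapply(lat_names, function(l) {
        pmax(0, cs$base + cs$slope * (A[, l] - mu_A) / sd_A)
      }, numeric(n))
      S <- matrix(S, nrow = n, dimnames = list(ids, lat_names))
      tot <- rowSums(S)
      over <- tot > cs$max
      if (any(over)) S[over, ] <- S[over, , drop = FALSE] * (cs$max / tot[over])
      tot <- rowSums(S)

      causal_sigs <- unique(map$signature)
      W <- matrix(0, nrow = n, ncol = k, dimnames = list(ids, rownames(catalog)))
      for (l in lat_names) {
        js <- sig_by_latent[[l]]
        for (j in js) W[, j] <- W[, j] + S[, l] / length(js)
      }
      others <- setdiff(rownames(catalog), causal_sigs)
      if (length(others)) {
        B <- .rdirichlet(n, rep(config$baseline_alpha, length(others)))
        W[, others] <- B * (1 - tot)
      } else {
        W <- W / rowSums(W)
      }
    } else {
      W <- .rdirichlet(n, rep(config$baseline_alpha, k))
      dimnames(W) <- list(ids, rownames(catalog))
    }

    mps <- config$mutations_per_sample
    m <- if (is.numeric(mps)) {
      rep(as.integer(round(mps)), n)
    } else {
      raw <- stats::rlnorm(n, meanlog = log(mps$median), sdlog = mps$sdlog)
      as.integer(pmin(pmax(round(raw), mps$min), mps$max))
    }

    probs <- W %*% unclass(catalog)
    counts <- t(vapply(seq_len(n), function(i) {
      stats::rmultinom(1L, m[i], probs[i, ])[, 1L]
    }, numeric(96L)))
    rownames(counts) <- ids

    features <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    if (nrow(map)) {
      per_feat <- map[!duplicated(map$feature), , drop = FALSE]
      for (i in seq_len(nrow(per_feat))) {
        rho <- per_feat$coupling[i]
        a <- A[, per_feat$latent[i]]
        if (per_feat$type[i] == "binary") {
          prev <- per_feat$prevalence[i]
          flag <- as.integer(a > stats::quantile(a, 1 - prev))
          flip <- stats::runif(n) < (1 - abs(rho)) / 2
          flag[flip] <- 1L - flag[flip]
          if (rho < 0) flag <- 1L - flag
          features[[per_feat$feature[i]]] <- flag
        } else {
          a_std <- as.numeric(scale(a))
          noise <- if (abs(rho) < 1) sqrt(1 - rho^2) * stats::rnorm(n) else 0
          features[[per_feat$feature[i]]] <- rho * a_std + noise
        }
      }
    }

    list(
      spectra = new_spectra(counts, tmb = m),
      features = features,
      truth = list(
        exposures = W,
        activity = A,
        latent = z,
        n_mut = stats::setNames(m, ids)
      ),
      config = config
    )
  })
}

# ---- scenario presets ---------------------------------------------------

.SCENARIOS <- c("apobec", "mlh1", "pole", "hypoxia", "hrd")

#' Scenario presets for feature-driven signature discovery
#'
#' Four canonical study designs plus a hypoxia analogue, expressed as
#' [simulation_config()]s over the [preset_catalog()]:
#' \describe{
#'   \item{apobec}{`APOBEC3A_expr` (coupling +0.8) drives `APOBEC.CtoT`; a
#'     repair-gene modifier `NHEJ1_expr` is anti-coupled (-0.4) to the same
#'     activity. Derivation: 95th/5th expression percentiles.}
#'   \item{mlh1}{`MLH1_expr` (coupling -0.8) drives `MMRd.like` — low
#'     expression is the mutagenic state, so derivation inverts the groups;
#'     `MLH1_promoter_meth` (+0.7) rides the same latent as the anti-coupled
#'     methylation readout.}
#'   \item{pole}{binary `POLE_mutant` status (prevalence 0.15, coupling 0.8)
#'     drives `POLE.like`; derivation compares mutant vs wild-type.}
#'   \item{hrd}{three copy-number scores `NtAI`, `LST`, `HRD_LOH` (coupling
#'     0.85 each) share one latent driving `HRD.like`.}
#'   \item{hypoxia}{a continuous `hypoxia_score` (coupling 0.85) drives both
#'     APOBEC signatures jointly; `APOBEC3A_expr` (+0.7) rides the same
#'     latent.}
#' }
#' Score-based presets (hrd, hypoxia) default to coupling 0.85: aggregate
#' copy-number/mRNA scores are direct molecular readouts of the latent
#' process, tighter than a single gene's expression (0.8).
#'
#' @param scenario One of `"apobec"`, `"mlh1"`, `"pole"`, `"hypoxia"`,
#'   `"hrd"`.
#' @param n_samples Cohort size (default 300).
#' @param mutations_per_sample Per-genome burden (default 2000, fixed).
#' @param coupling Override the preset's feature-activity coupling.
#' @param seed Integer seed (required).
#' @return A `sim_config` with attribute `scenario` (list: `name`,
#'   `feature` used for derivation, `mode`, `invert`, `causal_signatures`).
#' @export
scenario_config <- function(scenario = .SCENARIOS, n_samples = 300L,
                            mutations_per_sample = 2000L, coupling = NULL, seed) {
  scenario <- match.arg(scenario)
  default_coupling <- c(
    apobec = 0.8, mlh1 = 0.8, pole = 0.8,
    hypoxia = 0.85, hrd = 0.85
  )[[scenario]]
  rho <- if (is.null(coupling)) default_coupling else coupling

  spec <- switch(scenario,
    apobec = list(
      map = data.frame(
        feature = c("APOBEC3A_expr", "NHEJ1_expr"),
        signature = c("APOBEC.CtoT", "APOBEC.CtoT"),
        coupling = c(rho, -0.4),
        latent = c("apobec", "apobec"),
        stringsAsFactors = FALSE
      ),
      feature = "APOBEC3A_expr", mode = "percentile", invert = FALSE,
      causal = "APOBEC.CtoT"
    ),
    mlh1 = list(
      map = data.frame(
        feature = c("MLH1_expr", "MLH1_promoter_meth"),
        signature = c("MMRd.like", "MMRd.like"),
        coupling = c(-rho, 0.7),
        latent = c("mmrd", "mmrd"),
        stringsAsFactors = FALSE
      ),
      feature = "MLH1_expr", mode = "percentile", invert = TRUE,
      causal = "MMRd.like"
    ),
    pole = list(
      map = data.frame(
        feature = "POLE_mutant",
        signature = "POLE.like",
        coupling = rho,
        type = "binary",
        latent = "pole",
        prevalence = 0.15,
        stringsAsFactors = FALSE
      ),
      feature = "POLE_mutant", mode = "binary", invert = FALSE,
      causal = "POLE.like"
    ),
    hrd = list(
      map = data.frame(
        feature = c("NtAI", "LST", "HRD_LOH"),
        signature = "HRD.like",
        coupling = rho,
        latent = "hrd",
        stringsAsFactors = FALSE
      ),
      feature = "NtAI", mode = "percentile", invert = FALSE,
      causal = "HRD.like"
    ),
    hypoxia = list(
      map = data.frame(
        feature = c("hypoxia_score", "hypoxia_score", "APOBEC3A_expr"),
        signature = c("APOBEC.CtoT", "APOBEC.CtoG", "APOBEC.CtoT"),
        coupling = c(rho, rho, 0.7),
        latent = "hyp",
        stringsAsFactors = FALSE
      ),
      feature = "hypoxia_score", mode = "percentile", invert = FALSE,
      causal = c("APOBEC.CtoT", "APOBEC.CtoG")
    )
  )

  cfg <- simulation_config(
    n_samples = n_samples,
    catalog = preset_catalog(),
    causal_map = spec$map,
    mutations_per_sample = mutations_per_sample,
    seed = seed
  )
  attr(cfg, "scenario") <- list(
    name = scenario, feature = spec$feature, mode = spec$mode,
    invert = spec$invert, causal_signatures = spec$causal
  )
  cfg
}

#' Simulate a preset scenario cohort
#'
#' Convenience wrapper: [scenario_config()] then [simulate_cohort()]; the
#' scenario descriptor is carried over on the result.
#'
#' @inheritParams scenario_config
#' @return A cohort list (see [simulate_cohort()]) with element `scenario`.
#' @export
simulate_scenario <- function(scenario = .SCENARIOS, n_samples = 300L,
                              mutations_per_sample = 2000L, coupling = NULL, seed) {
  cfg <- scenario_config(scenario,
    n_samples = n_samples,
    mutations_per_sample = mutations_per_sample,
    coupling = coupling, seed = seed
  )
  cohort <- simulate_cohort(cfg)
  cohort$scenario <- attr(cfg, "scenario")
  cohort
}

#' Derive the feature-driven signature pair of a scenario cohort
#'
#' Runs the scenario's intended stratification (feature, mode, inversion)
#' and returns the resulting [differential_signature()] pair.
#'
#' @param cohort Output of [simulate_scenario()].
#' @param ... Passed to [derive_feature_signature()] (e.g. `hi_q`, `pooled`).
#' @return A `signature_pair`.
#' @export
derive_scenario_signature <- function(cohort, ...) {
  sc <- cohort$scenario
  if (is.null(sc)) stop("cohort does not carry a scenario descriptor")
  vals <- stats::setNames(
    cohort$features[[sc$feature]],
    cohort$features$sample_id
  )
  derive_feature_signature(cohort$spectra, vals,
    mode = sc$mode, invert = sc$invert,
    feature_name = sc$feature, ...
  )
}

# ---- MAF round trip -----------------------------------------------------

# The 32 pyrimidine-centered trinucleotides, C-centered block then
# T-centered, flanks lexicographic; one "block" of the synthetic reference
# is their 96 bp concatenation.
.context_block <- function() {
  out <- character(32L)
  i <- 0L
  for (center in c("C", "T")) {
    for (p5 in .BASES) {
      for (p3 in .BASES) {
        i <- i + 1L
        out[i] <- paste0(p5, center, p3)
      }
    }
  }
  out
}

#' Write a cohort's spectra as a MAF plus matching reference FASTA
#'
#' Materializes every SNV of a count matrix as one MAF record on a synthetic
#' single-contig reference built from repeated blocks of all 32
#' pyrimidine-centered trinucleotide contexts, sized so that every mutation
#' gets its own position (re-ingestion is therefore not affected by
#' duplicate-record removal). Re-running [build_spectra()] on the outputs
#' reproduces the input counts exactly, and the files are byte-identical for
#' identical cohorts. The reference is synthetic scaffolding for round
#' trips, not a genome.
#'
#' @param spectra `mutation_spectra` or samples x 96 count matrix.
#' @param maf_path Output MAF path.
#' @param fasta_path Output FASTA path.
#' @return Invisibly, `list(maf = maf_path, fasta = fasta_path)`.
#' @export
write_maf <- function(spectra, maf_path, fasta_path) {
  counts <- .spectra_counts(spectra)
  parts <- .channel_parts(1:96)
  # context index within the 32-trinucleotide block, and center offset
  ctx_idx <- (parts$ref == "T") * 16L + (match(parts$five, .BASES) - 1L) * 4L +
    match(parts$three, .BASES)
  center0 <- 3L * (ctx_idx - 1L) + 2L # position within one 96 bp block

  nz <- which(counts > 0L, arr.ind = TRUE)
  if (nrow(nz)) {
    cnt <- counts[nz]
    rows <- rep(seq_len(nrow(nz)), cnt)
    occ <- sequence(cnt)
    ch <- nz[rows, 2L]
    rec <- data.table::data.table(
      Hugo_Symbol = "SYNTH",
      Chromosome = "chrSYN",
      Start_Position = center0[ch] + 96L * (occ - 1L),
      Reference_Allele = parts$ref[ch],
      Tumor_Seq_Allele2 = parts$alt[ch],
      Variant_Type = "SNP",
      Tumor_Sample_Barcode = rownames(counts)[nz[rows, 1L]]
    )
    rec$End_Position <- rec$Start_Position
    data.table::setcolorder(rec, c(
      "Hugo_Symbol", "Chromosome", "Start_Position", "End_Position",
      "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Type",
      "Tumor_Sample_Barcode"
    ))
    data.table::setorder(rec, Tumor_Sample_Barcode, Start_Position, Tumor_Seq_Allele2)
    n_blocks <- max(counts)
  } else {
    rec <- data.table::data.table(
      Hugo_Symbol = character(0), Chromosome = character(0),
      Start_Position = integer(0), End_Position = integer(0),
      Reference_Allele = character(0), Tumor_Seq_Allele2 = character(0),
      Variant_Type = character(0), Tumor_Sample_Barcode = character(0)
    )
    n_blocks <- 1L
  }
  data.table::fwrite(rec, maf_path, sep = "\t", quote = FALSE)

  seq <- strrep(paste(.context_block(), collapse = ""), n_blocks)
  chunks <- substring(seq, seq(1L, nchar(seq), 60L), pmin(seq(1L, nchar(seq), 60L) + 59L, nchar(seq)))
  writeLines(c(">chrSYN synthetic context scaffold", chunks), fasta_path)
  invisible(list(maf = maf_path, fasta = fasta_path))
}
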