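#' Stratify samples into feature-high and feature-low groups
#'
#' Three modes mirror the three kinds of driving features: `percentile`
#' (extreme tails of a continuous feature, default 95th/5th percentiles, the
#' setting used to contrast e.g. APOBEC3A-high against APOBEC3A-low tumors),
#' `median` (two halves; ties go low), and `binary` (mutated vs wild-type
#' status flags in `{0, 1}`). Missing values are dropped before
#' stratification. Quantiles use R's default (type 7) definition with
#' inclusive comparison, so on values `1..100` the default tails are
#' `{96..100}` and `{1..5}`.
#'
#' @param values Named numeric vector (names = sample ids).
#' @param mode One of `"percentile"`, `"median"`, `"binary"`.
#' @param hi_q,lo_q High/low quantiles for percentile mode.
#' @return List with character vectors `high` and `low` (disjoint, each
#'   nonempty).
#' @export
stratify_samples <- function(values, mode = c("percentile", "median", "binary"),
                             hi_q = 0.95, lo_q = 0.05) {
  mode <- match.arg(mode)
  if (is.null(names(values))) stop("values must be named by sample id")
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 non-missing values to stratify")

  if (mode == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary mode requires values in {0, 1}")
    high <- names(values)[values == 1]
    low <- names(values)[values == 0]
  } else if (mode == "median") {
    med <- stats::median(values)
    high <- names(values)[values > med]
    low <- names(values)[values <= med]
  } else {
    if (!(lo_q < hi_q)) stop("lo_q must be below hi_q")
    qh <- stats::quantile(values, hi_q, names = FALSE)
    ql <- stats::quantile(values, lo_q, names = FALSE)
    high <- names(values)[values >= qh]
    low <- names(values)[values <= ql]
  }
  if (!length(high) || !length(low)) {
    stop("degenerate stratification: one group is empty (constant feature?)")
  }
  if (length(intersect(high, low))) {
    stop("degenerate stratification: high and low groups overlap (near-constant feature?)")
  }
  list(high = high, low = low)
}

#' Differential trinucleotide-frequency signature between two groups
#'
#' The raw differential is the mean of per-sample normalized 96-channel
#' frequencies in the high group minus the same mean in the low group (or
#' pooled counts per group with `pooled = TRUE`). Its positive part,
#' renormalized to sum 1, is the feature-representing signature; the negative
#' part (sign flipped, renormalized) represents the opposite pole. The two
#' parts always have disjoint channel support. `invert = TRUE` swaps the
#' groups before differencing — the natural call for deficiency-driven
#' features such as MLH1, where low expression is the mutagenic state.
#'
#' The per-sample-mean default keeps a single hypermutant genome from
#' dominating its group; `pooled = TRUE` instead sums raw counts within each
#' group before normalizing.
#'
#' @param spectra `mutation_spectra` (or samples x 96 count matrix).
#' @param high_ids,low_ids Disjoint character vectors of sample ids; every
#'   sample needs at least one SNV.
#' @param invert Swap the roles of the two groups.
#' @param pooled Use pooled group counts instead of means of per-sample
#'   frequencies.
#' @param feature_name Label carried on the result.
#' @param min_group Hard minimum group size (default 3); below 10 a warning
#'   is issued because 96-bin mean frequencies from tiny groups are noisy.
#' @return Object of class `signature_pair`: `feature_name`, `pos`, `neg`
#'   (96 frequencies each, disjoint support), `raw_differential` (signed),
#'   `n_high`, `n_low`.
#' @export
differential_signature <- function(spectra, high_ids, low_ids, invert = FALSE,
                                   pooled = FALSE, feature_name = NULL,
                                   min_group = 3L) {
  counts <- .spectra_counts(spectra)
  high_ids <- as.character(high_ids)
  low_ids <- as.character(low_ids)
  if (length(intersect(high_ids, low_ids))) stop("high and low groups must be disjoint")
  missing_ids <- setdiff(c(high_ids, low_ids), rownames(counts))
  if (length(missing_ids)) {
    stop("no spectrum for sample(s): ", paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  if (invert) {
    tmp <- high_ids
    high_ids <- low_ids
    low_ids <- tmp
  }
  if (length(high_ids) < min_group || length(low_ids) < min_group) {
    stop("group smaller than min_group = ", min_group)
  }
  if (length(high_ids) < 10L || length(low_ids) < 10L) {
    warning("group with fewer than 10 samples: differential will be noisy")
  }

  grp_freq <- function(ids) {
    m <- counts[ids, , drop = FALSE]
    if (any(rowSums(m) == 0)) stop("sample(s) with zero SNVs in a stratified group")
    if (pooled) {
      tot <- colSums(m)
      tot / sum(tot)
    } else {
      colMeans(m / rowSums(m))
    }
  }
  raw <- grp_freq(high_ids) - grp_freq(low_ids)
  if (all(raw == 0)) stop("identical group spectra: empty differential signature")

  pos_raw <- pmax(raw, 0)
  neg_raw <- pmax(-raw, 0)
  pos <- if (sum(pos_raw) > 0) pos_raw / sum(pos_raw) else pos_raw
  neg <- if (sum(neg_raw) > 0) neg_raw / sum(neg_raw) else neg_raw
  structure(
    list(
      feature_name = if (is.null(feature_name)) "feature" else as.character(feature_name),
      pos = pos,
      neg = neg,
      raw_differential = raw,
      n_high = length(high_ids),
      n_low = length(low_ids)
    ),
    class = "signature_pair"
  )
}

#' @export
print.signature_pair <- function(x, ...) {
  top <- function(v) {
    nz <- sort(v[v > 0], decreasing = TRUE)
    paste(utils::head(names(nz), 3L), collapse = ", ")
  }
  cat(sprintf(
    "signature_pair '%s' (n_high = %d, n_low = %d)\n  pos top channels: %s\n  neg top channels: %s\n",
    x$feature_name, x$n_high, x$n_low, top(x$pos), top(x$neg)
  ))
  invisible(x)
}

#' Derive a feature-driven signature pair in one call
#'
#' Convenience wrapper: stratifies samples on a feature and computes the
#' differential signature pair between the resulting groups.
#'
#' @inheritParams stratify_samples
#' @inheritParams differential_signature
#' @param feature_values Named numeric feature vector.
#' @return A `signature_pair` (see [differential_signature()]).
#' @export
derive_feature_signature <- function(spectra, feature_values,
                                     mode = c("percentile", "median", "binary"),
                                     hi_q = 0.95, lo_q = 0.05, invert = FALSE,
                                     pooled = FALSE, feature_name = NULL,
                                     min_group = 3L) {
  groups <- stratify_samples(feature_values, mode = mode, hi_q = hi_q, lo_q = lo_q)
  differential_signature(spectra, groups$high, groups$low,
    invert = invert,
    pooled = pooled, feature_name = feature_name, min_group = min_group
  )
}

#' Write a signature pair as a 96-row TSV
#'
#' Columns: `channel`, `pos`, `neg`, `raw` (the signed differential).
#'
#' @param pair A `signature_pair`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_pair_tsv <- function(pair, path) {
  stopifnot(inherits(pair, "signature_pair"))
  df <- data.frame(
    channel = channel_labels(),
    pos = pair$pos,
    neg = pair$neg,
    raw = pair$raw_differential,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_signature_pair_tsv
#' @param feature_name Label for the re-read pair.
#' @export
read_signature_pair_tsv <- function(path, feature_name = NULL) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ord <- match(channel_labels(), df$channel)
  if (anyNA(ord)) stop("signature-pair TSV does not cover all 96 channels")
  structure(
    list(
      feature_name = if (is.null(feature_name)) "feature" else feature_name,
      pos = stats::setNames(df$pos[ord], channel_labels()),
      neg = stats::setNames(df$neg[ord], channel_labels()),
      raw_differential = stats::setNames(df$raw[ord], channel_labels()),
      n_high = NA_integer_,
      n_low = NA_integer_
    ),
    class = "signature_pair"
  )
}
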