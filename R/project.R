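#' Estimate per-genome levels of a signature pair by metagene projection
#'
#' Stacks the positive and negative signatures of a pair into a 96 x 2 basis
#' `M = [pos, neg]` and, for each genome, applies the Moore-Penrose
#' generalized pseudoinverse of `M` to the genome's normalized 96-channel
#' frequency vector, yielding one level per signature — the metagene
#' projection used to read a feature score back out of mutation profiles.
#' Spectra are normalized per sample (frequencies summing to 1); no
#' across-genome standardization is applied.
#'
#' The unconstrained pseudoinverse can return negative levels on genomes
#' whose spectra lie outside the cone of the pair; these are reported as-is
#' (with a one-line warning giving the count). `nonneg = TRUE` instead solves
#' the per-sample nonnegative least-squares problem `min || f - M s ||`,
#' `s >= 0`. When the unconstrained solution is already nonnegative the two
#' modes agree.
#'
#' @param spectra `mutation_spectra` or samples x 96 count matrix; every
#'   sample needs at least one SNV.
#' @param pair A `signature_pair` with linearly independent, nonzero `pos`
#'   and `neg`.
#' @param nonneg Constrain levels to be nonnegative (default `FALSE`).
#' @return `data.frame` with `sample_id`, `pos_level`, `neg_level`; the pair
#'   name is attached as attribute `pair_name`.
#' @export
project_levels <- function(spectra, pair, nonneg = FALSE) {
  stopifnot(inherits(pair, "signature_pair"))
  M <- cbind(pos = as.numeric(pair$pos), neg = as.numeric(pair$neg))
  if (any(colSums(abs(M)) == 0)) {
    stop("singular pair: pos and neg must both be nonzero")
  }
  cs <- sum(M[, 1L] * M[, 2L]) / sqrt(sum(M[, 1L]^2) * sum(M[, 2L]^2))
  if (abs(cs) > 1 - 1e-10) {
    stop("singular pair: pos and neg are collinear")
  }
  f <- normalize_spectrum(spectra) # samples x 96

  if (nonneg) {
    lv <- t(vapply(seq_len(nrow(f)), function(i) {
      pracma::lsqnonneg(M, as.numeric(f[i, ]))$x
    }, numeric(2L)))
  } else {
    lv <- f %*% t(MASS::ginv(M))
    n_neg <- sum(lv < 0)
    if (n_neg > 0) {
      warning(n_neg, " negative projected level(s); use nonneg = TRUE to constrain")
    }
  }
  out <- data.frame(
    sample_id = rownames(f),
    pos_level = lv[, 1L],
    neg_level = lv[, 2L],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "pair_name") <- pair$feature_name
  out
}

#' Concordance of projected levels with a reference score
#'
#' Pearson correlations of `pos_level` and `neg_level` against the feature
#' score the pair was derived from. For a pair derived from the score itself,
#' the expected sign pattern is a positive `r_pos` and a negative `r_neg`.
#'
#' @param result Output of [project_levels()].
#' @param scores Named numeric vector of reference scores (names = sample
#'   ids); at least 3 overlapping non-missing pairs are required.
#' @return Named numeric vector `c(r_pos = ..., r_neg = ...)`.
#' @export
score_concordance <- function(result, scores) {
  if (is.null(names(scores))) stop("scores must be named by sample id")
  idx <- match(result$sample_id, names(scores))
  s <- as.numeric(scores)[idx]
  keep <- !is.na(s) & !is.na(result$pos_level) & !is.na(result$neg_level)
  if (sum(keep) < 3L) stop("need at least 3 overlapping samples with scores")
  s <- s[keep]
  if (stats::sd(s) == 0 || stats::sd(result$pos_level[keep]) == 0 ||
    stats::sd(result$neg_level[keep]) == 0) {
    stop("undefined correlation: zero variance in levels or scores")
  }
  c(
    r_pos = stats::cor(result$pos_level[keep], s),
    r_neg = stats::cor(result$neg_level[keep], s)
  )
}
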