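#' Rank features by Pearson correlation with a response
#'
#' The correlative layer that links TMB or a signature level to per-sample
#' molecular features (gene expression, promoter methylation, scores): one
#' Pearson correlation per feature over the samples where both values are
#' non-missing, with two-sided p-values, Benjamini-Hochberg q-values, and
#' rows sorted by `r`. Log transforms use `log2(x + 1)`, the usual scale for
#' RSEM-like expression values and TMB.
#'
#' @param response Named numeric vector (names = sample ids), e.g. TMB or a
#'   signature level column.
#' @param features `data.frame` or matrix of features: one column per
#'   feature, rownames (or a `sample_id` column) identifying samples.
#' @param log_response,log_features Apply `log2(x + 1)` to the respective
#'   side (values must be nonnegative).
#' @return `data.frame` with columns `feature`, `r`, `p`, `n`, `q`, sorted by
#'   `r`; features with zero variance or fewer than 3 complete pairs carry
#'   `NA` statistics.
#' @export
correlate_features <- function(response, features, log_response = FALSE,
                               log_features = FALSE) {
  if (is.null(names(response))) stop("response must be named by sample id")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(features)) {
    rownames(features) <- as.character(features$sample_id)
    features$sample_id <- NULL
  }
  if (is.null(rownames(features))) stop("features must identify samples (rownames or sample_id)")
  common <- intersect(names(response), rownames(features))
  if (length(common) < 3L) stop("fewer than 3 samples shared between response and features")
  y <- as.numeric(response[common])
  if (log_response) {
    if (any(y < 0, na.rm = TRUE)) stop("log_response requires nonnegative values")
    y <- log2(y + 1)
  }
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    stop("zero variance in response")
  }

  one <- function(x) {
    x <- as.numeric(x)
    if (log_features) {
      if (any(x < 0, na.rm = TRUE)) stop("log_features requires nonnegative values")
      x <- log2(x + 1)
    }
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    if (n < 3L || stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
      return(c(r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  stats_m <- t(vapply(features[common, , drop = FALSE], one, numeric(3L)))
  out <- data.frame(
    feature = colnames(features),
    r = stats_m[, "r"],
    p = stats_m[, "p"],
    n = as.integer(stats_m[, "n"]),
    stringsAsFactors = FALSE
  )
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-split four-class stratification on two features
#'
#' Classifies every sample with both features non-missing into one of four
#' classes by the medians of the two features ("hi" is strictly above the
#' median, "lo" at or below it): `a_hi_b_hi`, `a_hi_b_lo`, `a_lo_b_hi`,
#' `a_lo_b_lo`. This is the layout behind contrasts such as
#' APOBEC3A-high/NHEJ1-low versus APOBEC3A-high/NHEJ1-high.
#'
#' @param feat_a,feat_b Named numeric vectors (names = sample ids).
#' @return Named factor with the four class levels.
#' @export
four_class_stratify <- function(feat_a, feat_b) {
  if (is.null(names(feat_a)) || is.null(names(feat_b))) {
    stop("features must be named by sample id")
  }
  common <- intersect(names(feat_a)[!is.na(feat_a)], names(feat_b)[!is.na(feat_b)])
  if (length(common) < 2L) stop("need at least 2 samples with both features")
  a <- as.numeric(feat_a[common])
  b <- as.numeric(feat_b[common])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate stratification: constant feature")
  }
  lab <- paste0(
    "a_", ifelse(a > stats::median(a), "hi", "lo"),
    "_b_", ifelse(b > stats::median(b), "hi", "lo")
  )
  factor(stats::setNames(lab, common),
    levels = c("a_hi_b_hi", "a_hi_b_lo", "a_lo_b_hi", "a_lo_b_lo")
  )
}

#' Welch t-test between two stratification classes
#'
#' Compares a per-sample level (TMB or signature level) between two classes
#' of a stratification with a two-sample t-test not assuming equal variances.
#'
#' @param levels Named numeric vector of levels (names = sample ids).
#' @param classes Named factor as returned by [four_class_stratify()] (or any
#'   named class labels).
#' @param pair Character vector of length 2: the two classes to compare.
#' @return List with `t`, `p`, `means` (named per class), `ns` (named per
#'   class).
#' @export
compare_levels <- function(levels, classes, pair) {
  if (length(pair) != 2L) stop("pair must name exactly 2 classes")
  if (is.null(names(levels)) || is.null(names(classes))) {
    stop("levels and classes must be named by sample id")
  }
  pick <- function(cl) {
    ids <- names(classes)[!is.na(classes) & classes == cl]
    v <- levels[intersect(ids, names(levels))]
    v[!is.na(v)]
  }
  x <- pick(pair[1L])
  y <- pick(pair[2L])
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: each class needs at least 2 samples with levels")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(
    t = unname(tt$statistic),
    p = tt$p.value,
    means = stats::setNames(c(mean(x), mean(y)), pair),
    ns = stats::setNames(c(length(x), length(y)), pair)
  )
}
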