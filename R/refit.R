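#' Refit known-signature exposures for one spectrum
#'
#' Estimates nonnegative contributions ("exposures") of catalog signatures to
#' one observed spectrum: the normalized 96-channel frequency vector `f` is
#' decomposed as `f ~ t(P) %*% w`, `w >= 0`, by nonnegative least squares;
#' signatures whose relative weight falls below `min_weight` are then zeroed
#' and the remaining subcatalog is re-fit (the same role as the 6% cutoff in
#' iterative refitting tools). Samples with fewer than `min_mutations` SNVs
#' are not fit: they return an excluded record rather than an error, since
#' low-burden genomes carry too little spectral information.
#'
#' Weights depend only on the normalized frequencies, so exposures are scale
#' invariant given the mutation-count gate. A plain NNLS optimum can exceed
#' total mass 1 by a small margin on noisy spectra; in that case weights are
#' rescaled to sum 1. With `renormalize = TRUE` weights are always rescaled
#' to proportions summing to 1.
#'
#' @param x A 96-channel count vector, or a `mutation_spectra` object with a
#'   single row.
#' @param catalog A [signature_catalog()].
#' @param min_mutations Minimum SNV count to attempt a fit (default 50).
#' @param min_weight Relative-weight cutoff below which a signature is
#'   dropped and the fit repeated (default 0.06).
#' @param renormalize Rescale final weights to sum to 1 (default `FALSE`:
#'   unexplained mass is left to the residual).
#' @return List of class `exposure_fit`: `weights` (named, length K),
#'   `counts` (`weights * n_snv`), `residual` (L2 reconstruction error on
#'   frequencies), `n_snv`, `excluded` (logical).
#' @export
refit_exposures <- function(x, catalog, min_mutations = 50L, min_weight = 0.06,
                            renormalize = FALSE) {
  stopifnot(inherits(catalog, "signature_catalog"))
  if (inherits(x, "mutation_spectra")) {
    if (nrow(x$counts) != 1L) stop("pass a single-sample spectrum or use exposure_matrix()")
    x <- x$counts[1L, ]
  }
  x <- as.numeric(x)
  if (length(x) != 96L) stop("spectrum and catalog channel dimensions disagree")
  n_snv <- sum(x)
  k <- nrow(catalog)
  empty <- rep(NA_real_, k)
  names(empty) <- rownames(catalog)
  if (n_snv < min_mutations) {
    return(structure(
      list(
        weights = empty, counts = empty, residual = NA_real_,
        n_snv = n_snv, excluded = TRUE
      ),
      class = "exposure_fit"
    ))
  }

  f <- x / n_snv
  A <- t(unclass(catalog)) # 96 x K
  w <- .nnls_fit(A, f)
  if (min_weight > 0 && sum(w) > 0) {
    keep <- w / sum(w) >= min_weight
    if (!all(keep) && any(keep)) {
      w2 <- numeric(k)
      w2[keep] <- .nnls_fit(A[, keep, drop = FALSE], f)
      w <- w2
    } else if (!any(keep)) {
      w <- numeric(k)
    }
  }
  s <- sum(w)
  if (renormalize && s > 0) {
    w <- w / s
  } else if (s > 1) {
    w <- w / s
  }
  residual <- sqrt(sum((f - as.vector(A %*% w))^2))
  names(w) <- rownames(catalog)
  structure(
    list(
      weights = w, counts = w * n_snv, residual = residual,
      n_snv = n_snv, excluded = FALSE
    ),
    class = "exposure_fit"
  )
}

.nnls_fit <- function(A, f) {
  fit <- pracma::lsqnonneg(A, f)
  pmax(fit$x, 0)
}

#' @export
print.exposure_fit <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("exposure_fit: excluded (%d SNVs below threshold)\n", x$n_snv))
  } else {
    nz <- x$weights[x$weights > 0]
    cat(sprintf(
      "exposure_fit: %d SNVs, %d active signature(s), residual %.4g\n",
      x$n_snv, length(nz), x$residual
    ))
    print(round(sort(nz, decreasing = TRUE), 4L))
  }
  invisible(x)
}

#' Exposure table for a cohort of spectra
#'
#' Applies [refit_exposures()] to every sample. Samples below the mutation
#' threshold yield rows of `NA` weights with `excluded = TRUE`; the result is
#' deterministic given its inputs.
#'
#' @param spectra A `mutation_spectra` object (or samples x 96 count matrix).
#' @param catalog A [signature_catalog()].
#' @param type `"weights"` for proportional contributions, `"counts"` for
#'   estimated mutation counts per signature (`weights * n_snv`). Both are
#'   legitimate "signature level" scales for downstream correlation.
#' @inheritParams refit_exposures
#' @return `data.frame` with `sample_id`, one column per signature,
#'   `residual`, `n_snv`, `excluded`.
#' @export
exposure_matrix <- function(spectra, catalog, type = c("weights", "counts"),
                            min_mutations = 50L, min_weight = 0.06,
                            renormalize = FALSE) {
  type <- match.arg(type)
  counts <- .spectra_counts(spectra)
  fits <- lapply(seq_len(nrow(counts)), function(i) {
    refit_exposures(counts[i, ], catalog,
      min_mutations = min_mutations,
      min_weight = min_weight, renormalize = renormalize
    )
  })
  vals <- t(vapply(fits, function(fit) fit[[type]], numeric(nrow(catalog))))
  out <- data.frame(
    sample_id = rownames(counts),
    vals,
    residual = vapply(fits, `[[`, numeric(1L), "residual"),
    n_snv = vapply(fits, `[[`, numeric(1L), "n_snv"),
    excluded = vapply(fits, `[[`, logical(1L), "excluded"),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
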