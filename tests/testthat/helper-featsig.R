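# Shared fixtures and independent oracles, all built in code.

# --- tiny reference + mutation-table helpers -----------------------------

# single-chromosome toy reference
toy_reference <- function(seq = "GGACGTTACGTACCA", name = "chr1") {
  stats::setNames(toupper(seq), name)
}

# reverse-complement a reference (named character vector), per chromosome
mirror_reference <- function(seqs) {
  out <- vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), NULL)[[1L]]), collapse = "")
  }, character(1L))
  stats::setNames(out, names(seqs))
}

# map a mutation table onto the mirrored reference: pos -> L - pos + 1,
# alleles complemented (strand flip leaves indel "-" markers untouched)
mirror_mutations <- function(mut, seqs) {
  out <- mut
  out$pos <- nchar(seqs)[mut$chrom] - mut$pos + 1L
  out$ref <- chartr("ACGT", "TGCA", mut$ref)
  out$alt <- chartr("ACGT", "TGCA", mut$alt)
  out
}

# --- independent refitting oracle ----------------------------------------

# exhaustive simplex grid search (sum(w) <= 1) minimizing ||f - t(P) w||^2;
# independent of the NNLS path used by the package
grid_search_weights <- function(f, P, step = 0.01) {
  K <- nrow(P)
  stopifnot(K <= 3L)
  A <- t(unclass(P))
  g <- seq(0, 1, by = step)
  W <- as.matrix(do.call(expand.grid, rep(list(g), K)))
  W <- W[rowSums(W) <= 1 + 1e-9, , drop = FALSE]
  G <- crossprod(A)
  b <- as.vector(crossprod(A, f))
  obj <- rowSums((W %*% G) * W) - 2 * as.vector(W %*% b)
  w <- W[which.min(obj), ]
  stats::setNames(as.numeric(w), rownames(P))
}

# --- misc ----------------------------------------------------------------

# counts vector (length 96) with given channel counts
counts96 <- function(...) {
  x <- integer(96L)
  v <- c(...)
  x[as.integer(names(v))] <- as.integer(v)
  x
}

# a signature_pair built directly from two profile vectors
manual_pair <- function(pos, neg, name = "manual") {
  structure(
    list(
      feature_name = name,
      pos = pos / sum(pos),
      neg = neg / sum(neg),
      raw_differential = pos / sum(pos) - neg / sum(neg),
      n_high = NA_integer_,
      n_low = NA_integer_
    ),
    class = "signature_pair"
  )
}
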