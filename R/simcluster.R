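#' Cosine similarity between two 96-channel signatures
#'
#' `a . b / (||a|| ||b||)`; for nonnegative signature vectors the value lies
#' in `[0, 1]`, 1 for proportional vectors and 0 for disjoint support. Scale
#' invariant: `cosine_similarity(a, c * a) == 1` for any `c > 0`.
#'
#' @param a,b Numeric vectors of equal length with positive norm.
#' @return A single numeric similarity.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined similarity: zero vector")
  sum(a * b) / (na * nb)
}

# Coerce catalog / signature_pair parts / named list of vectors / matrix
# into a named signatures x 96 matrix.
.as_signature_matrix <- function(x) {
  if (inherits(x, "signature_catalog")) {
    return(unclass(x))
  }
  if (inherits(x, "signature_pair")) {
    m <- rbind(x$pos, x$neg)
    rownames(m) <- paste0(x$feature_name, c(".pos", ".neg"))
    return(m)
  }
  if (is.list(x) && !is.data.frame(x)) {
    m <- do.call(rbind, lapply(x, as.numeric))
    rownames(m) <- if (is.null(names(x))) paste0("sig", seq_along(x)) else names(x)
    return(m)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("sig", seq_len(nrow(m)))
  m
}

#' Pairwise cosine-similarity matrix of signatures
#'
#' @param signatures A `signature_catalog`, a named list of 96-vectors, or a
#'   signatures x 96 matrix (at least 2 rows). Multiple inputs are row-bound,
#'   so a catalog and a derived signature can be compared in one call.
#' @param ... Further signature sets to append.
#' @return Symmetric matrix with unit diagonal.
#' @export
similarity_matrix <- function(signatures, ...) {
  parts <- c(list(signatures), list(...))
  m <- do.call(rbind, lapply(parts, .as_signature_matrix))
  if (nrow(m) < 2L) stop("need at least 2 signatures")
  if (anyDuplicated(rownames(m))) stop("signature names must be unique")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("undefined similarity: zero vector")
  s <- (m / nrm) %*% t(m / nrm)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

#' Hierarchical clustering of signatures on cosine distance
#'
#' Agglomerative clustering on distance `1 - cosine` — the standard way to
#' ask which known signatures a derived signature segregates with. Leaves are
#' ordered lexicographically by name before clustering so that merge order is
#' deterministic under input permutation and renaming.
#'
#' @inheritParams similarity_matrix
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An [stats::hclust] tree.
#' @export
hcluster <- function(signatures, ..., linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  s <- similarity_matrix(signatures, ...)
  ord <- order(rownames(s))
  s <- s[ord, ord, drop = FALSE]
  stats::hclust(stats::as.dist(1 - s), method = linkage)
}

#' Export a signature dendrogram as a Newick string
#'
#' @param hc An [stats::hclust] tree from [hcluster()].
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when `path` is given).
#' @export
signature_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) {
    return(ape::write.tree(phy))
  }
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Nearest known signature to a derived signature
#'
#' @param derived A 96-channel signature vector (e.g. the `pos` part of a
#'   [differential_signature()] pair).
#' @param catalog A [signature_catalog()] (nonempty).
#' @return List with `name` and `similarity`; ties broken lexicographically.
#' @export
nearest_known <- function(derived, catalog) {
  stopifnot(inherits(catalog, "signature_catalog"))
  sims <- vapply(seq_len(nrow(catalog)), function(i) {
    cosine_similarity(derived, catalog[i, ])
  }, numeric(1L))
  names(sims) <- rownames(catalog)
  ord <- order(-sims, names(sims))
  list(name = names(sims)[ord[1L]], similarity = unname(sims[ord[1L]]))
}

#' Members of the cluster a signature first joins
#'
#' Walks the merge table of an [hcluster()] tree and returns the labels of
#' the cluster formed by the first merge involving `label` — i.e. the
#' signatures it co-segregates with most tightly (useful for asking whether
#' a derived signature first joins, say, the APOBEC branch of a catalog).
#'
#' @param hc An [stats::hclust] tree.
#' @param label Leaf label of interest.
#' @return Character vector of labels in that first cluster, excluding
#'   `label` itself.
#' @export
first_merge_partners <- function(hc, label) {
  stopifnot(inherits(hc, "hclust"))
  leaf <- match(label, hc$labels)
  if (is.na(leaf)) stop("label not found in tree: ", label)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members[[i]] <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) -j else members[[j]]
    }))
    if (leaf %in% members[[i]]) {
      return(setdiff(hc$labels[members[[i]]], label))
    }
  }
  character(0)
}
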