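#' Signature catalog (K x 96 row-stochastic matrix)
#'
#' A catalog of mutational signatures: one row per signature, 96 columns in
#' canonical channel order, each row a probability distribution over the
#' channels (sums to 1 within `1e-6`). Signature names must be unique.
#'
#' @param profiles Numeric K x 96 matrix (rows = signatures).
#' @param names Signature names (defaults to `rownames(profiles)`).
#' @param renormalize If `TRUE`, rescale each row to sum exactly 1 instead of
#'   erroring on rows that deviate by more than `1e-6`.
#' @return A matrix of class `signature_catalog`.
#' @export
signature_catalog <- function(profiles, names = rownames(profiles), renormalize = FALSE) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 96L) stop("signature profiles must have 96 channels")
  if (nrow(profiles) < 1L) stop("catalog must contain at least one signature")
  if (any(profiles < 0)) stop("signature profiles must be nonnegative")
  if (is.null(names)) names <- paste0("Signature.", seq_len(nrow(profiles)))
  names <- as.character(names)
  if (anyDuplicated(names)) stop("signature names must be unique")
  rs <- rowSums(profiles)
  if (any(rs <= 0)) stop("signature rows must have positive mass")
  if (renormalize) {
    profiles <- profiles / rs
  } else if (any(abs(rs - 1) > 1e-6)) {
    stop("signature rows must sum to 1 (within 1e-6); use renormalize = TRUE")
  }
  dimnames(profiles) <- list(names, channel_labels())
  class(profiles) <- c("signature_catalog", class(profiles))
  profiles
}

#' @export
print.signature_catalog <- function(x, ...) {
  cat(sprintf("signature_catalog: %d signatures x 96 channels\n", nrow(x)))
  cat("  ", paste(utils::head(rownames(x), 8L), collapse = ", "),
    if (nrow(x) > 8L) ", ..." else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' Read a COSMIC v2-style 30-signature TSV
#'
#' Parses the classic COSMIC v2 layout: 96 rows, columns `Substitution Type`,
#' `Trinucleotide`, `Somatic Mutation Type`, then one column per signature.
#' Rows are reordered to the canonical channel order regardless of file
#' order, and the matrix is transposed to K x 96.
#'
#' @param path Path to the TSV.
#' @param renormalize Passed to [signature_catalog()]; COSMIC files carry
#'   rounded probabilities, so `TRUE` (default) rescales rows to sum to 1.
#' @return A `signature_catalog`.
#' @export
read_cosmic_catalog <- function(path, renormalize = TRUE) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  key_col <- grep("Somatic Mutation Type", names(df), fixed = TRUE, value = TRUE)
  if (!length(key_col)) stop("not a COSMIC v2 catalog: no 'Somatic Mutation Type' column")
  keys <- as.character(df[[key_col]])
  ord <- match(channel_labels(), keys)
  if (anyNA(ord)) stop("COSMIC catalog does not cover all 96 channels")
  meta <- c("Substitution Type", "Trinucleotide", key_col)
  sig_cols <- setdiff(names(df), meta)
  sig_cols <- sig_cols[vapply(df[sig_cols], is.numeric, logical(1L))]
  if (!length(sig_cols)) stop("no numeric signature columns found")
  m <- t(as.matrix(df[ord, sig_cols, drop = FALSE]))
  signature_catalog(m, names = sig_cols, renormalize = renormalize)
}

#' Read / write a plain K x 96 signature matrix TSV
#'
#' Plain dialect: one row per signature, first column `signature`, remaining
#' 96 columns labeled with the canonical channel labels in any order.
#'
#' @param path TSV path.
#' @param catalog A `signature_catalog` (for writing).
#' @param renormalize Passed to [signature_catalog()].
#' @return `read_catalog_tsv()` returns a `signature_catalog`;
#'   `write_catalog_tsv()` returns `path` invisibly.
#' @export
read_catalog_tsv <- function(path, renormalize = FALSE) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  labs <- channel_labels()
  missing_cols <- setdiff(labs, names(df))
  if (length(missing_cols)) {
    stop("catalog TSV is missing ", length(missing_cols), " channel column(s)")
  }
  m <- as.matrix(df[, labs, drop = FALSE])
  nm <- if ("signature" %in% names(df)) as.character(df$signature) else NULL
  signature_catalog(m, names = nm, renormalize = renormalize)
}

#' @rdname read_catalog_tsv
#' @export
write_catalog_tsv <- function(catalog, path) {
  stopifnot(inherits(catalog, "signature_catalog"))
  df <- data.frame(
    signature = rownames(catalog),
    unclass(catalog),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
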