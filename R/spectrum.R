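#' Per-sample 96-channel mutation spectra
#'
#' Container for a cohort of 96-channel trinucleotide spectra. `counts` holds
#' one row per sample in canonical channel order ([channel_labels()]); `tmb`
#' is the tumor mutation burden (all accepted somatic calls: SNVs plus short
#' indels and other non-SNV substitutions), which is always `>=` the SNV count
#' because only SNVs populate channels. Samples with fewer than `min_snv`
#' SNVs are flagged ineligible for signature analysis but kept for TMB-level
#' analyses.
#'
#' @param counts Integer matrix, samples x 96, rownames = sample ids.
#' @param tmb Optional named/numeric vector of total mutation burdens
#'   (defaults to the per-sample SNV count).
#' @param min_snv Eligibility threshold on the SNV count (default 50).
#' @return An object of class `mutation_spectra` with elements `counts`,
#'   `n_snv`, `tmb`, `eligible`, `min_snv`.
#' @export
new_spectra <- function(counts, tmb = NULL, min_snv = 50L) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 96L) stop("spectra must have 96 channels, got ", ncol(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("spectrum counts must be nonnegative integers")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%03d", seq_len(nrow(counts)))
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- channel_labels()
  n_snv <- rowSums(counts)
  if (is.null(tmb)) tmb <- n_snv
  tmb <- rep_len(as.numeric(tmb), nrow(counts))
  names(tmb) <- rownames(counts)
  if (any(tmb < n_snv)) stop("tmb must be >= the per-sample SNV count")
  structure(
    list(
      counts = counts,
      n_snv = n_snv,
      tmb = tmb,
      eligible = n_snv >= min_snv,
      min_snv = min_snv
    ),
    class = "mutation_spectra"
  )
}

#' @export
print.mutation_spectra <- function(x, ...) {
  cat(sprintf(
    "mutation_spectra: %d samples x 96 channels; %d eligible (>= %d SNVs)\n",
    nrow(x$counts), sum(x$eligible), x$min_snv
  ))
  cat(sprintf(
    "  SNVs/sample: median %s [%s-%s]; TMB/sample: median %s\n",
    format(stats::median(x$n_snv)), format(min(x$n_snv)), format(max(x$n_snv)),
    format(stats::median(x$tmb))
  ))
  invisible(x)
}

#' @export
as.matrix.mutation_spectra <- function(x, ...) x$counts

#' @export
dim.mutation_spectra <- function(x) dim(x$counts)

.spectra_counts <- function(x) {
  if (inherits(x, "mutation_spectra")) {
    return(x$counts)
  }
  m <- as.matrix(x)
  if (is.null(dim(m)) || ncol(m) == 1L) m <- matrix(as.numeric(m), nrow = 1L)
  if (ncol(m) != 96L) stop("expected a 96-channel spectrum matrix")
  m
}

#' Normalize spectra to per-sample trinucleotide frequencies
#'
#' Divides each spectrum by its total so channel values sum to 1. Accepts a
#' single 96-vector, a samples x 96 matrix, or a [new_spectra()] object.
#'
#' @param x Counts (vector, matrix, or `mutation_spectra`).
#' @return Frequencies in the same shape as the input (matrix for
#'   `mutation_spectra`).
#' @export
normalize_spectrum <- function(x) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 96L) stop("expected a 96-channel spectrum")
    s <- sum(x)
    if (s <= 0) stop("cannot normalize an all-zero spectrum")
    return(x / s)
  }
  m <- .spectra_counts(x)
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    stop(
      "cannot normalize all-zero spectra: ",
      paste(utils::head(rownames(m)[tot <= 0], 5L), collapse = ", ")
    )
  }
  m / tot
}

# ---- reference genome handling ------------------------------------------

# Accepts a FASTA path, a Biostrings::DNAStringSet, or a named character
# vector of chromosome sequences; returns a named character vector. The whole
# reference is held in memory as character data, which is appropriate for the
# targeted-context and synthetic references this package works with.
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(toupper(seqs))
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(toupper(reference))
  }
  stop("reference must be a FASTA path, a DNAStringSet, or a named character vector")
}

# ---- mutation table readers ---------------------------------------------

#' Read somatic mutations from a MAF-dialect table
#'
#' Reads the tab-separated MAF dialect used by TCGA PanCanAtlas. Required
#' columns: `Tumor_Sample_Barcode`, `Chromosome`, `Start_Position`,
#' `Reference_Allele`, `Tumor_Seq_Allele2`; `Variant_Type` is used when
#' present, otherwise the class is inferred from the alleles.
#'
#' @param path Path to the MAF file (plain text, tab separated).
#' @return A `data.frame` with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class` (one of `SNV`, `INS`, `DEL`, `other`).
#' @export
read_maf <- function(path) {
  req <- c(
    "Tumor_Sample_Barcode", "Chromosome", "Start_Position",
    "Reference_Allele", "Tumor_Seq_Allele2"
  )
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("MAF is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    sample_id = as.character(dt$Tumor_Sample_Barcode),
    chrom = as.character(dt$Chromosome),
    pos = as.integer(dt$Start_Position),
    ref = toupper(as.character(dt$Reference_Allele)),
    alt = toupper(as.character(dt$Tumor_Seq_Allele2)),
    stringsAsFactors = FALSE
  )
  out$variant_class <- if ("Variant_Type" %in% names(dt)) {
    .map_variant_type(as.character(dt$Variant_Type), out$ref, out$alt)
  } else {
    .infer_variant_class(out$ref, out$alt)
  }
  out
}

#' Read somatic mutations from a VCF file
#'
#' Light-weight single-sample VCF reader (via the vcfR package): CHROM, POS,
#' REF and ALT are taken from the fixed fields and every record is assigned
#' to `sample_id`. Multi-allelic ALT entries are split into one record per
#' allele.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @param sample_id Sample identifier to assign to the records.
#' @return A `data.frame` in the same layout as [read_maf()].
#' @export
read_vcf <- function(path, sample_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  out <- data.frame(
    sample_id = as.character(sample_id),
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = toupper(rep(fix$REF, n_alt)),
    alt = toupper(unlist(alt_list)),
    stringsAsFactors = FALSE
  )
  out$variant_class <- .infer_variant_class(out$ref, out$alt)
  out
}

.infer_variant_class <- function(ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref %in% .BASES & alt %in% .BASES & ref != alt
  del <- alt == "-" | (nchar(alt) < nchar(ref) & alt != "-" & ref != "-")
  ins <- ref == "-" | nchar(alt) > nchar(ref)
  cls <- rep("other", length(ref))
  cls[ins] <- "INS"
  cls[del] <- "DEL"
  cls[snv] <- "SNV"
  cls
}

.map_variant_type <- function(vt, ref, alt) {
  cls <- rep("other", length(vt))
  cls[toupper(vt) %in% c("SNP", "SNV")] <- "SNV"
  cls[toupper(vt) == "INS"] <- "INS"
  cls[toupper(vt) == "DEL"] <- "DEL"
  # guard against mislabeled SNVs (e.g. multi-base alleles marked SNP)
  bad_snv <- cls == "SNV" & !(nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% .BASES & alt %in% .BASES & ref != alt)
  cls[bad_snv] <- "other"
  cls
}

# ---- spectrum construction ----------------------------------------------

#' Build 96-channel spectra and TMB from a mutation table
#'
#' Classifies each SNV into its trinucleotide channel using the flanking
#' reference bases at `pos - 1` and `pos + 1` (1-based coordinates, MAF
#' convention) and tallies per-sample spectra. Indels and other non-SNV calls
#' contribute to TMB but to no channel. Records are deduplicated on
#' (sample, chrom, pos, alt); records on chromosomes absent from the
#' reference, with a reference-allele mismatch, or with an ambiguous (non
#' A/C/G/T) context are skipped with a warning.
#'
#' @param mutations `data.frame` with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt` and optionally `variant_class` (inferred when absent), as
#'   returned by [read_maf()] / [read_vcf()].
#' @param reference FASTA path, `DNAStringSet`, or named character vector of
#'   chromosome sequences.
#' @param min_snv Eligibility threshold on SNV count (default 50).
#' @return A [new_spectra()] object, one row per sample present in
#'   `mutations`.
#' @export
build_spectra <- function(mutations, reference, min_snv = 50L) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(req, names(mutations))
  if (length(missing_cols)) {
    stop("mutation table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  mut <- mutations
  mut$sample_id <- as.character(mut$sample_id)
  mut$chrom <- as.character(mut$chrom)
  mut$pos <- as.integer(mut$pos)
  mut$ref <- toupper(as.character(mut$ref))
  mut$alt <- toupper(as.character(mut$alt))
  if (any(mut$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1 (1-based)")
  if (is.null(mut$variant_class)) {
    mut$variant_class <- .infer_variant_class(mut$ref, mut$alt)
  }
  samples <- unique(mut$sample_id)
  seqs <- .as_reference(reference)
  chrom_len <- nchar(seqs)

  # record-level deduplication (same sample/chrom/pos/alt)
  key <- paste(mut$sample_id, mut$chrom, mut$pos, mut$alt, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate mutation record(s) removed")
    mut <- mut[!dup, , drop = FALSE]
  }

  known <- mut$chrom %in% names(seqs)
  if (!all(known)) {
    warning(
      sum(!known), " record(s) on chromosomes absent from the reference skipped"
    )
    mut <- mut[known, , drop = FALSE]
  }

  is_snv <- mut$variant_class == "SNV"
  snv <- mut[is_snv, , drop = FALSE]
  accepted_snv_idx <- integer(0)
  channel <- integer(0)
  if (nrow(snv)) {
    in_range <- snv$pos >= 2L & snv$pos + 1L <= chrom_len[snv$chrom]
    if (!all(in_range)) {
      warning(sum(!in_range), " SNV(s) without full flanking context skipped")
    }
    snv <- snv[in_range, , drop = FALSE]
    tri <- substring(seqs[snv$chrom], snv$pos - 1L, snv$pos + 1L)
    ref_base <- substr(tri, 2L, 2L)
    mism <- ref_base != snv$ref
    if (any(mism)) {
      warning(sum(mism), " SNV(s) with reference-allele mismatch skipped")
      snv <- snv[!mism, , drop = FALSE]
      tri <- tri[!mism]
    }
    p5 <- substr(tri, 1L, 1L)
    p3 <- substr(tri, 3L, 3L)
    ctx_ok <- p5 %in% .BASES & p3 %in% .BASES
    if (!all(ctx_ok)) {
      warning(sum(!ctx_ok), " SNV(s) with ambiguous (non-ACGT) context skipped")
      snv <- snv[ctx_ok, , drop = FALSE]
      p5 <- p5[ctx_ok]
      p3 <- p3[ctx_ok]
    }
    if (nrow(snv)) {
      channel <- classify_substitution(snv$ref, snv$alt, p5, p3)
    }
  }

  non_snv <- mut[!is_snv, , drop = FALSE]
  if (nrow(snv) + nrow(non_snv) == 0L) {
    stop("no mutation records were accepted; cannot build spectra")
  }

  counts <- unclass(table(
    factor(snv$sample_id, levels = samples),
    factor(channel, levels = 1:96)
  ))
  counts <- matrix(as.integer(counts),
    nrow = length(samples),
    dimnames = list(samples, channel_labels())
  )
  other_burden <- table(factor(non_snv$sample_id, levels = samples))
  tmb <- rowSums(counts) + as.numeric(other_burden)
  new_spectra(counts, tmb = tmb, min_snv = min_snv)
}

# ---- spectrum matrix IO -------------------------------------------------

#' Write / read a sample x 96 count matrix as TSV
#'
#' The header row carries the canonical channel labels (`A[C>A]A` ...) plus a
#' leading `sample_id` column and a `tmb` column, so spectra round-trip with
#' their mutation burdens.
#'
#' @param spectra A `mutation_spectra` object.
#' @param path Output (input) TSV path.
#' @param min_snv Eligibility threshold applied on re-reading.
#' @return `write_spectra_tsv()` returns `path` invisibly;
#'   `read_spectra_tsv()` returns a `mutation_spectra` object.
#' @export
write_spectra_tsv <- function(spectra, path) {
  stopifnot(inherits(spectra, "mutation_spectra"))
  df <- data.frame(
    sample_id = rownames(spectra$counts),
    spectra$counts,
    tmb = spectra$tmb,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @export
read_spectra_tsv <- function(path, min_snv = 50L) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  labs <- channel_labels()
  missing_cols <- setdiff(labs, names(df))
  if (length(missing_cols)) {
    stop("spectrum TSV is missing ", length(missing_cols), " channel column(s)")
  }
  counts <- as.matrix(df[, labs, drop = FALSE])
  rownames(counts) <- as.character(df$sample_id)
  tmb <- if ("tmb" %in% names(df)) df$tmb else NULL
  new_spectra(counts, tmb = tmb, min_snv = min_snv)
}
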