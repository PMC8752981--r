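# Canonical 96-channel layout: six substitution blocks C>A, C>G, C>T, T>A,
# T>C, T>G; within a block the 16 flanking contexts ordered lexicographically
# by (5' base, 3' base) over A,C,G,T. Channel 1 = A[C>A]A, channel 96 = T[T>G]T.

.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical labels of the 96 trinucleotide substitution channels
#'
#' Channels are ordered by substitution block (`C>A`, `C>G`, `C>T`, `T>A`,
#' `T>C`, `T>G`) and, within a block, lexicographically by the 5' then the 3'
#' flanking base over `A, C, G, T`. This is the fixed column order of every
#' spectrum and signature matrix in the package.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"` ... `"T[T>G]T"`.
#' @export
#' @examples
#' channel_labels()[c(1, 96)]
channel_labels <- function() {
  labs <- character(96L)
  i <- 0L
  for (s in .SUBS) {
    for (p5 in .BASES) {
      for (p3 in .BASES) {
        i <- i + 1L
        labs[i] <- paste0(p5, "[", s, "]", p3)
      }
    }
  }
  labs
}

#' Classify a single-base substitution into its trinucleotide channel
#'
#' Maps a substitution plus its immediate 5'/3' reference context to one of
#' the 96 canonical channels. Purine-reference mutations (`A`/`G`) are
#' reverse-complemented first — mutation and both flanks — so that every
#' channel is reported on the pyrimidine strand, the standard collapsing
#' behind 96-channel spectra. All arguments are vectorized and recycled.
#'
#' @param ref Reference base(s), one of `A,C,G,T`.
#' @param alt Alternate base(s), one of `A,C,G,T`, different from `ref`.
#' @param five_prime Reference base immediately 5' of the mutated position.
#' @param three_prime Reference base immediately 3' of the mutated position.
#' @return Integer channel index in `1:96` (1 = `A[C>A]A`, 96 = `T[T>G]T`).
#' @export
#' @examples
#' classify_substitution("C", "A", "A", "A") # 1
#' classify_substitution("G", "T", "T", "T") # 1, via reverse complement
#' classify_substitution("T", "G", "T", "T") # 96
classify_substitution <- function(ref, alt, five_prime, three_prime) {
  n <- max(length(ref), length(alt), length(five_prime), length(three_prime))
  ref <- toupper(rep_len(as.character(ref), n))
  alt <- toupper(rep_len(as.character(alt), n))
  five_prime <- toupper(rep_len(as.character(five_prime), n))
  three_prime <- toupper(rep_len(as.character(three_prime), n))

  ok <- ref %in% .BASES & alt %in% .BASES &
    five_prime %in% .BASES & three_prime %in% .BASES & ref != alt
  if (!all(ok)) {
    stop("invalid mutation: ref/alt/flanks must be single A/C/G/T bases with ref != alt")
  }

  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, unname(.COMP[ref]), ref)
  a <- ifelse(pur, unname(.COMP[alt]), alt)
  p5 <- ifelse(pur, unname(.COMP[three_prime]), five_prime)
  p3 <- ifelse(pur, unname(.COMP[five_prime]), three_prime)

  sub_i <- match(paste0(r, ">", a), .SUBS)
  (sub_i - 1L) * 16L + (match(p5, .BASES) - 1L) * 4L + match(p3, .BASES)
}

# channel index -> list(sub, ref, alt, five, three) on the pyrimidine strand
.channel_parts <- function(channel) {
  stopifnot(all(channel >= 1L & channel <= 96L))
  sub_i <- (channel - 1L) %/% 16L + 1L
  rest <- (channel - 1L) %% 16L
  list(
    sub = .SUBS[sub_i],
    ref = substr(.SUBS[sub_i], 1L, 1L),
    alt = substr(.SUBS[sub_i], 3L, 3L),
    five = .BASES[rest %/% 4L + 1L],
    three = .BASES[rest %% 4L + 1L]
  )
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1L)))
}
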