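#' Normalize a nucleotide string to uppercase RNA
#'
#' Input may be DNA or RNA, upper or lower case; `T` is transliterated to `U`.
#' Any character outside `A/C/G/U/T` is an error that names the first offending
#' position, so malformed input fails at ingestion rather than deep inside a
#' folding call.
#'
#' @param seq character scalar, DNA or RNA.
#' @param what label used in error messages.
#' @return uppercase RNA string (A/C/G/U only).
#' @examples
#' normalize_rna("acgt")  # "ACGU"
#' @export
normalize_rna <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  s <- chartr("acgut", "ACGUT", seq)
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGU]", s)
  if (bad != -1L) {
    stop(sprintf("%s contains non-RNA character '%s' at position %d",
                 what, substr(s, bad, bad), bad), call. = FALSE)
  }
  s
}

.COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' Watson-Crick complement (A<->U, C<->G) read 3'->5'. Applying it twice
#' returns the input.
#'
#' @param seq RNA string (normalized with [normalize_rna()] if needed).
#' @return RNA string, the reverse complement.
#' @examples
#' revcomp_rna("GCAU")  # "AUGC"
#' @export
revcomp_rna <- function(seq) {
  s <- normalize_rna(seq)
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

#' Reverse complement of a DNA string
#' @param seq DNA string (A/C/G/T).
#' @return DNA string.
#' @export
revcomp_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (grepl("[^ACGT]", s)) stop("not a DNA string: ", seq, call. = FALSE)
  if (nchar(s) == 0L) return(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Transliterate RNA to DNA (U -> T)
#' @param seq RNA string.
#' @return DNA string.
#' @export
rna_to_dna <- function(seq) chartr("U", "T", normalize_rna(seq))

#' Prepend the U6 +G1 nucleotide when absent
#'
#' Pol-III transcription from the human U6 promoter requires a G at position 1.
#' Returns the sequence unchanged if it already starts with G, otherwise
#' prepends one. Idempotent.
#'
#' @param seq RNA string, non-empty.
#' @return RNA string starting with G.
#' @examples
#' apply_u6_g("ACGU")  # "GACGU"
#' @export
apply_u6_g <- function(seq) {
  s <- normalize_rna(seq)
  if (nchar(s) == 0L) stop("empty sequence", call. = FALSE)
  if (substr(s, 1L, 1L) == "G") s else paste0("G", s)
}

#' GC fraction of a nucleotide string
#' @param seq RNA or DNA string.
#' @return numeric in \[0, 1\]; NaN for the empty string.
#' @export
gc_fraction <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n == 0L) return(NaN)
  gc <- nchar(gsub("[^GC]", "", s))
  gc / n
}

#' Longest homopolymer run in a nucleotide string
#' @param seq RNA or DNA string.
#' @return integer, the maximum run length of a single base (0 for empty input).
#' @export
max_homopolymer_run <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  r <- rle(strsplit(toupper(seq), "")[[1]])
  max(r$lengths)
}
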