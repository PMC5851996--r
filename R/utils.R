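# Internal sequence helpers shared across modules.

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around
#' [Biostrings::reverseComplement()]; accepts IUPAC ambiguity codes.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverseComplementSeq("ACGT")
#' @export
reverseComplementSeq <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## IUPAC code -> set of concrete bases it can stand for
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.splitBases <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.checkACGT <- function(x, what = "sequence") {
  ch <- unique(.splitBases(x))
  bad <- setdiff(ch, c("A", "C", "G", "T"))
  if (length(bad))
    stop(what, " contains non-ACGT character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.checkNucleotide <- function(x, what = "sequence") {
  ch <- unique(.splitBases(x))
  bad <- setdiff(ch, names(.IUPAC_SETS))
  if (length(bad))
    stop(what, " contains non-nucleotide character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## membership of concrete base `base` in the IUPAC set of code `code`,
## vectorised over equal-length character vectors
.iupacContains <- function(code, base) {
  mapply(function(cd, b) b %in% .IUPAC_SETS[[cd]], code, base,
         USE.NAMES = FALSE)
}
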