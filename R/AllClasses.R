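#' Primer: a PCR oligo with orientation and adapter decoration
#'
#' An S4 container for a metabarcoding primer: the core annealing
#' oligonucleotide (no degenerate bases), its orientation, and the optional
#' sequencing-adapter tail and random-base spacer used in two-step library
#' construction.
#'
#' The core is stored 5'-to-3' in primer orientation. For a forward primer
#' the core reads the same as the reference sense strand at a perfectly
#' matched binding site; for a reverse primer the reverse complement of the
#' core appears on the sense strand.
#'
#' @slot name Primer label.
#' @slot core Core oligo sequence, uppercase ACGT only.
#' @slot orientation Either \code{"forward"} or \code{"reverse"}.
#' @slot adapter Optional adapter sequence 5' of the spacer (may be empty).
#' @slot nRandomBases Number of random bases (N spacer) between adapter and
#'   core; non-negative integer.
#'
#' @seealso [Primer()], [mibirdPrimers()]
#' @name Primer-class
#' @aliases Primer-class
#' @exportClass Primer
setClass("Primer",
  representation(
    name = "character",
    core = "character",
    orientation = "character",
    adapter = "character",
    nRandomBases = "integer"
  ),
  prototype(adapter = "", nRandomBases = 0L)
)

setValidity("Primer", function(object) {
  msg <- character()
  if (length(object@core) != 1L || !nzchar(object@core))
    msg <- c(msg, "core must be a single non-empty string")
  else {
    if (object@core != toupper(object@core))
      msg <- c(msg, "core must be uppercase")
    ch <- unique(strsplit(object@core, "")[[1L]])
    if (length(setdiff(ch, c("A", "C", "G", "T"))))
      msg <- c(msg, "core must contain only A, C, G, T (no degenerate bases)")
  }
  if (!object@orientation %in% c("forward", "reverse"))
    msg <- c(msg, "orientation must be 'forward' or 'reverse'")
  if (length(object@adapter) == 1L && nzchar(object@adapter)) {
    ch <- unique(strsplit(toupper(object@adapter), "")[[1L]])
    if (length(setdiff(ch, c("A", "C", "G", "T"))))
      msg <- c(msg, "adapter must contain only A, C, G, T")
  }
  if (is.na(object@nRandomBases) || object@nRandomBases < 0L)
    msg <- c(msg, "nRandomBases must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' ReferencePanel: reference sequences with taxonomy
#'
#' An S4 container pairing a [Biostrings::DNAStringSet] of reference
#' (typically mitogenome or 12S) sequences with a taxonomy table carrying
#' accession, species, genus, family and order for each record. Accessions
#' are unique and key both components.
#'
#' @slot sequences A [Biostrings::DNAStringSet] named by accession.
#' @slot taxonomy A \code{data.frame} with columns \code{accession},
#'   \code{species}, \code{genus}, \code{family}, \code{order}, one row per
#'   sequence, in the same order.
#'
#' @seealso [ReferencePanel()], [readReferencePanel()]
#' @name ReferencePanel-class
#' @aliases ReferencePanel-class
#' @exportClass ReferencePanel
setClass("ReferencePanel",
  representation(
    sequences = "DNAStringSet",
    taxonomy = "data.frame"
  )
)

setValidity("ReferencePanel", function(object) {
  msg <- character()
  tx <- object@taxonomy
  need <- c("accession", "species", "genus", "family", "order")
  if (!all(need %in% names(tx)))
    msg <- c(msg, paste("taxonomy must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(tx$accession))
      msg <- c(msg, "accessions must be unique")
    if (length(object@sequences) != nrow(tx))
      msg <- c(msg, "sequences and taxonomy must have the same length")
    else if (!identical(names(object@sequences), as.character(tx$accession)))
      msg <- c(msg, "sequence names must equal taxonomy accessions, in order")
    if (any(Biostrings::width(object@sequences) == 0L))
      msg <- c(msg, "sequences must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' DetectionTable: sample-by-species read-count matrix
#'
#' Aggregated metabarcoding detections: a read-count matrix indexed by
#' sample (rows) and detected species (columns), plus per-sample counts of
#' reads that could not be assigned to any species (\code{nonTarget} here
#' means unassigned/ambiguous reads; assigned-but-unexpected species keep
#' their own columns).
#'
#' @slot counts Integer matrix, samples x species.
#' @slot unassigned Named integer vector of unassigned/ambiguous reads per
#'   sample (same rownames as \code{counts}).
#'
#' @seealso [detectionTable()], [targetPercentages()], [controlCheck()]
#' @name DetectionTable-class
#' @aliases DetectionTable-class
#' @exportClass DetectionTable
setClass("DetectionTable",
  representation(
    counts = "matrix",
    unassigned = "numeric"
  )
)

setValidity("DetectionTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@counts)))
    msg <- c(msg, "counts must have sample rownames")
  if (!identical(names(object@unassigned), rownames(object@counts)))
    msg <- c(msg, "unassigned must be named by the sample rownames")
  if (any(object@counts < 0) || any(object@unassigned < 0))
    msg <- c(msg, "read counts must be non-negative")
  if (length(msg)) msg else TRUE
})
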