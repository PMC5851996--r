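#' Construct a ReferencePanel
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector of
#'   reference sequences.
#' @param taxonomy \code{data.frame} with columns \code{accession},
#'   \code{species}, \code{genus}, \code{family}, \code{order}, one row
#'   per sequence. Row order must match \code{sequences}; sequence names
#'   are set to the accessions.
#' @return A [ReferencePanel-class] object.
#' @export
ReferencePanel <- function(sequences, taxonomy) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  rownames(taxonomy) <- NULL
  names(sequences) <- as.character(taxonomy$accession)
  methods::new("ReferencePanel", sequences = sequences, taxonomy = taxonomy)
}

#' Accessors for ReferencePanel objects
#'
#' @param x A [ReferencePanel-class] object.
#' @return \code{panelSequences} returns the [Biostrings::DNAStringSet];
#'   \code{panelTaxonomy} the taxonomy \code{data.frame}.
#' @name ReferencePanel-accessors
#' @aliases panelSequences panelTaxonomy
NULL

#' @rdname ReferencePanel-accessors
#' @export
setMethod("panelSequences", "ReferencePanel", function(x) x@sequences)
#' @rdname ReferencePanel-accessors
#' @export
setMethod("panelTaxonomy", "ReferencePanel", function(x) x@taxonomy)

setMethod("length", "ReferencePanel", function(x) length(x@sequences))

setMethod("show", "ReferencePanel", function(object) {
  tx <- object@taxonomy
  cat("ReferencePanel with", length(object), "record(s):",
      length(unique(tx$species)), "species,",
      length(unique(tx$genus)), "genera,",
      length(unique(tx$order)), "order(s)\n")
  cat("  sequence widths:", paste(range(Biostrings::width(object@sequences)),
      collapse = "-"), "nt\n")
  invisible(NULL)
})

#' Read and write reference panels as FASTA
#'
#' Taxonomy travels in the FASTA header as a pipe-delimited string,
#' \code{>accession|species|genus|family|order}, or in a sidecar TSV keyed
#' by accession (columns \code{accession}, \code{species}, \code{genus},
#' \code{family}, \code{order}).
#'
#' @param path FASTA file path.
#' @param taxonomyFile Optional sidecar TSV; when given, headers are
#'   treated as bare accessions.
#' @param panel A [ReferencePanel-class] (for writing).
#' @param sidecar Logical; write taxonomy to \code{<path>.taxonomy.tsv}
#'   with bare-accession headers instead of pipe-delimited headers.
#' @return \code{readReferencePanel} returns a [ReferencePanel-class];
#'   \code{writeReferencePanel} returns \code{path} invisibly.
#' @export
readReferencePanel <- function(path, taxonomyFile = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  if (is.null(taxonomyFile)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 5L))
      stop("expected 5 pipe-delimited header fields ",
           "(accession|species|genus|family|order); offending header: ",
           headers[which(nf != 5L)[1L]], call. = FALSE)
    tx <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(tx) <- c("accession", "species", "genus", "family", "order")
  } else {
    tx <- utils::read.delim(taxonomyFile, stringsAsFactors = FALSE)
    acc <- sub("\\s.*$", "", headers)
    idx <- match(acc, tx$accession)
    if (anyNA(idx))
      stop("no taxonomy for accession(s): ",
           paste(acc[is.na(idx)], collapse = ", "), call. = FALSE)
    tx <- tx[idx, , drop = FALSE]
  }
  ReferencePanel(seqs, tx)
}

#' @rdname readReferencePanel
#' @export
writeReferencePanel <- function(panel, path, sidecar = FALSE) {
  seqs <- panelSequences(panel)
  tx <- panelTaxonomy(panel)
  if (sidecar) {
    names(seqs) <- tx$accession
    utils::write.table(tx, paste0(path, ".taxonomy.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    names(seqs) <- paste(tx$accession, tx$species, tx$genus, tx$family,
                         tx$order, sep = "|")
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
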