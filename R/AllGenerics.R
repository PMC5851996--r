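#' @rdname Primer-accessors
#' @export
setGeneric("primerCore", function(x) standardGeneric("primerCore"))

#' @rdname Primer-accessors
#' @export
setGeneric("primerName", function(x) standardGeneric("primerName"))

#' @rdname Primer-accessors
#' @export
setGeneric("primerOrientation",
           function(x) standardGeneric("primerOrientation"))

#' @rdname Primer-accessors
#' @export
setGeneric("primerAdapter", function(x) standardGeneric("primerAdapter"))

#' @rdname Primer-accessors
#' @export
setGeneric("nRandomBases", function(x) standardGeneric("nRandomBases"))

#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelSequences", function(x) standardGeneric("panelSequences"))

#' @rdname ReferencePanel-accessors
#' @export
setGeneric("panelTaxonomy", function(x) standardGeneric("panelTaxonomy"))

#' @rdname DetectionTable-accessors
#' @export
setGeneric("detectionCounts", function(x) standardGeneric("detectionCounts"))

#' @rdname DetectionTable-accessors
#' @export
setGeneric("unassignedReads", function(x) standardGeneric("unassignedReads"))

#' @rdname DetectionTable-accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' GC content of nucleotide sequences
#'
#' Fraction of G and C bases, \eqn{(\#G + \#C)/L}. Universal-primer design
#' practice keeps primer GC content between 40 and 60\%.
#'
#' @param x Character vector of ACGT sequences, or a [Primer] (the core is
#'   used).
#' @return Numeric vector of fractions in \eqn{[0, 1]}.
#' @examples
#' gcContent("GGCC")
#' gcContent(mibirdPrimers()$fwd)
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname meltingTemperature
#' @export
setGeneric("meltingTemperature",
           function(x, params = thermoParams()) {
             standardGeneric("meltingTemperature")
           })
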