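#' Construct a Primer
#'
#' @param name Primer label.
#' @param core Core annealing oligo, 5'-to-3', uppercase ACGT (degenerate
#'   bases are deliberately not supported: the design strategy replaces
#'   them with G/T wobble-tolerant bases).
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @param adapter Optional sequencing-adapter tail (default none).
#' @param nRandomBases Number of random bases between adapter and core
#'   (default 0).
#'
#' @return A [Primer-class] object.
#' @examples
#' Primer("toy-F", "GGGTTGGTAAATCTTGTGCCAGC", "forward")
#' @export
Primer <- function(name, core, orientation = c("forward", "reverse"),
                   adapter = "", nRandomBases = 0L) {
  orientation <- match.arg(orientation)
  methods::new("Primer", name = as.character(name),
               core = toupper(as.character(core)),
               orientation = orientation,
               adapter = toupper(as.character(adapter)),
               nRandomBases = as.integer(nRandomBases))
}

#' The MiBird-U universal avian 12S primer pair
#'
#' The packaged default primer set: MiBird-U-F/R, a universal pair
#' targeting a hypervariable ~171 bp insert of the avian mitochondrial 12S
#' rRNA gene, derived from the MiFish/MiMammal primers. Cores carry no
#' degenerate bases; wobble-tolerant G/T bases stand in for template
#' variation. Adapters are the MiSeq sequencing-primer tails used in
#' first-round PCR, separated from the core by six random bases.
#'
#' @return A list with elements \code{fwd} and \code{rev}, each a
#'   [Primer-class].
#' @examples
#' mibirdPrimers()$fwd
#' @export
mibirdPrimers <- function() {
  list(
    fwd = Primer("MiBird-U-F", "GGGTTGGTAAATCTTGTGCCAGC", "forward",
                 adapter = "ACACTCTTTCCCTACACGACGCTCTTCCGATCT",
                 nRandomBases = 6L),
    rev = Primer("MiBird-U-R", "CATAGTGGGGTATCTAATCCCAGTTTG", "reverse",
                 adapter = "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
                 nRandomBases = 6L)
  )
}

#' Accessors for Primer objects
#'
#' @param x A [Primer-class] object.
#' @return \code{primerCore}, \code{primerName}, \code{primerOrientation}
#'   and \code{primerAdapter} return single strings; \code{nRandomBases}
#'   an integer.
#' @name Primer-accessors
#' @aliases primerCore primerName primerOrientation primerAdapter
#'   nRandomBases
#' @examples
#' primerCore(mibirdPrimers()$rev)
NULL

#' @rdname Primer-accessors
#' @export
setMethod("primerCore", "Primer", function(x) x@core)
#' @rdname Primer-accessors
#' @export
setMethod("primerName", "Primer", function(x) x@name)
#' @rdname Primer-accessors
#' @export
setMethod("primerOrientation", "Primer", function(x) x@orientation)
#' @rdname Primer-accessors
#' @export
setMethod("primerAdapter", "Primer", function(x) x@adapter)
#' @rdname Primer-accessors
#' @export
setMethod("nRandomBases", "Primer", function(x) x@nRandomBases)

setMethod("show", "Primer", function(object) {
  cat("Primer:", object@name, "(", object@orientation, ")\n")
  cat("  core:", object@core, sprintf("[%d nt, GC %.1f%%]",
      nchar(object@core), 100 * gcContent(object@core)), "\n")
  if (nzchar(object@adapter))
    cat("  adapter:", object@adapter,
        sprintf("+ %d random base(s)\n", object@nRandomBases))
  invisible(NULL)
})

#' Read and write primer definitions
#'
#' Primer sets are stored as a small YAML document: a named list of
#' primers, each with fields \code{core}, \code{orientation} and optional
#' \code{adapter} and \code{n_random_bases}.
#'
#' @param path File path.
#' @param primers Named list of [Primer-class] objects (for writing).
#' @return \code{readPrimerConfig} returns a named list of
#'   [Primer-class] objects; \code{writePrimerConfig} returns \code{path}
#'   invisibly.
#' @examples
#' tf <- tempfile(fileext = ".yaml")
#' writePrimerConfig(mibirdPrimers(), tf)
#' readPrimerConfig(tf)$fwd
#' @export
readPrimerConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- lapply(names(doc), function(nm) {
    p <- doc[[nm]]
    Primer(name = if (!is.null(p$name)) p$name else nm,
           core = p$core,
           orientation = p$orientation,
           adapter = if (is.null(p$adapter)) "" else p$adapter,
           nRandomBases = if (is.null(p$n_random_bases)) 0L
                          else p$n_random_bases)
  })
  names(out) <- names(doc)
  out
}

#' @rdname readPrimerConfig
#' @export
writePrimerConfig <- function(primers, path) {
  doc <- lapply(primers, function(p) {
    list(name = primerName(p), core = primerCore(p),
         orientation = primerOrientation(p),
         adapter = primerAdapter(p),
         n_random_bases = nRandomBases(p))
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}
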