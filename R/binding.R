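#' BindingSiteAlignment: a primer laid against one binding site
#'
#' Position-wise comparison of a primer core with a candidate binding
#' site, with per-position status \code{match}, \code{wobble_match} or
#' \code{mismatch}.
#'
#' @slot primerBase,siteBase Character vectors of per-position bases.
#' @slot status Character vector of per-position statuses.
#' @slot totalMismatches Number of positions with status \code{mismatch}.
#' @slot threePrimeMismatch \code{TRUE} when any position inside the
#'   3'-terminal window is a mismatch.
#' @slot wobbleEnabled Whether G/T wobble pairs were accepted.
#' @name BindingSiteAlignment-class
#' @aliases BindingSiteAlignment-class
#' @exportClass BindingSiteAlignment
setClass("BindingSiteAlignment",
  representation(
    primerBase = "character",
    siteBase = "character",
    status = "character",
    totalMismatches = "integer",
    threePrimeMismatch = "logical",
    wobbleEnabled = "logical"
  )
)

setValidity("BindingSiteAlignment", function(object) {
  msg <- character()
  n <- length(object@primerBase)
  if (length(object@siteBase) != n || length(object@status) != n)
    msg <- c(msg, "primerBase, siteBase and status must have equal length")
  if (!all(object@status %in% c("match", "wobble_match", "mismatch")))
    msg <- c(msg, "invalid status value")
  if (object@totalMismatches != sum(object@status == "mismatch"))
    msg <- c(msg, "totalMismatches must equal the count of 'mismatch' entries")
  if (!object@wobbleEnabled && any(object@status == "wobble_match"))
    msg <- c(msg, "wobble_match entries require wobbleEnabled")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BindingSiteAlignment", function(object) {
  cat("BindingSiteAlignment:", length(object@status), "positions,",
      object@totalMismatches, "mismatch(es)",
      if (object@wobbleEnabled) "(G/T wobble accepted)" else "", "\n")
  cat("  primer:", paste(object@primerBase, collapse = ""), "\n")
  cat("  site:  ", paste(object@siteBase, collapse = ""), "\n")
  mark <- c(match = "|", wobble_match = ":", mismatch = " ")
  cat("         ", paste(mark[object@status], collapse = ""), "\n")
  if (object@threePrimeMismatch) cat("  3'-terminal mismatch present\n")
  invisible(NULL)
})

#' @describeIn evaluateBinding Total mismatch count of an alignment.
#' @export
totalMismatches <- function(x) x@totalMismatches

#' @describeIn evaluateBinding Per-position statuses of an alignment.
#' @export
bindingStatus <- function(x) x@status

## Vectorised per-position status core shared by evaluateBinding and the
## window scan. `primerBases`: split primer core; `siteMat`: matrix of
## site bases (rows = candidate sites, cols = positions).
## Returns matrix of statuses. Sites are written in PRIMER ORIENTATION:
## a perfectly matched site reads identically to the core. At the level of
## the annealing template strand, primer G over template T and primer T
## over template G are the wobble pairs; in primer-orientation (sense-like)
## coordinates that is primer G over site A and primer T over site C.
.statusMatrix <- function(primerBases, siteMat, wobble, ambig = "lenient") {
  n <- length(primerBases)
  status <- matrix("mismatch", nrow = nrow(siteMat), ncol = n)
  for (j in seq_len(n)) {
    p <- primerBases[j]
    s <- siteMat[, j]
    isMatch <- s == p
    if (ambig == "lenient") {
      amb <- !(s %in% c("A", "C", "G", "T"))
      if (any(amb))
        isMatch[amb] <- .iupacContains(s[amb], p)
    }
    status[isMatch, j] <- "match"
    if (wobble) {
      partner <- if (p == "G") "A" else if (p == "T") "C" else NA_character_
      if (!is.na(partner)) {
        isWob <- !isMatch & s == partner
        if (ambig == "lenient") {
          amb <- !isMatch & !(s %in% c("A", "C", "G", "T"))
          if (any(amb))
            isWob[amb] <- .iupacContains(s[amb], partner)
        }
        status[isWob, j] <- "wobble_match"
      }
    }
  }
  status
}

#' Evaluate a primer against one binding site
#'
#' Position-by-position comparison of a primer core with a binding site of
#' identical length, optionally accepting G/T wobble pairs: a primer G
#' facing a T on the annealing template (equivalently an A in
#' primer-orientation site coordinates) and a primer T facing a template G
#' (a site C) are scored \code{wobble_match} rather than \code{mismatch}.
#'
#' The site is supplied in primer orientation, i.e. the reading in which a
#' perfectly matched site equals the core sequence: for a forward primer
#' this is the reference sense strand, for a reverse primer the reverse
#' complement of the sense segment. [siteFromReference()] produces this
#' reading from sense-strand coordinates.
#'
#' IUPAC ambiguity codes in the site count as a match when the primer base
#' is within the code's base set (N matches everything); with
#' \code{ambig = "strict"} any non-ACGT site base is a mismatch.
#'
#' @param primer A [Primer-class].
#' @param site Binding-site string, same length as the core; ACGT plus
#'   IUPAC codes.
#' @param wobble Accept G/T wobble pairs (default \code{TRUE}).
#' @param ambig \code{"lenient"} (default) or \code{"strict"} handling of
#'   IUPAC codes.
#' @param terminalWindow Number of 3'-terminal positions inspected for the
#'   terminal-mismatch flag (default 1, the last base).
#' @return A [BindingSiteAlignment-class].
#' @examples
#' p <- Primer("toy", "GGC", "forward")
#' evaluateBinding(p, "GAC")            # G over site A: wobble match
#' evaluateBinding(p, "GAC", wobble = FALSE)
#' @export
evaluateBinding <- function(primer, site, wobble = TRUE,
                            ambig = c("lenient", "strict"),
                            terminalWindow = 1L) {
  ambig <- match.arg(ambig)
  core <- primerCore(primer)
  site <- toupper(site)
  if (nchar(site) != nchar(core))
    stop("site length (", nchar(site), ") incompatible with primer core ",
         "length (", nchar(core), ")", call. = FALSE)
  .checkNucleotide(site, "site")
  pb <- .splitBases(core)
  sb <- .splitBases(site)
  status <- .statusMatrix(pb, matrix(sb, nrow = 1L), wobble, ambig)[1L, ]
  n <- length(pb)
  win <- seq.int(max(1L, n - terminalWindow + 1L), n)
  methods::new("BindingSiteAlignment",
    primerBase = pb, siteBase = sb, status = status,
    totalMismatches = sum(status == "mismatch"),
    threePrimeMismatch = any(status[win] == "mismatch"),
    wobbleEnabled = wobble)
}

#' Extract a binding site from a reference in primer orientation
#'
#' Converts a sense-strand interval of a reference sequence into the
#' primer-orientation reading used by [evaluateBinding()]: the subsequence
#' itself for a forward primer, its reverse complement for a reverse
#' primer.
#'
#' @param reference Reference sense-strand sequence (character).
#' @param start,end 1-based closed interval on the sense strand.
#' @param orientation \code{"forward"} or \code{"reverse"}.
#' @return Site string in primer orientation.
#' @export
siteFromReference <- function(reference, start, end,
                              orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  s <- substr(reference, start, end)
  if (orientation == "reverse") s <- reverseComplementSeq(s)
  s
}

#' Mismatch histogram of a primer over a panel of binding sites
#'
#' Tallies per-site mismatch counts from [evaluateBinding()] into bins
#' 0, 1, 2, 3, 4 and >=5 — the classical way of summarising how well a
#' universal primer matches a reference panel. Panel members for which no
#' site could be located (\code{NA} entries) are reported separately by
#' default, or folded into the >=5 bin with \code{unlocated = "ge5"}.
#'
#' @param primer A [Primer-class].
#' @param sites Character vector of located binding sites in primer
#'   orientation (see [evaluateBinding()]); \code{NA} marks a panel member
#'   without a locatable site.
#' @param wobble Accept G/T wobble pairs (default \code{TRUE}).
#' @param unlocated \code{"separate"} (default) or \code{"ge5"}.
#' @param ambig Passed to [evaluateBinding()].
#' @return A list of class \code{MismatchHistogram}: \code{histogram}
#'   (data.frame with \code{mismatches}, \code{count},
#'   \code{proportion}), \code{nTotal} (sites binned) and
#'   \code{nUnlocated}.
#' @examples
#' p <- Primer("toy", "ACGTACGT", "forward")
#' mismatchHistogram(p, c("ACGTACGT", "ACGTACGT", "TCGTACGT"))
#' @export
mismatchHistogram <- function(primer, sites, wobble = TRUE,
                              unlocated = c("separate", "ge5"),
                              ambig = "lenient") {
  unlocated <- match.arg(unlocated)
  if (length(sites) == 0L) stop("empty panel", call. = FALSE)
  located <- sites[!is.na(sites)]
  nUnloc <- sum(is.na(sites))
  mm <- vapply(located, function(s) {
    totalMismatches(evaluateBinding(primer, s, wobble = wobble,
                                    ambig = ambig))
  }, integer(1), USE.NAMES = FALSE)
  lev <- c("0", "1", "2", "3", "4", "ge5")
  binned <- ifelse(mm >= 5L, "ge5", as.character(mm))
  counts <- table(factor(binned, levels = lev))
  counts <- as.integer(counts)
  if (unlocated == "ge5") {
    counts[6L] <- counts[6L] + nUnloc
    nUnloc <- 0L
  }
  nTotal <- sum(counts)
  out <- list(
    histogram = data.frame(mismatches = lev, count = counts,
                           proportion = if (nTotal > 0) counts / nTotal
                                        else rep(NA_real_, 6L)),
    nTotal = nTotal, nUnlocated = nUnloc)
  class(out) <- "MismatchHistogram"
  out
}

#' @export
print.MismatchHistogram <- function(x, ...) {
  cat("MismatchHistogram over", x$nTotal, "site(s)")
  if (x$nUnlocated > 0) cat(" (+", x$nUnlocated, "unlocated, reported separately)")
  cat("\n")
  print(x$histogram, row.names = FALSE)
  invisible(x)
}

#' Positional base composition of panel binding sites
#'
#' Per-primer-position counts of A/C/G/T observed across located binding
#' sites of a panel, with the number of members matching the primer base
#' at each position — the table used to judge conserved positions and the
#' 3'-end during primer design.
#'
#' @param sites Character vector of located binding sites in primer
#'   orientation, all the same length as the primer core.
#' @param primer A [Primer-class].
#' @return data.frame with columns \code{position}, \code{primer_base},
#'   \code{A}, \code{C}, \code{G}, \code{T}, \code{match_count}.
#' @export
positionalBaseProfile <- function(sites, primer) {
  core <- primerCore(primer)
  if (length(sites) == 0L) stop("empty panel", call. = FALSE)
  if (any(nchar(sites) != nchar(core)))
    stop("ragged site lengths: all sites must match the primer core length",
         call. = FALSE)
  n <- nchar(core)
  pb <- .splitBases(core)
  mat <- do.call(rbind, strsplit(toupper(sites), "", fixed = TRUE))
  prof <- data.frame(position = seq_len(n), primer_base = pb,
                     A = 0L, C = 0L, G = 0L, T = 0L, match_count = 0L)
  for (j in seq_len(n)) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T")))
    prof$A[j] <- tab[["A"]]; prof$C[j] <- tab[["C"]]
    prof$G[j] <- tab[["G"]]; prof$T[j] <- tab[["T"]]
    prof$match_count[j] <- sum(mat[, j] == pb[j])
  }
  prof
}

#' Locate binding sites of a primer across a panel
#'
#' Runs [locatePrimerSite()] over every panel record and returns the site
#' sequences in primer orientation, \code{NA} for records without a
#' qualifying window — the input expected by [mismatchHistogram()] and
#' [positionalBaseProfile()].
#'
#' @param panel A [ReferencePanel-class].
#' @param primer A [Primer-class].
#' @param maxMismatch Maximum mismatches for a window to qualify
#'   (default \code{Inf}: always report the best window).
#' @param wobble Accept G/T wobble pairs while scoring windows.
#' @return Named character vector (accession names), \code{NA} where no
#'   site qualified.
#' @export
panelBindingSites <- function(panel, primer, maxMismatch = Inf,
                              wobble = TRUE) {
  seqs <- as.character(panelSequences(panel))
  out <- vapply(seqs, function(s) {
    hit <- locatePrimerSite(s, primer, maxMismatch = maxMismatch,
                            wobble = wobble)
    if (is.null(hit)) NA_character_
    else siteFromReference(s, hit$start, hit$end, primerOrientation(primer))
  }, character(1))
  names(out) <- panelTaxonomy(panel)$accession
  out
}

#' Write primer-evaluation reports as TSV
#'
#' @param x A \code{MismatchHistogram} (from [mismatchHistogram()]) or the
#'   profile data.frame from [positionalBaseProfile()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeMismatchHistogram <- function(x, path) {
  df <- x$histogram
  df$n <- x$nTotal
  utils::write.table(df[, c("mismatches", "count", "n", "proportion")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMismatchHistogram
#' @export
writeBaseProfile <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
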