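#' Locate a primer binding site in a reference sequence
#'
#' Exhaustive substitution-only window scan of the strand appropriate to
#' the primer's orientation (sense strand for a forward primer, reverse
#' complement for a reverse primer). Every window the length of the core
#' is scored with the wobble-aware position-wise comparison of
#' [evaluateBinding()]; the window with the fewest mismatches wins, ties
#' going to the leftmost window on the scanned strand. Windows disrupted
#' by indels are not modelled: a site carrying a deletion is reported
#' absent, mirroring the exclusion of deletion-bearing references from
#' in-silico evaluation.
#'
#' @param reference Reference sense-strand sequence (character or
#'   [Biostrings::DNAString]).
#' @param primer A [Primer-class].
#' @param maxMismatch Maximum mismatch count for a window to qualify
#'   (default 3).
#' @param wobble Accept G/T wobble pairs (default \code{TRUE}).
#' @param ambig IUPAC handling, see [evaluateBinding()].
#' @return \code{NULL} when no window qualifies (including a primer longer
#'   than the reference); otherwise a list with \code{start}, \code{end}
#'   (1-based closed interval on the sense strand), \code{mismatches} and
#'   \code{orientation}.
#' @examples
#' fwd <- mibirdPrimers()$fwd
#' ref <- paste0("AAAA", primerCore(fwd), "CCCC")
#' locatePrimerSite(ref, fwd)
#' @export
locatePrimerSite <- function(reference, primer, maxMismatch = 3L,
                             wobble = TRUE, ambig = "lenient") {
  stopifnot(maxMismatch >= 0)
  reference <- toupper(as.character(reference))
  core <- primerCore(primer)
  k <- nchar(core)
  L <- nchar(reference)
  if (k > L) return(NULL)
  scanned <- if (primerOrientation(primer) == "reverse")
    reverseComplementSeq(reference) else reference
  ch <- .splitBases(scanned)
  nw <- L - k + 1L
  idx <- outer(seq_len(nw) - 1L, seq_len(k), "+")
  siteMat <- matrix(ch[idx], nrow = nw, ncol = k)
  status <- .statusMatrix(.splitBases(core), siteMat, wobble, ambig)
  mm <- rowSums(status == "mismatch")
  best <- which.min(mm)                       # ties -> leftmost window
  if (mm[best] > maxMismatch) return(NULL)
  w <- best
  if (primerOrientation(primer) == "reverse") {
    start <- L - (w + k - 1L) + 1L
    end <- L - w + 1L
  } else {
    start <- w
    end <- w + k - 1L
  }
  list(start = start, end = end, mismatches = as.integer(mm[best]),
       orientation = primerOrientation(primer))
}

#' In-silico PCR: extract amplicon inserts from a reference panel
#'
#' Locates the forward and reverse primer sites in each panel record and
#' extracts the insert — the sequence strictly between the two primer
#' regions, primers excluded. Records lacking either site within
#' \code{maxMismatch}, or whose sites are inverted/overlapping, are
#' excluded with a reason rather than dropped silently.
#'
#' @param panel A [ReferencePanel-class].
#' @param fwd,rev Forward and reverse [Primer-class] objects (defaults:
#'   the MiBird-U pair).
#' @param maxMismatch Maximum per-site mismatches (default 3).
#' @param wobble Accept G/T wobble pairs while locating sites.
#' @return data.frame with one row per record: \code{accession},
#'   \code{status} (\code{"extracted"}/\code{"excluded"}), \code{reason},
#'   \code{insert}, 1-based sense-strand site coordinates
#'   (\code{fwd_start}, \code{fwd_end}, \code{rev_start}, \code{rev_end}),
#'   per-site mismatch counts and \code{insert_length}.
#' @examples
#' prm <- mibirdPrimers()
#' ref <- paste0("AAAAA", primerCore(prm$fwd), strrep("ACGT", 10),
#'               reverseComplementSeq(primerCore(prm$rev)), "TTTTT")
#' pan <- ReferencePanel(ref, data.frame(accession = "X1", species = "sp1",
#'   genus = "g1", family = "f1", order = "o1"))
#' extractInserts(pan)
#' @export
extractInserts <- function(panel, fwd = mibirdPrimers()$fwd,
                           rev = mibirdPrimers()$rev, maxMismatch = 3L,
                           wobble = TRUE) {
  stopifnot(primerOrientation(fwd) == "forward",
            primerOrientation(rev) == "reverse")
  seqs <- as.character(panelSequences(panel))
  acc <- panelTaxonomy(panel)$accession
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    out <- data.frame(accession = acc[i], status = "excluded",
                      reason = NA_character_, insert = NA_character_,
                      fwd_start = NA_integer_, fwd_end = NA_integer_,
                      rev_start = NA_integer_, rev_end = NA_integer_,
                      fwd_mismatches = NA_integer_,
                      rev_mismatches = NA_integer_,
                      insert_length = NA_integer_,
                      stringsAsFactors = FALSE)
    fh <- locatePrimerSite(s, fwd, maxMismatch, wobble)
    if (is.null(fh)) { out$reason <- "fwd_site_absent"; return(out) }
    rh <- locatePrimerSite(s, rev, maxMismatch, wobble)
    out$fwd_start <- fh$start; out$fwd_end <- fh$end
    out$fwd_mismatches <- fh$mismatches
    if (is.null(rh)) { out$reason <- "rev_site_absent"; return(out) }
    out$rev_start <- rh$start; out$rev_end <- rh$end
    out$rev_mismatches <- rh$mismatches
    if (rh$start <= fh$end) { out$reason <- "inverted_sites"; return(out) }
    ins <- substr(s, fh$end + 1L, rh$start - 1L)
    out$status <- "extracted"
    out$insert <- ins
    out$insert_length <- nchar(ins)
    out
  })
  do.call(rbind, rows)
}

#' Levenshtein edit distance
#'
#' Minimum number of single-nucleotide substitutions, insertions or
#' deletions transforming one sequence into the other; the measure of
#' inter-species divergence of amplicon inserts. Wraps [utils::adist()]
#' with unit costs.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' editDistance("ACGT", "ACGA")
#' editDistance("kitten", "sitting")
#' @export
editDistance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) as.integer(utils::adist(a[i], b[i])),
         integer(1))
}

#' @describeIn editDistance Full pairwise distance matrix for a set of
#'   sequences.
#' @param x Character vector of sequences.
#' @export
editDistanceMatrix <- function(x) {
  d <- utils::adist(x)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(names(x), names(x))
  d
}

.binDistances <- function(d) {
  lev <- c("0", "1", "2", "3", "4", "ge5")
  binned <- ifelse(d >= 5L, "ge5", as.character(d))
  as.integer(table(factor(binned, levels = lev)))
}

#' Taxonomic-resolution analysis: edit-distance distributions
#'
#' Pairwise Levenshtein distances between amplicon inserts, binned at
#' 0, 1, 2, 3, 4 and >=5, at two levels: inter-species (all unordered
#' pairs of distinct species) and inter-genus. A distance >=5-6 between
#' inserts is the working criterion for reliable discrimination of the
#' pair.
#'
#' The genus-level statistic is, by default, the distance of every species
#' pair whose genera differ (\code{genusMode = "different-genus"}, the
#' literal definition). Two alternative readings are available:
#' \code{"within-genus"} (congeneric species pairs — the hardest pairs to
#' separate) and \code{"genus-pair-min"} (the minimum distance over each
#' unordered pair of genera).
#'
#' @param inserts Named character vector of insert sequences (names =
#'   accessions), or the data.frame returned by [extractInserts()] (its
#'   \code{"extracted"} rows are used).
#' @param taxonomy data.frame with columns \code{accession},
#'   \code{species}, \code{genus} (e.g. [panelTaxonomy()]).
#' @param genusMode Genus-level pair definition, see Details.
#' @return data.frame with rows \code{inter_species} and
#'   \code{inter_genus}; columns \code{category}, \code{d0}..\code{d4},
#'   \code{dge5}, \code{total}.
#' @export
distanceDistributions <- function(inserts, taxonomy,
                                  genusMode = c("different-genus",
                                                "within-genus",
                                                "genus-pair-min")) {
  genusMode <- match.arg(genusMode)
  if (is.data.frame(inserts)) {
    ok <- inserts$status == "extracted"
    x <- inserts$insert[ok]
    names(x) <- inserts$accession[ok]
    inserts <- x
  }
  idx <- match(names(inserts), taxonomy$accession)
  if (anyNA(idx))
    stop("no taxonomy for accession(s): ",
         paste(names(inserts)[is.na(idx)], collapse = ", "), call. = FALSE)
  species <- taxonomy$species[idx]
  genus <- taxonomy$genus[idx]
  if (anyDuplicated(species)) {
    warning("duplicate species collapsed to first occurrence: ",
            paste(unique(species[duplicated(species)]), collapse = ", "))
    keep <- !duplicated(species)
    inserts <- inserts[keep]; species <- species[keep]; genus <- genus[keep]
  }
  n <- length(inserts)
  if (n < 2L) stop("need at least two species", call. = FALSE)
  D <- editDistanceMatrix(unname(inserts))
  ut <- upper.tri(D)
  dSpecies <- D[ut]
  gi <- matrix(genus[row(D)], n, n)
  gj <- matrix(genus[col(D)], n, n)
  dGenus <- switch(genusMode,
    "different-genus" = D[ut & gi != gj],
    "within-genus" = D[ut & gi == gj],
    "genus-pair-min" = {
      diff <- ut & gi != gj
      if (!any(diff)) integer(0)
      else {
        key <- paste(pmin(gi[diff], gj[diff]), pmax(gi[diff], gj[diff]),
                     sep = "\r")
        as.integer(tapply(D[diff], key, min))
      }
    })
  out <- data.frame(category = c("inter_species", "inter_genus"),
                    stringsAsFactors = FALSE)
  bins <- rbind(.binDistances(dSpecies), .binDistances(dGenus))
  colnames(bins) <- c("d0", "d1", "d2", "d3", "d4", "dge5")
  out <- cbind(out, as.data.frame(bins))
  out$total <- c(length(dSpecies), length(dGenus))
  out
}

#' Write insert-extraction and distance reports as TSV
#'
#' @param x The data.frame from [extractInserts()] or
#'   [distanceDistributions()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceTable
#' @export
writeExtractionReport <- function(x, path) {
  utils::write.table(x[, setdiff(names(x), "insert")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
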