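#' Parameters for taxonomic assignment
#'
#' @param minIdentity Minimum percent identity of the top hit (default
#'   97).
#' @param maxEvalue Maximum E-value of the top hit (default 1e-5).
#' @param minRatio Optional minimum top/second reliability ratio; the
#'   ratio is reported as an indicator and, by default
#'   (\code{minRatio = NULL}), never used to reject an assignment.
#' @return A list of class \code{assignParams}.
#' @export
assignParams <- function(minIdentity = 97, maxEvalue = 1e-5,
                         minRatio = NULL) {
  stopifnot(minIdentity > 0, minIdentity <= 100, maxEvalue > 0)
  p <- list(minIdentity = minIdentity, maxEvalue = maxEvalue,
            minRatio = minRatio)
  class(p) <- "assignParams"
  p
}

.HIT_COLS <- c("query", "subject", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Parse a 12-column tabular similarity-search hit file
#'
#' Reads the standard 12-column tabular dialect (BLAST "outfmt 6": query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score) and optionally
#' resolves subject accessions to species through a panel taxonomy.
#'
#' @param path Path to the tab-separated hit file (or a character vector
#'   of lines via \code{text}).
#' @param taxonomy Optional data.frame with \code{accession} and
#'   \code{species} columns; when given, a \code{species} column is added.
#' @param text Optional character vector of lines, used instead of
#'   \code{path}.
#' @return data.frame of hits, one row per line, input order preserved.
#' @export
parseHitTable <- function(path, taxonomy = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.HIT_COLS)), .HIT_COLS))
    if (!is.null(taxonomy)) out$species <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1L],
         " at line ", which(nf != 12L)[1L], call. = FALSE)
  m <- do.call(rbind, fields)
  out <- data.frame(query = m[, 1], subject = m[, 2],
                    stringsAsFactors = FALSE)
  numCols <- .HIT_COLS[3:12]
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("unparseable numeric field '", numCols[j - 2L], "' at line ",
           which(is.na(v))[1L], call. = FALSE)
    out[[.HIT_COLS[j]]] <- v
  }
  for (j in c("length", "mismatch", "gapopen", "qstart", "qend",
              "sstart", "send"))
    out[[j]] <- as.integer(out[[j]])
  if (!is.null(taxonomy)) {
    idx <- match(out$subject, taxonomy$accession)
    if (anyNA(idx))
      stop("no taxonomy for subject accession(s): ",
           paste(unique(out$subject[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    out$species <- taxonomy$species[idx]
  }
  out
}

## ungapped Karlin-Altschul lambda for match/mismatch scoring at uniform
## base frequencies: solves sum_ij p_i p_j exp(lambda s_ij) = 1
.kaLambda <- function(match, mismatch) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Built-in local aligner for desk-scale assignment
#'
#' Smith-Waterman local alignment (via
#' [Biostrings::pairwiseAlignment()]) of a query against one reference,
#' on both strands, returning a hit row in the same 12-column shape as
#' [parseHitTable()]. Percent identity, alignment length and mismatches
#' come from the traceback; the E-value uses Karlin-Altschul statistics
#' with lambda solved for the configured match/mismatch scores and a
#' default K of 0.621.
#'
#' @param query Query sequence (character).
#' @param subject Reference sequence (character).
#' @param queryId,subjectId Labels for the output row.
#' @param scoring list with \code{match}, \code{mismatch} (signed),
#'   \code{gapOpen}, \code{gapExtend} (positive costs).
#' @param K Karlin-Altschul K (default 0.621).
#' @return One-row data.frame in hit-table shape, plus a \code{strand}
#'   column.
#' @export
alignLocal <- function(query, subject, queryId = "query",
                       subjectId = "subject",
                       scoring = list(match = 2, mismatch = -3,
                                      gapOpen = 5, gapExtend = 2),
                       K = 0.621) {
  stopifnot(nzchar(query), nzchar(subject))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = TRUE)
  alnFor <- function(q) {
    Biostrings::pairwiseAlignment(q, subject, type = "local",
      substitutionMatrix = mat, gapOpening = scoring$gapOpen,
      gapExtension = scoring$gapExtend)
  }
  paF <- alnFor(query)
  paR <- alnFor(reverseComplementSeq(query))
  strand <- if (Biostrings::score(paR) > Biostrings::score(paF)) "-" else "+"
  pa <- if (strand == "-") paR else paF
  L <- Biostrings::nchar(pa)                  # alignment length incl. gaps
  nmat <- Biostrings::nmatch(pa)
  nmis <- Biostrings::nmismatch(pa)
  qin <- Biostrings::indel(Biostrings::pattern(pa))
  sin <- Biostrings::indel(Biostrings::subject(pa))
  gapopen <- length(qin[[1L]]) + length(sin[[1L]])
  S <- Biostrings::score(pa)
  lambda <- .kaLambda(scoring$match, scoring$mismatch)
  mn <- as.numeric(nchar(query)) * nchar(subject)
  evalue <- K * mn * exp(-lambda * S)
  bitscore <- (lambda * S - log(K)) / log(2)
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  if (strand == "-") {                        # report query coords on +
    n <- nchar(query)
    tmp <- qs; qs <- n - qe + 1L; qe <- n - tmp + 1L
  }
  data.frame(query = queryId, subject = subjectId,
             pident = 100 * nmat / L, length = L, mismatch = nmis,
             gapopen = gapopen, qstart = qs, qend = qe,
             sstart = Biostrings::start(Biostrings::subject(pa)),
             send = Biostrings::end(Biostrings::subject(pa)),
             evalue = evalue, bitscore = bitscore, strand = strand,
             stringsAsFactors = FALSE)
}

#' Align a set of queries against a reference panel
#'
#' Runs [alignLocal()] for every query/record combination and attaches
#' species labels from the panel taxonomy, producing the hit table
#' expected by [assignTaxa()].
#'
#' @param queries Named character vector of query sequences (e.g.
#'   dereplicated representatives).
#' @param panel A [ReferencePanel-class].
#' @param ... Passed to [alignLocal()].
#' @return data.frame of hits with a \code{species} column.
#' @export
alignLocalPanel <- function(queries, panel, ...) {
  if (is.null(names(queries)))
    names(queries) <- paste0("unit", seq_along(queries))
  tx <- panelTaxonomy(panel)
  seqs <- as.character(panelSequences(panel))
  rows <- list()
  for (qi in seq_along(queries)) {
    for (si in seq_along(seqs)) {
      h <- alignLocal(queries[[qi]], seqs[[si]],
                      queryId = names(queries)[qi],
                      subjectId = tx$accession[si], ...)
      h$species <- tx$species[si]
      rows[[length(rows) + 1L]] <- h
    }
  }
  do.call(rbind, rows)
}

#' Reliability score of an alignment hit
#'
#' Alignment length divided by one plus the mismatch count,
#' \eqn{L/(m+1)}; the added one avoids division by zero for perfect hits.
#' Longer, cleaner alignments score higher.
#'
#' @param length Alignment length(s), \eqn{L \ge 1}.
#' @param mismatch Mismatch count(s), \eqn{m \ge 0}.
#' @return Numeric vector of scores.
#' @examples
#' reliabilityScore(150, 1)   # 75
#' @export
reliabilityScore <- function(length, mismatch) {
  stopifnot(all(length >= 1), all(mismatch >= 0))
  length / (mismatch + 1)
}

#' Assign a species to each query from its similarity-search hits
#'
#' Per query: hits are collapsed to the best hit per species (by bit
#' score, then reliability score, then accession), ranked, and the top
#' species accepted when its best hit reaches \code{minIdentity} percent
#' identity with E-value at most \code{maxEvalue}. The reliability ratio
#' is the top species' reliability score over that of the best hit to any
#' other species — an indicator of how clearly the winner separates from
#' the runner-up. Different species tied on both bit score and
#' reliability at the top yield status \code{"ambiguous"}.
#'
#' @param hits data.frame of hits (shape of [parseHitTable()]) with a
#'   \code{species} column; may cover many queries.
#' @param params An [assignParams()] bundle.
#' @param readCounts Optional named vector mapping query ids to read
#'   counts, copied into the output.
#' @return data.frame with one row per query: \code{query},
#'   \code{status} (\code{assigned}/\code{ambiguous}/\code{unassigned}),
#'   \code{reason}, \code{species}, \code{pident}, \code{length},
#'   \code{mismatch}, \code{evalue}, \code{reliability},
#'   \code{second_species}, \code{second_reliability},
#'   \code{ratio_score}, \code{read_count}.
#' @export
assignTaxa <- function(hits, params = assignParams(), readCounts = NULL) {
  if (!"species" %in% names(hits))
    stop("hits must carry a 'species' column (see parseHitTable taxonomy)",
         call. = FALSE)
  queries <- unique(hits$query)
  if (length(queries) == 0L) {
    out <- data.frame(query = character(0), status = character(0),
                      reason = character(0), species = character(0),
                      pident = numeric(0), length = integer(0),
                      mismatch = integer(0), evalue = numeric(0),
                      reliability = numeric(0),
                      second_species = character(0),
                      second_reliability = numeric(0),
                      ratio_score = numeric(0), read_count = integer(0))
    return(out)
  }
  emptyRow <- function(q, reason) {
    data.frame(query = q, status = "unassigned", reason = reason,
               species = NA_character_, pident = NA_real_,
               length = NA_integer_, mismatch = NA_integer_,
               evalue = NA_real_, reliability = NA_real_,
               second_species = NA_character_,
               second_reliability = NA_real_, ratio_score = NA_real_,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(queries, function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (nrow(h) == 0L) return(emptyRow(q, "no hits"))
    h$reliability <- reliabilityScore(h$length, h$mismatch)
    ## best hit per species: bitscore desc, reliability desc, accession asc
    h <- h[order(-h$bitscore, -h$reliability, h$subject), , drop = FALSE]
    h <- h[!duplicated(h$species), , drop = FALSE]
    top <- h[1L, ]
    if (!(top$pident >= params$minIdentity &&
          top$evalue <= params$maxEvalue))
      return(emptyRow(q, "below_threshold"))
    second <- if (nrow(h) > 1L) h[2L, ] else NULL
    ratio <- NA_real_
    secondSpecies <- NA_character_
    secondRel <- NA_real_
    status <- "assigned"; reason <- NA_character_
    if (!is.null(second)) {
      secondSpecies <- second$species
      secondRel <- second$reliability
      ratio <- top$reliability / second$reliability
      if (second$bitscore == top$bitscore &&
          second$reliability == top$reliability) {
        status <- "ambiguous"
        reason <- paste("tied top species:",
                        paste(h$species[h$bitscore == top$bitscore &
                                        h$reliability == top$reliability],
                              collapse = ";"))
      }
    }
    if (status == "assigned" && !is.null(params$minRatio) &&
        !is.na(ratio) && ratio < params$minRatio) {
      status <- "unassigned"; reason <- "ratio_below_threshold"
    }
    data.frame(query = q, status = status, reason = reason,
               species = if (status == "assigned") top$species
                         else NA_character_,
               pident = top$pident, length = top$length,
               mismatch = top$mismatch, evalue = top$evalue,
               reliability = top$reliability,
               second_species = secondSpecies,
               second_reliability = secondRel, ratio_score = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$read_count <- if (is.null(readCounts)) NA_integer_
                    else as.integer(readCounts[out$query])
  rownames(out) <- NULL
  out
}

#' Write assignments as TSV
#'
#' @param x The data.frame from [assignTaxa()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeAssignments <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
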