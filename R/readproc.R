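#' Parameters of the amplicon read-processing pipeline
#'
#' Bundles the tunable thresholds of the pipeline: Phred tail-trimming
#' cutoff, minimum merge overlap and overlap mismatch ceiling, amplicon
#' length window, primer-removal mismatch allowance, and the two-tier
#' dereplication rule (minimum reads for a representative; identity for
#' rescuing under-represented variants).
#'
#' @param phredCutoff Phred quality cutoff for tail trimming (default 10,
#'   i.e. an error rate of 1e-1).
#' @param minOverlap Minimum read-pair overlap for merging (default 10 nt).
#' @param maxOverlapMismatchFrac Maximum mismatch fraction in the chosen
#'   overlap (default 0.25).
#' @param lengthWindow Numeric \code{c(min, max)} acceptable merged-read
#'   (full amplicon) length; \code{NULL} (default) derives
#'   \code{expected amplicon length * c(0.8, 1.2)} from the primers and
#'   \code{expectedInsertLength}.
#' @param expectedInsertLength Expected insert length used to derive the
#'   default window (default 171 nt).
#' @param maxPrimerMismatch Maximum substitutions tolerated when removing
#'   each primer (default 3).
#' @param minReads Minimum identical-read count for a dereplicated
#'   representative (default 10).
#' @param rescueIdentity Minimum identity at which an under-represented
#'   sequence is absorbed into a representative (default 0.99).
#' @param identityMode \code{"levenshtein"} (default,
#'   \code{1 - d/max(len)}) or \code{"hamming"} (equal lengths only).
#' @param leadingRandom Number of random spacer bases tolerated before the
#'   anchored forward primer (and after the reverse); default 0, i.e.
#'   spacers already removed upstream.
#' @return A list of class \code{processingParams}.
#' @export
processingParams <- function(phredCutoff = 10L, minOverlap = 10L,
                             maxOverlapMismatchFrac = 0.25,
                             lengthWindow = NULL,
                             expectedInsertLength = 171L,
                             maxPrimerMismatch = 3L, minReads = 10L,
                             rescueIdentity = 0.99,
                             identityMode = c("levenshtein", "hamming"),
                             leadingRandom = 0L) {
  identityMode <- match.arg(identityMode)
  stopifnot(phredCutoff >= 0, minOverlap >= 1, maxPrimerMismatch >= 0,
            minReads >= 1, rescueIdentity >= 0, rescueIdentity <= 1)
  if (!is.null(lengthWindow)) {
    stopifnot(length(lengthWindow) == 2L, lengthWindow[1] <= lengthWindow[2])
  }
  p <- list(phredCutoff = phredCutoff, minOverlap = minOverlap,
            maxOverlapMismatchFrac = maxOverlapMismatchFrac,
            lengthWindow = lengthWindow,
            expectedInsertLength = expectedInsertLength,
            maxPrimerMismatch = maxPrimerMismatch, minReads = minReads,
            rescueIdentity = rescueIdentity, identityMode = identityMode,
            leadingRandom = leadingRandom)
  class(p) <- "processingParams"
  p
}

#' Quality tail trimming of a single read
#'
#' Keeps the longest contiguous segment in which every base has a Phred
#' score at or above the cutoff (ties broken to the leftmost segment); the
#' output may be empty. An alternative \code{"first"} rule cuts at the
#' first below-cutoff base.
#'
#' @param bases Read sequence (single string).
#' @param quals Integer vector of per-base Phred scores, same length.
#' @param cutoff Phred cutoff (default 10).
#' @param method \code{"longest"} (default) or \code{"first"}.
#' @return list with trimmed \code{bases} and \code{quals}.
#' @examples
#' qualityTrim("ACGTACGT", c(30, 30, 30, 5, 30, 30, 30, 30))
#' @export
qualityTrim <- function(bases, quals, cutoff = 10L,
                        method = c("longest", "first")) {
  method <- match.arg(method)
  stopifnot(nchar(bases) == length(quals), cutoff >= 0)
  ok <- quals >= cutoff
  if (!any(ok)) return(list(bases = "", quals = integer(0)))
  if (method == "first") {
    firstBad <- which(!ok)
    end <- if (length(firstBad)) firstBad[1L] - 1L else length(ok)
    if (end == 0L) return(list(bases = "", quals = integer(0)))
    return(list(bases = substr(bases, 1L, end), quals = quals[seq_len(end)]))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  pick <- good[which.max(r$lengths[good])]    # ties -> leftmost
  list(bases = substr(bases, starts[pick], ends[pick]),
       quals = quals[starts[pick]:ends[pick]])
}

.hammingVec <- function(a, b) sum(a != b)

#' Merge a trimmed read pair into one amplicon read
#'
#' Overlap-based merging in the style of FLASH: the reverse read is
#' reverse-complemented, candidate overlap lengths from
#' \code{minOverlap} up to the shorter read length are scored by mismatch
#' fraction, and the overlap minimising that fraction (ties to the longest
#' overlap) is adopted when its fraction is at most
#' \code{maxOverlapMismatchFrac}. At disagreeing overlap positions the
#' higher-quality base wins; the per-position maximum quality is retained.
#' Only overlap offsets of at least the minimum are considered, so a pair
#' whose true overlap is shorter comes back unmerged.
#'
#' @param fwdBases,revBases Read sequences (single strings, reverse read
#'   in raw orientation).
#' @param fwdQuals,revQuals Integer Phred vectors matching the bases.
#' @param params A [processingParams()] bundle.
#' @return list with \code{status} (\code{"merged"}/\code{"unmerged"}),
#'   and when merged: \code{bases}, \code{quals}, \code{overlapLength},
#'   \code{overlapMismatches}.
#' @export
mergePair <- function(fwdBases, fwdQuals, revBases, revQuals,
                      params = processingParams()) {
  lf <- nchar(fwdBases); lr <- nchar(revBases)
  if (lf == 0L || lr == 0L || min(lf, lr) < params$minOverlap)
    return(list(status = "unmerged"))
  rcBases <- reverseComplementSeq(revBases)
  rcQuals <- rev(revQuals)
  fv <- .splitBases(fwdBases)
  rv <- .splitBases(rcBases)
  offs <- seq.int(params$minOverlap, min(lf, lr))
  mm <- vapply(offs, function(o) {
    .hammingVec(fv[(lf - o + 1L):lf], rv[seq_len(o)])
  }, numeric(1))
  frac <- mm / offs
  best <- which(frac == min(frac))
  best <- best[length(best)]                   # ties -> longest overlap
  if (frac[best] > params$maxOverlapMismatchFrac)
    return(list(status = "unmerged"))
  o <- offs[best]
  fIdx <- (lf - o + 1L):lf
  rIdx <- seq_len(o)
  consBase <- fv[fIdx]
  consQual <- pmax(fwdQuals[fIdx], rcQuals[rIdx])
  dis <- fv[fIdx] != rv[rIdx]
  takeRev <- dis & rcQuals[rIdx] > fwdQuals[fIdx]
  consBase[takeRev] <- rv[rIdx][takeRev]
  list(status = "merged",
       bases = paste0(substr(fwdBases, 1L, lf - o),
                      paste(consBase, collapse = ""),
                      substr(rcBases, o + 1L, lr)),
       quals = c(fwdQuals[seq_len(lf - o)], consQual,
                 if (o < lr) rcQuals[(o + 1L):lr] else integer(0)),
       overlapLength = o,
       overlapMismatches = as.integer(mm[best]))
}

#' Filter merged reads on ambiguity and length
#'
#' Removes merged reads containing ambiguous bases (anything outside
#' A/C/G/T) and reads whose length falls outside the expected amplicon
#' window; every removal carries a reason code, so read counts are
#' conserved across the stage.
#'
#' @param bases Character vector of merged-read sequences.
#' @param lengthWindow Numeric \code{c(min, max)} acceptable length.
#' @return list with \code{keep} (logical vector) and \code{reason}
#'   (character vector, \code{NA} for kept reads, else
#'   \code{"ambiguous"} or \code{"length"}).
#' @export
filterMerged <- function(bases, lengthWindow) {
  stopifnot(length(lengthWindow) == 2L)
  chars <- strsplit(bases, "", fixed = TRUE)
  ambiguous <- vapply(chars, function(b) {
    any(!(b %in% c("A", "C", "G", "T")))
  }, logical(1))
  len <- nchar(bases)
  badLen <- len < lengthWindow[1] | len > lengthWindow[2]
  reason <- rep(NA_character_, length(bases))
  reason[badLen] <- "length"
  reason[ambiguous] <- "ambiguous"
  list(keep = is.na(reason), reason = reason)
}

## anchored substitution-only primer match at one end;
## returns list(offset, mismatches) or NULL
.anchoredMatch <- function(chars, coreChars, maxMismatch, maxOffset,
                           fromEnd = FALSE) {
  k <- length(coreChars)
  L <- length(chars)
  best <- NULL
  for (off in 0:maxOffset) {
    if (k + off > L) break
    idx <- if (fromEnd) (L - off - k + 1L):(L - off) else (off + 1L):(off + k)
    mm <- .hammingVec(chars[idx], coreChars)
    if (is.null(best) || mm < best$mismatches)
      best <- list(offset = off, mismatches = mm)
    if (best$mismatches == 0L) break
  }
  if (is.null(best) || best$mismatches > maxMismatch) NULL else best
}

#' Remove primer regions from a merged read
#'
#' Anchored, substitution-only matching of the forward core at the 5' end
#' and of the reverse complement of the reverse core at the 3' end, each
#' tolerating up to \code{maxPrimerMismatch} substitutions (and up to
#' \code{leadingRandom} spacer bases before/after the anchor). Both primer
#' regions and any spacer are removed, leaving the bare insert.
#'
#' @param bases Merged read sequence (single string).
#' @param fwd,rev Forward and reverse [Primer-class] objects.
#' @param params A [processingParams()] bundle.
#' @return list with \code{status} (\code{"trimmed"}/\code{"rejected"}),
#'   \code{insert}, \code{reason}, \code{fwdMismatches},
#'   \code{revMismatches}.
#' @examples
#' prm <- mibirdPrimers()
#' amp <- paste0(primerCore(prm$fwd), strrep("A", 20),
#'               reverseComplementSeq(primerCore(prm$rev)))
#' trimPrimers(amp, prm$fwd, prm$rev)$insert
#' @export
trimPrimers <- function(bases, fwd, rev, params = processingParams()) {
  fc <- .splitBases(primerCore(fwd))
  rc <- .splitBases(reverseComplementSeq(primerCore(rev)))
  chars <- .splitBases(bases)
  if (length(chars) < length(fc) + length(rc))
    return(list(status = "rejected", insert = NA_character_,
                reason = "too_short", fwdMismatches = NA_integer_,
                revMismatches = NA_integer_))
  fhit <- .anchoredMatch(chars, fc, params$maxPrimerMismatch,
                         params$leadingRandom)
  if (is.null(fhit))
    return(list(status = "rejected", insert = NA_character_,
                reason = "fwd_primer", fwdMismatches = NA_integer_,
                revMismatches = NA_integer_))
  rhit <- .anchoredMatch(chars, rc, params$maxPrimerMismatch,
                         params$leadingRandom, fromEnd = TRUE)
  if (is.null(rhit))
    return(list(status = "rejected", insert = NA_character_,
                reason = "rev_primer", fwdMismatches = fhit$mismatches,
                revMismatches = NA_integer_))
  from <- fhit$offset + length(fc) + 1L
  to <- length(chars) - rhit$offset - length(rc)
  if (to < from - 1L)
    return(list(status = "rejected", insert = NA_character_,
                reason = "too_short", fwdMismatches = fhit$mismatches,
                revMismatches = rhit$mismatches))
  list(status = "trimmed",
       insert = substr(bases, from, to),
       reason = NA_character_,
       fwdMismatches = fhit$mismatches,
       revMismatches = rhit$mismatches)
}

#' Two-tier dereplication of insert sequences
#'
#' Exact dereplication first: identical sequences collapse to one record
#' with their read count. Sequences seen at least \code{minReads} times
#' become representatives. Each under-represented sequence is then
#' compared against all representatives and absorbed into the best one
#' (highest identity; ties to the higher-count representative, then
#' lexicographic) when its identity reaches \code{rescueIdentity} — the
#' operational "99 percent, one or two nucleotide differences" rescue.
#' Unabsorbed under-represented sequences are discarded but reported, so
#' total read counts are conserved.
#'
#' @param seqs Character vector of insert-only read sequences (one entry
#'   per read).
#' @param params A [processingParams()] bundle.
#' @return list with \code{units} (data.frame \code{representative},
#'   \code{read_count}, \code{n_members}), \code{members} (list of
#'   data.frames \code{sequence}, \code{count}, \code{identity}, parallel
#'   to \code{units}) and \code{discarded} (data.frame \code{sequence},
#'   \code{count}, \code{best_identity}).
#' @export
dereplicate <- function(seqs, params = processingParams()) {
  stopifnot(all(nzchar(seqs)))
  if (length(seqs) == 0L)
    return(list(units = data.frame(representative = character(0),
                                   read_count = integer(0),
                                   n_members = integer(0)),
                members = list(),
                discarded = data.frame(sequence = character(0),
                                       count = integer(0),
                                       best_identity = numeric(0))))
  tab <- table(seqs)
  cnt <- as.integer(tab)
  sq <- names(tab)
  ord <- order(-cnt, sq)                       # count desc, then sequence
  cnt <- cnt[ord]; sq <- sq[ord]
  isRep <- cnt >= params$minReads
  reps <- sq[isRep]; repCnt <- cnt[isRep]
  members <- lapply(seq_along(reps), function(i) {
    data.frame(sequence = reps[i], count = repCnt[i], identity = 1,
               stringsAsFactors = FALSE)
  })
  absorbed <- integer(length(reps))
  discarded <- list()
  under <- which(!isRep)
  for (i in under) {
    if (length(reps) == 0L) {
      discarded[[length(discarded) + 1L]] <-
        data.frame(sequence = sq[i], count = cnt[i],
                   best_identity = NA_real_, stringsAsFactors = FALSE)
      next
    }
    if (params$identityMode == "hamming") {
      id <- vapply(reps, function(r) {
        if (nchar(r) != nchar(sq[i])) return(-Inf)
        1 - .hammingVec(.splitBases(r), .splitBases(sq[i])) / nchar(r)
      }, numeric(1), USE.NAMES = FALSE)
    } else {
      d <- as.integer(utils::adist(sq[i], reps))
      id <- 1 - d / pmax(nchar(sq[i]), nchar(reps))
    }
    best <- which(id == max(id))
    if (length(best) > 1L) {                   # ties: higher count, then seq
      best <- best[order(-repCnt[best], reps[best])][1L]
    }
    if (is.finite(id[best]) && id[best] >= params$rescueIdentity) {
      absorbed[best] <- absorbed[best] + cnt[i]
      members[[best]] <- rbind(members[[best]],
        data.frame(sequence = sq[i], count = cnt[i], identity = id[best],
                   stringsAsFactors = FALSE))
    } else {
      discarded[[length(discarded) + 1L]] <-
        data.frame(sequence = sq[i], count = cnt[i],
                   best_identity = if (is.finite(id[best])) id[best]
                                   else NA_real_,
                   stringsAsFactors = FALSE)
    }
  }
  units <- data.frame(representative = reps,
                      read_count = repCnt + absorbed,
                      n_members = vapply(members, nrow, integer(1)),
                      stringsAsFactors = FALSE)
  disc <- if (length(discarded)) do.call(rbind, discarded)
          else data.frame(sequence = character(0), count = integer(0),
                          best_identity = numeric(0))
  list(units = units, members = members, discarded = disc)
}

## Coerce a QualityScaledDNAStringSet or a bases/quals list into the
## internal read-set representation.
.asReadSet <- function(x) {
  if (methods::is(x, "QualityScaledDNAStringSet")) {
    list(id = if (is.null(names(x))) paste0("read", seq_along(x))
              else names(x),
         bases = as.character(x),
         quals = as.list(methods::as(Biostrings::quality(x),
                                     "IntegerList")))
  } else if (is.list(x) && all(c("bases", "quals") %in% names(x))) {
    list(id = if (is.null(x$id)) paste0("read", seq_along(x$bases))
              else x$id,
         bases = x$bases, quals = x$quals)
  } else {
    stop("unsupported read-set input", call. = FALSE)
  }
}

#' Read a paired-end FASTQ sample
#'
#' @param fwdPath,revPath Paths to R1/R2 FASTQ files (Phred+33).
#' @return list with elements \code{fwd} and \code{rev}, each a
#'   [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastqPair <- function(fwdPath, revPath) {
  rd <- function(p) {
    ## the reader warns about dropping FASTQ metadata columns we never use
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
  }
  list(fwd = rd(fwdPath), rev = rd(revPath))
}

#' Run the full read-processing pipeline on one sample
#'
#' Quality tail trimming, pair merging, ambiguity/length filtering,
#' primer removal and two-tier dereplication, with per-stage accounting so
#' the read budget is conserved end to end.
#'
#' @param fwd,rev Paired reads: [Biostrings::QualityScaledDNAStringSet]
#'   objects or lists with \code{bases} (character) and \code{quals}
#'   (list of integer vectors).
#' @param fwdPrimer,revPrimer [Primer-class] objects (defaults: MiBird-U).
#' @param params A [processingParams()] bundle.
#' @return list with \code{units}, \code{members}, \code{discarded} (see
#'   [dereplicate()]) and \code{log}, a data.frame with columns
#'   \code{stage}, \code{kept}, \code{removed}, \code{reason}.
#' @export
processReads <- function(fwd, rev, fwdPrimer = mibirdPrimers()$fwd,
                         revPrimer = mibirdPrimers()$rev,
                         params = processingParams()) {
  f <- .asReadSet(fwd); r <- .asReadSet(rev)
  stopifnot(length(f$bases) == length(r$bases))
  n <- length(f$bases)
  log <- data.frame(stage = "input", kept = n, removed = 0L,
                    reason = NA_character_, stringsAsFactors = FALSE)
  ## tail trimming (no reads dropped here)
  for (i in seq_len(n)) {
    tf <- qualityTrim(f$bases[i], f$quals[[i]], params$phredCutoff)
    f$bases[i] <- tf$bases; f$quals[[i]] <- tf$quals
    tr <- qualityTrim(r$bases[i], r$quals[[i]], params$phredCutoff)
    r$bases[i] <- tr$bases; r$quals[[i]] <- tr$quals
  }
  log <- rbind(log, data.frame(stage = "quality_trim", kept = n,
                               removed = 0L, reason = NA_character_))
  ## merging
  merged <- vector("list", n)
  for (i in seq_len(n))
    merged[[i]] <- mergePair(f$bases[i], f$quals[[i]], r$bases[i],
                             r$quals[[i]], params)
  ok <- vapply(merged, function(m) m$status == "merged", logical(1))
  log <- rbind(log, data.frame(stage = "merge", kept = sum(ok),
                               removed = sum(!ok), reason = "unmerged"))
  mBases <- vapply(merged[ok], `[[`, character(1), "bases")
  ## ambiguity / length filter
  win <- params$lengthWindow
  if (is.null(win)) {
    expAmp <- nchar(primerCore(fwdPrimer)) + params$expectedInsertLength +
      nchar(primerCore(revPrimer))
    win <- c(floor(0.8 * expAmp), ceiling(1.2 * expAmp))
  }
  if (length(mBases)) {
    flt <- filterMerged(mBases, win)
    for (rs in c("ambiguous", "length")) {
      nrem <- sum(flt$reason == rs, na.rm = TRUE)
      log <- rbind(log, data.frame(stage = "filter", kept = NA_integer_,
                                   removed = nrem, reason = rs))
    }
    mBases <- mBases[flt$keep]
  } else {
    log <- rbind(log, data.frame(stage = "filter", kept = 0L, removed = 0L,
                                 reason = NA_character_))
  }
  log$kept[log$stage == "filter"] <- length(mBases)
  ## primer removal
  inserts <- character(0)
  nrej <- c(too_short = 0L, fwd_primer = 0L, rev_primer = 0L)
  for (b in mBases) {
    tp <- trimPrimers(b, fwdPrimer, revPrimer, params)
    if (tp$status == "trimmed") inserts <- c(inserts, tp$insert)
    else nrej[tp$reason] <- nrej[tp$reason] + 1L
  }
  for (rs in names(nrej))
    log <- rbind(log, data.frame(stage = "trim_primers",
                                 kept = NA_integer_, removed = nrej[[rs]],
                                 reason = rs))
  log$kept[log$stage == "trim_primers"] <- length(inserts)
  ## dereplication
  drp <- dereplicate(inserts, params)
  log <- rbind(log, data.frame(stage = "dereplicate",
                               kept = sum(drp$units$read_count),
                               removed = sum(drp$discarded$count),
                               reason = "under_represented"))
  rownames(log) <- NULL
  c(drp, list(log = log))
}

#' Write dereplicated representatives as size-annotated FASTA
#'
#' Headers use the \code{>unitN;size=COUNT} dialect common to
#' dereplication tools, carrying the absorbed read count of each
#' representative.
#'
#' @param derep Result of [dereplicate()] or [processReads()].
#' @param path Output FASTA file.
#' @return \code{path}, invisibly.
#' @export
writeDerepFasta <- function(derep, path) {
  u <- derep$units
  seqs <- Biostrings::DNAStringSet(u$representative)
  names(seqs) <- sprintf("unit%d;size=%d", seq_len(nrow(u)), u$read_count)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname writeDerepFasta
#' @param log The \code{log} component of a [processReads()] result.
#' @export
writeStageLog <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
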