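.expectedList <- function(manifest) {
  if (is.list(manifest$expected_species) &&
      !is.character(manifest$expected_species)) {
    lapply(manifest$expected_species, function(x) x[nzchar(x)])
  } else {
    lapply(strsplit(ifelse(is.na(manifest$expected_species), "",
                           manifest$expected_species), ";", fixed = TRUE),
           function(x) trimws(x[nzchar(trimws(x))]))
  }
}

.checkManifest <- function(manifest) {
  need <- c("sample_id", "expected_species", "is_control")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$sample_id))
    stop("sample_ids must be unique", call. = FALSE)
  invisible(TRUE)
}

#' Build a detection table from per-sample assignments
#'
#' Accumulates assigned unit read counts into a sample-by-species count
#' matrix; reads of unassigned or ambiguous units accumulate into a
#' per-sample unassigned pool. Samples listed in the manifest but absent
#' from the assignments get all-zero rows, so negative controls always
#' appear.
#'
#' @param assignments data.frame in the shape of [assignTaxa()] output
#'   plus a \code{sample_id} column; \code{read_count} must be filled.
#' @param manifest data.frame with columns \code{sample_id},
#'   \code{expected_species} (semicolon-separated string, possibly
#'   empty) and \code{is_control} (logical). Assignments referencing an
#'   unknown sample are an error.
#' @return A [DetectionTable-class].
#' @export
detectionTable <- function(assignments, manifest) {
  .checkManifest(manifest)
  samples <- as.character(manifest$sample_id)
  unknown <- setdiff(unique(assignments$sample_id), samples)
  if (length(unknown))
    stop("unknown sample_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (nrow(assignments) && anyNA(assignments$read_count))
    stop("assignments must carry read counts", call. = FALSE)
  assigned <- assignments[assignments$status == "assigned", , drop = FALSE]
  species <- sort(unique(assigned$species))
  counts <- matrix(0L, nrow = length(samples), ncol = length(species),
                   dimnames = list(samples, species))
  if (nrow(assigned)) {
    agg <- stats::aggregate(read_count ~ sample_id + species, assigned, sum)
    counts[cbind(as.character(agg$sample_id), as.character(agg$species))] <-
      as.integer(agg$read_count)
  }
  other <- assignments[assignments$status != "assigned", , drop = FALSE]
  unassigned <- stats::setNames(rep(0, length(samples)), samples)
  if (nrow(other)) {
    agg <- tapply(other$read_count, other$sample_id, sum)
    unassigned[names(agg)] <- as.numeric(agg)
  }
  methods::new("DetectionTable", counts = counts, unassigned = unassigned)
}

#' Accessors for DetectionTable objects
#'
#' @param x A [DetectionTable-class].
#' @return \code{detectionCounts}: the sample-by-species integer matrix;
#'   \code{unassignedReads}: named per-sample unassigned read counts;
#'   \code{totalReads}: named per-sample totals (assigned + unassigned).
#' @name DetectionTable-accessors
#' @aliases detectionCounts unassignedReads totalReads
NULL

#' @rdname DetectionTable-accessors
#' @export
setMethod("detectionCounts", "DetectionTable", function(x) x@counts)
#' @rdname DetectionTable-accessors
#' @export
setMethod("unassignedReads", "DetectionTable", function(x) x@unassigned)
#' @rdname DetectionTable-accessors
#' @export
setMethod("totalReads", "DetectionTable", function(x) {
  rowSums(x@counts) + x@unassigned
})

setMethod("show", "DetectionTable", function(object) {
  cat("DetectionTable:", nrow(object@counts), "sample(s) x",
      ncol(object@counts), "species,",
      sum(totalReads(object)), "reads total\n")
  invisible(NULL)
})

#' Per-sample percentage of reads from expected species
#'
#' For each non-control sample, the percentage of its total reads
#' (assigned plus unassigned) carried by the species expected in that
#' sample — the "percent target" summary of a known-composition survey.
#' Percentages are reported rounded to one decimal; raw fractions are
#' retained alongside. Samples with zero total reads get \code{NA}.
#'
#' @param x A [DetectionTable-class].
#' @param manifest Sample manifest (see [detectionTable()]).
#' @return data.frame: \code{sample_id}, \code{is_control},
#'   \code{total}, \code{target}, \code{non_target},
#'   \code{percent_target} (1 decimal), \code{fraction_target} (raw).
#' @export
targetPercentages <- function(x, manifest) {
  .checkManifest(manifest)
  counts <- detectionCounts(x)
  samples <- rownames(counts)
  idx <- match(samples, manifest$sample_id)
  if (anyNA(idx))
    stop("manifest missing sample(s): ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  expected <- .expectedList(manifest)[idx]
  isCtrl <- manifest$is_control[idx]
  total <- totalReads(x)
  target <- vapply(seq_along(samples), function(i) {
    sp <- intersect(expected[[i]], colnames(counts))
    sum(counts[samples[i], sp])
  }, numeric(1))
  frac <- ifelse(total > 0, target / total, NA_real_)
  frac[isCtrl] <- NA_real_
  data.frame(sample_id = samples, is_control = isCtrl,
             total = as.numeric(total), target = target,
             non_target = as.numeric(total) - target,
             percent_target = round(100 * frac, 1),
             fraction_target = frac,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Contamination screening of negative controls
#'
#' Lists, for every control sample, the species detected with nonzero
#' read counts. An empty report means all controls are clean — the
#' expected outcome when no contamination occurred during sampling or
#' processing. Non-control samples never appear.
#'
#' @param x A [DetectionTable-class].
#' @param manifest Sample manifest with at least one control.
#' @return data.frame with columns \code{sample_id}, \code{species},
#'   \code{reads}; zero rows when all controls pass.
#' @export
controlCheck <- function(x, manifest) {
  .checkManifest(manifest)
  if (!any(manifest$is_control))
    stop("manifest has no control samples", call. = FALSE)
  counts <- detectionCounts(x)
  ctrl <- intersect(rownames(counts),
                    manifest$sample_id[manifest$is_control])
  rows <- list()
  for (s in ctrl) {
    hit <- which(counts[s, ] > 0)
    if (length(hit))
      rows[[s]] <- data.frame(sample_id = s,
                              species = colnames(counts)[hit],
                              reads = as.integer(counts[s, hit]),
                              stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else {
    data.frame(sample_id = character(0), species = character(0),
               reads = integer(0))
  }
}

#' Read and write sample manifests and detection tables
#'
#' Manifests are TSV with columns \code{sample_id},
#' \code{expected_species} (semicolon-separated list, possibly empty) and
#' \code{is_control}. Detection tables round-trip as a wide TSV count
#' matrix (first column \code{sample_id}, one column per species, plus
#' \code{unassigned}).
#'
#' @param path File path.
#' @return \code{readSampleManifest} returns the manifest data.frame;
#'   \code{readDetectionTable} a [DetectionTable-class]; writers return
#'   \code{path} invisibly.
#' @export
readSampleManifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(expected_species = "character"))
  m$expected_species[is.na(m$expected_species)] <- ""
  m$is_control <- as.logical(m$is_control)
  .checkManifest(m)
  m
}

#' @rdname readSampleManifest
#' @param manifest Manifest data.frame (for writing).
#' @export
writeSampleManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readSampleManifest
#' @param x A [DetectionTable-class] (for writing).
#' @export
writeDetectionTable <- function(x, path) {
  df <- data.frame(sample_id = rownames(detectionCounts(x)),
                   detectionCounts(x),
                   unassigned = unassignedReads(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readSampleManifest
#' @export
readDetectionTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("sample_id", "unassigned")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$sample_id
  methods::new("DetectionTable", counts = counts,
               unassigned = stats::setNames(as.numeric(df$unassigned),
                                            df$sample_id))
}
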