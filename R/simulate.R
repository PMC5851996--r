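#' Per-species primer-site plan for a simulated panel
#'
#' Describes, for each simulated reference, how many substitutions to
#' plant in the forward/reverse primer binding sites, whether those
#' substitutions are G/T-wobble-compatible (primer G over a site A,
#' primer T over a site C: a wobble match when wobble pairing is
#' accepted, a mismatch otherwise), and whether a whole primer region is
#' deleted — the mechanism behind references that drop out of in-silico
#' PCR.
#'
#' @param nSpecies Number of species.
#' @param fwdMismatches,revMismatches Integer substitution counts per
#'   species (recycled).
#' @param wobbleCompatible Logical, plant wobble-compatible substitutions
#'   (recycled; applies to both sites).
#' @param fwdDeleted,revDeleted Logical site-deletion flags (recycled).
#' @return data.frame with one row per species.
#' @export
makeSitePlan <- function(nSpecies, fwdMismatches = 0L, revMismatches = 0L,
                         wobbleCompatible = FALSE, fwdDeleted = FALSE,
                         revDeleted = FALSE) {
  data.frame(species_index = seq_len(nSpecies),
             fwd_mismatches = rep_len(as.integer(fwdMismatches), nSpecies),
             rev_mismatches = rep_len(as.integer(revMismatches), nSpecies),
             wobble_compatible = rep_len(wobbleCompatible, nSpecies),
             fwd_deleted = rep_len(fwdDeleted, nSpecies),
             rev_deleted = rep_len(revDeleted, nSpecies))
}

#' Configuration of a simulated reference panel and survey
#'
#' Bundles everything the simulator needs: the taxonomy plan, the
#' primer-site mismatch/deletion plan, insert geometry, the sample sheet
#' with per-species read abundances, and the sequencing model (read
#' length, substitution error rate, quality profile). Identical
#' configurations (same seed) give byte-identical output.
#'
#' The defaults emulate the geometry of a universal-primer 12S survey:
#' a ~171 bp hypervariable insert flanked by conserved primer sites,
#' 2 x 150 bp paired-end reads, and inserts kept at least 6 edits apart
#' so every species pair is resolvable.
#'
#' @param seed Integer RNG seed.
#' @param nSpecies Number of reference species (default 16).
#' @param speciesPerGenus Species per simulated genus (default 2).
#' @param insertLength Insert length between the primer regions (default
#'   171 nt).
#' @param minInsertDistance Minimum pairwise Levenshtein distance between
#'   inserts (default 6).
#' @param padLength Random flanking sequence on each side of the
#'   amplicon region (default 50 nt).
#' @param sitePlan A [makeSitePlan()] data.frame, or \code{NULL} for
#'   all-perfect sites.
#' @param samples Survey design: list of lists with \code{sample_id},
#'   \code{abundance} (named read counts by species) and
#'   \code{is_control}; \code{NULL} defers to [zooSurveyDesign()] at
#'   survey time.
#' @param readLength Read length (default 150 nt).
#' @param errorRate Per-base substitution error rate in reads (default
#'   0.001).
#' @param meanPhred Phred score of the read body (default 35).
#' @param tailLength,tailPhred Length and Phred score of the low-quality
#'   read tail (defaults 10 nt at Q2, below the Q10 trimming cutoff).
#' @param abundanceMode \code{"exact"} (default; abundances are realised
#'   verbatim) or \code{"multinomial"} (abundances are weights;
#'   \code{readsPerSample} reads are drawn).
#' @param readsPerSample Reads per sample in multinomial mode (default
#'   1000).
#' @param fwd,rev The primer pair (defaults: MiBird-U).
#' @return A list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nSpecies = 16L,
                             speciesPerGenus = 2L, insertLength = 171L,
                             minInsertDistance = 6L, padLength = 50L,
                             sitePlan = NULL, samples = NULL,
                             readLength = 150L, errorRate = 0.001,
                             meanPhred = 35L, tailLength = 10L,
                             tailPhred = 2L,
                             abundanceMode = c("exact", "multinomial"),
                             readsPerSample = 1000L,
                             fwd = mibirdPrimers()$fwd,
                             rev = mibirdPrimers()$rev) {
  abundanceMode <- match.arg(abundanceMode)
  stopifnot(nSpecies >= 1, insertLength >= 1, errorRate >= 0,
            errorRate < 1, padLength >= 0)
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              speciesPerGenus = as.integer(speciesPerGenus),
              insertLength = as.integer(insertLength),
              minInsertDistance = as.integer(minInsertDistance),
              padLength = as.integer(padLength), sitePlan = sitePlan,
              samples = samples, readLength = as.integer(readLength),
              errorRate = errorRate, meanPhred = as.integer(meanPhred),
              tailLength = as.integer(tailLength),
              tailPhred = as.integer(tailPhred),
              abundanceMode = abundanceMode,
              readsPerSample = as.integer(readsPerSample),
              fwd = fwd, rev = rev)
  class(cfg) <- "simulationConfig"
  cfg
}

.randomSeq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, character(1))
}

.simTaxonomy <- function(n, perGenus) {
  g <- ceiling(seq_len(n) / perGenus)
  f <- ceiling(g / 2)
  o <- ceiling(f / 2)
  data.frame(accession = sprintf("SIM%04d", seq_len(n)),
             species = sprintf("Simus sp%03d", seq_len(n)),
             genus = sprintf("Genus%03d", g),
             family = sprintf("Family%03d", f),
             order = sprintf("Order%02d", o),
             stringsAsFactors = FALSE)
}

## plant `k` substitutions into a primer-orientation site
.plantSite <- function(core, k, wobbleCompatible) {
  if (k == 0L) return(core)
  b <- .splitBases(core)
  if (wobbleCompatible) {
    cand <- which(b %in% c("G", "T"))
    if (length(cand) < k)
      stop("not enough G/T primer positions for ", k,
           " wobble-compatible substitutions", call. = FALSE)
    pos <- sample(cand, k)
    b[pos] <- ifelse(b[pos] == "G", "A", "C")  # G->A, T->C: wobble pairs
  } else {
    pos <- sample(length(b), k)
    for (p in pos) {
      ## avoid the matching base and the wobble partner, so the change is
      ## a mismatch even with wobble pairing accepted
      avoid <- switch(b[p], G = c("G", "A"), T = c("T", "C"),
                      A = "A", C = "C")
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
    }
  }
  paste(b, collapse = "")
}

#' Simulate a reference panel with planted primer-site features
#'
#' Generates \code{nSpecies} mitogenome-like references, each
#' \code{pad + forward site + insert + revcomp(reverse site) + pad}, with
#' the substitutions/deletions of the site plan applied and all pairwise
#' insert distances at least \code{minInsertDistance}. The truth sidecar
#' carries the realised site plan, the bare inserts and the full pairwise
#' Levenshtein distance matrix (recomputed from the emitted inserts, so
#' truth and data cannot drift apart). Identical seeds give identical
#' panels.
#'
#' @param config A [simulationConfig()].
#' @return list with \code{panel} (a [ReferencePanel-class]) and
#'   \code{truth}: \code{sitePlan}, \code{inserts} (named by accession),
#'   \code{distances} (integer matrix), \code{taxonomy}.
#' @examples
#' sim <- simulatePanel(simulationConfig(seed = 7, nSpecies = 4,
#'                                       insertLength = 40))
#' sim$panel
#' @export
simulatePanel <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  n <- config$nSpecies
  if (config$minInsertDistance > config$insertLength)
    stop("distance plan infeasible: minimum distance exceeds insert length",
         call. = FALSE)
  tx <- .simTaxonomy(n, config$speciesPerGenus)
  plan <- if (is.null(config$sitePlan)) makeSitePlan(n) else config$sitePlan
  stopifnot(nrow(plan) == n)
  ## inserts with enforced minimum pairwise distance
  inserts <- .randomSeq(n, config$insertLength)
  D <- if (n > 1L) editDistanceMatrix(inserts) else
    matrix(0L, 1, 1)
  tries <- 0L
  while (n > 1L) {
    offd <- D + diag(Inf, n)
    bad <- unique(which(offd < config$minInsertDistance,
                        arr.ind = TRUE)[, 2L])
    if (!length(bad)) break
    tries <- tries + 1L
    if (tries > 25L)
      stop("distance plan infeasible: could not separate inserts by ",
           config$minInsertDistance, " edits", call. = FALSE)
    inserts[bad] <- .randomSeq(length(bad), config$insertLength)
    D <- editDistanceMatrix(inserts)
  }
  dimnames(D) <- list(tx$accession, tx$accession)
  names(inserts) <- tx$accession
  fwdCore <- primerCore(config$fwd)
  revCore <- primerCore(config$rev)
  seqs <- character(n)
  for (i in seq_len(n)) {
    fwdSite <- if (plan$fwd_deleted[i]) "" else
      .plantSite(fwdCore, plan$fwd_mismatches[i], plan$wobble_compatible[i])
    revSite <- if (plan$rev_deleted[i]) "" else
      .plantSite(revCore, plan$rev_mismatches[i], plan$wobble_compatible[i])
    seqs[i] <- paste0(.randomSeq(1L, config$padLength), fwdSite,
                      inserts[i],
                      if (nzchar(revSite)) reverseComplementSeq(revSite)
                      else "",
                      .randomSeq(1L, config$padLength))
  }
  plan$accession <- tx$accession
  list(panel = ReferencePanel(seqs, tx),
       truth = list(sitePlan = plan, inserts = inserts, distances = D,
                    taxonomy = tx))
}

#' A zoo-like survey design over a simulated panel
#'
#' Thirteen single-cage water samples plus three field negative controls,
#' emulating a known-composition zoo survey: twelve cages each hold one
#' species, one walk-through cage holds five species with uneven
#' abundances, and controls hold nothing. Requires at least 16 species.
#'
#' @param speciesNames Character vector of panel species names.
#' @param depth Reads for a typical single-species cage (default 500).
#' @return Survey design list suitable for
#'   \code{simulationConfig(samples = )}.
#' @export
zooSurveyDesign <- function(speciesNames, depth = 500L) {
  if (length(speciesNames) < 16L)
    stop("zoo-like design needs at least 16 species", call. = FALSE)
  design <- list()
  single <- c(1:4, 6:13)
  for (i in single) {
    design[[length(design) + 1L]] <- list(
      sample_id = sprintf("cage%02d", i),
      abundance = stats::setNames(depth, speciesNames[i]),
      is_control = FALSE)
  }
  ## walk-through cage: its resident plus four co-housed species
  design[[length(design) + 1L]] <- list(
    sample_id = "cage05",
    abundance = stats::setNames(
      as.integer(depth * c(1.0, 0.1, 0.5, 0.3, 0.6)),
      speciesNames[c(5, 4, 14, 15, 16)]),
    is_control = FALSE)
  for (k in 1:3)
    design[[length(design) + 1L]] <- list(
      sample_id = sprintf("fieldNC%d", k),
      abundance = stats::setNames(integer(0), character(0)),
      is_control = TRUE)
  design
}

.phredProfile <- function(len, config) {
  q <- rep(config$meanPhred, len)
  tl <- min(config$tailLength, len)
  if (tl > 0L) q[(len - tl + 1L):len] <- config$tailPhred
  as.integer(q)
}

.addErrors <- function(bases, rate) {
  if (rate <= 0) return(bases)
  b <- .splitBases(bases)
  hit <- which(stats::runif(length(b)) < rate)
  for (p in hit) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

#' Simulate a multi-sample paired-end amplicon survey
#'
#' Draws 150 bp (configurable) paired-end reads from the two ends of each
#' species' full amplicon (forward primer + insert + reverse-complemented
#' reverse primer), with seeded substitution errors and a flat quality
#' profile with a low-quality tail. Negative controls receive zero
#' biological reads. The truth manifest records the realised per-sample
#' per-species read counts; the sample manifest (expected species,
#' control flags) is derived from the design.
#'
#' @param config A [simulationConfig()]; its \code{samples} design is
#'   used, defaulting to [zooSurveyDesign()] over the panel.
#' @param sim Result of [simulatePanel()] (panel + truth).
#' @return list with \code{samples} (named list; each element has
#'   \code{fwd}/\code{rev} read sets usable by [processReads()]),
#'   \code{truth} (data.frame \code{sample_id}, \code{species},
#'   \code{reads}) and \code{manifest} (see [detectionTable()]).
#' @export
simulateSurvey <- function(config, sim) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed + 1L)
  tx <- sim$truth$taxonomy
  design <- config$samples
  if (is.null(design)) design <- zooSurveyDesign(tx$species)
  fwdCore <- primerCore(config$fwd)
  revCore <- primerCore(config$rev)
  amplicon <- stats::setNames(
    paste0(fwdCore, sim$truth$inserts, reverseComplementSeq(revCore)),
    tx$species)
  rl <- config$readLength
  samples <- list()
  truthRows <- list()
  manifestRows <- list()
  for (d in design) {
    ab <- d$abundance
    unknown <- setdiff(names(ab), tx$species)
    if (length(unknown))
      stop("species absent from panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (d$is_control) ab <- ab[0]
    if (config$abundanceMode == "multinomial" && length(ab)) {
      ab <- stats::setNames(
        as.integer(stats::rmultinom(1L, config$readsPerSample,
                                    ab / sum(ab))),
        names(ab))
    }
    ab <- ab[ab > 0]
    f <- list(id = character(0), bases = character(0), quals = list())
    r <- list(id = character(0), bases = character(0), quals = list())
    for (sp in names(ab)) {
      amp <- amplicon[[sp]]
      rcAmp <- reverseComplementSeq(amp)
      for (k in seq_len(ab[[sp]])) {
        id <- sprintf("%s:%s:%d", d$sample_id, gsub(" ", "_", sp), k)
        r1 <- .addErrors(substr(amp, 1L, rl), config$errorRate)
        r2 <- .addErrors(substr(rcAmp, 1L, rl), config$errorRate)
        f$id <- c(f$id, id); r$id <- c(r$id, id)
        f$bases <- c(f$bases, r1); r$bases <- c(r$bases, r2)
        f$quals <- c(f$quals, list(.phredProfile(nchar(r1), config)))
        r$quals <- c(r$quals, list(.phredProfile(nchar(r2), config)))
      }
    }
    samples[[d$sample_id]] <- list(fwd = f, rev = r)
    if (length(ab))
      truthRows[[d$sample_id]] <- data.frame(sample_id = d$sample_id,
                                             species = names(ab),
                                             reads = as.integer(ab),
                                             stringsAsFactors = FALSE)
    manifestRows[[d$sample_id]] <- data.frame(
      sample_id = d$sample_id,
      expected_species = paste(names(d$abundance), collapse = ";"),
      is_control = d$is_control, stringsAsFactors = FALSE)
  }
  truth <- if (length(truthRows)) do.call(rbind, truthRows)
           else data.frame(sample_id = character(0),
                           species = character(0), reads = integer(0))
  rownames(truth) <- NULL
  manifest <- do.call(rbind, manifestRows)
  rownames(manifest) <- NULL
  list(samples = samples, truth = truth, manifest = manifest)
}

#' Write a simulated survey to FASTQ files plus manifests
#'
#' One pair of Phred+33 FASTQ files per sample
#' (\code{<sample>_R1.fastq} / \code{_R2.fastq}; controls yield empty
#' files), with the truth manifest and sample manifest as TSV.
#'
#' @param survey Result of [simulateSurvey()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSurvey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(survey$samples)) {
    for (end in c("fwd", "rev")) {
      rs <- survey$samples[[sid]][[end]]
      suffix <- if (end == "fwd") "_R1.fastq" else "_R2.fastq"
      path <- file.path(dir, paste0(sid, suffix))
      if (length(rs$bases) == 0L) {
        file.create(path)
      } else {
        qs <- Biostrings::QualityScaledDNAStringSet(
          Biostrings::DNAStringSet(stats::setNames(rs$bases, rs$id)),
          methods::as(IRanges::IntegerList(rs$quals), "PhredQuality"))
        Biostrings::writeQualityScaledXStringSet(qs, path)
      }
    }
  }
  utils::write.table(survey$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSampleManifest(survey$manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
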