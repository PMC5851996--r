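prm <- mibirdPrimers()
fwdCore <- primerCore(prm$fwd)
revCore <- primerCore(prm$rev)

test_that("quality trimming keeps the longest above-cutoff segment", {
  r <- qualityTrim("ACGTACGT", rep(30L, 8), cutoff = 10)
  expect_equal(r$bases, "ACGTACGT")

  r2 <- qualityTrim(paste0(strrep("A", 50), "CC"),
                    c(rep(30L, 50), 2L, 2L), cutoff = 10)
  expect_equal(nchar(r2$bases), 50L)
  expect_equal(r2$bases, strrep("A", 50))

  # all below cutoff: empty output is allowed
  r3 <- qualityTrim("ACGT", rep(2L, 4), cutoff = 10)
  expect_equal(r3$bases, "")
  expect_length(r3$quals, 0L)

  # 'first' rule cuts at the first bad base
  r4 <- qualityTrim("ACGTACGT", c(30L, 2L, 30L, 30L, 30L, 30L, 30L, 30L),
                    method = "first")
  expect_equal(r4$bases, "A")
})

test_that("quality trimming matches exhaustive segment enumeration", {
  set.seed(21)
  for (i in 1:60) {
    n <- sample(5:30, 1)
    quals <- sample(0:40, n, replace = TRUE)
    bases <- randSeq(n)
    got <- qualityTrim(bases, quals, cutoff = 10)
    orc <- oracleQualityTrim(quals, 10)
    expect_equal(nchar(got$bases), unname(orc["len"]))
    if (orc["len"] > 0) {
      expect_equal(got$bases,
                   substr(bases, orc["start"], orc["start"] + orc["len"] - 1))
      expect_true(all(got$quals >= 10))
      # contiguity: output is a substring of the input
      expect_true(grepl(got$bases, bases, fixed = TRUE))
    }
  }
})

test_that("pair merging honours the minimum overlap and length arithmetic", {
  set.seed(22)
  amplicon <- randSeq(280)
  fwd <- substr(amplicon, 1, 150)
  rev <- rcSeq(substr(amplicon, 131, 280))   # exact 20-base overlap
  m <- mergePair(fwd, rep(30L, 150), rev, rep(30L, 150))
  expect_equal(m$status, "merged")
  expect_equal(nchar(m$bases), 280L)
  expect_equal(m$bases, amplicon)
  expect_equal(m$overlapLength, 20L)
  expect_equal(m$overlapMismatches, 0L)

  # true overlap of 9 < minimum of 10: unmerged
  amplicon2 <- paste0(strrep("A", 141), "GATTACAGA", strrep("C", 141))
  fwd2 <- substr(amplicon2, 1, 150)
  rev2 <- rcSeq(substr(amplicon2, 142, 291))
  m2 <- mergePair(fwd2, rep(30L, 150), rev2, rep(30L, 150))
  expect_equal(m2$status, "unmerged")
})

test_that("merge consensus takes the higher-quality base with max quality", {
  set.seed(220)
  amplicon <- paste0(randSeq(130), "ACGTACGTACGTACGTACGT", randSeq(130))
  fwd <- substr(amplicon, 1, 150)
  rev <- rcSeq(substr(amplicon, 131, 280))
  # corrupt one overlap position on the reverse read (position 20 of rc)
  rcRev <- substr(amplicon, 131, 280)
  substr(rcRev, 10, 10) <- if (substr(rcRev, 10, 10) == "A") "C" else "A"
  rev <- rcSeq(rcRev)
  fq <- rep(35L, 150); rq <- rep(12L, 150)
  m <- mergePair(fwd, fq, rev, rq)
  expect_equal(m$status, "merged")
  expect_equal(m$overlapMismatches, 1L)
  expect_equal(m$bases, amplicon)          # fwd (Q35) beats rev (Q12)
  expect_equal(max(m$quals), 35L)

  # with the qualities swapped the reverse base wins
  m2 <- mergePair(fwd, rep(12L, 150), rev, rep(35L, 150))
  expect_equal(substr(m2$bases, 140, 140), substr(rcRev, 10, 10))
})

test_that("merge choice equals exhaustive offset enumeration", {
  set.seed(23)
  for (i in 1:25) {
    lf <- sample(40:80, 1); lr <- sample(40:80, 1)
    trueOv <- sample(5:35, 1)
    amp <- randSeq(lf + lr - trueOv)
    fwd <- substr(amp, 1, lf)
    rev <- rcSeq(substr(amp, lf - trueOv + 1, nchar(amp)))
    # sprinkle errors into the forward read
    nerr <- sample(0:2, 1)
    if (nerr > 0) for (p in sample(lf, nerr)) {
      substr(fwd, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(fwd, p, p)), 1)
    }
    got <- mergePair(fwd, rep(30L, lf), rev, rep(20L, lr))
    orc <- oracleMergeChoice(fwd, rcSeq(rev), 10, 0.25)
    if (is.null(orc)) {
      expect_equal(got$status, "unmerged")
    } else {
      expect_equal(got$status, "merged")
      expect_equal(got$overlapLength, orc$o)
      expect_equal(got$overlapMismatches, orc$mm)
      expect_equal(nchar(got$bases), lf + lr - orc$o)
    }
  }
})

test_that("merged-read filter removes ambiguous and odd-length reads with reasons", {
  bases <- c("ACGTACGTAC", "ACGTNCGTAC", strrep("A", 40), "ACGT")
  flt <- filterMerged(bases, lengthWindow = c(8, 20))
  expect_equal(flt$keep, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(flt$reason[2], "ambiguous")
  expect_equal(flt$reason[3], "length")
  expect_equal(flt$reason[4], "length")
  # conservation: every read is kept or carries a reason
  expect_equal(sum(flt$keep) + sum(!is.na(flt$reason)), length(bases))
})

test_that("primer removal is anchored with a mismatch budget", {
  set.seed(24)
  insert <- randSeq(171)
  amp <- paste0(fwdCore, insert, rcSeq(revCore))
  t0 <- trimPrimers(amp, prm$fwd, prm$rev)
  expect_equal(t0$status, "trimmed")
  expect_equal(t0$insert, insert)
  expect_equal(nchar(t0$insert), 171L)

  # exactly 3 substitutions in the forward primer region: still trimmed
  amp3 <- amp
  for (p in c(2, 9, 17))
    substr(amp3, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(amp3, p, p)), 1)
  t3 <- trimPrimers(amp3, prm$fwd, prm$rev)
  expect_equal(t3$status, "trimmed")
  expect_equal(t3$fwdMismatches, 3L)

  # four substitutions: rejected
  amp4 <- amp3
  substr(amp4, 21, 21) <- sample(setdiff(c("A", "C", "G", "T"),
                                         substr(amp4, 21, 21)), 1)
  t4 <- trimPrimers(amp4, prm$fwd, prm$rev)
  expect_equal(t4$status, "rejected")
  expect_equal(t4$reason, "fwd_primer")

  # random-base spacers are consumed when allowed for
  spaced <- paste0("ACGTAC", amp, rcSeq("TTGCAG"))
  tSp <- trimPrimers(spaced, prm$fwd, prm$rev,
                     processingParams(leadingRandom = 6))
  expect_equal(tSp$status, "trimmed")
  expect_equal(tSp$insert, insert)

  expect_equal(trimPrimers("ACGT", prm$fwd, prm$rev)$reason, "too_short")
})

test_that("two-tier dereplication groups, rescues and conserves reads", {
  set.seed(25)
  rep1 <- randSeq(171)
  # one-substitution variant: identity 170/171 ~ 99.4% -> absorbed
  var1 <- rep1
  substr(var1, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                  substr(var1, 50, 50))[1]
  # three-substitution variant: identity 168/171 ~ 98.2% -> discarded
  var3 <- rep1
  for (p in c(10, 60, 120))
    substr(var3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(var3, p, p))[1]
  reads <- c(rep(rep1, 15), rep(var1, 9), rep(var3, 9))
  drp <- dereplicate(reads)
  expect_equal(nrow(drp$units), 1L)
  expect_equal(drp$units$representative, rep1)
  expect_equal(drp$units$read_count, 24L)
  expect_equal(drp$discarded$count, 9L)
  expect_lt(drp$discarded$best_identity, 0.99)
  # conservation
  expect_equal(sum(drp$units$read_count) + sum(drp$discarded$count),
               length(reads))

  # 12 identical reads -> one unit of 12
  drp2 <- dereplicate(rep(rep1, 12))
  expect_equal(drp2$units$read_count, 12L)

  # input order invariance
  drp3 <- dereplicate(sample(reads))
  expect_equal(drp3$units, drp$units)
})

test_that("dereplication matches brute-force grouping on small instances", {
  set.seed(26)
  for (trial in 1:5) {
    base <- randSeq(60)
    pool <- c(rep(base, sample(10:14, 1)))
    truthAbsorb <- 0L; truthDiscard <- 0L
    for (v in 1:3) {
      nsub <- sample(1:4, 1)
      var <- base
      for (p in sample(60, nsub))
        substr(var, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(var, p, p)), 1)
      cnt <- sample(1:9, 1)
      pool <- c(pool, rep(var, cnt))
      id <- 1 - oracleEditDistance(base, var) / 60
      if (id >= 0.99) truthAbsorb <- truthAbsorb + cnt
      else truthDiscard <- truthDiscard + cnt
    }
    drp <- dereplicate(pool)
    expect_equal(nrow(drp$units), 1L)
    expect_equal(drp$units$read_count, length(pool) - truthDiscard)
    expect_equal(sum(drp$discarded$count), truthDiscard)
  }
})

test_that("hamming identity mode only rescues equal-length variants", {
  base <- strrep("ACGT", 50)               # 200 nt
  var <- paste0(substr(base, 1, 199), "T") # 1 sub, id 99.5%
  short <- substr(base, 1, 150)
  drp <- dereplicate(c(rep(base, 12), rep(var, 3), rep(short, 3)),
                     processingParams(identityMode = "hamming"))
  expect_equal(drp$units$read_count, 15L)
  expect_equal(sum(drp$discarded$count), 3L)
})

test_that("the pipeline recovers distinct species amplicons losslessly", {
  cfg <- simulationConfig(seed = 27, nSpecies = 16, insertLength = 171,
                          errorRate = 0)
  sim <- simulatePanel(cfg)
  k <- 3
  species <- sim$truth$taxonomy$species[seq_len(k)]
  cfg$samples <- list(list(sample_id = "s1",
                           abundance = setNames(c(40L, 25L, 12L), species),
                           is_control = FALSE))
  sv <- simulateSurvey(cfg, sim)
  res <- processReads(sv$samples$s1$fwd, sv$samples$s1$rev)
  expect_equal(nrow(res$units), k)
  expect_setequal(res$units$representative,
                  unname(sim$truth$inserts[seq_len(k)]))
  expect_equal(sum(res$units$read_count), 40L + 25L + 12L)
  # stage accounting conserves the read budget
  lg <- res$log
  expect_equal(lg$kept[lg$stage == "input"], 77L)
  expect_equal(lg$kept[lg$stage == "merge"] +
               lg$removed[lg$stage == "merge"], 77L)
  expect_equal(lg$kept[lg$stage == "dereplicate"] +
               lg$removed[lg$stage == "dereplicate"],
               lg$kept[lg$stage == "trim_primers"][1])
})

test_that("dereplicated units and stage logs write to standard formats", {
  drp <- dereplicate(rep("ACGTACGTACGT", 11))
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeDerepFasta(drp, tf)
  fa <- Biostrings::readDNAStringSet(tf)
  expect_equal(names(fa), "unit1;size=11")
  expect_equal(as.character(fa[[1]]), "ACGTACGTACGT")
})

test_that("FASTQ pairs round-trip through files", {
  cfg <- simulationConfig(seed = 28, nSpecies = 16, insertLength = 60,
                          errorRate = 0)
  sim <- simulatePanel(cfg)
  cfg$samples <- list(
    list(sample_id = "s1",
         abundance = setNames(12L, sim$truth$taxonomy$species[1]),
         is_control = FALSE),
    list(sample_id = "nc1", abundance = setNames(integer(0), character(0)),
         is_control = TRUE))
  sv <- simulateSurvey(cfg, sim)
  dir <- withr::local_tempdir()
  writeSurvey(sv, dir)
  expect_true(file.exists(file.path(dir, "s1_R1.fastq")))
  expect_equal(file.size(file.path(dir, "nc1_R1.fastq")), 0)
  pr <- readFastqPair(file.path(dir, "s1_R1.fastq"),
                      file.path(dir, "s1_R2.fastq"))
  expect_length(pr$fwd, 12L)
  res <- processReads(pr$fwd, pr$rev,
                      params = processingParams(expectedInsertLength = 60,
                                                minReads = 10))
  expect_equal(res$units$read_count, 12L)
  expect_equal(res$units$representative, unname(sim$truth$inserts[1]))
})
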