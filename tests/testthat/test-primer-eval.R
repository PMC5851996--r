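test_that("binding evaluation scores matches, wobble pairs and mismatches", {
  p <- Primer("toy", "GGC", "forward")
  expect_equal(totalMismatches(evaluateBinding(p, "GGC")), 0L)

  # primer G over a site A is the G:T wobble at template level
  wobOn <- evaluateBinding(p, "GAC", wobble = TRUE)
  expect_equal(totalMismatches(wobOn), 0L)
  expect_equal(bindingStatus(wobOn)[2], "wobble_match")
  wobOff <- evaluateBinding(p, "GAC", wobble = FALSE)
  expect_equal(totalMismatches(wobOff), 1L)

  # primer T over a site C is the T:G wobble
  pt <- Primer("toy", "ATA", "forward")
  expect_equal(totalMismatches(evaluateBinding(pt, "ACA")), 0L)
  expect_equal(totalMismatches(evaluateBinding(pt, "ACA", wobble = FALSE)),
               1L)

  # planted non-wobble substitutions in a 23-mer are all counted
  core <- "GGGTTGGTAAATCTTGTGCCAGC"
  site <- core
  substr(site, 4, 4) <- "A"   # primer T vs site A: mismatch either way
  substr(site, 10, 10) <- "C" # primer A vs site C
  substr(site, 19, 19) <- "A" # primer C vs site A
  p23 <- Primer("toy23", core, "forward")
  ev <- evaluateBinding(p23, site)
  expect_equal(totalMismatches(ev), 3L)
  expect_equal(totalMismatches(ev), oracleMismatchCount(core, site, TRUE))
})

test_that("binding evaluation flags the 3'-terminal base and rejects bad input", {
  p <- Primer("toy", "ACGT", "forward")
  bad <- evaluateBinding(p, "ACGG", wobble = FALSE)
  expect_true(bad@threePrimeMismatch)
  expect_false(evaluateBinding(p, "TCGT", wobble = FALSE)@threePrimeMismatch)
  # configurable window
  expect_true(evaluateBinding(p, "ATGT", wobble = FALSE,
                              terminalWindow = 3)@threePrimeMismatch)

  expect_error(evaluateBinding(p, "ACG"), "incompatible")
  expect_error(evaluateBinding(p, "AC+T"), "\\+")
})

test_that("IUPAC site codes match leniently by default, strictly on demand", {
  p <- Primer("toy", "ACGT", "forward")
  expect_equal(totalMismatches(evaluateBinding(p, "ACNT")), 0L)
  expect_equal(totalMismatches(evaluateBinding(p, "RCGT")), 0L)  # R = A/G
  expect_equal(totalMismatches(evaluateBinding(p, "YCGT")), 1L)  # Y = C/T
  expect_equal(totalMismatches(evaluateBinding(p, "ACNT",
                                               ambig = "strict")), 1L)
  # code containing only the wobble partner still rescues with wobble on
  pg <- Primer("toy", "GGGG", "forward")
  expect_equal(totalMismatches(evaluateBinding(pg, "GGWG")), 0L)  # W = A/T
  expect_equal(totalMismatches(evaluateBinding(pg, "GGWG",
                                               wobble = FALSE)), 1L)
})

test_that("wobble acceptance never increases the mismatch count", {
  set.seed(42)
  p <- Primer("toy", randSeq(23), "forward")
  for (i in 1:50) {
    site <- randSeq(23)
    on <- totalMismatches(evaluateBinding(p, site, wobble = TRUE))
    off <- totalMismatches(evaluateBinding(p, site, wobble = FALSE))
    expect_lte(on, off)
    expect_equal(on, oracleMismatchCount(primerCore(p), site, TRUE))
    expect_equal(off, oracleMismatchCount(primerCore(p), site, FALSE))
  }
})

test_that("mismatch histogram bins and conserves panel counts", {
  p <- Primer("toy", "ACGTACGTAC", "forward")
  exact <- rep(primerCore(p), 7)
  one <- rep("CCGTACGTAC", 2)          # primer A vs C: plain mismatch
  six <- "CACTGCATAC"
  h <- mismatchHistogram(p, c(exact, one, six), wobble = FALSE)
  expect_equal(h$histogram$proportion[h$histogram$mismatches == "0"], 0.7)
  expect_equal(h$histogram$proportion[h$histogram$mismatches == "1"], 0.2)
  expect_equal(h$histogram$proportion[h$histogram$mismatches == "ge5"], 0.1)
  expect_equal(sum(h$histogram$count), h$nTotal)
  expect_equal(sum(h$histogram$proportion), 1, tolerance = 1e-12)

  allSame <- mismatchHistogram(p, rep(primerCore(p), 5))
  expect_equal(allSame$histogram$proportion[1], 1.0)

  # random panel equals an independent tally
  set.seed(7)
  sites <- vapply(1:40, function(i) randSeq(10), "")
  h2 <- mismatchHistogram(p, sites, wobble = TRUE)
  mm <- vapply(sites, oracleMismatchCount, integer(1),
               core = primerCore(p), wobble = TRUE)
  expected <- table(factor(ifelse(mm >= 5, "ge5", mm),
                           levels = c("0", "1", "2", "3", "4", "ge5")))
  expect_equal(h2$histogram$count, as.integer(expected))

  # unlocated members reported separately or folded into >=5
  h3 <- mismatchHistogram(p, c(primerCore(p), NA, NA))
  expect_equal(h3$nUnlocated, 2L)
  expect_equal(h3$nTotal, 1L)
  h4 <- mismatchHistogram(p, c(primerCore(p), NA, NA), unlocated = "ge5")
  expect_equal(h4$histogram$count[6], 2L)
  expect_equal(h4$nTotal, 3L)

  expect_error(mismatchHistogram(p, character(0)), "empty")
})

test_that("positional base profile counts bases and primer matches", {
  p <- Primer("toy", "ACGTAC", "forward")
  prof <- positionalBaseProfile(rep(primerCore(p), 5), p)
  expect_equal(prof$match_count, rep(5L, 6))
  expect_equal(rowSums(prof[, c("A", "C", "G", "T")]), rep(5, 6),
               ignore_attr = TRUE)

  # one C->T variant at position 4... planted in 2 of 6 members
  sites <- c(rep("ACGTAC", 4), rep("ACTTAC", 2))
  p2 <- Primer("toy", "ACGTAC", "forward")
  prof2 <- positionalBaseProfile(sites, p2)
  expect_equal(prof2$G[3], 4L)
  expect_equal(prof2$T[3], 2L)
  expect_equal(prof2$match_count[3], 4L)

  expect_error(positionalBaseProfile(c("ACGTAC", "ACGTA"), p), "ragged")
})

test_that("GC content follows the primer-design band", {
  expect_equal(gcContent("GGCC"), 1.0)
  expect_equal(gcContent("ATAT"), 0.0)
  expect_equal(gcContent("GGGTTGGTAAATCTTGTGCCAGC"), 12 / 23)
  expect_error(gcContent(""), "empty")
  expect_error(gcContent("ACGN"), "non-ACGT")
})

test_that("nearest-neighbour Tm matches an independent reimplementation", {
  seqs <- c("ACGTACGTACGTACGTACGT", "GGGTTGGTAAATCTTGTGCCAGC",
            "CATAGTGGGGTATCTAATCCCAGTTTG")
  for (s in seqs)
    expect_lt(abs(meltingTemperature(s) - oracleTm(s)), 0.1)
  # duplex symmetry: both strands melt together
  set.seed(3)
  for (i in 1:10) {
    s <- randSeq(20)
    expect_equal(meltingTemperature(s), meltingTemperature(rcSeq(s)),
                 tolerance = 1e-10)
  }
  # GC-rich duplexes are more stable than AT-rich ones
  expect_gt(meltingTemperature(strrep("GC", 10)),
            meltingTemperature(strrep("AT", 10)))
  # parameters are injectable: more salt stabilises the duplex
  expect_gt(meltingTemperature("ACGTACGTACGTACGT",
                               thermoParams(Na = 0.5)),
            meltingTemperature("ACGTACGTACGTACGT",
                               thermoParams(Na = 0.05)))
  expect_error(meltingTemperature("ACGT"), "short")
  expect_error(meltingTemperature("ACGTNACGTA"), "non-ACGT")
})

test_that("the packaged universal primers are well-formed", {
  prm <- mibirdPrimers()
  expect_s4_class(prm$fwd, "Primer")
  expect_equal(primerOrientation(prm$fwd), "forward")
  expect_equal(primerOrientation(prm$rev), "reverse")
  expect_equal(nRandomBases(prm$fwd), 6L)
  # the pair was designed with nearly identical melting temperatures
  expect_lt(abs(meltingTemperature(prm$fwd) - meltingTemperature(prm$rev)),
            3)
})

test_that("primer objects validate and round-trip through config files", {
  expect_error(Primer("x", "ACGN", "forward"), "degenerate")
  expect_error(Primer("x", "", "forward"), "non-empty")
  tf <- withr::local_tempfile(fileext = ".yaml")
  writePrimerConfig(mibirdPrimers(), tf)
  back <- readPrimerConfig(tf)
  expect_equal(primerCore(back$fwd), primerCore(mibirdPrimers()$fwd))
  expect_equal(nRandomBases(back$rev), 6L)
  expect_equal(primerAdapter(back$fwd), primerAdapter(mibirdPrimers()$fwd))
})

test_that("histogram and profile reports write as TSV", {
  p <- Primer("toy", "ACGTACGTAC", "forward")
  h <- mismatchHistogram(p, rep(primerCore(p), 3))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeMismatchHistogram(h, tf)
  back <- read.delim(tf)
  expect_equal(back$count[1], 3L)
  expect_equal(back$n[1], 3L)
  prof <- positionalBaseProfile(rep(primerCore(p), 3), p)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeBaseProfile(prof, tf2)
  expect_equal(read.delim(tf2)$match_count, prof$match_count)
})
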