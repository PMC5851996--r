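# Independent brute-force oracles used to validate the implementation.
# All are deliberately naive re-derivations, sharing no code with R/.

randSeq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# classical O(nm) Levenshtein dynamic programme
oracleEditDistance <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (av[i] != bv[j]))
    }
    prev <- cur
  }
  as.integer(prev[m + 1])
}

# naive per-position primer/site comparison with the G/T wobble rule in
# primer-orientation coordinates (primer G ~ site A, primer T ~ site C)
oracleMismatchCount <- function(core, site, wobble) {
  p <- strsplit(core, "")[[1]]
  s <- strsplit(site, "")[[1]]
  mm <- 0L
  for (i in seq_along(p)) {
    if (p[i] == s[i]) next
    if (wobble && ((p[i] == "G" && s[i] == "A") ||
                   (p[i] == "T" && s[i] == "C"))) next
    mm <- mm + 1L
  }
  mm
}

# exhaustive window scan for the best primer site on the given strand
oracleBestWindow <- function(scanned, core, wobble) {
  k <- nchar(core); L <- nchar(scanned)
  if (k > L) return(NULL)
  mm <- vapply(seq_len(L - k + 1), function(w) {
    oracleMismatchCount(core, substr(scanned, w, w + k - 1), wobble)
  }, integer(1))
  list(window = which.min(mm), mismatches = min(mm))
}

# enumerate every substring; return the longest all-above-cutoff one
# (ties -> leftmost)
oracleQualityTrim <- function(quals, cutoff) {
  n <- length(quals)
  best <- c(start = 1L, len = 0L)
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (all(quals[s:e] >= cutoff)) {
        len <- e - s + 1L
        if (len > best["len"]) best <- c(start = s, len = len)
      }
    }
  }
  best
}

# exhaustive merge-offset enumeration mirroring the documented rule:
# offsets >= minOverlap, minimise mismatch fraction, ties -> longest
oracleMergeChoice <- function(fwd, revRC, minOverlap, maxFrac) {
  lf <- nchar(fwd); lr <- nchar(revRC)
  if (min(lf, lr) < minOverlap) return(NULL)
  fv <- strsplit(fwd, "")[[1]]
  rv <- strsplit(revRC, "")[[1]]
  best <- NULL
  for (o in minOverlap:min(lf, lr)) {
    mm <- sum(fv[(lf - o + 1):lf] != rv[1:o])
    frac <- mm / o
    if (is.null(best) || frac < best$frac ||
        (frac == best$frac && o > best$o)) {
      best <- list(o = o, mm = mm, frac = frac)
    }
  }
  if (best$frac > maxFrac) NULL else best
}

# affine-gap Smith-Waterman score (Gotoh), gap of length k costs
# gapOpen + k * gapExt, matching the built-in aligner's convention
oracleSWScore <- function(a, b, match = 2, mismatch = -3, gapOpen = 5,
                          gapExt = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - gapOpen - gapExt, X[i - 1, j] - gapExt)
      Y[i, j] <- max(M[i, j - 1] - gapOpen - gapExt, Y[i, j - 1] - gapExt)
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i, j], Y[i, j])
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# independent nearest-neighbour Tm arithmetic (unified 1998 table typed
# afresh, two-strand keys enumerated explicitly)
oracleTm <- function(seq, Na = 0.05, ct = 5e-7) {
  dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5,
          TG = -8.5, GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8,
          GA = -8.2, TC = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
          CC = -8.0)
  dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  pairs <- paste0(b[-n], b[-1])
  H <- sum(dH[pairs]); S <- sum(dS[pairs])
  for (x in c(b[1], b[n])) {
    if (x %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1) * log(Na)
  H * 1000 / (S + 1.987 * log(ct / 4)) - 273.15
}

# build a one-record (or multi-record) panel from raw sequences
toyPanel <- function(seqs, species = NULL, genus = NULL) {
  n <- length(seqs)
  if (is.null(species)) species <- sprintf("Toyus sp%02d", seq_len(n))
  if (is.null(genus)) genus <- sprintf("Toyus%02d", seq_len(n))
  ReferencePanel(seqs, data.frame(
    accession = sprintf("TOY%03d", seq_len(n)), species = species,
    genus = genus, family = "Toyidae", order = "Toyiformes",
    stringsAsFactors = FALSE))
}

rcSeq <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
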