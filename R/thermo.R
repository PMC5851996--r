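#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x) {
  if (any(!nzchar(x))) stop("empty sequence", call. = FALSE)
  vapply(x, function(s) {
    .checkACGT(s)
    b <- .splitBases(s)
    sum(b %in% c("G", "C")) / length(b)
  }, numeric(1), USE.NAMES = FALSE)
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "Primer", function(x) gcContent(primerCore(x)))

## SantaLucia (1998) unified nearest-neighbour parameters.
## dH in kcal/mol, dS in cal/(mol K); keyed by the 5'->3' dinucleotide of
## one strand (complementary stacks share an entry).
.NN_UNIFIED <- local({
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  full_dH <- full_dS <- numeric(0)
  for (a in names(comp)) for (b in names(comp)) {
    k <- paste0(a, b)
    if (k %in% names(dH)) {
      full_dH[k] <- dH[[k]]; full_dS[k] <- dS[[k]]
    } else {
      rc <- paste0(comp[[b]], comp[[a]])   # equivalent stack on the
      full_dH[k] <- dH[[rc]]; full_dS[k] <- dS[[rc]]  # complementary strand
    }
  }
  list(dH = full_dH, dS = full_dS,
       init_dH = c(GC = 0.1, AT = 2.3),   # duplex initiation by terminal pair
       init_dS = c(GC = -2.8, AT = 4.1))
})

#' Thermodynamic parameters for melting-temperature prediction
#'
#' Parameter bundle for the nearest-neighbour duplex model: stack
#' enthalpies/entropies, monovalent salt concentration and total oligo
#' concentration. Defaults are the unified parameter set of SantaLucia
#' (1998) at 50 mM Na+ and 0.5 uM oligo; all values are injectable so a
#' different published table can be swapped in.
#'
#' @param Na Monovalent cation concentration, mol/L (default 0.05).
#' @param oligo Total single-strand oligo concentration, mol/L (default
#'   5e-7).
#' @param nn Optional replacement list with elements \code{dH}, \code{dS}
#'   (named by 5'->3' dinucleotide, kcal/mol and cal/(mol K)) and
#'   \code{init_dH}, \code{init_dS} (named \code{GC}, \code{AT}).
#' @return A list of class \code{thermoParams}.
#' @export
thermoParams <- function(Na = 0.05, oligo = 5e-7, nn = NULL) {
  if (Na <= 0 || oligo <= 0)
    stop("concentrations must be strictly positive", call. = FALSE)
  p <- list(Na = Na, oligo = oligo, nn = if (is.null(nn)) .NN_UNIFIED else nn)
  class(p) <- "thermoParams"
  p
}

#' Nearest-neighbour melting temperature
#'
#' Duplex melting temperature in degrees Celsius from summed
#' nearest-neighbour stack enthalpies/entropies with duplex-initiation
#' terms, an entropic salt correction of
#' \eqn{0.368 (L-1) \ln[\mathrm{Na}^+]} cal/(mol K), and
#' \eqn{T_m = \Delta H / (\Delta S + R \ln(C_T/4)) - 273.15} for a
#' non-self-complementary oligo at total strand concentration \eqn{C_T}.
#'
#' @param x Sequence (single ACGT string of length >= 8) or a
#'   [Primer-class] (the core is used).
#' @param params A [thermoParams()] bundle.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("GGGTTGGTAAATCTTGTGCCAGC")
#' @export
#' @name meltingTemperature
#' @aliases meltingTemperature,character-method
setMethod("meltingTemperature", "character", function(x, params) {
  stopifnot(length(x) == 1L)
  .checkACGT(x)
  b <- .splitBases(x)
  n <- length(b)
  if (n < 8L) stop("sequence too short for the NN model (need >= 8 nt)",
                   call. = FALSE)
  nn <- params$nn
  stacks <- paste0(b[-n], b[-1L])
  dH <- sum(nn$dH[stacks])
  dS <- sum(nn$dS[stacks])
  for (term in b[c(1L, n)]) {
    key <- if (term %in% c("G", "C")) "GC" else "AT"
    dH <- dH + nn$init_dH[[key]]
    dS <- dS + nn$init_dS[[key]]
  }
  dS <- dS + 0.368 * (n - 1L) * log(params$Na)
  R <- 1.987            # gas constant, cal/(mol K)
  tmK <- (dH * 1000) / (dS + R * log(params$oligo / 4))
  tmK - 273.15
})

#' @rdname meltingTemperature
#' @export
setMethod("meltingTemperature", "Primer", function(x, params) {
  meltingTemperature(primerCore(x), params)
})
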