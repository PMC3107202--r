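#' Exact two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two samples (e.g. microhomology length
#' distributions of two genotypes). When the number of group assignments
#' `choose(nx + ny, nx)` is small enough to enumerate (default limit 5e4,
#' which covers all sample-size pairs with `nx + ny <= 10` and far beyond),
#' the permutation distribution of U is enumerated exactly — ties included,
#' since enumeration permutes the observed (possibly tied) ranks. Otherwise
#' a tie-corrected normal approximation with continuity correction is used.
#' The two-sided p value is `2 * min(one-sided p)` capped at 1.
#'
#' @param x,y numeric samples, both nonempty.
#' @param exactLimit enumerate exactly when `choose(nx+ny, nx)` is at most
#'   this (default 5e4); set to 0 to force the normal approximation.
#' @return list with `U` (for sample `x`) and `p.value`.
#' @examples
#' mannWhitneyTwoTailed(c(1, 2), c(3, 4))$p.value  # exact 1/3
#' @export
mannWhitneyTwoTailed <- function(x, y, exactLimit = 5e4) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  x <- as.numeric(x)
  y <- as.numeric(y)
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  Uobs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2

  if (choose(nx + ny, nx) <= exactLimit) {
    combos <- utils::combn(nx + ny, nx)
    Rsums <- colSums(matrix(rk[combos], nrow = nx))
    Uall <- Rsums - nx * (nx + 1) / 2
    eps <- 1e-9
    pLow <- mean(Uall <= Uobs + eps)
    pHigh <- mean(Uall >= Uobs - eps)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    ties <- table(pooled)
    tieTerm <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tieTerm)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (Uobs - mu - sign(Uobs - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = Uobs, p.value = p)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of tables at most as probable as the
#' observed one (via [stats::fisher.test()]).
#'
#' @param a,b,c,d nonnegative cell counts (row-wise).
#' @return two-sided p value.
#' @examples
#' fishersExact2x2(5, 0, 0, 5)  # 2 / choose(10, 5)
#' @export
fishersExact2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (all(counts == 0)) stop("all counts are zero")
  stats::fisher.test(matrix(counts, nrow = 2L, byrow = TRUE))$p.value
}

#' Two-tailed unpaired t test on replicate frequencies
#'
#' Student's pooled-variance t test by default (Welch by `welch = TRUE`),
#' via [stats::t.test()].
#'
#' @param a,b numeric replicate vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form; default `FALSE`.
#' @return list with `t`, `df`, `p.value`.
#' @export
tTestUnpairedTwoTailed <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs >= 2 replicates")
  if (stats::var(a) + stats::var(b) == 0)
    stop("zero pooled variance: t statistic undefined")
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Construct a PlateAssay
#'
#' @param wells number of wells (default 96).
#' @param cellsPerWell cells seeded per well (default 208, i.e. 2e4 cells
#'   distributed over a 96-well plate).
#' @param positiveWells number of wells positive for a junction-spanning
#'   PCR product.
#' @return a [PlateAssay-class].
#' @export
PlateAssay <- function(positiveWells, wells = 96L, cellsPerWell = 208L) {
  new("PlateAssay", wells = as.integer(wells),
      cellsPerWell = as.integer(cellsPerWell),
      positiveWells = as.integer(positiveWells))
}

setMethod("show", "PlateAssay", function(object) {
  cat(sprintf("PlateAssay: %d/%d wells positive, %d cells/well\n",
              object@positiveWells, object@wells, object@cellsPerWell))
})

#' Translocation frequency from well-level positivity
#'
#' The naive estimate assumes at most one event per positive well:
#' `positive / (wells * cellsPerWell)`. Because multiple independent events
#' can occur among the cells of one well, a Poisson (limiting-dilution)
#' correction is also returned:
#' `-log(1 - positive/wells) / cellsPerWell >= naive`. A fully positive
#' plate leaves the corrected estimate undefined (saturation).
#'
#' @param plate a [PlateAssay-class].
#' @return list with `naive` and `poissonCorrected` (events per cell).
#' @examples
#' translocationFrequency(PlateAssay(4))  # ~2e-4 per cell
#' @export
translocationFrequency <- function(plate) {
  stopifnot(is(plate, "PlateAssay"))
  k <- plate@positiveWells
  w <- plate@wells
  c_ <- plate@cellsPerWell
  if (k == w)
    stop("all wells positive: assay saturated, corrected estimate ",
         "undefined; dilute and repeat")
  list(naive = k / (w * c_),
       poissonCorrected = -log(1 - k / w) / c_)
}

#' Fold change between two frequencies
#'
#' @param numerator,denominator frequencies (denominator > 0).
#' @param decimals decimals to round to, half-up (default 1).
#' @return rounded ratio.
#' @examples
#' foldChange(9e-4, 3.7e-4)  # 2.4
#' @export
foldChange <- function(numerator, denominator, decimals = 1L) {
  if (denominator <= 0) stop("denominator must be > 0")
  scale <- 10^decimals
  floor(numerator / denominator * scale + 0.5) / scale
}

#' Indel percentage from a Surveyor (mismatch nuclease) assay
#'
#' Converts the cleaved fraction of reannealed duplexes into the percentage
#' of alleles carrying indels: `100 * (1 - sqrt(1 - fractionCleaved))`.
#'
#' @param fractionCleaved proportion in \[0, 1\].
#' @return indel percentage.
#' @seealso [surveyorFractionCleaved()] for the inverse.
#' @examples
#' surveyorIndelPercent(0.19)  # 10
#' @export
surveyorIndelPercent <- function(fractionCleaved) {
  if (any(fractionCleaved < 0 | fractionCleaved > 1))
    stop("fractionCleaved must be in [0, 1]")
  100 * (1 - sqrt(1 - fractionCleaved))
}

#' Inverse of the Surveyor indel formula
#'
#' @param indelPercent percentage in \[0, 100\].
#' @return the cleaved fraction `1 - (1 - indelPercent/100)^2`.
#' @export
surveyorFractionCleaved <- function(indelPercent) {
  if (any(indelPercent < 0 | indelPercent > 100))
    stop("indelPercent must be in [0, 100]")
  1 - (1 - indelPercent / 100)^2
}

#' Indel percentage from colony hybridization
#'
#' Colonies that hybridize with neither locus probe carry modified
#' (imprecisely rejoined) alleles.
#'
#' @param nonHybridizing count of non-hybridizing colonies.
#' @param total total colonies analyzed (>= 1).
#' @return `100 * nonHybridizing / total`.
#' @export
colonyIndelPercent <- function(nonHybridizing, total) {
  if (total < 1) stop("total must be >= 1")
  if (nonHybridizing < 0 || nonHybridizing > total)
    stop("need 0 <= nonHybridizing <= total")
  100 * nonHybridizing / total
}
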