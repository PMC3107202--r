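#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.checkDna <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    return(sprintf("%s must be a single nonempty string", what))
  bad <- setdiff(unique(strsplit(x, "", fixed = TRUE)[[1L]]), .DNA_ALPHABET)
  if (length(bad))
    return(sprintf("%s contains disallowed character(s): %s",
                   what, paste(bad, collapse = ", ")))
  NULL
}

#' ReferenceLocus: a cut chromosome side with nick coordinates
#'
#' Models one nuclease-cut locus: the genomic sequence around the cut and the
#' positions of the two strand nicks. A FokI-type nuclease (e.g. a ZFN pair)
#' leaves a short 5' overhang: `nickTop` is the 0-based top-strand nick offset
#' and `nickBottom` the top-strand coordinate of the bottom-strand nick, so
#' `nickBottom - nickTop` is the overhang length (0 for a blunt cut).
#' `variableTerminalBases` declares how many end-proximal bases are cleaved
#' variably (used by the terminal-base annotation rule, see
#' [annotateJunction()]).
#'
#' All coordinates are 0-based, half-open, on the top strand. `N` bases are
#' legal but never match anything during annotation.
#'
#' @slot name character label.
#' @slot sequence DNA string over A/C/G/T/N (uppercase).
#' @slot nickTop integer, 0-based top-strand nick offset.
#' @slot nickBottom integer, 0-based top-strand coordinate of the
#'   bottom-strand nick; `nickTop <= nickBottom`.
#' @slot variableTerminalBases integer >= 0.
#' @aliases ReferenceLocus
#' @exportClass ReferenceLocus
setClass("ReferenceLocus",
  representation(
    name = "character",
    sequence = "character",
    nickTop = "integer",
    nickBottom = "integer",
    variableTerminalBases = "integer"
  )
)

setValidity("ReferenceLocus", function(object) {
  msg <- character()
  err <- .checkDna(object@sequence)
  if (!is.null(err)) msg <- c(msg, err)
  n <- nchar(object@sequence)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single nonempty string")
  if (!(object@nickTop >= 0L && object@nickTop <= object@nickBottom &&
        object@nickBottom <= n))
    msg <- c(msg, "need 0 <= nickTop <= nickBottom <= length(sequence)")
  if (object@variableTerminalBases < 0L)
    msg <- c(msg, "variableTerminalBases must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DerivativeReference: expected perfect-join translocation chromosome
#'
#' The reference sequence of a derivative chromosome formed by joining the
#' 5' (left) fragment of one cut locus to the 3' (right) fragment of the
#' other, assuming fill-in of the 5' overhangs and no loss of sequence from
#' the DNA ends. The post-fill-in blunt ends define the zero-deletion state
#' for all downstream deletion measurements.
#'
#' @slot name character, e.g. `"der6"`.
#' @slot leftLocus,rightLocus [ReferenceLocus-class] parents.
#' @slot leftEnd integer, blunt-end coordinate after fill-in
#'   (= `nickBottom(leftLocus)`), 0-based.
#' @slot rightStart integer, blunt-start coordinate after fill-in
#'   (= `nickTop(rightLocus)`), 0-based.
#' @slot perfectJoin DNA string of the expected junction-spanning reference.
#' @aliases DerivativeReference
#' @exportClass DerivativeReference
setClass("DerivativeReference",
  representation(
    name = "character",
    leftLocus = "ReferenceLocus",
    rightLocus = "ReferenceLocus",
    leftEnd = "integer",
    rightStart = "integer",
    perfectJoin = "character"
  )
)

setValidity("DerivativeReference", function(object) {
  msg <- character()
  if (object@leftEnd != object@leftLocus@nickBottom)
    msg <- c(msg, "leftEnd must equal nickBottom(leftLocus)")
  if (object@rightStart != object@rightLocus@nickTop)
    msg <- c(msg, "rightStart must equal nickTop(rightLocus)")
  expect <- paste0(
    substr(object@leftLocus@sequence, 1L, object@leftEnd),
    substr(object@rightLocus@sequence, object@rightStart + 1L,
           nchar(object@rightLocus@sequence))
  )
  if (!identical(object@perfectJoin, expect))
    msg <- c(msg, "perfectJoin does not equal left prefix + right suffix")
  if (length(msg)) msg else TRUE
})

#' ChanceNullModel: microhomology length expected by chance
#'
#' Analytic pmf of junctional microhomology length under random (unbiased)
#' end joining. With per-position match probability `m = sum(p_b^2)` over the
#' base composition, the one-sided variant is geometric,
#' `P(k) = (1 - m) m^k`, and the two-sided variant (overlap scored on both
#' sides of the joint, as the annotator does) is the sum of two independent
#' geometric runs, `P(k) = (k + 1) (1 - m)^2 m^k`. The final bin is an open
#' tail holding the remaining mass beyond `maxLen`.
#'
#' @slot baseComposition named numeric over A/C/G/T summing to 1.
#' @slot variant `"one_sided"` or `"two_sided"`.
#' @slot maxLen integer, largest explicit microhomology length bin.
#' @slot pmf numeric of length `maxLen + 2`: `P(0) .. P(maxLen)` then the
#'   open tail bin `P(> maxLen)`.
#' @aliases ChanceNullModel
#' @exportClass ChanceNullModel
setClass("ChanceNullModel",
  representation(
    baseComposition = "numeric",
    variant = "character",
    maxLen = "integer",
    pmf = "numeric"
  )
)

setValidity("ChanceNullModel", function(object) {
  msg <- character()
  if (!identical(sort(names(object@baseComposition)), c("A", "C", "G", "T")))
    msg <- c(msg, "baseComposition must be named over A,C,G,T")
  if (abs(sum(object@baseComposition) - 1) > 1e-9)
    msg <- c(msg, "baseComposition must sum to 1")
  if (!object@variant %in% c("one_sided", "two_sided"))
    msg <- c(msg, "variant must be one_sided or two_sided")
  if (length(object@pmf) != object@maxLen + 2L)
    msg <- c(msg, "pmf must have maxLen + 2 bins (0..maxLen plus tail)")
  if (abs(sum(object@pmf) - 1) > 1e-12)
    msg <- c(msg, "pmf must sum to 1 (within 1e-12)")
  if (length(msg)) msg else TRUE
})

#' PlateAssay: well-level positivity counts from a plate assay
#'
#' A 96-well style translocation quantification: cells are distributed at a
#' fixed number per well and each well is scored positive/negative for a
#' junction-spanning nested-PCR product.
#'
#' @slot wells integer number of wells.
#' @slot cellsPerWell integer cells seeded per well.
#' @slot positiveWells integer number of PCR-positive wells.
#' @aliases PlateAssay
#' @exportClass PlateAssay
setClass("PlateAssay",
  representation(
    wells = "integer",
    cellsPerWell = "integer",
    positiveWells = "integer"
  )
)

setValidity("PlateAssay", function(object) {
  msg <- character()
  if (object@wells < 1L) msg <- c(msg, "wells must be >= 1")
  if (object@cellsPerWell < 1L) msg <- c(msg, "cellsPerWell must be >= 1")
  if (object@positiveWells < 0L || object@positiveWells > object@wells)
    msg <- c(msg, "need 0 <= positiveWells <= wells")
  if (length(msg)) msg else TRUE
})

#' GenotypeSummary: per-genotype junction aggregate statistics
#'
#' Aggregates a set of junction annotations from a single genotype:
#' percentages of junctions without microhomology and with insertions
#' (denominator = all junctions), the microhomology length distribution over
#' simple-deletion junctions, the median combined deletion over
#' simple-deletion junctions, the median insertion length over
#' insertion-bearing junctions, and the percentage with long insertions
#' (length strictly greater than the threshold, default 50 nt).
#'
#' @slot genotype character label.
#' @slot n integer number of junctions.
#' @slot pctWithoutMH numeric percent with `mh_len == 0` (all junctions).
#' @slot pctWithInsertions numeric percent with `insertion_len > 0`.
#' @slot mhDistribution named integer vector of microhomology-length counts
#'   over simple-deletion junctions.
#' @slot medianDelTotal numeric median combined deletion (simple deletions);
#'   `NA` if none.
#' @slot medianInsertionLen numeric median insertion length (insertion
#'   junctions); `NA` if none.
#' @slot pctLongInsertions numeric percent with insertions longer than
#'   `longInsertThreshold`.
#' @slot longInsertThreshold integer threshold in nt (default 50).
#' @aliases GenotypeSummary
#' @exportClass GenotypeSummary
setClass("GenotypeSummary",
  representation(
    genotype = "character",
    n = "integer",
    pctWithoutMH = "numeric",
    pctWithInsertions = "numeric",
    mhDistribution = "integer",
    medianDelTotal = "numeric",
    medianInsertionLen = "numeric",
    pctLongInsertions = "numeric",
    longInsertThreshold = "integer"
  )
)

#' SimulationConfig: generative end-joining parameters
#'
#' Parameters of the synthetic junction generator (see
#' [simulateJunctions()]). Resection at each end is geometric with parameter
#' `resectionP` (mean resection `(1 - p)/p` nt). Joining is either direct
#' (at the resected ends) or, with probability `mhBiasWeight /
#' (1 + mhBiasWeight)`, at the offset within the resected windows exposing
#' the longest microhomology (a Lig3-like, microhomology-driven joint;
#' `mhBiasWeight = 0` gives unbiased, Lig1-like joining). Insertions occur
#' with probability `insertionProb` and are templated (copied, possibly
#' inverted, from within `templateWindow` nt of a cut) with probability
#' `templatedInsertionProb`; untemplated insert length is
#' `1 + Geometric(insertLenP)`. Independently, with probability
#' `longInsertRate` a junction carries a long (> 50 nt) templated insert.
#'
#' @slot resectionP numeric in (0, 1].
#' @slot mhBiasWeight numeric >= 0.
#' @slot insertionProb numeric in \[0, 1\].
#' @slot templatedInsertionProb numeric in \[0, 1\].
#' @slot insertLenP numeric in (0, 1].
#' @slot longInsertRate numeric in \[0, 1\].
#' @slot templateWindow integer nt around each cut searched/copied for
#'   templated inserts.
#' @slot seed integer RNG seed.
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    resectionP = "numeric",
    mhBiasWeight = "numeric",
    insertionProb = "numeric",
    templatedInsertionProb = "numeric",
    insertLenP = "numeric",
    longInsertRate = "numeric",
    templateWindow = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pr01 <- function(x, nm) {
    if (x < 0 || x > 1) sprintf("%s must be in [0, 1]", nm) else NULL
  }
  if (object@resectionP <= 0 || object@resectionP > 1)
    msg <- c(msg, "resectionP must be in (0, 1]")
  if (object@insertLenP <= 0 || object@insertLenP > 1)
    msg <- c(msg, "insertLenP must be in (0, 1]")
  if (object@mhBiasWeight < 0) msg <- c(msg, "mhBiasWeight must be >= 0")
  for (nm in c("insertionProb", "templatedInsertionProb", "longInsertRate"))
    msg <- c(msg, pr01(slot(object, nm), nm))
  if (object@templateWindow < 1L) msg <- c(msg, "templateWindow must be >= 1")
  if (length(msg)) msg else TRUE
})
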