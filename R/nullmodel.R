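#' Microhomology length distribution expected by chance
#'
#' Analytic pmf of junctional microhomology under random end joining with an
#' independent, identically distributed base composition. With
#' `m = sum(p_b^2)` the per-position probability that two random bases
#' match:
#'
#' * `one_sided`: `P(k) = (1 - m) m^k` — a single geometric run of matches
#'   on one side of the joint.
#' * `two_sided` (default): `P(k) = (k + 1) (1 - m)^2 m^k` — the sum of two
#'   independent geometric runs flanking the breakpoint, which is exactly
#'   the distribution the annotator's maximal two-sided overlap scoring
#'   induces on random joins (see [annotateJunction()]).
#'
#' For an unbiased composition (`m = 1/4`), the two-sided probability of no
#' microhomology is `(3/4)^2 = 0.5625`.
#'
#' @param baseComposition probabilities over A/C/G/T summing to 1; default
#'   uniform.
#' @param variant `"two_sided"` (default) or `"one_sided"`.
#' @param maxLen largest explicit length bin; remaining mass goes to an
#'   open tail bin (default 10).
#' @return a [ChanceNullModel-class].
#' @examples
#' chancePmf()                      # P(0) = 0.5625
#' chancePmf(variant = "one_sided") # P(0) = 0.75
#' @export
chancePmf <- function(baseComposition = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                      variant = c("two_sided", "one_sided"),
                      maxLen = 10L) {
  variant <- match.arg(variant)
  baseComposition <- .normalizeComposition(baseComposition)
  maxLen <- as.integer(maxLen)
  stopifnot(maxLen >= 0L)
  m <- sum(baseComposition^2)
  k <- 0:maxLen
  pmf <- if (variant == "one_sided") {
    (1 - m) * m^k
  } else {
    (k + 1) * (1 - m)^2 * m^k
  }
  pmf <- c(pmf, max(0, 1 - sum(pmf)))
  names(pmf) <- c(as.character(k), sprintf(">%d", maxLen))
  new("ChanceNullModel",
      baseComposition = baseComposition,
      variant = variant,
      maxLen = maxLen,
      pmf = pmf)
}

#' @describeIn ChanceNullModel-class the pmf (named numeric; last bin is the
#'   open tail)
#' @param object,x a `ChanceNullModel`.
#' @export
setGeneric("nullPmf", function(x) standardGeneric("nullPmf"))
#' @rdname ChanceNullModel-class
#' @export
setMethod("nullPmf", "ChanceNullModel", function(x) x@pmf)

setMethod("show", "ChanceNullModel", function(object) {
  cat(sprintf("ChanceNullModel (%s, match prob %.4f)\n", object@variant,
              sum(object@baseComposition^2)))
  print(round(object@pmf, 4))
})

#' Monte-Carlo microhomology lengths under random joining
#'
#' Draws `n` independent random-reference end pairs, forms the direct joint,
#' and scores each junction with the same exact-matching decomposition the
#' annotator uses (maximal two-sided overlap at the joint). Because every
#' junction gets its own independent reference pair, the resulting counts
#' are a multinomial sample from the [chancePmf()] two-sided distribution —
#' this is the simulation oracle tying the null model to the annotation
#' convention.
#'
#' @param n number of simulated joints.
#' @param baseComposition probabilities over A/C/G/T (default uniform).
#' @param seed optional RNG seed for reproducibility.
#' @param maxLen tail cap; overlaps longer than `maxLen` are pooled into the
#'   tail bin (default 10).
#' @param flank number of reference bases drawn per side of each end
#'   (default 40; the probability a matching run is truncated at 40 uniform
#'   bases is negligible).
#' @return named integer vector of counts for microhomology length
#'   `0..maxLen` and the open tail bin.
#' @export
simulateChanceMH <- function(n, baseComposition = c(A = 0.25, C = 0.25,
                                                    G = 0.25, T = 0.25),
                             seed = NULL, maxLen = 10L, flank = 40L) {
  stopifnot(n >= 1L)
  n <- as.integer(n)
  flank <- as.integer(flank)
  baseComposition <- .normalizeComposition(baseComposition)
  rawBases <- charToRaw(paste(names(baseComposition), collapse = ""))
  runChunk <- function() {
    # each junction: an independent left and right reference of 2*flank nt,
    # cut bluntly in the middle, joined directly with no resection (the
    # chance overlap does not depend on resection depth)
    pool <- sample(rawBases, n * 4L * flank, replace = TRUE,
                   prob = baseComposition)
    mh <- integer(n)
    off <- 0L
    half <- flank
    full <- 2L * flank
    for (i in seq_len(n)) {
      leftRaw <- pool[(off + 1L):(off + full)]
      rightRaw <- pool[(off + full + 1L):(off + 2L * full)]
      off <- off + 2L * full
      jnRaw <- c(leftRaw[1:half], rightRaw[(half + 1L):full])
      dec <- .decompose(jnRaw, leftRaw, rightRaw, half, half, 0L)
      mh[i] <- dec$mh_len
    }
    mh
  }
  mh <- if (is.null(seed)) runChunk() else withr::with_seed(seed, runChunk())
  mh <- pmin(mh, maxLen + 1L)
  tab <- table(factor(mh, levels = 0:(maxLen + 1L)))
  stats::setNames(as.integer(tab),
                  c(as.character(0:maxLen), sprintf(">%d", maxLen)))
}

#' Chi-square goodness of fit of microhomology lengths to a chance null
#'
#' Bins observed microhomology lengths as in the model (explicit lengths
#' `0..maxLen` plus an open tail), pools right-hand bins until every
#' expected count is at least 5, and applies a chi-square goodness-of-fit
#' test.
#'
#' @param mhLengths integer vector of observed microhomology lengths (e.g.
#'   `mh_len` of non-insertion junctions).
#' @param model a [ChanceNullModel-class].
#' @return list with `statistic`, `df`, `p.value`, `observed`, `expected`.
#' @export
nullModelGof <- function(mhLengths, model) {
  stopifnot(is(model, "ChanceNullModel"))
  maxLen <- model@maxLen
  obs <- table(factor(pmin(mhLengths, maxLen + 1L), levels = 0:(maxLen + 1L)))
  obs <- as.numeric(obs)
  p <- model@pmf
  n <- sum(obs)
  # pool tail bins with expected < 5
  while (length(p) > 2L && n * p[length(p)] < 5) {
    k <- length(p)
    p[k - 1L] <- p[k - 1L] + p[k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]
    p <- p[-k]
    obs <- obs[-k]
  }
  expected <- n * p
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = expected)
}
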