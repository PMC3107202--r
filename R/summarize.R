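#' Summarize junction annotations for one genotype
#'
#' Percentages of junctions without microhomology and with insertions are
#' computed over all junctions; the microhomology length distribution and
#' the median combined deletion are computed over simple-deletion junctions
#' only (insertion junctions are excluded from the microhomology
#' distribution, since microhomology is scored only at direct joints);
#' the median insertion length is over insertion-bearing junctions; the
#' long-insertion percentage counts insertions strictly longer than
#' `longInsertThreshold` (default 50 nt), over all junctions.
#'
#' @param annotations an [annotateJunctions()] result, single genotype.
#' @param longInsertThreshold long-insertion threshold in nt (default 50).
#' @param genotype label; defaults to the (single) genotype in
#'   `annotations`.
#' @return a [GenotypeSummary-class].
#' @examples
#' a <- ReferenceLocus("a", strrep("ACGGT", 30), 75, 79)
#' b <- ReferenceLocus("b", strrep("TGCAA", 30), 75, 79)
#' der <- buildDerivative(a, b)
#' sim <- simulateJunctions(SimulationConfig(seed = 7), der, 50)
#' summarizeGenotype(annotateJunctions(sim$sequences, der))
#' @export
summarizeGenotype <- function(annotations, longInsertThreshold = 50L,
                              genotype = NULL) {
  n <- nrow(annotations)
  if (is.null(n) || n == 0L) stop("empty annotation set")
  gt <- unique(annotations$genotype)
  gt <- gt[!is.na(gt)]
  if (length(gt) > 1L)
    stop("annotations span multiple genotypes; summarize one at a time ",
         "(see summarizeGenotypes)")
  if (is.null(genotype))
    genotype <- if (length(gt)) gt else NA_character_

  simple <- annotations[annotations$junction_class == "simple_deletion", ,
                        drop = FALSE]
  withIns <- annotations$insertion_len > 0L

  mhCounts <- integer(0L)
  if (nrow(simple)) {
    tab <- table(factor(simple$mh_len, levels = 0:max(simple$mh_len)))
    mhCounts <- stats::setNames(as.integer(tab), names(tab))
  }

  new("GenotypeSummary",
      genotype = as.character(genotype),
      n = as.integer(n),
      pctWithoutMH = 100 * sum(annotations$mh_len == 0L) / n,
      pctWithInsertions = 100 * sum(withIns) / n,
      mhDistribution = mhCounts,
      medianDelTotal = if (nrow(simple))
        stats::median(as.numeric(simple$del_total)) else NA_real_,
      medianInsertionLen = if (any(withIns))
        stats::median(as.numeric(annotations$insertion_len[withIns]))
        else NA_real_,
      pctLongInsertions =
        100 * sum(annotations$insertion_len > longInsertThreshold) / n,
      longInsertThreshold = as.integer(longInsertThreshold))
}

#' Summarize junction annotations per genotype
#'
#' @inheritParams summarizeGenotype
#' @return [S4Vectors::DataFrame], one row per genotype, columns matching
#'   the [GenotypeSummary-class] scalar slots.
#' @export
summarizeGenotypes <- function(annotations, longInsertThreshold = 50L) {
  n <- nrow(annotations)
  if (is.null(n) || n == 0L) stop("empty annotation set")
  gts <- unique(annotations$genotype)
  rows <- lapply(gts, function(g) {
    idx <- if (is.na(g)) is.na(annotations$genotype)
           else !is.na(annotations$genotype) & annotations$genotype == g
    as(summarizeGenotype(annotations[idx, , drop = FALSE],
                         longInsertThreshold, genotype = g), "DataFrame")
  })
  do.call(rbind, rows)
}

setAs("GenotypeSummary", "DataFrame", function(from) {
  DataFrame(genotype = from@genotype,
            n = from@n,
            pct_without_mh = from@pctWithoutMH,
            pct_with_insertions = from@pctWithInsertions,
            median_del_total = from@medianDelTotal,
            median_insertion_len = from@medianInsertionLen,
            pct_long_insertions = from@pctLongInsertions)
})

#' @describeIn GenotypeSummary-class microhomology-length counts over
#'   simple-deletion junctions
#' @param object,x a `GenotypeSummary`.
#' @export
setGeneric("mhDistribution", function(x) standardGeneric("mhDistribution"))
#' @rdname GenotypeSummary-class
#' @export
setMethod("mhDistribution", "GenotypeSummary", function(x) x@mhDistribution)

setMethod("show", "GenotypeSummary", function(object) {
  cat(sprintf("GenotypeSummary '%s' (n = %d junctions)\n",
              object@genotype, object@n))
  cat(sprintf("  without microhomology: %.1f%%\n", object@pctWithoutMH))
  cat(sprintf("  with insertions:       %.1f%%\n", object@pctWithInsertions))
  cat(sprintf("  long insertions (>%d nt): %.1f%%\n",
              object@longInsertThreshold, object@pctLongInsertions))
  cat(sprintf("  median combined deletion (simple deletions): %s nt\n",
              format(object@medianDelTotal)))
  cat(sprintf("  median insertion length: %s nt\n",
              format(object@medianInsertionLen)))
})
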