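#' Construct a SimulationConfig
#'
#' Defaults are stylized to the scale of nuclease-induced translocation
#' junction data: geometric resection with mean ~11.5 nt per end (median
#' combined deletion in the tens of nt), a moderate bias toward joining at
#' exposed microhomology (`mhBiasWeight = 4`, i.e. 80% of direct joints are
#' microhomology-driven), ~20% of junctions carrying an insertion (half
#' templated), and a 2.8% rate of long (> 50 nt) templated inserts. Setting
#' `mhBiasWeight = 0` gives unbiased joining whose annotated microhomology
#' follows [chancePmf()] exactly; raising `longInsertRate` emulates a
#' genotype prone to long, complex insertions.
#'
#' @param resectionP geometric resection parameter per end (mean resection
#'   `(1-p)/p` nt); default 0.08.
#' @param mhBiasWeight relative weight of microhomology-driven joining;
#'   a joint is microhomology-driven with probability `w / (1 + w)`.
#' @param insertionProb probability a junction carries an insertion.
#' @param templatedInsertionProb probability an insertion is templated
#'   (copied, possibly inverted, from near a cut).
#' @param insertLenP geometric parameter for untemplated insert length
#'   (`1 + Geometric(p)`).
#' @param longInsertRate per-junction probability of a long (> 50 nt)
#'   templated insert; default 0.028.
#' @param templateWindow nt around each cut from which templated inserts are
#'   copied (default 100).
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class].
#' @export
SimulationConfig <- function(resectionP = 0.08, mhBiasWeight = 4,
                             insertionProb = 0.2,
                             templatedInsertionProb = 0.5,
                             insertLenP = 0.25, longInsertRate = 0.028,
                             templateWindow = 100L, seed = 1L) {
  new("SimulationConfig",
      resectionP = resectionP, mhBiasWeight = mhBiasWeight,
      insertionProb = insertionProb,
      templatedInsertionProb = templatedInsertionProb,
      insertLenP = insertLenP, longInsertRate = longInsertRate,
      templateWindow = as.integer(templateWindow), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: resectionP=%.3g (mean resection %.1f nt), ",
           "mhBiasWeight=%.3g, insertionProb=%.3g (templated %.3g), ",
           "longInsertRate=%.3g, seed=%d\n"),
    object@resectionP, (1 - object@resectionP) / object@resectionP,
    object@mhBiasWeight, object@insertionProb,
    object@templatedInsertionProb, object@longInsertRate, object@seed))
})

#' Generate a synthetic cut locus
#'
#' A random uniform-composition locus with a nuclease cut site leaving a
#' 5' overhang, emulating a ~600 bp amplicon around a ZFN target.
#'
#' @param name locus label.
#' @param length locus length in nt (default 600).
#' @param overhang 5' overhang length in nt (default 4, FokI-type).
#' @param nickTop 0-based top-strand nick; default centers the cut.
#' @param variableTerminalBases variably-cleaved terminal base count
#'   (default 0).
#' @param baseComposition probabilities over A/C/G/T (default uniform).
#' @param seed optional RNG seed.
#' @return a [ReferenceLocus-class].
#' @export
syntheticLocus <- function(name, length = 600L, overhang = 4L,
                           nickTop = (length - overhang) %/% 2L,
                           variableTerminalBases = 0L,
                           baseComposition = c(A = 0.25, C = 0.25,
                                               G = 0.25, T = 0.25),
                           seed = NULL) {
  baseComposition <- .normalizeComposition(baseComposition)
  gen <- function() .randomDna(as.integer(length), baseComposition)
  sq <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  ReferenceLocus(name, sq, nickTop = nickTop,
                 nickBottom = nickTop + overhang,
                 variableTerminalBases = variableTerminalBases)
}

# forward/backward longest-common-extension tables between the two parental
# sequences; padded by one row/column of zeros so lookups at sequence ends
# are in range. fwd[i, j] = matching run of left[i..] vs right[j..];
# bwd[i+1, j+1] = matching run of left[..i] vs right[..j]. 'N' never
# matches.
.lceTables <- function(leftSeq, rightSeq) {
  l <- strsplit(leftSeq, "", fixed = TRUE)[[1L]]
  r <- strsplit(rightSeq, "", fixed = TRUE)[[1L]]
  Ll <- length(l)
  Lr <- length(r)
  fwd <- matrix(0L, Ll + 1L, Lr + 1L)
  for (i in Ll:1L) {
    eq <- (l[i] == r) & (l[i] != "N") & (r != "N")
    fwd[i, 1:Lr] <- ifelse(eq, fwd[i + 1L, 2:(Lr + 1L)] + 1L, 0L)
  }
  bwd <- matrix(0L, Ll + 1L, Lr + 1L)
  for (i in 1:Ll) {
    eq <- (l[i] == r) & (l[i] != "N") & (r != "N")
    bwd[i + 1L, 2:(Lr + 1L)] <- ifelse(eq, bwd[i, 1:Lr] + 1L, 0L)
  }
  list(fwd = fwd, bwd = bwd)
}

#' Simulate translocation junctions with ground truth
#'
#' Generative stand-in for sequenced breakpoint junctions. For each
#' junction: resection lengths for the two ends are drawn geometrically;
#' with probability `mhBiasWeight / (1 + mhBiasWeight)` the joint is placed
#' at the offset within the resected windows exposing the longest
#' microhomology (ties resolved toward the unresected ends), otherwise the
#' resected ends are joined directly; with probability `insertionProb` (or
#' `longInsertRate` for the long class) a templated or untemplated segment
#' is inserted at the joint (insertion junctions join at the resected ends).
#' Truth records are emitted pre-canonicalized with the
#' [annotateJunction()] conventions, so round-trip comparisons are exact.
#'
#' @param config a [SimulationConfig-class]; its `seed` makes the output
#'   reproducible.
#' @param der a [DerivativeReference-class] built from loci long enough for
#'   the configured resection (resection draws that would exhaust a
#'   reference are resampled, at most 10 times each).
#' @param n number of junctions.
#' @param genotype label stored with the junctions (default `"synthetic"`).
#' @return list with `sequences` (named character) and `truth`
#'   ([S4Vectors::DataFrame] of canonical annotations, including the
#'   generated `true_del_left`/`true_del_right` resection pair as
#'   `resected_left`/`resected_right`).
#' @examples
#' der <- buildDerivative(syntheticLocus("a", seed = 1),
#'                        syntheticLocus("b", seed = 2))
#' sim <- simulateJunctions(SimulationConfig(seed = 3), der, 5)
#' sim$truth[, c("del_total", "mh_len", "junction_class")]
#' @export
simulateJunctions <- function(config, der, n, genotype = "synthetic") {
  stopifnot(is(config, "SimulationConfig"), is(der, "DerivativeReference"),
            n >= 1L)
  leftSeq <- der@leftLocus@sequence
  rightSeq <- der@rightLocus@sequence
  leftEnd <- der@leftEnd
  rightStart <- der@rightStart
  Lr <- nchar(rightSeq)
  vt <- der@rightLocus@variableTerminalBases
  leftRaw <- .rawDna(leftSeq)
  rightRaw <- .rawDna(rightSeq)

  # resection must leave enough anchor sequence for annotation
  reserve <- 20L
  maxDL <- leftEnd - reserve
  maxDR <- (Lr - rightStart) - reserve
  if (maxDL < 0L || maxDR < 0L)
    stop("references too short for simulation (need >= ", reserve,
         " nt on each retained side)")

  needBias <- config@mhBiasWeight > 0
  if (needBias) {
    lce <- .lceTables(leftSeq, rightSeq)
    mhAt <- function(q, s) lce$fwd[q + 1L, s + 1L] + lce$bwd[q + 1L, s + 1L]
  }
  pBias <- config@mhBiasWeight / (1 + config@mhBiasWeight)

  resectionWarned <- FALSE
  drawResection <- function(maxAllowed) {
    for (try in 1:11) {
      d <- stats::rgeom(1L, config@resectionP)
      if (d <= maxAllowed) return(d)
      if (!resectionWarned) {
        warning("resection draw(s) exceeded reference length; resampling")
        resectionWarned <<- TRUE
      }
    }
    stop("resection repeatedly exceeded reference length (10 retries)")
  }

  windowBounds <- function(locus) {
    lo <- max(0L, locus@nickTop - config@templateWindow)
    hi <- min(nchar(locus@sequence), locus@nickBottom + config@templateWindow)
    c(lo, hi)
  }

  drawInsert <- function(templated, long) {
    if (!templated) {
      len <- 1L + stats::rgeom(1L, config@insertLenP)
      return(.randomDna(len, .uniformComposition()))
    }
    len <- if (long) 51L + stats::rgeom(1L, 0.028) else
      7L + stats::rgeom(1L, 0.15)
    srcLocus <- if (stats::runif(1L) < 0.5) der@leftLocus else der@rightLocus
    wb <- windowBounds(srcLocus)
    len <- min(len, wb[2L] - wb[1L])
    start <- wb[1L] + sample.int(wb[2L] - wb[1L] - len + 1L, 1L) - 1L
    seg <- substr(srcLocus@sequence, start + 1L, start + len)
    if (stats::runif(1L) < 0.5) seg <- .revcomp(seg)
    seg
  }

  run <- function() {
    seqs <- character(n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      dL <- drawResection(maxDL)
      dR <- drawResection(maxDR)

      long <- stats::runif(1L) < config@longInsertRate
      withIns <- long || stats::runif(1L) < config@insertionProb
      ins <- ""
      if (withIns) {
        templated <- long || stats::runif(1L) < config@templatedInsertionProb
        ins <- drawInsert(templated, long)
      }

      if (!withIns && needBias && stats::runif(1L) < pBias) {
        # joint at the offset exposing the longest microhomology within
        # the resected windows; ties -> closest to the unresected ends
        qs <- leftEnd - (0:dL)
        ss <- rightStart + (0:dR)
        M <- lce$fwd[qs + 1L, ss + 1L, drop = FALSE] +
             lce$bwd[qs + 1L, ss + 1L, drop = FALSE]
        hits <- which(M == max(M), arr.ind = TRUE)
        aL <- hits[, 1L] - 1L
        aR <- hits[, 2L] - 1L
        pick <- order(aL + aR, aL)[1L]
        q <- leftEnd - aL[pick]
        s <- rightStart + aR[pick]
      } else {
        q <- leftEnd - dL
        s <- rightStart + dR
      }

      jn <- paste0(substr(leftSeq, 1L, q), ins,
                   substr(rightSeq, s + 1L, Lr))
      seqs[i] <- jn
      dec <- .decompose(.rawDna(jn), leftRaw, rightRaw, leftEnd, rightStart,
                        vt)
      dec$resected_left <- leftEnd - q
      dec$resected_right <- s - rightStart
      rows[[i]] <- dec
    }
    list(seqs = seqs, rows = rows)
  }

  res <- withr::with_seed(config@seed, run())
  ids <- sprintf("%s_%06d", genotype, seq_len(n))
  names(res$seqs) <- ids
  col <- function(nm, mode) vapply(res$rows, `[[`, vector(mode, 1L), nm)
  truth <- DataFrame(
    junction_id = ids,
    genotype = genotype,
    del_left = col("del_left", "integer"),
    del_right = col("del_right", "integer"),
    del_total = col("del_total", "integer"),
    mh_len = col("mh_len", "integer"),
    mh_seq = col("mh_seq", "character"),
    insertion_seq = col("insertion_seq", "character"),
    insertion_len = col("insertion_len", "integer"),
    junction_class = col("junction_class", "character"),
    terminal_rule_applied = col("terminal_rule_applied", "logical"),
    terminal_copies = col("terminal_copies", "integer"),
    resected_left = col("resected_left", "integer"),
    resected_right = col("resected_right", "integer"))
  list(sequences = res$seqs, truth = truth)
}

#' Simulate a plate assay at a known translocation frequency
#'
#' Each well holds `cellsPerWell` cells; with events per cell
#' `trueFrequency`, a well is positive with probability
#' `1 - exp(-trueFrequency * cellsPerWell)` (Poisson occupancy).
#'
#' @param trueFrequency events per cell in \[0, 1\].
#' @param wells number of wells (default 96).
#' @param cellsPerWell cells per well (default 208).
#' @param seed optional RNG seed.
#' @return a [PlateAssay-class].
#' @examples
#' simulatePlate(3.7e-4, seed = 1)
#' @export
simulatePlate <- function(trueFrequency, wells = 96L, cellsPerWell = 208L,
                          seed = NULL) {
  stopifnot(trueFrequency >= 0, trueFrequency <= 1)
  pPos <- 1 - exp(-trueFrequency * cellsPerWell)
  gen <- function() stats::rbinom(1L, wells, pPos)
  k <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  PlateAssay(k, wells = wells, cellsPerWell = cellsPerWell)
}
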