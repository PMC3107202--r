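#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.unalignable <- function(id) {
  stop(structure(
    class = c("unalignableJunction", "error", "condition"),
    list(message = sprintf(
           "junction '%s': no exact seed match to both references in either orientation",
           id),
         call = sys.call(-1L))))
}

# Core decomposition of an orientation-normalized junction against the two
# parental references. Matching is exact; 'N' never matches. Returns the
# canonical decomposition: maximal left prefix match (eL), maximal right
# suffix match (r), overlap -> microhomology, gap -> insertion. The
# breakpoint is canonicalized at the right edge of the microhomology, so
# reconstruction = left[0:eL] + middle + right[rightMatchStart:], with the
# shared bases written once (charged to the left-side prefix).
.decompose <- function(jnRaw, leftRaw, rightRaw, leftEnd, rightStart,
                       variableTerminal = 0L) {
  eL <- .lcpRaw(jnRaw, leftRaw)
  r <- .lcsRaw(jnRaw, rightRaw)
  n <- length(jnRaw)
  sR <- length(rightRaw) - r            # 0-based start of right match
  m0 <- eL + r - n                      # overlap (>=0) or -gap (<0)

  termApplied <- FALSE
  termCopies <- 0L
  if (m0 >= 0L) {
    mhLen <- m0
    mhSeq <- if (m0 > 0L) rawToChar(jnRaw[(n - r + 1L):eL]) else ""
    insSeq <- ""
    insLen <- 0L
    rightMatchStart <- sR + m0
  } else {
    g <- -m0
    mhLen <- 0L
    mhSeq <- ""
    insSeq <- rawToChar(jnRaw[(eL + 1L):(eL + g)])
    insLen <- g
    rightMatchStart <- sR
    if (variableTerminal > 0L && g <= variableTerminal) {
      tb <- rawToChar(rightRaw[rightStart + 1L])
      if (identical(insSeq, strrep(tb, g))) {
        # variably-cleaved terminal base(s): retained copies of the
        # reference end base are neither insertion nor deletion
        termApplied <- TRUE
        termCopies <- g
        insSeq <- ""
        insLen <- 0L
      }
    }
  }
  delLeft <- leftEnd - eL
  delRight <- rightMatchStart - rightStart
  list(del_left = delLeft,
       del_right = delRight,
       del_total = delLeft + delRight,
       mh_len = mhLen,
       mh_seq = mhSeq,
       insertion_seq = insSeq,
       insertion_len = insLen,
       junction_class = if (insLen > 0L) "insertion"
                        else if (delLeft + delRight == 0L) "perfect"
                        else "simple_deletion",
       terminal_rule_applied = termApplied,
       terminal_copies = termCopies,
       left_match_end = eL,
       right_match_start = rightMatchStart)
}

.reconstruct <- function(dec, leftSeq, rightSeq) {
  middle <- if (dec$terminal_rule_applied) {
    strrep(substr(rightSeq, dec$right_match_start - dec$del_right + 1L,
                  dec$right_match_start - dec$del_right + 1L),
           dec$terminal_copies)
  } else {
    dec$insertion_seq
  }
  paste0(substr(leftSeq, 1L, dec$left_match_end),
         middle,
         substr(rightSeq, dec$right_match_start + 1L, nchar(rightSeq)))
}

#' Anchor a junction read to a derivative reference
#'
#' Determines read orientation by exact seed matching (the first `seedLen`
#' bases of the left reference and the last `seedLen` bases of the right
#' reference must both occur in the read, in one orientation), then measures
#' the maximal exact prefix match into the left reference and suffix match
#' into the right reference. Matches are exact and stop at the first
#' mismatch or `N`.
#'
#' @param junctionSeq DNA string of the junction amplicon.
#' @param der a [DerivativeReference-class].
#' @param seedLen seed length in nt (>= 8; default 15).
#' @return list with `leftMatchLen`, `rightMatchLen`, `orientation`
#'   (`"forward"` or `"reverse"`).
#' @seealso [annotateJunction()]
#' @export
anchorJunction <- function(junctionSeq, der, seedLen = 15L) {
  stopifnot(is(der, "DerivativeReference"), seedLen >= 8L)
  junctionSeq <- toupper(junctionSeq)
  leftSeq <- der@leftLocus@sequence
  rightSeq <- der@rightLocus@sequence
  leftSeed <- substr(leftSeq, 1L, seedLen)
  rightSeed <- substr(rightSeq, nchar(rightSeq) - seedLen + 1L,
                      nchar(rightSeq))
  hasBoth <- function(s) {
    grepl(leftSeed, s, fixed = TRUE) && grepl(rightSeed, s, fixed = TRUE)
  }
  if (hasBoth(junctionSeq)) {
    orientation <- "forward"
    jn <- junctionSeq
  } else {
    rc <- .revcomp(junctionSeq)
    if (hasBoth(rc)) {
      orientation <- "reverse"
      jn <- rc
    } else {
      .unalignable("<unnamed>")
    }
  }
  jnRaw <- .rawDna(jn)
  list(leftMatchLen = .lcpRaw(jnRaw, .rawDna(leftSeq)),
       rightMatchLen = .lcsRaw(jnRaw, .rawDna(rightSeq)),
       orientation = orientation)
}

#' Annotate a translocation breakpoint junction
#'
#' Decomposes a junction amplicon into deletion, microhomology and insertion
#' components relative to the perfect-join derivative reference. The read is
#' orientation-normalized, the maximal exact prefix match into the left
#' reference and suffix match into the right reference are computed, and:
#'
#' * if the two matches overlap by `m` read bases, the junction carries `m`
#'   nt of microhomology (`mh_len = m`, no insertion). The breakpoint is
#'   canonicalized at the right edge of the microhomology: `del_left =
#'   leftEnd - eL` with `eL` the maximal left-match endpoint (so `del_left`
#'   may be negative when the right flank incidentally extends the left
#'   match past the blunt end), `del_right = rightMatchStart - rightStart`.
#'   `del_total` is invariant under the choice of breakpoint within the
#'   microhomology.
#' * if the matches leave a gap, the gap is the insertion (`mh_len = 0`).
#' * terminal-base rule: when the right locus declares
#'   `variableTerminalBases = v > 0` and the putative insertion is exactly
#'   `<= v` copies of the right fragment's first retained base, it is scored
#'   as neither insertion nor deletion (`terminal_rule_applied = TRUE`,
#'   copies in `terminal_copies`). This generalizes scoring conventions for
#'   nucleases whose cut position varies by a base.
#'
#' The reconstruction invariant — left prefix + middle + right suffix equals
#' the read byte-for-byte — is checked and an internal error raised on
#' failure.
#'
#' @param junctionSeq DNA string of the junction amplicon.
#' @param der a [DerivativeReference-class].
#' @param seedLen seed length for anchoring (default 15).
#' @param id junction identifier carried into the output.
#' @param genotype genotype label carried into the output.
#' @return a one-row [S4Vectors::DataFrame] with columns `junction_id`,
#'   `genotype`, `del_left`, `del_right`, `del_total`, `mh_len`, `mh_seq`,
#'   `insertion_seq`, `insertion_len`, `junction_class`,
#'   `terminal_rule_applied`, `terminal_copies`, `orientation`,
#'   `left_match_end`, `right_match_start` (coordinates 0-based).
#' @examples
#' a <- ReferenceLocus("a", strrep("ACGGT", 10), 20, 24)
#' b <- ReferenceLocus("b", strrep("TTGCA", 10), 20, 24)
#' der <- buildDerivative(a, b)
#' annotateJunction(perfectJoin(der), der)
#' @export
annotateJunction <- function(junctionSeq, der, seedLen = 15L,
                             id = "junction", genotype = NA_character_) {
  ann <- annotateJunctions(stats::setNames(junctionSeq, id), der,
                           genotype = genotype, seedLen = seedLen,
                           onUnalignable = "error")
  ann
}

#' Annotate a set of junction sequences
#'
#' Vectorized form of [annotateJunction()]. Unalignable junctions either
#' raise an error or are dropped (with their ids recorded in
#' `metadata(result)$unalignable`).
#'
#' @param sequences named character vector of junction DNA strings (names =
#'   junction ids).
#' @param der a [DerivativeReference-class].
#' @param genotype genotype label(s), length 1 or `length(sequences)`.
#' @param seedLen seed length for anchoring.
#' @param onUnalignable `"error"` (default) or `"drop"`.
#' @return [S4Vectors::DataFrame], one row per annotated junction (see
#'   [annotateJunction()] for columns).
#' @export
annotateJunctions <- function(sequences, der, genotype = NA_character_,
                              seedLen = 15L,
                              onUnalignable = c("error", "drop")) {
  stopifnot(is(der, "DerivativeReference"), seedLen >= 8L)
  onUnalignable <- match.arg(onUnalignable)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("junction%d", seq_along(sequences))
  genotype <- rep_len(as.character(genotype), length(sequences))

  leftSeq <- der@leftLocus@sequence
  rightSeq <- der@rightLocus@sequence
  leftRaw <- .rawDna(leftSeq)
  rightRaw <- .rawDna(rightSeq)
  leftSeed <- substr(leftSeq, 1L, seedLen)
  rightSeed <- substr(rightSeq, nchar(rightSeq) - seedLen + 1L,
                      nchar(rightSeq))
  vt <- der@rightLocus@variableTerminalBases

  n <- length(sequences)
  rows <- vector("list", n)
  orient <- character(n)
  keep <- logical(n)
  unaligned <- character(0L)

  for (i in seq_len(n)) {
    jn <- toupper(sequences[[i]])
    if (grepl(leftSeed, jn, fixed = TRUE) &&
        grepl(rightSeed, jn, fixed = TRUE)) {
      orient[i] <- "forward"
    } else {
      rc <- .revcomp(jn)
      if (grepl(leftSeed, rc, fixed = TRUE) &&
          grepl(rightSeed, rc, fixed = TRUE)) {
        orient[i] <- "reverse"
        jn <- rc
      } else {
        if (onUnalignable == "error") .unalignable(names(sequences)[i])
        unaligned <- c(unaligned, names(sequences)[i])
        next
      }
    }
    dec <- .decompose(.rawDna(jn), leftRaw, rightRaw,
                      der@leftEnd, der@rightStart, vt)
    if (!identical(.reconstruct(dec, leftSeq, rightSeq), jn))
      stop("internal consistency error: reconstruction failed for junction '",
           names(sequences)[i], "'")
    keep[i] <- TRUE
    rows[[i]] <- dec
  }

  rows <- rows[keep]
  col <- function(nm, mode) vapply(rows, `[[`, vector(mode, 1L), nm)
  out <- DataFrame(
    junction_id = names(sequences)[keep],
    genotype = genotype[keep],
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
    orientation = orient[keep],
    left_match_end = col("left_match_end", "integer"),
    right_match_start = col("right_match_start", "integer"))
  if (length(unaligned)) {
    message(length(unaligned), " unalignable junction(s) dropped")
    metadata(out)$unalignable <- unaligned
  }
  out
}

#' Trace the origin of an inserted junction segment
#'
#' Searches both strands of both parental loci for an exact full-length
#' match of an insertion (length >= `minLen`, default 7 nt, i.e. inserts
#' longer than 6 bp). Ties are broken by left locus before right locus,
#' forward before inverted, then smallest source start. `flanking_mh` is
#' the longer of the exact overlaps between each insert edge and the
#' junction-adjacent parental sequence (insert prefix vs the bases ending at
#' the left match end; insert suffix vs the bases starting at the right
#' match start).
#'
#' @param annotation one row of an [annotateJunctions()] result (DataFrame,
#'   data.frame or list) with a nonempty `insertion_seq`.
#' @param der the [DerivativeReference-class] the junction was annotated
#'   against.
#' @param minLen minimum insertion length to attempt derivation (default 7).
#' @param window restrict the search to within `window` nt of each cut;
#'   `NULL` (default) searches the whole locus.
#' @return one-row [S4Vectors::DataFrame] with `junction_id`, `source`
#'   (`"left_locus"`, `"right_locus"` or `"unknown"`), `source_start`,
#'   `source_end` (0-based half-open), `inverted`, `flanking_mh`.
#' @export
deriveInsertion <- function(annotation, der, minLen = 7L, window = NULL) {
  stopifnot(is(der, "DerivativeReference"))
  ann <- as.list(as.data.frame(annotation))
  ins <- ann$insertion_seq
  if (is.null(ins) || nchar(ins) < minLen)
    stop("insertion_len < minLen (", minLen, "): derivation not attempted")

  searchIn <- function(locus) {
    seqFull <- locus@sequence
    if (is.null(window)) {
      lo <- 0L
      hi <- nchar(seqFull)
    } else {
      lo <- max(0L, locus@nickTop - as.integer(window))
      hi <- min(nchar(seqFull), locus@nickBottom + as.integer(window))
    }
    sub <- substr(seqFull, lo + 1L, hi)
    hit <- function(query) {
      p <- regexpr(query, sub, fixed = TRUE)
      if (p[1L] > 0L) lo + as.integer(p[1L]) - 1L else NA_integer_
    }
    list(fwd = hit(ins), inv = hit(.revcomp(ins)))
  }

  cand <- list(
    list(src = "left_locus", inverted = FALSE,
         start = searchIn(der@leftLocus)$fwd),
    list(src = "left_locus", inverted = TRUE,
         start = searchIn(der@leftLocus)$inv),
    list(src = "right_locus", inverted = FALSE,
         start = searchIn(der@rightLocus)$fwd),
    list(src = "right_locus", inverted = TRUE,
         start = searchIn(der@rightLocus)$inv))
  found <- Filter(function(x) !is.na(x$start), cand)

  if (length(found)) {
    best <- found[[1L]]
    src <- best$src
    s0 <- best$start
    s1 <- s0 + nchar(ins)
    inverted <- best$inverted
  } else {
    src <- "unknown"
    s0 <- NA_integer_
    s1 <- NA_integer_
    inverted <- NA
  }

  # flanking microhomology at the two insert edges
  leftSeq <- der@leftLocus@sequence
  rightSeq <- der@rightLocus@sequence
  eL <- ann$left_match_end
  rms <- ann$right_match_start
  edgeOverlap <- function(edge) {
    kmax <- nchar(ins)
    if (edge == "left") kmax <- min(kmax, eL)
    else kmax <- min(kmax, nchar(rightSeq) - rms)
    for (k in seq_len(kmax)[order(seq_len(kmax), decreasing = TRUE)]) {
      if (edge == "left") {
        if (identical(substr(ins, 1L, k),
                      substr(leftSeq, eL - k + 1L, eL))) return(k)
      } else {
        if (identical(substr(ins, nchar(ins) - k + 1L, nchar(ins)),
                      substr(rightSeq, rms + 1L, rms + k))) return(k)
      }
    }
    0L
  }
  flankingMH <- max(edgeOverlap("left"), edgeOverlap("right"))

  DataFrame(junction_id = if (is.null(ann$junction_id)) NA_character_
                          else ann$junction_id,
            source = src,
            source_start = s0,
            source_end = s1,
            inverted = inverted,
            flanking_mh = as.integer(flankingMH))
}

#' Derive origins for all qualifying insertions in an annotation table
#'
#' @param annotations an [annotateJunctions()] result.
#' @inheritParams deriveInsertion
#' @return [S4Vectors::DataFrame], one row per junction with
#'   `insertion_len >= minLen`.
#' @export
deriveInsertions <- function(annotations, der, minLen = 7L, window = NULL) {
  idx <- which(annotations$insertion_len >= minLen)
  rows <- lapply(idx, function(i)
    deriveInsertion(annotations[i, ], der, minLen = minLen, window = window))
  if (!length(rows))
    return(DataFrame(junction_id = character(0L), source = character(0L),
                     source_start = integer(0L), source_end = integer(0L),
                     inverted = logical(0L), flanking_mh = integer(0L)))
  do.call(rbind, rows)
}

#' Read junction sequences from FASTA or TSV
#'
#' FASTA record ids encode the genotype as `"genotype|id"`; TSV files need
#' columns `id`, `genotype`, `derivative`, `sequence`.
#'
#' @param path input file (`.fa`/`.fasta`/`.fna` or `.tsv`/`.txt`).
#' @return [S4Vectors::DataFrame] with columns `id`, `genotype`,
#'   `derivative`, `sequence` (`derivative` is `NA` for FASTA input).
#' @export
readJunctions <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "genotype", "derivative", "sequence")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("junction TSV missing column(s): ", paste(miss, collapse = ", "))
    return(DataFrame(id = as.character(tab$id),
                     genotype = as.character(tab$genotype),
                     derivative = as.character(tab$derivative),
                     sequence = toupper(tab$sequence)))
  }
  seqs <- loadFasta(path)
  ids <- names(seqs)
  hasGt <- grepl("|", ids, fixed = TRUE)
  genotype <- ifelse(hasGt, sub("\\|.*$", "", ids), NA_character_)
  id <- ifelse(hasGt, sub("^[^|]*\\|", "", ids), ids)
  DataFrame(id = id, genotype = genotype,
            derivative = NA_character_, sequence = unname(seqs))
}
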