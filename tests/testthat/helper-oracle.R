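# Independent oracles used to freeze expected values. These deliberately use
# different code paths from the package internals: character-vector scans and
# explicit enumeration instead of raw-vector run arithmetic.

# Exhaustive decomposition oracle: enumerate every (prefix match x, suffix
# match r) pair, keep the decomposition maximizing total matched length
# (then maximal left match), and derive deletion / microhomology / insertion
# fields from it, including the terminal-base rule.
oracleDecompose <- function(junctionSeq, der) {
  j <- strsplit(junctionSeq, "", fixed = TRUE)[[1L]]
  l <- strsplit(locusSequence(leftLocus(der)), "", fixed = TRUE)[[1L]]
  r <- strsplit(locusSequence(rightLocus(der)), "", fixed = TRUE)[[1L]]
  n <- length(j)
  lE <- leftEnd(der)
  rS <- rightStart(der)
  vtb <- variableTerminalBases(rightLocus(der))

  match1 <- function(a, b) a == b & a != "N" & b != "N"

  kmax <- min(n, length(l))
  prefixOK <- c(TRUE, cumprod(match1(j[seq_len(kmax)],
                                     l[seq_len(kmax)])) > 0)
  P <- which(prefixOK) - 1L            # all valid prefix-match lengths
  kmax <- min(n, length(r))
  suffixOK <- c(TRUE, cumprod(match1(rev(j)[seq_len(kmax)],
                                     rev(r)[seq_len(kmax)])) > 0)
  S <- which(suffixOK) - 1L            # all valid suffix-match lengths

  best <- NULL
  for (x in P) {
    for (rr in S) {
      cand <- c(total = x + rr, x = x, r = rr)
      if (is.null(best) || cand["total"] > best["total"] ||
          (cand["total"] == best["total"] && cand["x"] > best["x"]))
        best <- cand
    }
  }
  x <- unname(best["x"])
  rr <- unname(best["r"])
  sR <- length(r) - rr
  m0 <- x + rr - n

  termApplied <- FALSE
  termCopies <- 0L
  if (m0 >= 0) {
    mhLen <- m0
    mhSeq <- if (m0 > 0) paste(j[(n - rr + 1L):x], collapse = "") else ""
    insSeq <- ""
    rightMatchStart <- sR + m0
  } else {
    g <- -m0
    mhLen <- 0L
    mhSeq <- ""
    insSeq <- paste(j[(x + 1L):(x + g)], collapse = "")
    rightMatchStart <- sR
    if (vtb > 0L && g <= vtb && identical(insSeq, strrep(r[rS + 1L], g))) {
      termApplied <- TRUE
      termCopies <- g
      insSeq <- ""
    }
  }
  list(del_left = lE - x,
       del_right = rightMatchStart - rS,
       del_total = (lE - x) + (rightMatchStart - rS),
       mh_len = as.integer(mhLen),
       mh_seq = mhSeq,
       insertion_seq = insSeq,
       insertion_len = nchar(insSeq),
       junction_class = if (nchar(insSeq) > 0) "insertion"
                        else if ((lE - x) + (rightMatchStart - rS) == 0)
                          "perfect" else "simple_deletion",
       terminal_rule_applied = termApplied,
       terminal_copies = termCopies)
}

# Full-enumeration Mann-Whitney oracle: iterate over all 2^n group masks
# with the right group size, compute U by direct pair counting (ties count
# half), and take the two-sided p as 2 * min(one-sided) capped at 1.
oracleMannWhitney <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  uOf <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  uObs <- uOf(x, y)
  us <- c()
  for (mask in 0:(2^n - 1)) {
    sel <- as.logical(intToBits(mask)[1:n])
    if (sum(sel) != nx) next
    us <- c(us, uOf(pooled[sel], pooled[!sel]))
  }
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= uObs + eps), mean(us >= uObs - eps)))
  list(U = uObs, p.value = p)
}
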