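# Programmatic fixtures; nothing is read from disk.

# fresh random derivative from two independent synthetic loci
freshDer <- function(seed, length = 200L, overhang = 4L, vtb = 0L) {
  left <- syntheticLocus("chr6like", length = length, overhang = overhang,
                         seed = seed)
  right <- syntheticLocus("chr11like", length = length, overhang = overhang,
                          variableTerminalBases = vtb, seed = seed + 1e6L)
  buildDerivative(left, right, "derTest")
}

# mutate one character of a sequence string (1-based position)
setBase <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# Derivative engineered so that deleting delL from the left end and delR
# from the right end leaves exactly `m` bases of microhomology at the joint
# (backward overlap), with no incidental extension on either side.
engineeredMHCase <- function(seed = 421L, delL = 3L, delR = 2L, m = 2L,
                             length = 120L) {
  repeat {
    left <- syntheticLocus("eL", length = length, seed = seed)
    right <- syntheticLocus("eR", length = length, seed = seed + 1e6L)
    L <- locusSequence(left)
    R <- locusSequence(right)
    lE <- nickBottom(left)
    rS <- nickTop(right)
    q <- lE - delL
    s <- rS + delR
    # right[s-m+1 .. s] := left[q-m+1 .. q]   (the engineered overlap)
    for (i in seq_len(m))
      R <- setBase(R, s - m + i, substr(L, q - m + i, q - m + i))
    # block extension beyond the engineered overlap
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    R <- setBase(R, s - m, other(substr(L, q - m, q - m)))     # stop backward
    L <- setBase(L, q + 1L, other(substr(R, s + 1L, s + 1L)))  # stop forward
    leftLoc <- ReferenceLocus("eL", L, nickTop(left), nickBottom(left))
    rightLoc <- ReferenceLocus("eR", R, nickTop(right), nickBottom(right))
    der <- buildDerivative(leftLoc, rightLoc, "derMH")
    jn <- paste0(substr(L, 1L, q), substr(R, s + 1L, nchar(R)))
    # accept only if the construction is clean (no incidental extra overlap)
    a <- annotateJunction(jn, der)
    if (a$del_left == delL && a$del_right == delR && a$mh_len == m)
      return(list(der = der, junction = jn, delL = delL, delR = delR, m = m))
    seed <- seed + 1L
  }
}

# random junction built from a derivative: resections + optional insertion
randomTestJunction <- function(der, maxDel = 25L, insProb = 0.3,
                               maxIns = 12L) {
  L <- locusSequence(leftLocus(der))
  R <- locusSequence(rightLocus(der))
  q <- leftEnd(der) - sample.int(maxDel + 1L, 1L) + 1L
  s <- rightStart(der) + sample.int(maxDel + 1L, 1L) - 1L
  ins <- ""
  if (runif(1L) < insProb) {
    len <- sample.int(maxIns, 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  }
  paste0(substr(L, 1L, q), ins, substr(R, s + 1L, nchar(R)))
}

# minimal annotation table for summary tests (only the columns the
# summarizer reads)
annFixture <- function(mh, ins, class, delTotal = NULL,
                       genotype = "gt") {
  n <- length(mh)
  if (is.null(delTotal)) delTotal <- rep(5L, n)
  S4Vectors::DataFrame(
    junction_id = sprintf("f%02d", seq_len(n)),
    genotype = genotype,
    del_total = as.integer(delTotal),
    mh_len = as.integer(mh),
    insertion_len = as.integer(ins),
    junction_class = class)
}
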