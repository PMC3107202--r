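test_that("perfect joins are annotated as perfect in both orientations", {
  der <- freshDer(11L, length = 300L)
  pj <- perfectJoin(der)

  anc <- anchorJunction(pj, der)
  expect_identical(anc$orientation, "forward")
  expect_gte(anc$leftMatchLen + anc$rightMatchLen, nchar(pj))

  ann <- annotateJunction(pj, der)
  expect_identical(ann$junction_class, "perfect")
  expect_identical(ann$del_total, 0L)
  expect_identical(ann$insertion_len, 0L)

  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(pj)))
  annR <- annotateJunction(rc, der)
  expect_identical(annR$orientation, "reverse")
  for (f in c("del_left", "del_right", "mh_len", "insertion_seq",
              "junction_class"))
    expect_identical(annR[[f]], ann[[f]])
})

test_that("junctions without seed matches raise an unalignable error", {
  der <- freshDer(13L, length = 120L)
  expect_error(annotateJunction("AAAAGGGG", der),
               class = "unalignableJunction")
  # batch mode drops and records them
  pj <- perfectJoin(der)
  seqs <- c(good = pj, bad = strrep("AAAAGGGG", 10L))
  expect_message(
    ann <- annotateJunctions(seqs, der, onUnalignable = "drop"),
    "unalignable")
  expect_identical(nrow(ann), 1L)
  expect_identical(S4Vectors::metadata(ann)$unalignable, "bad")
})

test_that("engineered deletion/microhomology junctions are scored as built", {
  case <- engineeredMHCase(seed = 421L, delL = 3L, delR = 2L, m = 2L)
  ann <- annotateJunction(case$junction, case$der)
  expect_identical(ann$del_left, 3L)
  expect_identical(ann$del_right, 2L)
  expect_identical(ann$mh_len, 2L)
  expect_identical(ann$insertion_len, 0L)
  orc <- oracleDecompose(case$junction, case$der)
  expect_identical(ann$del_left, orc$del_left)
  expect_identical(ann$del_right, orc$del_right)
  expect_identical(ann$mh_len, orc$mh_len)

  # a second geometry
  case2 <- engineeredMHCase(seed = 900L, delL = 7L, delR = 0L, m = 3L)
  ann2 <- annotateJunction(case2$junction, case2$der)
  expect_identical(c(ann2$del_left, ann2$del_right, ann2$mh_len),
                   c(7L, 0L, 3L))
})

test_that("an untemplated insert at the joint is recovered verbatim", {
  der <- freshDer(51L, length = 200L)
  L <- locusSequence(leftLocus(der))
  R <- locusSequence(rightLocus(der))
  ins <- "TTAGGC"
  # guard the construction: insert must not extend either flank match
  stopifnot(substr(ins, 1, 1) != substr(L, leftEnd(der) + 1, leftEnd(der) + 1),
            substr(ins, 6, 6) != substr(R, rightStart(der), rightStart(der)))
  jn <- paste0(substr(L, 1, leftEnd(der)), ins,
               substr(R, rightStart(der) + 1, nchar(R)))
  ann <- annotateJunction(jn, der)
  expect_identical(ann$insertion_seq, ins)
  expect_identical(ann$insertion_len, 6L)
  expect_identical(ann$mh_len, 0L)
  expect_identical(ann$junction_class, "insertion")
  orc <- oracleDecompose(jn, der)
  expect_identical(orc$insertion_seq, ins)
})

test_that("the variable terminal base is not scored as an insertion", {
  # pick a derivative whose left flank cannot absorb the extra terminal
  # base (left continuation base must differ from it)
  for (s in 77:120) {
    der <- freshDer(s, length = 200L, vtb = 1L)
    L <- locusSequence(leftLocus(der))
    R <- locusSequence(rightLocus(der))
    rS <- rightStart(der)
    tb <- substr(R, rS + 1L, rS + 1L)
    if (substr(L, leftEnd(der) + 1L, leftEnd(der) + 1L) != tb) break
  }
  # delete from the right end until the base preceding the cut differs from
  # the terminal base, so the extra copy cannot re-extend the right match
  dR <- 5L
  while (substr(R, rS + dR, rS + dR) == tb) dR <- dR + 1L
  jn <- paste0(substr(L, 1L, leftEnd(der)), tb,
               substr(R, rS + dR + 1L, nchar(R)))
  ann <- annotateJunction(jn, der)
  expect_true(ann$terminal_rule_applied)
  expect_identical(ann$terminal_copies, 1L)
  expect_identical(ann$insertion_len, 0L)
  expect_identical(oracleDecompose(jn, der)$terminal_rule_applied, TRUE)

  # two copies exceed variableTerminalBases = 1 and stay an insertion
  jn2 <- paste0(substr(L, 1L, leftEnd(der)), strrep(tb, 2L),
                substr(R, rS + dR + 1L, nchar(R)))
  ann2 <- annotateJunction(jn2, der)
  expect_false(ann2$terminal_rule_applied)
  expect_identical(ann2$insertion_seq, strrep(tb, 2L))

  # a non-terminal single-base gap stays an insertion too
  nb <- setdiff(c("A", "C", "G", "T"),
                c(tb, substr(L, leftEnd(der) + 1L, leftEnd(der) + 1L),
                  substr(R, rS + dR, rS + dR)))[1L]
  jn3 <- paste0(substr(L, 1L, leftEnd(der)), nb,
                substr(R, rS + dR + 1L, nchar(R)))
  ann3 <- annotateJunction(jn3, der)
  expect_false(ann3$terminal_rule_applied)
  expect_identical(ann3$insertion_seq, nb)
})

test_that("annotation agrees with the exhaustive decomposition oracle", {
  set.seed(202)
  for (d in 1:6) {
    der <- freshDer(3000L + d, length = 160L)
    for (k in 1:50) {
      jn <- randomTestJunction(der)
      ann <- annotateJunction(jn, der)
      orc <- oracleDecompose(jn, der)
      for (f in names(orc))
        expect_identical(ann[[f]], orc[[f]],
                         info = sprintf("der %d junction %d field %s",
                                        d, k, f))
    }
  }
})

test_that("annotated parts reconstruct the junction byte-for-byte", {
  der <- freshDer(404L, length = 300L)
  sim <- simulateJunctions(SimulationConfig(seed = 8L), der, 100L)
  ann <- annotateJunctions(sim$sequences, der)
  L <- locusSequence(leftLocus(der))
  R <- locusSequence(rightLocus(der))
  for (i in seq_len(nrow(ann))) {
    middle <- if (ann$terminal_rule_applied[i]) {
      strrep(substr(R, rightStart(der) + 1L, rightStart(der) + 1L),
             ann$terminal_copies[i])
    } else ann$insertion_seq[i]
    rebuilt <- paste0(substr(L, 1L, ann$left_match_end[i]), middle,
                      substr(R, ann$right_match_start[i] + 1L, nchar(R)))
    expect_identical(rebuilt, unname(sim$sequences[[i]]))
  }
})

test_that("extending a reference flank never changes the annotation", {
  set.seed(88)
  der <- freshDer(88L, length = 160L)
  jns <- replicate(20L, randomTestJunction(der))
  base <- annotateJunctions(stats::setNames(jns, paste0("j", 1:20)), der)

  extraL <- paste(sample(c("A", "C", "G", "T"), 30L, TRUE), collapse = "")
  extraR <- paste(sample(c("A", "C", "G", "T"), 30L, TRUE), collapse = "")
  la <- leftLocus(der)
  lb <- rightLocus(der)
  la2 <- ReferenceLocus(locusName(la), paste0(extraL, locusSequence(la)),
                        nickTop(la) + 30L, nickBottom(la) + 30L)
  lb2 <- ReferenceLocus(locusName(lb), paste0(locusSequence(lb), extraR),
                        nickTop(lb), nickBottom(lb))
  der2 <- buildDerivative(la2, lb2)
  jns2 <- paste0(extraL, jns, extraR)
  ext <- annotateJunctions(stats::setNames(jns2, paste0("j", 1:20)), der2)
  for (f in c("del_left", "del_right", "mh_len", "mh_seq", "insertion_seq",
              "insertion_len", "junction_class"))
    expect_identical(ext[[f]], base[[f]])
})

test_that("insertion origins are traced to the correct locus and strand", {
  der <- freshDer(640L, length = 200L)
  L <- locusSequence(leftLocus(der))
  R <- locusSequence(rightLocus(der))
  lE <- leftEnd(der)
  rS <- rightStart(der)

  plant <- function(ins) {
    jn <- paste0(substr(L, 1L, lE), ins, substr(R, rS + 1L, nchar(R)))
    ann <- annotateJunction(jn, der)
    # construction guard: the whole insert must survive annotation
    stopifnot(identical(ann$insertion_seq, ins))
    ann
  }

  # copied verbatim from left locus positions 10..20 (0-based half-open)
  insL <- substr(L, 11L, 20L)
  if (substr(insL, 1, 1) != substr(L, lE + 1L, lE + 1L) &&
      substr(insL, 10, 10) != substr(R, rS, rS)) {
    d <- deriveInsertion(plant(insL), der, minLen = 7L)
    expect_identical(d$source, "left_locus")
    expect_false(d$inverted)
    expect_identical(d$source_start, 10L)
    expect_identical(d$source_end, 20L)
  }

  # reverse complement of right locus positions 30..40
  seg <- substr(R, 31L, 40L)
  insI <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  if (!grepl(insI, L, fixed = TRUE) && !grepl(insI, R, fixed = TRUE) &&
      substr(insI, 1, 1) != substr(L, lE + 1L, lE + 1L) &&
      substr(insI, 10, 10) != substr(R, rS, rS)) {
    d <- deriveInsertion(plant(insI), der, minLen = 7L)
    expect_identical(d$source, "right_locus")
    expect_true(d$inverted)
    expect_identical(d$source_start, 30L)
  }

  # a 12-mer verified absent from both loci on both strands -> unknown
  set.seed(5)
  repeat {
    insU <- paste(sample(c("A", "C", "G", "T"), 12L, TRUE), collapse = "")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(insU)))
    if (!grepl(insU, L, fixed = TRUE) && !grepl(insU, R, fixed = TRUE) &&
        !grepl(rc, L, fixed = TRUE) && !grepl(rc, R, fixed = TRUE) &&
        substr(insU, 1, 1) != substr(L, lE + 1L, lE + 1L) &&
        substr(insU, 12, 12) != substr(R, rS, rS)) break
  }
  d <- deriveInsertion(plant(insU), der, minLen = 7L)
  expect_identical(d$source, "unknown")
  expect_true(is.na(d$source_start))

  # below the derivation threshold -> precondition error
  shortAnn <- S4Vectors::DataFrame(junction_id = "s", insertion_seq = "ACG",
                                   left_match_end = lE,
                                   right_match_start = rS)
  expect_error(deriveInsertion(shortAnn, der, minLen = 7L), "minLen")
})

test_that("flanking microhomology at an insert edge is measured", {
  # search derivative seeds until the construction is clean: an insert
  # whose first 3 bases repeat the last 3 retained left bases (a
  # direct-repeat annealing signature) without perturbing the flank matches
  found <- FALSE
  for (s in 901:980) {
    der <- freshDer(s, length = 200L)
    L <- locusSequence(leftLocus(der))
    R <- locusSequence(rightLocus(der))
    lE <- leftEnd(der)
    rS <- rightStart(der)
    pre <- substr(L, lE - 2L, lE)
    ins <- paste0(pre, "TTAACCG")
    jn <- paste0(substr(L, 1L, lE), ins, substr(R, rS + 1L, nchar(R)))
    ann <- annotateJunction(jn, der)
    if (!identical(ann$insertion_seq, ins)) next
    d <- deriveInsertion(ann, der, minLen = 7L)
    expect_gte(d$flanking_mh, 3L)
    found <- TRUE
    break
  }
  expect_true(found)
})
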