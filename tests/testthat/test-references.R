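test_that("FASTA reading normalizes case, preserves order, rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), fa)
  expect_identical(loadFasta(fa), c(x = "ACGT"))

  writeLines(c(">first", "AAAA", ">second desc text", "ccgg"), fa)
  got <- loadFasta(fa)
  expect_identical(names(got), c("first", "second"))
  expect_identical(unname(got), c("AAAA", "CCGG"))

  writeLines(c(">x", "ACGU"), fa)
  expect_error(loadFasta(fa), "line 2")

  writeLines(character(0L), fa)
  expect_error(loadFasta(fa), "empty")

  expect_error(loadFasta(file.path(tempdir(), "no-such-file.fa")),
               "not found")
})

test_that("locus validity enforces nick ordering and alphabet", {
  expect_s4_class(ReferenceLocus("ok", "ACGTN", 1, 3), "ReferenceLocus")
  expect_error(ReferenceLocus("bad", "ACGU", 1, 2), "disallowed")
  expect_error(ReferenceLocus("bad", "ACGT", 3, 2), "nickTop")
  expect_error(ReferenceLocus("bad", "ACGT", 1, 9), "nickTop")
})

test_that("fill-in returns the overhang-duplicating fragments", {
  loc <- ReferenceLocus("toy", "AAAATTTTCCCC", nickTop = 4, nickBottom = 8)
  expect_identical(fillInEnd(loc, "left"), "AAAATTTT")
  expect_identical(fillInEnd(loc, "right"), "TTTTCCCC")
  expect_identical(overhangLength(loc), 4L)

  blunt <- ReferenceLocus("blunt", "AAAATTTTCCCC", nickTop = 6)
  expect_identical(fillInEnd(blunt, "left"), "AAAATT")
  expect_identical(fillInEnd(blunt, "right"), "TTCCCC")
  expect_identical(paste0(fillInEnd(blunt, "left"), fillInEnd(blunt, "right")),
                   locusSequence(blunt))
})

test_that("both fill-in fragments of one locus reconstruct it plus one overhang copy", {
  set.seed(31)
  for (i in 1:20) {
    loc <- syntheticLocus("p", length = 80L, overhang = sample(0:6, 1L),
                          seed = 7000L + i)
    joined <- paste0(fillInEnd(loc, "left"), fillInEnd(loc, "right"))
    ovh <- substr(locusSequence(loc), nickTop(loc) + 1L, nickBottom(loc))
    expect_identical(
      joined,
      paste0(substr(locusSequence(loc), 1L, nickBottom(loc)),
             ovh,
             substr(locusSequence(loc), nickBottom(loc) + 1L,
                    nchar(locusSequence(loc)))))
  }
})

test_that("derivative is the concatenated perfect join with the expected length", {
  a <- ReferenceLocus("a", "AAAATTTTCCCC", 4, 8)
  b <- ReferenceLocus("b", "AAAATTTTCCCC", 4, 8)
  der <- buildDerivative(a, b)
  expect_identical(perfectJoin(der), "AAAATTTTTTTTCCCC")

  set.seed(17)
  for (i in 1:100) {
    la <- syntheticLocus("a", length = sample(60:200, 1L),
                         overhang = sample(0:5, 1L), seed = 100L + i)
    lb <- syntheticLocus("b", length = sample(60:200, 1L),
                         overhang = sample(0:5, 1L), seed = 5000L + i)
    der <- buildDerivative(la, lb)
    expect_identical(nchar(perfectJoin(der)),
                     nickBottom(la) +
                       (nchar(locusSequence(lb)) - nickTop(lb)))
  }
})

test_that("reciprocal derivatives cover each parental base once, overhangs twice", {
  la <- syntheticLocus("a", length = 90L, overhang = 4L, seed = 41L)
  lb <- syntheticLocus("b", length = 110L, overhang = 3L, seed = 42L)
  dAB <- buildDerivative(la, lb)
  dBA <- buildDerivative(lb, la)
  # der(A->B) holds A[0:nickBottom_A) and B[nickTop_B:); der(B->A) holds
  # B[0:nickBottom_B) and A[nickTop_A:): together each base once, each
  # overhang interval twice
  sa <- locusSequence(la)
  sb <- locusSequence(lb)
  expect_identical(perfectJoin(dAB),
                   paste0(substr(sa, 1, nickBottom(la)),
                          substr(sb, nickTop(lb) + 1, nchar(sb))))
  expect_identical(perfectJoin(dBA),
                   paste0(substr(sb, 1, nickBottom(lb)),
                          substr(sa, nickTop(la) + 1, nchar(sa))))
  expect_identical(nchar(perfectJoin(dAB)) + nchar(perfectJoin(dBA)),
                   nchar(sa) + nchar(sb) +
                     overhangLength(la) + overhangLength(lb))
})

test_that("locus JSON config round-trips through FASTA ids", {
  fa <- withr::local_tempfile(fileext = ".fa")
  js <- withr::local_tempfile(fileext = ".json")
  writeLines(c(">seqA", "AAAACCCCGGGGTTTT", ">seqB", "acgtacgtacgt"), fa)
  jsonlite::write_json(list(
    list(name = "locusA", fasta_id = "seqA", nick_top = 6, nick_bottom = 10),
    list(name = "locusB", fasta_id = "seqB", nick_top = 4, nick_bottom = 4,
         variable_terminal_bases = 1)), js, auto_unbox = TRUE)
  loci <- readLocusConfig(js, fa)
  expect_named(loci, c("locusA", "locusB"))
  expect_identical(overhangLength(loci$locusA), 4L)
  expect_identical(locusSequence(loci$locusB), "ACGTACGTACGT")
  expect_identical(variableTerminalBases(loci$locusB), 1L)
})
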