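#' Read named DNA sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that normalizes
#' sequences to uppercase, restricts the alphabet to A/C/G/T/N, and reports
#' the offending line on failure.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, input order
#'   preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' loadFasta(fa)
#' @export
loadFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty FASTA file: ", path)
  firstContent <- which(nzchar(trimws(lines)))[1L]
  if (!startsWith(trimws(lines[firstContent]), ">"))
    stop(sprintf("malformed FASTA (line %d): expected '>' header", firstContent))
  # pre-scan sequence lines: readDNAStringSet silently drops invalid codes,
  # but a restricted-alphabet violation must be an error naming the line
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, ">")) next
    bad <- setdiff(unique(strsplit(toupper(ln), "", fixed = TRUE)[[1L]]),
                   .DNA_ALPHABET)
    if (length(bad))
      stop(sprintf("malformed FASTA (line %d): disallowed character '%s'",
                   i, bad[1L]))
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e)
      stop("malformed FASTA: ", conditionMessage(e), call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  # first whitespace-delimited token of the header is the id
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("FASTA record with empty id")
  seqs
}

#' Construct a ReferenceLocus
#'
#' @param name locus label.
#' @param sequence DNA string (A/C/G/T/N, case-insensitive).
#' @param nickTop 0-based top-strand nick offset.
#' @param nickBottom 0-based top-strand coordinate of the bottom-strand
#'   nick; `nickBottom - nickTop` is the 5' overhang length. Defaults to
#'   `nickTop` (blunt cut).
#' @param variableTerminalBases number of end bases with variable cleavage
#'   (see [annotateJunction()]'s terminal-base rule); default 0.
#' @return a [ReferenceLocus-class] object.
#' @examples
#' ReferenceLocus("toy", "AAAATTTTCCCC", nickTop = 4, nickBottom = 8)
#' @export
ReferenceLocus <- function(name, sequence, nickTop, nickBottom = nickTop,
                           variableTerminalBases = 0L) {
  new("ReferenceLocus",
      name = as.character(name),
      sequence = toupper(as.character(sequence)),
      nickTop = as.integer(nickTop),
      nickBottom = as.integer(nickBottom),
      variableTerminalBases = as.integer(variableTerminalBases))
}

#' @describeIn ReferenceLocus-class locus label
#' @param object,x a `ReferenceLocus`.
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("locusName", "ReferenceLocus", function(x) x@name)

#' @describeIn ReferenceLocus-class locus sequence (character)
#' @export
setGeneric("locusSequence", function(x) standardGeneric("locusSequence"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("locusSequence", "ReferenceLocus", function(x) x@sequence)

#' @describeIn ReferenceLocus-class 0-based top-strand nick offset
#' @export
setGeneric("nickTop", function(x) standardGeneric("nickTop"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("nickTop", "ReferenceLocus", function(x) x@nickTop)

#' @describeIn ReferenceLocus-class 0-based bottom-strand nick coordinate
#' @export
setGeneric("nickBottom", function(x) standardGeneric("nickBottom"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("nickBottom", "ReferenceLocus", function(x) x@nickBottom)

#' @describeIn ReferenceLocus-class 5' overhang length in nt
#' @export
setGeneric("overhangLength", function(x) standardGeneric("overhangLength"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("overhangLength", "ReferenceLocus",
          function(x) x@nickBottom - x@nickTop)

#' @describeIn ReferenceLocus-class count of variably-cleaved terminal bases
#' @export
setGeneric("variableTerminalBases",
           function(x) standardGeneric("variableTerminalBases"))
#' @rdname ReferenceLocus-class
#' @export
setMethod("variableTerminalBases", "ReferenceLocus",
          function(x) x@variableTerminalBases)

setMethod("show", "ReferenceLocus", function(object) {
  cat(sprintf("ReferenceLocus '%s': %d nt, nicks %d/%d (%d-nt 5' overhang)",
              object@name, nchar(object@sequence), object@nickTop,
              object@nickBottom, object@nickBottom - object@nickTop))
  if (object@variableTerminalBases > 0L)
    cat(sprintf(", %d variable terminal base(s)", object@variableTerminalBases))
  cat("\n")
})

#' Blunt-end fragment of a cut locus after 5'-overhang fill-in
#'
#' Fill-in of a 5' overhang duplicates the overhang bases on both retained
#' fragments: the left (5') fragment runs to `nickBottom`, the right (3')
#' fragment starts at `nickTop`. For a blunt cut the two fragments partition
#' the sequence.
#'
#' @param locus a [ReferenceLocus-class].
#' @param side `"left"` (5' fragment) or `"right"` (3' fragment).
#' @return DNA string of the filled-in fragment.
#' @examples
#' loc <- ReferenceLocus("toy", "AAAATTTTCCCC", nickTop = 4, nickBottom = 8)
#' fillInEnd(loc, "left")   # "AAAATTTT"
#' fillInEnd(loc, "right")  # "TTTTCCCC"
#' @export
fillInEnd <- function(locus, side = c("left", "right")) {
  stopifnot(is(locus, "ReferenceLocus"))
  side <- match.arg(side)
  if (side == "left") {
    substr(locus@sequence, 1L, locus@nickBottom)
  } else {
    substr(locus@sequence, locus@nickTop + 1L, nchar(locus@sequence))
  }
}

#' Build the perfect-join derivative reference for two cut loci
#'
#' Concatenates the filled-in left (5') fragment of `left` with the
#' filled-in right (3') fragment of `right`, the sequence expected if the
#' two DNA ends joined with no loss or gain. The two reciprocal derivatives
#' `buildDerivative(A, B)` and `buildDerivative(B, A)` together contain each
#' parental base exactly once except the overhang bases, which fill-in
#' duplicates.
#'
#' @param left,right [ReferenceLocus-class] objects; `left` contributes its
#'   5' fragment, `right` its 3' fragment.
#' @param name derivative label; default `"der(<left>-<right>)"`.
#' @return a [DerivativeReference-class].
#' @examples
#' a <- ReferenceLocus("a", "AAAATTTTCCCC", 4, 8)
#' b <- ReferenceLocus("b", "AAAATTTTCCCC", 4, 8)
#' perfectJoin(buildDerivative(a, b))
#' @export
buildDerivative <- function(left, right,
                            name = sprintf("der(%s-%s)", left@name, right@name)) {
  stopifnot(is(left, "ReferenceLocus"), is(right, "ReferenceLocus"))
  leftEnd <- left@nickBottom
  rightStart <- right@nickTop
  new("DerivativeReference",
      name = name,
      leftLocus = left,
      rightLocus = right,
      leftEnd = leftEnd,
      rightStart = rightStart,
      perfectJoin = paste0(fillInEnd(left, "left"), fillInEnd(right, "right")))
}

#' @describeIn DerivativeReference-class perfect-join sequence (character)
#' @param object,x a `DerivativeReference`.
#' @export
setGeneric("perfectJoin", function(x) standardGeneric("perfectJoin"))
#' @rdname DerivativeReference-class
#' @export
setMethod("perfectJoin", "DerivativeReference", function(x) x@perfectJoin)

#' @describeIn DerivativeReference-class left parental locus
#' @export
setGeneric("leftLocus", function(x) standardGeneric("leftLocus"))
#' @rdname DerivativeReference-class
#' @export
setMethod("leftLocus", "DerivativeReference", function(x) x@leftLocus)

#' @describeIn DerivativeReference-class right parental locus
#' @export
setGeneric("rightLocus", function(x) standardGeneric("rightLocus"))
#' @rdname DerivativeReference-class
#' @export
setMethod("rightLocus", "DerivativeReference", function(x) x@rightLocus)

#' @describeIn DerivativeReference-class blunt-end coordinate after fill-in
#' @export
setGeneric("leftEnd", function(x) standardGeneric("leftEnd"))
#' @rdname DerivativeReference-class
#' @export
setMethod("leftEnd", "DerivativeReference", function(x) x@leftEnd)

#' @describeIn DerivativeReference-class blunt-start coordinate after fill-in
#' @export
setGeneric("rightStart", function(x) standardGeneric("rightStart"))
#' @rdname DerivativeReference-class
#' @export
setMethod("rightStart", "DerivativeReference", function(x) x@rightStart)

setMethod("show", "DerivativeReference", function(object) {
  cat(sprintf(
    "DerivativeReference '%s': %s[0:%d] + %s[%d:%d] (%d nt perfect join)\n",
    object@name, object@leftLocus@name, object@leftEnd,
    object@rightLocus@name, object@rightStart,
    nchar(object@rightLocus@sequence), nchar(object@perfectJoin)))
})

#' Read cut-locus definitions from a JSON config and FASTA
#'
#' The JSON config is an array of blocks
#' `{name, fasta_id, nick_top, nick_bottom, variable_terminal_bases}`;
#' sequences are taken from the FASTA by `fasta_id`.
#'
#' @param jsonPath path to the JSON locus config.
#' @param fastaPath path to the FASTA with the locus sequences.
#' @return named list of [ReferenceLocus-class] objects.
#' @export
readLocusConfig <- function(jsonPath, fastaPath) {
  cfg <- jsonlite::fromJSON(jsonPath, simplifyDataFrame = TRUE)
  seqs <- loadFasta(fastaPath)
  if (is.data.frame(cfg)) cfg <- split(cfg, seq_len(nrow(cfg)))
  loci <- lapply(cfg, function(b) {
    b <- as.list(b)
    if (is.null(seqs[[b$fasta_id]]))
      stop("locus '", b$name, "': fasta_id '", b$fasta_id, "' not in FASTA")
    vtb <- b$variable_terminal_bases
    if (is.null(vtb) || is.na(vtb)) vtb <- 0L
    ReferenceLocus(
      name = b$name,
      sequence = seqs[[b$fasta_id]],
      nickTop = b$nick_top,
      nickBottom = b$nick_bottom,
      variableTerminalBases = vtb)
  })
  names(loci) <- vapply(loci, locusName, character(1L))
  loci
}
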