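# Low-level exact-match helpers. Sequences are handled as raw vectors for
# speed; 'N' (0x4e) never matches anything, on either side.

.RAW_N <- charToRaw("N")

.rawDna <- function(x) charToRaw(x)

# longest common prefix of two raw vectors, N never matches
.lcpRaw <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  ia <- a[seq_len(n)]
  ib <- b[seq_len(n)]
  ok <- (ia == ib) & (ia != .RAW_N)
  bad <- which(!ok)
  if (length(bad)) bad[1L] - 1L else n
}

# longest common suffix of two raw vectors, N never matches
.lcsRaw <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  ia <- a[seq.int(length(a), by = -1L, length.out = n)]
  ib <- b[seq.int(length(b), by = -1L, length.out = n)]
  ok <- (ia == ib) & (ia != .RAW_N)
  bad <- which(!ok)
  if (length(bad)) bad[1L] - 1L else n
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# draw n random DNA strings of the given lengths under a base composition
.randomDna <- function(lengths, baseComposition = .uniformComposition()) {
  bases <- sample(names(baseComposition), sum(lengths), replace = TRUE,
                  prob = baseComposition)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  vapply(seq_along(lengths),
         function(i) paste(bases[starts[i]:ends[i]], collapse = ""),
         character(1L))
}

.uniformComposition <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}

.normalizeComposition <- function(baseComposition) {
  if (is.null(names(baseComposition)))
    names(baseComposition) <- c("A", "C", "G", "T")
  baseComposition <- baseComposition[c("A", "C", "G", "T")]
  if (anyNA(baseComposition))
    stop("baseComposition must be named over A, C, G, T")
  if (abs(sum(baseComposition) - 1) > 1e-9)
    stop("baseComposition must sum to 1 (within 1e-9)")
  baseComposition
}
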