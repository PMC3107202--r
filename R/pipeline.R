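.writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the junction analysis pipeline
#'
#' Orchestrates annotate -> summarize -> chance-null comparison -> pairwise
#' tests and writes tab-separated outputs ('.' decimal, header row):
#'
#' * `junctions_annotated.tsv` — one row per junction, all annotation fields;
#' * `genotype_summary.tsv` — per-genotype percentages and medians;
#' * `mh_distribution.tsv` — microhomology length counts per genotype over
#'   simple-deletion junctions, with the analytic chance-null probability
#'   column;
#' * `pairwise_tests.tsv` — two-tailed Mann-Whitney p values for every
#'   genotype pair and against the chance null (junction microhomology
#'   lengths vs a null-distributed reference sample of equal size is not
#'   attempted: the null column reports the goodness-of-fit chi-square p);
#' * `insertion_derivations.tsv` — origins of insertions >= the derivation
#'   threshold.
#'
#' @param config a list or path to a JSON file with elements: `fasta`
#'   (locus FASTA path), `loci` (blocks of `name`, `fasta_id`, `nick_top`,
#'   `nick_bottom`, optional `variable_terminal_bases`), `derivatives`
#'   (blocks of `name`, `left`, `right` locus names), `junctions` (FASTA or
#'   TSV path, see [readJunctions()]), `default_derivative` (name used for
#'   junctions without one), and optional `seed_len` (15),
#'   `min_insert_derivation_len` (7), `long_insert_threshold` (50),
#'   `max_mh_bin` (10), `out_dir` (".").
#' @return invisibly, a named list of output file paths plus the annotation
#'   table and summaries.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  need <- c("fasta", "loci", "junctions", "derivatives")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("pipeline config missing element(s): ", paste(miss, collapse = ", "))
  seedLen <- config$seed_len %||% 15L
  minDeriv <- config$min_insert_derivation_len %||% 7L
  longThr <- config$long_insert_threshold %||% 50L
  maxBin <- config$max_mh_bin %||% 10L
  outDir <- config$out_dir %||% "."
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(config$loci, tmp, auto_unbox = TRUE)
  loci <- readLocusConfig(tmp, config$fasta)
  unlink(tmp)

  derivCfg <- config$derivatives
  if (is.data.frame(derivCfg)) derivCfg <- split(derivCfg, seq_len(nrow(derivCfg)))
  ders <- lapply(derivCfg, function(d) {
    d <- as.list(d)
    buildDerivative(loci[[d$left]], loci[[d$right]], name = d$name)
  })
  names(ders) <- vapply(ders, function(d) d@name, character(1L))

  jx <- readJunctions(config$junctions)
  if (!nrow(jx)) stop("no junctions in input: ", config$junctions)
  derName <- ifelse(is.na(jx$derivative),
                    config$default_derivative %||% names(ders)[1L],
                    jx$derivative)
  unknown <- setdiff(unique(derName), names(ders))
  if (length(unknown))
    stop("junctions reference undefined derivative(s): ",
         paste(unknown, collapse = ", "))

  annList <- lapply(unique(derName), function(dn) {
    idx <- derName == dn
    annotateJunctions(stats::setNames(jx$sequence[idx], jx$id[idx]),
                      ders[[dn]], genotype = jx$genotype[idx],
                      seedLen = seedLen, onUnalignable = "drop")
  })
  nUnaligned <- sum(vapply(annList,
                           function(a) length(metadata(a)$unalignable),
                           integer(1L)))
  ann <- do.call(rbind, annList)
  message(sprintf("annotated %d junction(s); %d unalignable", nrow(ann),
                  nUnaligned))
  if (!nrow(ann)) stop("no junction could be aligned")

  summary <- summarizeGenotypes(ann, longInsertThreshold = longThr)

  # per-genotype microhomology distribution over simple deletions, with
  # the analytic chance column
  model <- chancePmf(maxLen = maxBin)
  gts <- unique(ann$genotype)
  bins <- c(as.character(0:maxBin), sprintf(">%d", maxBin))
  mhTab <- data.frame(mh_len = bins)
  for (g in gts) {
    sub <- ann[ann$genotype %in% g &
               ann$junction_class == "simple_deletion", , drop = FALSE]
    cnt <- table(factor(pmin(sub$mh_len, maxBin + 1L),
                        levels = 0:(maxBin + 1L)))
    mhTab[[paste0("count_", g)]] <- as.integer(cnt)
  }
  mhTab$chance_probability <- unname(nullPmf(model))

  # pairwise Mann-Whitney on microhomology of simple-deletion junctions,
  # plus chi-square fit of each genotype against the chance null
  pair <- list()
  mhOf <- function(g) {
    as.integer(ann$mh_len[ann$genotype %in% g &
                          ann$junction_class == "simple_deletion"])
  }
  if (length(gts) > 1L) {
    for (i in seq_len(length(gts) - 1L)) {
      for (j in (i + 1L):length(gts)) {
        mw <- mannWhitneyTwoTailed(mhOf(gts[i]), mhOf(gts[j]))
        pair[[length(pair) + 1L]] <- data.frame(
          a = gts[i], b = gts[j], test = "mann_whitney_two_tailed",
          statistic = mw$U, p_value = mw$p.value)
      }
    }
  }
  for (g in gts) {
    gof <- nullModelGof(mhOf(g), model)
    pair[[length(pair) + 1L]] <- data.frame(
      a = g, b = "expected_by_chance", test = "chisq_gof",
      statistic = gof$statistic, p_value = gof$p.value)
  }
  pairTab <- do.call(rbind, pair)

  derivTabs <- lapply(unique(derName), function(dn) {
    sub <- ann[ann$junction_id %in% jx$id[derName == dn], , drop = FALSE]
    deriveInsertions(sub, ders[[dn]], minLen = minDeriv)
  })
  derivTab <- do.call(rbind, derivTabs)

  paths <- list(
    annotations = .writeTsv(ann, file.path(outDir, "junctions_annotated.tsv")),
    summary = .writeTsv(summary, file.path(outDir, "genotype_summary.tsv")),
    mh_distribution = .writeTsv(mhTab, file.path(outDir, "mh_distribution.tsv")),
    pairwise_tests = .writeTsv(pairTab, file.path(outDir, "pairwise_tests.tsv")),
    insertion_derivations = .writeTsv(
      derivTab, file.path(outDir, "insertion_derivations.tsv")))
  invisible(c(paths, list(annotations_table = ann, summary_table = summary,
                          unalignable = nUnaligned)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
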