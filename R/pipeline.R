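#' Generate a synthetic narrative corpus with ground truth
#'
#' End-to-end generation: draws the ground-truth binary matrix
#' ([sample_binary_matrix()]), renders it as narratives
#' ([render_narratives()]), and injects the configured number of exact
#' duplicate narratives (fresh patient ids, identical text, duplicated
#' ground-truth rows), so the downstream cleaning step has real work to do.
#' The whole corpus is a deterministic function of the config seed.
#'
#' @param config a [generator_config()]; \code{n_patients} is the total
#'   record count including injected duplicates.
#' @param lexicon a \code{symptom_lexicon} covering every configured
#'   symptom.
#' @param nearest_psd passed to [sample_binary_matrix()].
#' @return A list with elements \code{corpus} (data frame
#'   \code{patient_id, text}), \code{truth} (binary matrix aligned with the
#'   corpus rows), and \code{manifest} (seed, record counts, zero-symptom
#'   and duplicate accounting).
#' @export
simulate_corpus <- function(config, lexicon, nearest_psd = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  n_dup <- min(config$n_duplicate_records, max(config$n_patients - 1L, 0L))
  n_unique <- config$n_patients - n_dup
  base_cfg <- config
  base_cfg$n_patients <- n_unique
  m <- sample_binary_matrix(base_cfg, nearest_psd = nearest_psd)
  corpus <- render_narratives(m, lexicon, config)

  if (n_dup > 0) {
    nonzero <- which(rowSums(m) > 0)
    if (length(nonzero) == 0) stop("cannot inject duplicates: no non-zero rows")
    set.seed(offset_seed(config$seed, 2L))
    src <- nonzero[sample.int(length(nonzero), n_dup, replace = n_dup > length(nonzero))]
    dup_ids <- sprintf("P%06d", n_unique + seq_len(n_dup))
    corpus <- rbind(corpus, data.frame(patient_id = dup_ids,
                                       text = corpus$text[src],
                                       stringsAsFactors = FALSE))
    extra <- m[src, , drop = FALSE]
    rownames(extra) <- dup_ids
    m <- rbind(m, extra)
  }

  manifest <- list(
    seed = config$seed,
    n_records = nrow(corpus),
    n_symptoms = length(config$prevalences),
    n_zero_symptom_records = sum(rowSums(m) == 0),
    n_duplicates_injected = n_dup,
    repeat_mention_rate = config$repeat_mention_rate,
    filler_rate = config$filler_rate
  )
  list(corpus = corpus, truth = m, manifest = manifest)
}

#' Run the full narrative-to-correlation analysis
#'
#' The analysis path a study would run on a real corpus: extract canonical
#' symptoms from every narrative, one-hot encode, compute the stratified
#' index-symptom report on the pre-cleaning matrix, clean (merge variant
#' columns, drop blacklisted columns, drop zero-symptom rows, drop
#' duplicate narratives), then screen every remaining symptom against the
#' index symptom and derive the frequency table, the small-band top
#' correlates and the independence list.
#'
#' @param corpus data frame with columns \code{patient_id}, \code{text}.
#' @param lexicon a \code{symptom_lexicon}.
#' @param config a [screen_config()].
#' @param negation_window passed to [extract_corpus()].
#' @param quiet suppress progress messages.
#' @return A list with elements \code{matrix} (cleaned binary matrix),
#'   \code{cleaning} (the [cleaning_report()]), \code{stratified}
#'   (pre-cleaning [stratified_report()]), \code{screen}
#'   ([screen_correlations()] results), \code{frequency}
#'   ([frequency_table()] of the cleaned matrix), \code{top}
#'   ([top_correlates()]) and \code{independent} ([independent_set()]).
#' @export
analyze_corpus <- function(corpus, lexicon, config = screen_config(),
                           negation_window = 0, quiet = FALSE) {
  sets <- extract_corpus(corpus, lexicon, negation_window, quiet = quiet)
  m_raw <- build_matrix(sets, lexicon, all_canonicals = TRUE)
  if (!(config$index_symptom %in% colnames(m_raw)) ||
      sum(m_raw[, config$index_symptom]) == 0) {
    stop("index symptom '", config$index_symptom,
         "' is never mentioned in this corpus")
  }
  strat <- stratified_report(m_raw, config$index_symptom)
  cleaned <- clean_matrix(m_raw, lexicon, raw_texts = corpus)
  # all_canonicals keeps never-reported columns for the stratified stage;
  # drop them before screening (they are constant zero)
  m <- cleaned$matrix[, colSums(cleaned$matrix) > 0, drop = FALSE]
  if (!quiet) print(cleaned$report)
  res <- screen_correlations(m, config)
  list(matrix = m,
       cleaning = cleaned$report,
       stratified = strat,
       screen = res,
       frequency = frequency_table(m),
       top = top_correlates(res, config),
       independent = independent_set(res, config))
}

#' Write simulation outputs to a directory
#'
#' Writes the corpus (two-column delimited text), the ground-truth binary
#' matrix, and a key/value manifest recording the seed and record counts.
#'
#' @param sim result of [simulate_corpus()].
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(sim$corpus, file.path(out_dir, "corpus.tsv"))
  write_binary_matrix(sim$truth, file.path(out_dir, "truth_matrix.tsv"))
  writeLines(sprintf("%s: %s", names(sim$manifest),
                     vapply(sim$manifest, format, character(1))),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' Write analysis outputs to a directory
#'
#' Writes the cleaned matrix, cleaning report, stratified report, screen
#' results (full precision, two-decimal display, independence list),
#' frequency table and top-correlates table. Every delimited report file
#' starts with \code{#}-prefixed header lines carrying the cleaning counts
#' and the screen configuration, so each output is self-describing.
#'
#' @param ana result of [analyze_corpus()].
#' @param out_dir output directory (created if missing).
#' @param config the [screen_config()] used.
#' @return \code{out_dir}, invisibly.
#' @export
write_analysis <- function(ana, out_dir, config = screen_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    sprintf("# index_symptom: %s", config$index_symptom),
    sprintf("# ci_level: %g | alpha: %g | band: %g:%g | zero_tolerance: %g | adjust: %s",
            config$ci_level, config$alpha, config$band_low, config$band_high,
            config$zero_tolerance, config$adjust),
    sprintf("# %s: %d", names(ana$cleaning), unlist(ana$cleaning))
  )
  write_with_header <- function(df, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_binary_matrix(ana$matrix, file.path(out_dir, "matrix_clean.tsv"))
  writeLines(c(hdr[1:2], sprintf("%s: %d", names(ana$cleaning), unlist(ana$cleaning))),
             file.path(out_dir, "cleaning_report.txt"))
  write_with_header(ana$stratified, file.path(out_dir, "stratified_report.tsv"))
  write_with_header(as.data.frame(ana$screen), file.path(out_dir, "screen.tsv"))
  write_with_header(format_screen_display(ana$screen),
                    file.path(out_dir, "screen_display.tsv"))
  write_with_header(ana$frequency, file.path(out_dir, "frequency_table.tsv"))
  write_with_header(as.data.frame(ana$top), file.path(out_dir, "top_correlates.tsv"))
  writeLines(ana$independent, file.path(out_dir, "independent_symptoms.txt"))
  invisible(out_dir)
}

#' One-call simulate pipeline
#'
#' Convenience wrapper: build (or accept) a generator config, simulate, and
#' write the outputs.
#'
#' @param out_dir output directory.
#' @param config a [generator_config()]; defaults to the study-scale
#'   [default_profile()].
#' @param lexicon lexicon used for rendering; defaults to [demo_lexicon()].
#' @param seed overrides the config seed when non-NULL.
#' @return The [simulate_corpus()] result, invisibly.
#' @export
run_simulate <- function(out_dir, config = default_profile(),
                         lexicon = demo_lexicon(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_corpus(config, lexicon)
  write_simulation(sim, out_dir)
  invisible(sim)
}

#' One-call analyze pipeline
#'
#' Reads a corpus and a lexicon from disk, runs [analyze_corpus()], and
#' writes all outputs.
#'
#' @param corpus_path two-column corpus file (see [read_corpus()]).
#' @param lexicon_path lexicon file (see [read_lexicon()]); \code{NULL}
#'   uses the demonstration lexicon.
#' @param out_dir output directory.
#' @param config a [screen_config()].
#' @param negation_window passed to [extract_corpus()].
#' @return The [analyze_corpus()] result, invisibly.
#' @export
run_analyze <- function(corpus_path, out_dir, lexicon_path = NULL,
                        config = screen_config(), negation_window = 0) {
  lexicon <- if (is.null(lexicon_path)) demo_lexicon() else read_lexicon(lexicon_path)
  corpus <- read_corpus(corpus_path)
  ana <- analyze_corpus(corpus, lexicon, config, negation_window)
  write_analysis(ana, out_dir, config)
  invisible(ana)
}
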