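#' Extract canonical symptoms from one narrative
#'
#' Scans the normalized token sequence of a narrative for lexicon surface
#' forms and returns the set of canonical symptoms mentioned at least once.
#' At each token position the longest matching surface form wins, and after
#' a multiword match scanning resumes past the matched span, so a lexicon
#' holding both \code{"low mood"} and \code{"mood"} fires only the former on
#' "low mood". How often a symptom is mentioned is deliberately discarded:
#' downstream encoding is strictly binary.
#'
#' Negation is ignored by default — lay narratives routinely report absent
#' sleep as "couldn't sleep", and a narrative that mentions a symptom at all
#' is treated as reporting it. Setting \code{negation_window > 0} enables a
#' simple divergent mode that skips a match when a negator token ("no",
#' "not", "never", "without") occurs within that many tokens before it.
#'
#' @param text raw narrative text (length-1 character).
#' @param lexicon a \code{symptom_lexicon}.
#' @param negation_window integer >= 0; 0 (default) disables negation
#'   handling.
#' @return Character vector of canonical symptom names (each at most once),
#'   in order of first mention.
#' @examples
#' lex <- symptom_lexicon(list("low mood" = "low mood",
#'                             lethargy = c("lethargy", "lethargic")))
#' extract_symptoms("I feel low mood. I just feel lethargic.", lex)
#' @export
extract_symptoms <- function(text, lexicon, negation_window = 0) {
  validate_lexicon(lexicon)
  idx <- build_match_index(lexicon)
  match_tokens(normalize_text(text), idx, negation_window)
}

# Matching index: surface forms as token vectors, bucketed by first token and
# ordered longest-first within each bucket.
build_match_index <- function(lexicon) {
  form2canon <- lexicon_forms(lexicon)
  forms <- names(form2canon)
  if (length(forms) == 0) {
    return(list(buckets = list(), canon = character(0)))
  }
  toks <- strsplit(forms, " ", fixed = TRUE)
  ord <- order(-lengths(toks))
  toks <- toks[ord]
  canon <- unname(form2canon)[ord]
  first <- vapply(toks, `[`, character(1), 1)
  buckets <- split(seq_along(toks), first)
  list(buckets = buckets, toks = toks, canon = canon)
}

negator_tokens <- c("no", "not", "never", "without", "dont", "didnt",
                    "doesnt", "wont", "cannot")

match_tokens <- function(tokens, idx, negation_window = 0) {
  n <- length(tokens)
  if (n == 0 || length(idx$buckets) == 0) return(character(0))
  found <- character(0)
  i <- 1
  while (i <= n) {
    cand <- idx$buckets[[tokens[i]]]
    advanced <- FALSE
    if (!is.null(cand)) {
      for (k in cand) {
        ft <- idx$toks[[k]]
        len <- length(ft)
        if (i + len - 1 <= n && all(tokens[i:(i + len - 1)] == ft)) {
          negated <- FALSE
          if (negation_window > 0) {
            lo <- max(1, i - negation_window)
            negated <- i > 1 && any(tokens[lo:(i - 1)] %in% negator_tokens)
          }
          if (!negated && !(idx$canon[k] %in% found)) {
            found <- c(found, idx$canon[k])
          }
          i <- i + len
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) i <- i + 1
  }
  found
}

#' Extract symptoms for a whole corpus
#'
#' Order-preserving, record-by-record application of [extract_symptoms()].
#' Emits a message with corpus-level counts (records processed, records with
#' zero extracted symptoms).
#'
#' @param corpus a data frame with columns \code{patient_id} and
#'   \code{text}, one row per narrative (see [read_corpus()]).
#' @param lexicon a \code{symptom_lexicon}.
#' @param negation_window passed to [extract_symptoms()].
#' @param quiet suppress the summary message.
#' @return A named list of character vectors (canonical symptoms), one per
#'   record, named by \code{patient_id}.
#' @export
extract_corpus <- function(corpus, lexicon, negation_window = 0, quiet = FALSE) {
  stopifnot(is.data.frame(corpus), all(c("patient_id", "text") %in% names(corpus)))
  ids <- as.character(corpus$patient_id)
  if (anyDuplicated(ids)) {
    stop("duplicate patient_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  validate_lexicon(lexicon)
  idx <- build_match_index(lexicon)
  sets <- lapply(corpus$text, function(txt) {
    match_tokens(normalize_text(txt), idx, negation_window)
  })
  names(sets) <- ids
  if (!quiet) {
    message(sprintf("extract_corpus: %d records processed, %d with zero symptoms",
                    length(sets), sum(lengths(sets) == 0)))
  }
  sets
}

#' Read / write a narrative corpus
#'
#' A corpus is stored as two-column tab-delimited UTF-8 text with header
#' \code{patient_id<TAB>text}, one narrative per line (embedded tabs and
#' newlines in narratives are replaced by spaces on write).
#'
#' @param path file path.
#' @return \code{read_corpus}: a data frame with character columns
#'   \code{patient_id} and \code{text}.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (!all(c("patient_id", "text") %in% names(tab))) {
    stop("corpus file must have columns 'patient_id' and 'text': ", path)
  }
  tab[, c("patient_id", "text")]
}

#' @rdname read_corpus
#' @param corpus data frame with columns \code{patient_id}, \code{text}.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is.data.frame(corpus), all(c("patient_id", "text") %in% names(corpus)))
  out <- corpus[, c("patient_id", "text")]
  out$text <- gsub("[\t\n\r]+", " ", out$text)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write extracted symptom sets as a filtered-narrative table
#'
#' Mirrors the "filtered narrative" presentation of a cleaned corpus: one
#' row per patient, symptoms joined by \code{"; "}.
#'
#' @param sets named list of canonical symptom vectors, as returned by
#'   [extract_corpus()].
#' @param path file path.
#' @export
write_symptom_sets <- function(sets, path) {
  tab <- data.frame(patient_id = names(sets),
                    symptoms = vapply(sets, paste, character(1), collapse = "; "),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
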