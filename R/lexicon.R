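#' Symptom lexicons
#'
#' A symptom lexicon is the vocabulary contract that drives narrative
#' extraction and column merging: it maps canonical symptom names to the
#' surface forms (possibly multiword, e.g. \code{"hearing voices"}) under
#' which they appear in lay text, and carries a blacklist of words declared
#' to be non-symptoms.
#'
#' Invariants enforced by [symptom_lexicon()] and checked again after
#' reading a file:
#' \itemize{
#'   \item every canonical name has at least one surface form;
#'   \item no surface form maps to two different canonical names;
#'   \item the blacklist is disjoint from the union of surface forms.
#' }
#'
#' Matching is case-insensitive and treats straight and curly apostrophes
#' identically (see [normalize_text()]). No stemming or lemmatisation is
#' applied beyond the explicit variant lists: merging \code{"sad"} and
#' \code{"sadness"} is the lexicon author's decision, not an algorithm's.
#'
#' @param entries named list; names are canonical symptom names, each
#'   element a character vector of lowercase surface forms.
#' @param blacklist character vector of non-symptom words.
#' @return An object of class \code{symptom_lexicon}: a list with elements
#'   \code{entries} and \code{blacklist}.
#' @examples
#' lex <- symptom_lexicon(list(
#'   sadness = c("sad", "sadness"),
#'   anxiety = c("anxiety", "anxious")
#' ))
#' lex
#' @seealso [read_lexicon()], [write_lexicon()], [extract_symptoms()]
#' @export
symptom_lexicon <- function(entries = list(), blacklist = character()) {
  if (length(entries) > 0 && is.null(names(entries))) {
    stop("'entries' must be a named list (canonical name -> surface forms)")
  }
  entries <- lapply(entries, function(v) {
    v <- normalize_forms(as.character(v))
    unique(v[nzchar(v)])
  })
  blacklist <- unique(normalize_forms(as.character(blacklist)))
  blacklist <- blacklist[nzchar(blacklist)]
  lex <- structure(list(entries = entries, blacklist = blacklist),
                   class = "symptom_lexicon")
  validate_lexicon(lex)
  lex
}

# canonicalise a surface form / blacklist word to its normalized token string
normalize_forms <- function(x) {
  vapply(x, function(s) paste(normalize_text(s), collapse = " "), character(1),
         USE.NAMES = FALSE)
}

#' @export
print.symptom_lexicon <- function(x, ...) {
  cat(sprintf("Symptom lexicon: %d canonical symptoms, %d surface forms, %d blacklisted words\n",
              length(x$entries), length(unlist(x$entries)), length(x$blacklist)))
  invisible(x)
}

#' Validate a symptom lexicon
#'
#' Checks the lexicon invariants and stops with an informative error on the
#' first violation.
#'
#' @param lexicon a \code{symptom_lexicon}.
#' @return The lexicon, invisibly, if valid.
#' @export
validate_lexicon <- function(lexicon) {
  stopifnot(inherits(lexicon, "symptom_lexicon") || is.list(lexicon))
  entries <- lexicon$entries
  empty <- names(entries)[lengths(entries) == 0]
  if (length(empty) > 0) {
    stop("canonical symptom(s) with no surface form: ",
         paste(empty, collapse = ", "))
  }
  all_forms <- unlist(entries, use.names = FALSE)
  dup <- unique(all_forms[duplicated(all_forms)])
  if (length(dup) > 0) {
    owners <- vapply(dup, function(f) {
      paste(names(entries)[vapply(entries, function(v) f %in% v, logical(1))],
            collapse = "', '")
    }, character(1))
    stop("surface form(s) mapped to more than one canonical symptom: ",
         paste(sprintf("'%s' (under '%s')", dup, owners), collapse = "; "))
  }
  clash <- intersect(lexicon$blacklist, all_forms)
  if (length(clash) > 0) {
    stop("blacklisted word(s) also appear as surface forms: ",
         paste(clash, collapse = ", "))
  }
  invisible(lexicon)
}

#' Canonical symptom names of a lexicon
#' @param lexicon a \code{symptom_lexicon}.
#' @return Character vector of canonical names.
#' @export
lexicon_canonicals <- function(lexicon) names(lexicon$entries)

#' Surface form to canonical lookup table
#'
#' @param lexicon a \code{symptom_lexicon}.
#' @return A named character vector mapping each surface form to its
#'   canonical symptom name.
#' @export
lexicon_forms <- function(lexicon) {
  forms <- unlist(lexicon$entries, use.names = FALSE)
  canon <- rep(names(lexicon$entries), lengths(lexicon$entries))
  stats::setNames(canon, forms)
}

#' Normalize raw narrative text to word tokens
#'
#' Lowercases, maps curly quotation marks and apostrophes to their straight
#' equivalents, deletes apostrophes (so \code{"don't"} and \code{"don’t"}
#' both yield \code{"dont"}), replaces every other punctuation character by a
#' space, and splits on whitespace. Normalization is idempotent: normalizing
#' the space-joined output returns the same tokens.
#'
#' @param text a character string (length-1).
#' @return Character vector of lowercase tokens, free of punctuation and
#'   whitespace; \code{character(0)} for empty input.
#' @examples
#' normalize_text("I feel low mood.")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[‘’ʼ]", "'", x)
  x <- gsub("[“”]", "\"", x)
  x <- gsub("'", "", x, fixed = TRUE)
  x <- gsub("[^[:alnum:]]+", " ", x)
  toks <- strsplit(trimws(x), " +")[[1]]
  toks[nzchar(toks)]
}

#' Read a symptom lexicon from a file
#'
#' Two plain-text formats are accepted and auto-detected:
#' \describe{
#'   \item{stanza}{one canonical per stanza: a line
#'     \code{canonical: <name>} followed by \code{variant: <surface form>}
#'     lines, with an optional \code{[blacklist]} section listing one
#'     non-symptom word per line. Blank lines and \code{#} comments are
#'     ignored. Grammar:
#'     \preformatted{
#' lexicon   ::= stanza* blacklist?
#' stanza    ::= "canonical:" name NL ("variant:" form NL)+
#' blacklist ::= "[blacklist]" NL (word NL)*}}
#'   \item{table}{a two-column delimited table (tab or comma) with header
#'     \code{surface_form, canonical}; blacklist words are rows whose
#'     canonical field is \code{"-"}.}
#' }
#'
#' @param path path to the lexicon file.
#' @return A validated \code{symptom_lexicon}.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stripped <- trimws(lines)
  keep <- nzchar(stripped) & !startsWith(stripped, "#")
  if (!any(keep)) return(symptom_lexicon())
  body <- stripped[keep]
  lineno <- which(keep)
  if (any(grepl("^(canonical|variant):", body)) || any(body == "[blacklist]")) {
    parse_lexicon_stanzas(body, lineno, path)
  } else {
    parse_lexicon_table(path)
  }
}

parse_lexicon_stanzas <- function(body, lineno, path) {
  entries <- list()
  blacklist <- character(0)
  current <- NULL
  in_blacklist <- FALSE
  for (i in seq_along(body)) {
    ln <- body[i]
    if (ln == "[blacklist]") {
      in_blacklist <- TRUE
      current <- NULL
    } else if (in_blacklist) {
      blacklist <- c(blacklist, ln)
    } else if (startsWith(ln, "canonical:")) {
      current <- trimws(sub("^canonical:", "", ln))
      if (!nzchar(current)) {
        stop(sprintf("%s:%d: empty canonical name", path, lineno[i]))
      }
      if (is.null(entries[[current]])) entries[[current]] <- character(0)
    } else if (startsWith(ln, "variant:")) {
      if (is.null(current)) {
        stop(sprintf("%s:%d: 'variant:' line before any 'canonical:' line",
                     path, lineno[i]))
      }
      form <- trimws(sub("^variant:", "", ln))
      entries[[current]] <- c(entries[[current]], form)
    } else {
      stop(sprintf("%s:%d: unrecognised lexicon line: '%s'", path, lineno[i], ln))
    }
  }
  symptom_lexicon(entries, blacklist)
}

parse_lexicon_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "\"", strip.white = TRUE)
  need <- c("surface_form", "canonical")
  if (!all(need %in% names(tab))) {
    stop("lexicon table must have columns 'surface_form' and 'canonical': ", path)
  }
  black <- tab$canonical == "-"
  entries <- split(tab$surface_form[!black], tab$canonical[!black])
  symptom_lexicon(entries, tab$surface_form[black])
}

#' Write a symptom lexicon in stanza format
#'
#' The written file reads back with [read_lexicon()] to an identical
#' lexicon (round-trip guarantee).
#'
#' @param lexicon a \code{symptom_lexicon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  validate_lexicon(lexicon)
  out <- character(0)
  for (canon in names(lexicon$entries)) {
    out <- c(out, paste0("canonical: ", canon),
             paste0("  variant: ", lexicon$entries[[canon]]), "")
  }
  if (length(lexicon$blacklist) > 0) {
    out <- c(out, "[blacklist]", lexicon$blacklist)
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Demonstration symptom lexicon
#'
#' A small lay-vocabulary lexicon (~28 canonical symptoms) shipped with the
#' package for worked examples and the synthetic corpus generator. It covers
#' common psychopathological experiences (auditory and visual hallucination,
#' delusion, paranoia, fear, anxiety, depression, trauma, pain, ...) plus a
#' few somatic terms (hypertension, nausea, weight loss) useful as plausible
#' independent symptoms. It makes no claim to clinical completeness: a real
#' study supplies its own lexicon file.
#'
#' @return A \code{symptom_lexicon}.
#' @export
demo_lexicon <- function() {
  path <- system.file("extdata", "demo_lexicon.txt", package = "symptomics")
  if (!nzchar(path)) stop("demo lexicon not found; is the package installed?")
  read_lexicon(path)
}
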