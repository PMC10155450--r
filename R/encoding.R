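#' Build the one-hot patient-by-symptom matrix
#'
#' Encodes extracted symptom sets as a binary matrix: one row per patient,
#' one column per canonical symptom, cell 1 if the patient's narrative
#' mentioned the symptom at least once and 0 otherwise. Mention multiplicity
#' is ignored by construction — a narrative using "anxiety" ten times still
#' encodes as 1.
#'
#' @param sets named list of canonical symptom character vectors (names are
#'   patient ids), as returned by [extract_corpus()].
#' @param lexicon a \code{symptom_lexicon}; sets may only contain its
#'   canonicals unless \code{strict = FALSE}.
#' @param all_canonicals if \code{TRUE}, include a column for every lexicon
#'   canonical even when no patient reports it; default keeps only symptoms
#'   reported by at least one patient.
#' @param strict error on symptoms outside the lexicon (default); if
#'   \code{FALSE} they are kept as their own columns with a warning.
#' @return Integer matrix of 0/1 cells with \code{rownames} = patient ids
#'   and \code{colnames} = canonical symptom names (sorted).
#' @export
build_matrix <- function(sets, lexicon, all_canonicals = FALSE, strict = TRUE) {
  stopifnot(is.list(sets))
  ids <- names(sets)
  if (is.null(ids) && length(sets) > 0) stop("'sets' must be named by patient id")
  canon <- lexicon_canonicals(lexicon)
  reported <- unique(unlist(sets, use.names = FALSE))
  unknown <- setdiff(reported, canon)
  if (length(unknown) > 0) {
    if (strict) {
      stop("symptom(s) not in lexicon: ", paste(unknown, collapse = ", "))
    }
    warning("retaining non-lexicon column(s): ", paste(unknown, collapse = ", "))
  }
  cols <- if (all_canonicals) union(canon, reported) else reported
  cols <- sort(cols)
  m <- matrix(0L, nrow = length(sets), ncol = length(cols),
              dimnames = list(ids, cols))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (length(s) > 0) m[i, s] <- 1L
  }
  m
}

#' Cleaning report
#'
#' Bookkeeping record of what [clean_matrix()] removed. Its arithmetic
#' invariant, \code{n_output_rows == n_input_rows - n_zero_symptom_rows_removed
#' - n_duplicate_rows_removed}, is checked on construction.
#'
#' @param n_input_rows,n_zero_symptom_rows_removed,n_duplicate_rows_removed
#'   row accounting.
#' @param n_columns_merged,n_columns_blacklisted,n_output_rows,n_output_columns
#'   column accounting and output dimensions.
#' @return A list of counts with class \code{cleaning_report}.
#' @export
cleaning_report <- function(n_input_rows, n_zero_symptom_rows_removed,
                            n_duplicate_rows_removed, n_columns_merged,
                            n_columns_blacklisted, n_output_rows,
                            n_output_columns) {
  rep <- structure(list(
    n_input_rows = n_input_rows,
    n_zero_symptom_rows_removed = n_zero_symptom_rows_removed,
    n_duplicate_rows_removed = n_duplicate_rows_removed,
    n_columns_merged = n_columns_merged,
    n_columns_blacklisted = n_columns_blacklisted,
    n_output_rows = n_output_rows,
    n_output_columns = n_output_columns
  ), class = "cleaning_report")
  if (rep$n_output_rows !=
      rep$n_input_rows - rep$n_zero_symptom_rows_removed - rep$n_duplicate_rows_removed) {
    stop("cleaning report arithmetic violated: ",
         rep$n_input_rows, " - ", rep$n_zero_symptom_rows_removed, " - ",
         rep$n_duplicate_rows_removed, " != ", rep$n_output_rows)
  }
  rep
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  for (f in names(x)) cat(sprintf("  %-28s %d\n", f, x[[f]]))
  invisible(x)
}

#' Clean a binary symptom matrix
#'
#' Applies, in order: (1) merge variant columns into their canonical column
#' by logical OR (e.g. separate "sad" and "sadness" columns become one
#' "sadness" column); (2) drop blacklisted non-symptom columns; (3) drop
#' rows whose cells are all zero (narratives mentioning no symptom);
#' (4) drop exact-duplicate records, keeping the first. Cleaning is
#' idempotent, and steps (1)-(2) never change the number of rows.
#'
#' Duplicate detection needs care: deduplicating on the binary row pattern
#' alone would delete thousands of genuinely distinct patients who happen to
#' report the same symptom set. When \code{raw_texts} is supplied,
#' duplicates are rows whose raw narrative text repeats an earlier row's
#' text; otherwise a row is a duplicate only if both its pattern and its
#' patient id repeat.
#'
#' Columns named by neither a lexicon canonical, a surface form, nor the
#' blacklist are retained as their own canonicals with a warning.
#'
#' @param m binary matrix from [build_matrix()] (rownames = patient ids).
#' @param lexicon a \code{symptom_lexicon}.
#' @param raw_texts optional data frame with columns \code{patient_id} and
#'   \code{text} covering the matrix rows; enables text-based duplicate
#'   removal.
#' @return A list with elements \code{matrix} (the cleaned binary matrix)
#'   and \code{report} (a [cleaning_report()]).
#' @export
clean_matrix <- function(m, lexicon, raw_texts = NULL) {
  stopifnot(is.matrix(m))
  validate_lexicon(lexicon)
  n_input <- nrow(m)
  form2canon <- lexicon_forms(lexicon)
  canon <- lexicon_canonicals(lexicon)

  # (1) merge variant-named columns into their canonical column
  n_merged <- 0L
  variants <- colnames(m)[colnames(m) %in% names(form2canon) &
                          !(colnames(m) %in% canon)]
  for (v in variants) {
    target <- form2canon[[v]]
    if (target %in% colnames(m)) {
      m[, target] <- as.integer(m[, target] | m[, v])
      m <- m[, colnames(m) != v, drop = FALSE]
    } else {
      colnames(m)[colnames(m) == v] <- target
    }
    n_merged <- n_merged + 1L
  }

  # (2) drop blacklisted columns
  black <- colnames(m) %in% lexicon$blacklist
  n_black <- sum(black)
  m <- m[, !black, drop = FALSE]

  unknown <- setdiff(colnames(m), canon)
  if (length(unknown) > 0) {
    warning("retaining column(s) not in lexicon as their own canonicals: ",
            paste(unknown, collapse = ", "))
  }

  # (3) drop all-zero rows
  zero <- rowSums(m) == 0
  n_zero <- sum(zero)
  m <- m[!zero, , drop = FALSE]

  # (4) drop exact duplicates, keeping the first occurrence
  if (!is.null(raw_texts)) {
    stopifnot(is.data.frame(raw_texts),
              all(c("patient_id", "text") %in% names(raw_texts)))
    txt <- raw_texts$text[match(rownames(m), as.character(raw_texts$patient_id))]
    if (anyNA(txt)) {
      stop("raw_texts does not cover matrix row(s): ",
           paste(utils::head(rownames(m)[is.na(txt)], 5), collapse = ", "))
    }
    dup <- duplicated(txt)
  } else {
    dup <- duplicated(data.frame(id = rownames(m), pat = apply(m, 1, paste, collapse = "")))
  }
  n_dup <- sum(dup)
  m <- m[!dup, , drop = FALSE]

  report <- cleaning_report(
    n_input_rows = n_input,
    n_zero_symptom_rows_removed = n_zero,
    n_duplicate_rows_removed = n_dup,
    n_columns_merged = n_merged,
    n_columns_blacklisted = n_black,
    n_output_rows = nrow(m),
    n_output_columns = ncol(m)
  )
  list(matrix = m, report = report)
}

#' Read / write a binary symptom matrix
#'
#' Tab-delimited text with a header row of canonical symptom names, first
#' column \code{patient_id}, cells 0/1. Writing then reading reproduces the
#' matrix bit-exactly (dimnames included).
#'
#' @param path file path.
#' @return \code{read_binary_matrix}: an integer 0/1 matrix with patient id
#'   rownames.
#' @export
read_binary_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (names(tab)[1] != "patient_id") {
    stop("first column of a matrix file must be 'patient_id': ", path)
  }
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix cells must be 0/1: ", path)
  rownames(m) <- ids
  m
}

#' @rdname read_binary_matrix
#' @param m binary matrix with patient id rownames.
#' @export
write_binary_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tab <- data.frame(patient_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
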