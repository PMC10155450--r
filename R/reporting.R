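#' Stratified index-symptom co-occurrence report
#'
#' Buckets narratives by how many distinct symptoms they report (0, 1, 2,
#' 3, "4 or more") and tabulates, per stratum, the number of narratives,
#' the number mentioning the index symptom, and the percentage (two
#' decimals, half away from zero), plus a totals row. This is computed on
#' the matrix \emph{before} zero-symptom rows are removed — the 0 stratum
#' is part of the description — but after variant columns are merged, so
#' symptom counts refer to canonical symptoms.
#'
#' @param m binary matrix including any all-zero rows.
#' @param index_symptom canonical name of the index symptom; must be a
#'   column of \code{m}.
#' @return A data frame with columns \code{stratum, n_narratives,
#'   n_with_index, percentage}; the last row is the totals row
#'   (\code{stratum == "Total"}).
#' @export
stratified_report <- function(m, index_symptom) {
  stopifnot(is.matrix(m))
  if (!(index_symptom %in% colnames(m))) {
    stop("index symptom '", index_symptom, "' is not a column of the matrix")
  }
  counts <- rowSums(m)
  labels <- c("0", "1", "2", "3", "4 or more")
  stratum_of <- ifelse(counts >= 4, "4 or more", as.character(counts))
  idx <- m[, index_symptom] == 1L
  rows <- lapply(labels, function(lab) {
    sel <- stratum_of == lab
    n <- sum(sel)
    ni <- sum(sel & idx)
    data.frame(stratum = lab, n_narratives = n, n_with_index = ni,
               percentage = if (n > 0) round_half_away(100 * ni / n, 2) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(stratum = "Total", n_narratives = nrow(m),
                      n_with_index = sum(idx),
                      percentage = if (nrow(m) > 0)
                        round_half_away(100 * sum(idx) / nrow(m), 2) else 0,
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Symptom frequency table
#'
#' Column sums of the binary matrix — how many narratives report each
#' symptom — sorted by descending count, ties broken alphabetically.
#'
#' @param m binary matrix.
#' @return A data frame with columns \code{symptom, count}.
#' @export
frequency_table <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) == 0) {
    return(data.frame(symptom = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  counts <- colSums(m)
  ord <- order(-counts, names(counts))
  data.frame(symptom = names(counts)[ord], count = as.integer(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Top correlates of the index symptom
#'
#' The screened results restricted to the Cohen small band (|r| between
#' \code{band_low} and \code{band_high}, either sign), order preserved.
#' The full, unfiltered screen remains the companion record: selection here
#' never loses a result, it only subsets for reporting. Editorial exclusion
#' of individual symptoms (e.g. somatic terms a study chooses not to
#' discuss) is supported via \code{exclude}, which annotates rather than
#' silently drops: excluded rows are returned in the \code{"excluded"}
#' attribute.
#'
#' @param results a \code{correlation_screen} data frame.
#' @param config a [screen_config()].
#' @param exclude character vector of symptoms to set aside from the
#'   reported subset.
#' @return The small-band subset of \code{results}; excluded small-band
#'   rows are attached as attribute \code{"excluded"}.
#' @export
top_correlates <- function(results, config = screen_config(), exclude = character(0)) {
  small <- results[results$band == "small", , drop = FALSE]
  kept <- small[!(small$symptom %in% exclude), , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "excluded") <- small[small$symptom %in% exclude, , drop = FALSE]
  kept
}

#' Plot the symptom frequency table
#'
#' Horizontal bar chart of the most frequently reported symptoms, most
#' frequent at the top.
#'
#' @param freq a data frame from [frequency_table()].
#' @param top number of symptoms to show.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot_frequency_table <- function(freq, top = 15, ...) {
  f <- utils::head(freq, top)
  graphics::barplot(rev(f$count), names.arg = rev(f$symptom), horiz = TRUE,
                    las = 1, xlab = "narratives reporting the symptom", ...)
}
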