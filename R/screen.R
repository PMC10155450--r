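#' Phi coefficient of two binary vectors
#'
#' The Pearson product-moment correlation of two 0/1 vectors, which for
#' binary data reduces to the classic 2x2 contingency-table form
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}.}
#' Computed from the table counts, which is exact and fast at any n.
#'
#' @param x,y equal-length 0/1 vectors, each non-constant, n >= 3.
#' @return Phi coefficient in [-1, 1].
#' @examples
#' x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
#' phi_correlation(x, y)
#' @export
phi_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  x <- as.integer(x); y <- as.integer(y)
  stopifnot(all(x %in% c(0L, 1L)), all(y %in% c(0L, 1L)))
  n <- length(x)
  n1x <- sum(x); n1y <- sum(y)
  if (n1x == 0L || n1x == n) stop("undefined correlation: first vector is constant")
  if (n1y == 0L || n1y == n) stop("undefined correlation: second vector is constant")
  n11 <- sum(x & y)
  n10 <- n1x - n11
  n01 <- n1y - n11
  n00 <- n - n11 - n10 - n01
  (n11 * n00 - n10 * n01) /
    sqrt(as.numeric(n1x) * (n - n1x) * n1y * (n - n1y))
}

#' Fisher-z confidence interval for a correlation
#'
#' Transforms r to \code{z = atanh(r)}, treats z as normal with standard
#' error \code{1 / sqrt(n - 3)}, and back-transforms the normal-quantile
#' interval with \code{tanh}.
#'
#' @param r observed correlation, |r| < 1.
#' @param n sample size, >= 4.
#' @param level confidence level (default 0.95).
#' @return Numeric vector \code{c(low = , high = )}, with
#'   \code{low < high} and \code{low <= r <= high}.
#' @examples
#' fisher_ci(0.26, 10228)  # approximately (0.242, 0.278)
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  stopifnot(n >= 4, level > 0, level < 1)
  if (abs(r) >= 1) stop("degenerate input: |r| must be < 1 for a Fisher-z interval")
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  c(low = tanh(z - q * se), high = tanh(z + q * se))
}

#' Two-sided p-value for a correlation test of rho = 0
#'
#' Uses the exact t reference: \code{t = r * sqrt((n - 2) / (1 - r^2))} on
#' \code{n - 2} degrees of freedom.
#'
#' @param r observed correlation, |r| < 1.
#' @param n sample size, >= 4.
#' @return Two-sided p-value.
#' @export
correlation_p_value <- function(r, n) {
  stopifnot(n >= 4)
  if (abs(r) >= 1) stop("degenerate input: |r| must be < 1")
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Post-hoc power of the correlation test
#'
#' Power of the two-sided test of rho = 0 at size \code{alpha}, evaluated
#' at a true effect equal to the observed one, via the Fisher-z normal
#' approximation:
#' \deqn{power = \Phi(|z_r|\sqrt{n-3} - q) + \Phi(-|z_r|\sqrt{n-3} - q)}
#' with \code{z_r = atanh(r)} and q the two-sided normal quantile. At
#' r = 0 this returns exactly \code{alpha} (the size of the test), and it
#' is strictly increasing in both |r| and n.
#'
#' @param r observed correlation, |r| < 1.
#' @param n sample size, >= 4.
#' @param alpha test size (default 0.05).
#' @return Power in [0, 1].
#' @export
post_hoc_power <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 4, alpha > 0, alpha < 1)
  if (abs(r) >= 1) stop("degenerate input: |r| must be < 1")
  if (r == 0) return(alpha)  # power at the null is the size, exactly
  q <- stats::qnorm(1 - alpha / 2)
  delta <- abs(atanh(r)) * sqrt(n - 3)
  stats::pnorm(delta - q) + stats::pnorm(-delta - q)
}

#' Screen configuration
#'
#' Tuning parameters of the correlation screen: the index symptom, the
#' confidence level, the test size used for power, the Cohen band edges,
#' the zero tolerance of the independence scan (0.005 makes "independent"
#' mean "rounds to 0.00 at two decimals"), and the optional
#' multiple-testing adjustment.
#'
#' @param index_symptom canonical name of the index symptom.
#' @param ci_level confidence level in (0, 1).
#' @param alpha test size in (0, 1).
#' @param band_low,band_high Cohen small-band edges, with
#'   \code{0 <= zero_tolerance < band_low < band_high <= 1}.
#' @param zero_tolerance |r| threshold below which a symptom is declared
#'   independent of the index.
#' @param adjust multiple-testing method: \code{"none"} (default) or
#'   \code{"benjamini-hochberg"}.
#' @return A list with class \code{screen_config}.
#' @export
screen_config <- function(index_symptom = "auditory hallucination",
                          ci_level = 0.95, alpha = 0.05,
                          band_low = 0.10, band_high = 0.30,
                          zero_tolerance = 0.005,
                          adjust = c("none", "benjamini-hochberg")) {
  adjust <- match.arg(adjust)
  stopifnot(ci_level > 0, ci_level < 1, alpha > 0, alpha < 1,
            zero_tolerance >= 0, zero_tolerance < band_low,
            band_low < band_high, band_high <= 1)
  structure(list(index_symptom = index_symptom, ci_level = ci_level,
                 alpha = alpha, band_low = band_low, band_high = band_high,
                 zero_tolerance = zero_tolerance, adjust = adjust),
            class = "screen_config")
}

#' Cohen effect-size band of a correlation
#'
#' Classifies |r| by Cohen's conventions: below \code{band_low} is
#' negligible, \code{[band_low, band_high)} small, \code{[band_high, 0.5)}
#' medium, and \code{>= 0.5} large (lower edges inclusive). The sign of r
#' is carried separately by the caller.
#'
#' @param r correlation, |r| <= 1.
#' @param config a [screen_config()].
#' @return One of \code{"negligible"}, \code{"small"}, \code{"medium"},
#'   \code{"large"}.
#' @export
cohen_band <- function(r, config = screen_config()) {
  stopifnot(abs(r) <= 1)
  a <- abs(r)
  if (a < config$band_low) "negligible"
  else if (a < config$band_high) "small"
  else if (a < 0.50) "medium"
  else "large"
}

#' Screen every symptom against the index symptom
#'
#' Computes, for each non-index column of a cleaned binary matrix, the phi
#' correlation with the index column, its Fisher-z confidence interval,
#' t-based p-value, post-hoc power, and Cohen band. Constant (zero-variance)
#' columns are skipped with a warning rather than aborting the screen.
#' Results are sorted by descending |r|, ties broken alphabetically.
#'
#' @param m cleaned binary matrix (see [clean_matrix()]).
#' @param config a [screen_config()]; its \code{index_symptom} must be a
#'   non-constant column of \code{m}.
#' @return A data frame of class \code{correlation_screen} with columns
#'   \code{symptom, r, ci_low, ci_high, p_value, power, n, df, band} (and
#'   \code{p_adjusted} when BH adjustment is configured). The index symptom
#'   name and sample size are attached as attributes.
#' @export
screen_correlations <- function(m, config = screen_config()) {
  stopifnot(is.matrix(m))
  index <- config$index_symptom
  if (!(index %in% colnames(m))) {
    stop("index symptom '", index, "' is not a column of the matrix")
  }
  xi <- m[, index]
  if (length(unique(xi)) < 2) {
    stop("index symptom '", index, "' is constant in this matrix")
  }
  n <- nrow(m)
  others <- setdiff(colnames(m), index)
  constant <- others[vapply(others, function(s) {
    v <- sum(m[, s]); v == 0 || v == n
  }, logical(1))]
  if (length(constant) > 0) {
    warning("skipping constant column(s): ", paste(constant, collapse = ", "))
    others <- setdiff(others, constant)
  }
  rows <- lapply(others, function(s) {
    r <- phi_correlation(xi, m[, s])
    ok <- abs(r) < 1 && n >= 4   # Fisher machinery needs n >= 4 and |r| < 1
    ci <- if (ok) fisher_ci(r, n, config$ci_level)
          else c(low = if (abs(r) < 1) NA_real_ else r,
                 high = if (abs(r) < 1) NA_real_ else r)
    p <- if (ok) correlation_p_value(r, n) else if (abs(r) >= 1) 0 else NA_real_
    pw <- if (ok) post_hoc_power(r, n, config$alpha) else if (abs(r) >= 1) 1 else NA_real_
    data.frame(symptom = s, r = r, ci_low = ci[["low"]], ci_high = ci[["high"]],
               p_value = p, power = pw, n = as.integer(n), df = as.integer(n) - 2L,
               band = cohen_band(r, config), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(symptom = character(0), r = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_value = numeric(0), power = numeric(0),
                      n = integer(0), df = integer(0), band = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(-abs(out$r), out$symptom), , drop = FALSE]
  rownames(out) <- NULL
  if (config$adjust == "benjamini-hochberg") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  }
  structure(out, class = c("correlation_screen", class(out)),
            index_symptom = index, n = n)
}

#' Symptoms independent of the index symptom
#'
#' The independence scan: symptoms whose screened |r| falls below the zero
#' tolerance (default 0.005, i.e. a coefficient that prints as 0.00 at two
#' decimals), sorted alphabetically.
#'
#' @param results a \code{correlation_screen} data frame.
#' @param config a [screen_config()].
#' @return Character vector of canonical symptom names.
#' @export
independent_set <- function(results, config = screen_config()) {
  sort(results$symptom[abs(results$r) < config$zero_tolerance])
}

#' @export
print.correlation_screen <- function(x, max_rows = 20, ...) {
  cat(sprintf("Correlation screen against '%s' (n = %d, df = %d)\n",
              attr(x, "index_symptom"), attr(x, "n"), attr(x, "n") - 2))
  print.data.frame(utils::head(format_screen_display(x), max_rows), ...)
  if (nrow(x) > max_rows) cat(sprintf("  ... %d more rows\n", nrow(x) - max_rows))
  invisible(x)
}

#' Two-decimal display rendering of screen results
#'
#' Renders r and CI bounds to two decimals (round half away from zero),
#' p-values below 1e-4 as \code{"< 0.0001"}, and power to two decimals.
#'
#' @param results a \code{correlation_screen} data frame.
#' @return A character-formatted data frame.
#' @export
format_screen_display <- function(results) {
  data.frame(
    symptom = results$symptom,
    r = sprintf("%.2f", round_half_away(results$r, 2)),
    ci_95 = sprintf("[%.2f, %.2f]", round_half_away(results$ci_low, 2),
                    round_half_away(results$ci_high, 2)),
    p_value = ifelse(results$p_value < 1e-4, "< 0.0001",
                     sprintf("%.4f", results$p_value)),
    power = sprintf("%.2f", round_half_away(results$power, 2)),
    band = results$band,
    stringsAsFactors = FALSE
  )
}

#' Round half away from zero
#'
#' Display rounding where x.xx5 moves away from zero (2.5 -> 3, -2.5 -> -3),
#' unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Write screen results
#'
#' Writes the full-precision results table, its two-decimal display
#' variant, and the independence list (one symptom per line).
#'
#' @param results a \code{correlation_screen} data frame.
#' @param path output path for the full table; the display variant gets
#'   suffix \code{".display.tsv"} and the independence list
#'   \code{".independent.txt"}.
#' @param config a [screen_config()].
#' @export
write_screen_results <- function(results, path, config = screen_config()) {
  utils::write.table(as.data.frame(results), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(format_screen_display(results),
                     paste0(path, ".display.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(independent_set(results, config), paste0(path, ".independent.txt"))
  invisible(path)
}
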