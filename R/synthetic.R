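#' Feasible phi range for two binary variables
#'
#' Two 0/1 variables with fixed marginal prevalences cannot attain every
#' correlation: the joint cell P11 is bounded by the Frechet limits
#' \code{max(0, p1 + p2 - 1) <= P11 <= min(p1, p2)}, which bound the phi
#' coefficient in turn. The generator refuses targets outside this range.
#'
#' @param p1,p2 marginal prevalences, strictly between 0 and 1.
#' @return Numeric vector \code{c(min = , max = )} of attainable phi values.
#' @examples
#' feasible_phi_bounds(0.5, 0.5)   # c(-1, 1)
#' feasible_phi_bounds(0.9, 0.1)   # max phi = 1/9
#' @export
feasible_phi_bounds <- function(p1, p2) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11_max <- min(p1, p2)
  p11_min <- max(0, p1 + p2 - 1)
  c(min = (p11_min - p1 * p2) / denom,
    max = (p11_max - p1 * p2) / denom)
}

# phi coefficient implied by a joint success probability and its margins
phi_from_joint <- function(p11, p1, p2) {
  (p11 - p1 * p2) / sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# Upper orthant probability P(Z1 > q1, Z2 > q2) of a standard bivariate
# normal with correlation rho, by one-dimensional adaptive quadrature of
# the conditional tail probability.
bvn_upper_prob <- function(q1, q2, rho) {
  if (abs(rho) < 1e-14) {
    return(stats::pnorm(q1, lower.tail = FALSE) *
           stats::pnorm(q2, lower.tail = FALSE))
  }
  s <- sqrt(1 - rho^2)
  f <- function(x) stats::dnorm(x) * stats::pnorm((rho * x - q2) / s)
  stats::integrate(f, lower = q1, upper = Inf,
                   rel.tol = 1e-11, abs.tol = 1e-13)$value
}

#' Phi implied by a latent bivariate normal
#'
#' Forward map of the latent-threshold construction: dichotomise a standard
#' bivariate normal with correlation \code{rho} at the upper-tail
#' prevalence quantiles and return the phi coefficient of the resulting
#' 2x2 table.
#'
#' @param p1,p2 marginal prevalences in (0,1).
#' @param rho latent correlation in [-1, 1].
#' @return The implied phi coefficient.
#' @export
phi_from_latent <- function(p1, p2, rho) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, rho >= -1, rho <= 1)
  q1 <- stats::qnorm(1 - p1)
  q2 <- stats::qnorm(1 - p2)
  phi_from_joint(bvn_upper_prob(q1, q2, rho), p1, p2)
}

#' Invert a phi target to a latent normal correlation
#'
#' Finds the correlation \code{rho} of the underlying bivariate normal such
#' that thresholding at the prevalence quantiles yields a 2x2 table with the
#' requested phi coefficient (the classic correlated-binary construction of
#' Emrich and Piedmonte). The forward map is continuous and strictly
#' increasing in \code{rho} for fixed margins, so a monotone root search
#' suffices; the returned \code{rho} reproduces the target phi to within
#' 1e-6.
#'
#' @param p1,p2 marginal prevalences in (0,1).
#' @param phi target phi, strictly inside [feasible_phi_bounds()].
#' @return The latent correlation (a number in (-1, 1)); exactly 0 for
#'   \code{phi = 0}.
#' @examples
#' phi_to_latent_correlation(0.5, 0.5, 0.5)  # sin(pi * 0.5 / 2) = 0.7071
#' @export
phi_to_latent_correlation <- function(p1, p2, phi) {
  bounds <- feasible_phi_bounds(p1, p2)
  if (phi <= bounds["min"] || phi >= bounds["max"]) {
    stop(sprintf(
      "phi target %.4f infeasible for prevalences (%.4g, %.4g): attainable range is (%.4f, %.4f), boundary excluded",
      phi, p1, p2, bounds["min"], bounds["max"]))
  }
  if (phi == 0) return(0)
  lim <- 1 - 1e-7
  f <- function(rho) phi_from_latent(p1, p2, rho) - phi
  interval <- if (phi > 0) c(0, lim) else c(-lim, 0)
  if (f(interval[1]) * f(interval[2]) > 0) {
    stop(sprintf("phi target %.4f is too close to the feasibility boundary to invert", phi))
  }
  stats::uniroot(f, interval = interval, tol = 1e-10)$root
}

#' Configuration for the synthetic corpus generator
#'
#' Collects everything the generator needs: corpus size, per-symptom
#' marginal prevalences, pairwise phi targets (pairs not listed are
#' generated independent), the filler vocabulary interleaved between
#' symptom mentions, the repeat-mention rate, and the seed. Each phi target
#' is validated against the Frechet feasibility bounds of its pair's
#' prevalences.
#'
#' @param n_patients number of records to generate (>= 0).
#' @param prevalences named numeric vector of marginal prevalences in
#'   (0, 1); names are canonical symptom names.
#' @param phi_targets data frame with columns \code{symptom_a},
#'   \code{symptom_b}, \code{phi}, one row per unordered pair; or
#'   \code{NULL} for a fully independent corpus.
#' @param filler_vocabulary character vector of non-symptom words used to
#'   pad narratives; must not collide with any lexicon surface-form token
#'   (checked at render time).
#' @param repeat_mention_rate non-negative mean number of extra mentions
#'   per present symptom; each present symptom is mentioned
#'   \code{1 + Poisson(repeat_mention_rate)} times.
#' @param filler_rate mean number of filler words per narrative (on top of
#'   a minimum of 3).
#' @param n_duplicate_records number of exact-duplicate narratives to
#'   inject when rendering a corpus (fresh patient ids, identical text).
#' @param seed integer seed; one seed determines the whole corpus.
#' @return A list with class \code{generator_config}.
#' @export
generator_config <- function(n_patients, prevalences, phi_targets = NULL,
                             filler_vocabulary = default_filler_vocabulary(),
                             repeat_mention_rate = 0.5, filler_rate = 8,
                             n_duplicate_records = 0, seed = 1) {
  stopifnot(n_patients >= 0, is.numeric(prevalences),
            !is.null(names(prevalences)),
            all(prevalences > 0), all(prevalences < 1),
            repeat_mention_rate >= 0, filler_rate >= 0,
            n_duplicate_records >= 0)
  if (anyDuplicated(names(prevalences))) stop("duplicated symptom names in prevalences")
  if (!is.null(phi_targets)) {
    stopifnot(is.data.frame(phi_targets),
              all(c("symptom_a", "symptom_b", "phi") %in% names(phi_targets)))
    phi_targets <- normalize_pairs(phi_targets)
    missing <- setdiff(unique(c(phi_targets$symptom_a, phi_targets$symptom_b)),
                       names(prevalences))
    if (length(missing) > 0) {
      stop("phi target symptom(s) missing from prevalences: ",
           paste(missing, collapse = ", "))
    }
    for (i in seq_len(nrow(phi_targets))) {
      b <- feasible_phi_bounds(prevalences[[phi_targets$symptom_a[i]]],
                               prevalences[[phi_targets$symptom_b[i]]])
      ph <- phi_targets$phi[i]
      if (ph != 0 && (ph <= b["min"] || ph >= b["max"])) {
        stop(sprintf("phi target %.4f for pair (%s, %s) outside feasible range (%.4f, %.4f)",
                     ph, phi_targets$symptom_a[i], phi_targets$symptom_b[i],
                     b["min"], b["max"]))
      }
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    prevalences = prevalences,
    phi_targets = phi_targets,
    filler_vocabulary = filler_vocabulary,
    repeat_mention_rate = repeat_mention_rate,
    filler_rate = filler_rate,
    n_duplicate_records = as.integer(n_duplicate_records),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# sort each pair alphabetically and drop duplicates
normalize_pairs <- function(targets) {
  a <- pmin(targets$symptom_a, targets$symptom_b)
  b <- pmax(targets$symptom_a, targets$symptom_b)
  if (any(a == b)) stop("phi target pairs a symptom with itself: ", a[a == b][1])
  out <- data.frame(symptom_a = a, symptom_b = b, phi = targets$phi,
                    stringsAsFactors = FALSE)
  key <- paste(out$symptom_a, out$symptom_b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated phi target pair(s): ",
         paste(unique(paste0("(", out$symptom_a, ", ", out$symptom_b, ")")[duplicated(key)]),
               collapse = ", "))
  }
  out
}

#' Default filler vocabulary
#'
#' Everyday non-symptom words used to pad synthetic narratives. Chosen to be
#' disjoint from every token of the demonstration lexicon's surface forms,
#' so filler can never create a false symptom match.
#' @return Character vector of words.
#' @export
default_filler_vocabulary <- function() {
  c("today", "yesterday", "morning", "evening", "went", "home", "again",
    "really", "quite", "started", "walking", "coffee", "garden", "music",
    "reading", "slowly", "maybe", "often", "always", "sometimes", "later",
    "myself", "because", "about", "still", "then", "wrote", "journal",
    "outside", "weather", "dinner", "talked", "phone", "watched",
    "television", "tried", "better", "days", "weeks", "little")
}

# assemble the latent correlation matrix implied by the config's phi targets
latent_correlation_matrix <- function(config) {
  syms <- names(config$prevalences)
  k <- length(syms)
  R <- diag(k)
  dimnames(R) <- list(syms, syms)
  tg <- config$phi_targets
  if (!is.null(tg)) {
    for (i in seq_len(nrow(tg))) {
      rho <- phi_to_latent_correlation(config$prevalences[[tg$symptom_a[i]]],
                                       config$prevalences[[tg$symptom_b[i]]],
                                       tg$phi[i])
      R[tg$symptom_a[i], tg$symptom_b[i]] <- rho
      R[tg$symptom_b[i], tg$symptom_a[i]] <- rho
    }
  }
  R
}

#' Sample a binary symptom matrix with known structure
#'
#' Draws \code{n_patients} rows from a latent multivariate normal whose
#' pairwise correlations are solved from the configured phi targets
#' ([phi_to_latent_correlation()]), then thresholds each column at its
#' prevalence quantile. Empirical prevalences and pairwise phi coefficients
#' converge to their targets as n grows; the draw is deterministic given the
#' config seed.
#'
#' If the assembled latent correlation matrix is not positive semidefinite
#' the target set is jointly infeasible and the call fails, naming the
#' targeted pairs; \code{nearest_psd = TRUE} instead clips negative
#' eigenvalues to zero (with a warning), trading exact pairwise targets for
#' a valid joint distribution.
#'
#' @param config a [generator_config()].
#' @param nearest_psd repair a non-PSD latent matrix by eigenvalue clipping
#'   instead of failing.
#' @return Integer 0/1 matrix, \code{n_patients} rows, one column per
#'   configured symptom, rownames \code{"P<seq>"}.
#' @export
sample_binary_matrix <- function(config, nearest_psd = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  syms <- names(config$prevalences)
  k <- length(syms)
  n <- config$n_patients
  R <- latent_correlation_matrix(config)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-6) {
    if (!nearest_psd) {
      pairs <- if (is.null(config$phi_targets)) "(none)" else
        paste0("(", config$phi_targets$symptom_a, ", ",
               config$phi_targets$symptom_b, ")", collapse = ", ")
      stop("phi target set is jointly infeasible: latent correlation matrix ",
           "is not positive semidefinite (min eigenvalue ",
           format(min(ev$values), digits = 4), "); targeted pairs: ", pairs,
           ". Re-run with nearest_psd = TRUE to clip eigenvalues.")
    }
    warning("latent correlation matrix repaired to nearest PSD by eigenvalue clipping; ",
            "pairwise phi targets are no longer exact")
  }
  vals <- pmax(ev$values, 0)
  sqrtR <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
  set.seed(config$seed)
  Z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k) %*% sqrtR
  q <- stats::qnorm(1 - config$prevalences)
  m <- matrix(0L, n, k, dimnames = list(make_patient_ids(n), syms))
  for (j in seq_len(k)) m[, j] <- as.integer(Z[, j] > q[j])
  m
}

make_patient_ids <- function(n) {
  if (n == 0) return(character(0))
  sprintf("P%06d", seq_len(n))
}

#' Render a binary matrix as free-text narratives
#'
#' Produces one narrative per matrix row: every present symptom appears as
#' \code{1 + Poisson(repeat_mention_rate)} mentions, each mention a
#' uniformly chosen surface form from the lexicon, shuffled together with
#' filler words. Absent symptoms never appear, so extraction followed by
#' encoding reproduces the input matrix exactly (the generator's round-trip
#' guarantee). All-zero rows render as filler-only narratives. Rendering is
#' deterministic given the config seed (an offset stream, so the same seed
#' also fixes the matrix draw independently).
#'
#' @param m binary matrix (e.g. from [sample_binary_matrix()]); column
#'   names must be canonicals of \code{lexicon}.
#' @param lexicon a \code{symptom_lexicon}.
#' @param config a [generator_config()].
#' @return A data frame with columns \code{patient_id} and \code{text}.
#' @export
render_narratives <- function(m, lexicon, config) {
  stopifnot(is.matrix(m), inherits(config, "generator_config"))
  validate_lexicon(lexicon)
  missing <- setdiff(colnames(m), lexicon_canonicals(lexicon))
  if (length(missing) > 0) {
    stop("matrix column(s) not in lexicon: ", paste(missing, collapse = ", "))
  }
  form_tokens <- unique(unlist(strsplit(unlist(lexicon$entries, use.names = FALSE),
                                        " ", fixed = TRUE)))
  clash <- intersect(config$filler_vocabulary, form_tokens)
  if (length(clash) > 0) {
    stop("filler word(s) collide with lexicon surface-form tokens: ",
         paste(clash, collapse = ", "))
  }
  variants <- lexicon$entries[colnames(m)]
  set.seed(offset_seed(config$seed, 1L))
  texts <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    present <- which(m[i, ] == 1L)
    units <- character(0)
    for (j in present) {
      n_mention <- 1L + stats::rpois(1, config$repeat_mention_rate)
      v <- variants[[j]]
      units <- c(units, v[sample.int(length(v), n_mention, replace = TRUE)])
    }
    n_filler <- 3L + stats::rpois(1, config$filler_rate)
    units <- c(units, sample(config$filler_vocabulary, n_filler, replace = TRUE))
    texts[i] <- paste(units[sample.int(length(units))], collapse = " ")
  }
  data.frame(patient_id = rownames(m), text = texts, stringsAsFactors = FALSE)
}

# derive an auxiliary stream seed, kept inside 32-bit integer range
offset_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 77777 * as.numeric(k)) %% 2147483647)
}

#' Study-scale default generator profile
#'
#' A [generator_config()] whose ground truth mirrors the statistical
#' structure of a large web-scraped narrative corpus: about 10,900 records;
#' a low-prevalence index symptom (auditory hallucination at 5.7%); a block
#' of symptoms correlated with the index at small phi values (0.10-0.26);
#' several symptoms exactly independent of the index (dissociation,
#' obsession, compulsion, hypertension, nausea, weight loss); two common
#' mood symptoms (depression, anxiety) driving a realistic zero-symptom
#' rate of roughly 6.4% of records; and one injected exact-duplicate
#' narrative.
#'
#' The index-correlate block is completed to a single-factor latent
#' structure: the latent correlation of each correlate with the index is
#' solved from its phi target, expressed as a loading on one shared factor,
#' and the implied correlate-correlate phi values are added as explicit
#' targets. This guarantees a positive semidefinite joint model while
#' keeping every pairwise target interpretable.
#'
#' @param n_patients corpus size before duplicate injection padding
#'   (default 10,933 records, of which one is the injected duplicate).
#' @param seed integer seed.
#' @param index_phi named numeric vector of phi targets between the index
#'   symptom and its correlates.
#' @return A \code{generator_config}.
#' @export
default_profile <- function(n_patients = 10933, seed = 1,
                            index_phi = c(
                              "visual hallucination" = 0.26,
                              "schizophrenia" = 0.17,
                              "head" = 0.16,
                              "fear" = 0.15,
                              "delusion" = 0.14,
                              "psychosis" = 0.14,
                              "paranoia" = 0.13,
                              "suicide" = 0.11,
                              "pain" = 0.11,
                              "trauma" = 0.10)) {
  prev <- default_prevalences()
  index <- "auditory hallucination"
  stopifnot(all(names(index_phi) %in% names(prev)))

  # latent correlations of each correlate with the index
  rho <- vapply(names(index_phi), function(s) {
    phi_to_latent_correlation(prev[[index]], prev[[s]], index_phi[[s]])
  }, numeric(1))
  lambda_hub <- min(0.98, max(0.8, 1.02 * max(rho)))
  lambda <- rho / lambda_hub

  targets <- data.frame(symptom_a = index, symptom_b = names(index_phi),
                        phi = unname(index_phi), stringsAsFactors = FALSE)
  # one-factor completion among the correlates
  cs <- names(index_phi)
  for (i in seq_along(cs)[-1]) {
    for (j in seq_len(i - 1)) {
      implied <- phi_from_latent(prev[[cs[i]]], prev[[cs[j]]],
                                 lambda[[i]] * lambda[[j]])
      targets <- rbind(targets, data.frame(
        symptom_a = cs[i], symptom_b = cs[j], phi = implied,
        stringsAsFactors = FALSE))
    }
  }
  # explicit independence of the planted-zero symptoms from the index
  zeros <- c("dissociation", "obsession", "compulsion", "hypertension",
             "nausea", "weight loss")
  targets <- rbind(targets, data.frame(symptom_a = index, symptom_b = zeros,
                                       phi = 0, stringsAsFactors = FALSE))
  # plausible background structure away from the index block
  targets <- rbind(targets, data.frame(
    symptom_a = c("depression", "sadness", "obsession"),
    symptom_b = c("anxiety", "low mood", "compulsion"),
    phi = c(0.25, 0.20, 0.30), stringsAsFactors = FALSE))

  generator_config(n_patients = n_patients, prevalences = prev,
                   phi_targets = targets, repeat_mention_rate = 0.6,
                   n_duplicate_records = 1, seed = seed)
}

# Marginal prevalences of the default profile. Calibrated so that the
# expected share of zero-symptom narratives under the profile's dependence
# structure is ~6.4% (see the methods vignette).
default_prevalences <- function() {
  c("auditory hallucination" = 0.057,
    "visual hallucination" = 0.035,
    "schizophrenia" = 0.050,
    "fear" = 0.160,
    "delusion" = 0.040,
    "psychosis" = 0.045,
    "paranoia" = 0.060,
    "suicide" = 0.090,
    "pain" = 0.080,
    "trauma" = 0.100,
    "head" = 0.050,
    "depression" = 0.460,
    "anxiety" = 0.410,
    "loneliness" = 0.160,
    "low mood" = 0.110,
    "lethargy" = 0.080,
    "lack of sleep" = 0.150,
    "panic attacks" = 0.080,
    "sadness" = 0.190,
    "anger" = 0.110,
    "guilt" = 0.100,
    "apprehension" = 0.040,
    "dissociation" = 0.030,
    "obsession" = 0.035,
    "compulsion" = 0.025,
    "hypertension" = 0.010,
    "nausea" = 0.020,
    "weight loss" = 0.015)
}
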