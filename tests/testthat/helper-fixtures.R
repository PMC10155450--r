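# Shared fixtures, built in code.

# Three archetypal narratives with their expected filtered symptom sets.
table1_corpus <- function() {
  data.frame(
    patient_id = c("1", "2", "3"),
    text = c(
      "I feel low mood. I don’t like doing anything, just feel lethargic.",
      paste("I am always having apprehensions. Often I can’t sleep at night",
            "and the lack of sleep is making it difficult for me to carry out",
            "my jobs. These days, I often feel panic attacks."),
      paste("I used to hear voices, and that used to make me feel anxious all",
            "the time. Often I wouldn’t be able to sleep at night. But then",
            "I started my medications, and it’s much better now.")),
    stringsAsFactors = FALSE)
}

table1_expected_sets <- function() {
  list("1" = c("low mood", "lethargy"),
       "2" = c("apprehension", "lack of sleep", "panic attacks"),
       "3" = c("auditory hallucination", "anxiety", "lack of sleep"))
}

# Small generator config with planted targets and planted-zero pairs.
small_config <- function(n = 10000, seed = 1) {
  generator_config(
    n_patients = n,
    prevalences = c(index = 0.057, voices = 0.06, dread = 0.10,
                    gloom = 0.30, numbness = 0.05, aches = 0.08),
    phi_targets = data.frame(
      symptom_a = c("index", "index", "dread"),
      symptom_b = c("voices", "dread", "gloom"),
      phi = c(0.26, 0.15, 0.20),
      stringsAsFactors = FALSE),
    seed = seed)
}

# A lexicon whose canonicals match small_config's symptoms (single-token
# variants plus one multiword variant each for round-trip coverage).
small_lexicon <- function() {
  symptom_lexicon(
    entries = list(
      index = c("index", "spiral feeling"),
      voices = c("voices", "strange voices"),
      dread = c("dread", "creeping dread"),
      gloom = c("gloom", "heavy gloom"),
      numbness = c("numbness"),
      aches = c("aches", "dull aches")),
    blacklist = c("breakfast", "stairs"))
}

small_filler <- function() {
  c("today", "morning", "went", "home", "again", "really", "quite",
    "started", "walking", "coffee", "garden", "music", "reading")
}

# Build a binary matrix with exact per-stratum composition: `strata` is a
# list of c(n, n_with_index, row_sum) triples.
matrix_with_strata <- function(strata, n_cols = 6, index_col = "index") {
  cols <- c(index_col, paste0("s", seq_len(n_cols - 1)))
  rows <- list()
  for (st in strata) {
    n <- st[1]; ni <- st[2]; k <- st[3]
    if (n == 0) next
    block <- matrix(0L, n, n_cols, dimnames = list(NULL, cols))
    if (ni > 0) {
      block[seq_len(ni), index_col] <- 1L
      if (k > 1) block[seq_len(ni), 1 + seq_len(k - 1)] <- 1L
    }
    if (ni < n && k > 0) block[(ni + 1):n, 1 + seq_len(k)] <- 1L
    rows[[length(rows) + 1]] <- block
  }
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("R%06d", seq_len(nrow(m)))
  m
}
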