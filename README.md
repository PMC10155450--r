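# symptomics

Symptom-level screening of free-text patient narratives.

Mental-health research increasingly treats the individual **symptom**, not
the diagnostic category, as the unit of analysis. One productive data
source is large collections of unrestricted first-person narratives, where
patients report whatever experiences matter to them rather than answering
a fixed questionnaire. `symptomics` implements the full narrative-to-
correlation pipeline for that setting, for researchers who want to screen
which symptoms co-occur with an index symptom of interest (the package
default: auditory hallucination):

1. **Lexicon** (`read_lexicon`, `symptom_lexicon`) — a user-supplied
   vocabulary mapping lay surface forms ("hearing voices", "can't sleep")
   to canonical symptom names, plus a blacklist of non-symptom words.
2. **Extraction** (`extract_symptoms`, `extract_corpus`) — longest-match
   scanning of normalized narrative text for lexicon surface forms.
3. **Encoding** (`build_matrix`, `clean_matrix`) — one-hot patient x
   symptom binary matrix (a symptom mentioned ten times still codes 1),
   then cleaning: merge variant columns by logical OR, drop blacklisted
   columns, drop zero-symptom narratives, drop duplicate narratives.
4. **Correlation screen** (`screen_correlations`) — for every symptom
   against the index symptom, the phi coefficient

   φ = (n₁₁ n₀₀ − n₁₀ n₀₁) / √(n₁. n₀. n.₁ n.₀),

   a Fisher-z confidence interval tanh(atanh r ∓ z<sub>α/2</sub>/√(n−3)),
   a two-sided p-value from t = r√((n−2)/(1−r²)) on n−2 df, post-hoc power
   Φ(|atanh r|√(n−3) − z<sub>α/2</sub>) + Φ(−|atanh r|√(n−3) − z<sub>α/2</sub>),
   Cohen's effect-size band (|r| ∈ [0.10, 0.30) "small", [0.30, 0.50)
   "medium", ≥ 0.50 "large"), and an independence scan (|r| < 0.005, i.e.
   coefficients that print as 0.00).
5. **Reporting** (`stratified_report`, `frequency_table`,
   `top_correlates`) — index-symptom prevalence stratified by
   symptoms-per-narrative, symptom frequencies, and the small-band
   correlate table.
6. **Synthetic corpora** (`generator_config`, `sample_binary_matrix`,
   `render_narratives`, `simulate_corpus`) — a latent-threshold (Gaussian
   copula) generator producing narrative corpora with *known* marginal
   prevalences and pairwise phi targets (inverted to latent correlations
   by `phi_to_latent_correlation`), so every downstream stage can be
   validated against ground truth without access to clinical data.

## Worked example

Generate a study-scale synthetic corpus (10,933 records, index-symptom
prevalence ~5.7%, ten planted small correlates, one injected duplicate)
and run the full analysis:

```r
library(symptomics)
lex <- demo_lexicon()
cfg <- default_profile(n_patients = 10933, seed = 1)
sim <- simulate_corpus(cfg, lex)
ana <- analyze_corpus(sim$corpus, lex, screen_config())
#> extract_corpus: 10933 records processed, 672 with zero symptoms
#> Cleaning report:
#>   n_input_rows                 10933
#>   n_zero_symptom_rows_removed  672
#>   n_duplicate_rows_removed     1
#>   n_output_rows                10260
#>   n_output_columns             28

head(format_screen_display(ana$screen), 8)
#>                symptom    r        ci_95  p_value power  band
#> 1 visual hallucination 0.22 [0.21, 0.24] < 0.0001  1.00 small
#> 2                 fear 0.16 [0.15, 0.18] < 0.0001  1.00 small
#> 3                 head 0.16 [0.14, 0.18] < 0.0001  1.00 small
#> 4        schizophrenia 0.15 [0.13, 0.17] < 0.0001  1.00 small
#> 5             delusion 0.15 [0.13, 0.16] < 0.0001  1.00 small
#> 6            psychosis 0.14 [0.12, 0.16] < 0.0001  1.00 small
#> 7             paranoia 0.13 [0.11, 0.15] < 0.0001  1.00 small
#> 8                 pain 0.12 [0.10, 0.14] < 0.0001  1.00 small
```

Reading the output: 672 narratives mentioned no lexicon symptom and one
was an exact duplicate, so 10,933 − 672 − 1 = 10,260 narratives enter the
analysis. Every screened symptom above sits in Cohen's "small" band — the
planted ground truth put visual hallucination at φ = 0.26 and trauma at
0.10 against the index symptom, and the screen recovers the planted
ordering within sampling error (for rare symptom pairs at this n the
standard error of φ̂ is ≈ 0.01–0.03). The planted-independent symptoms
(hypertension among them) surface in `ana$independent`.

`ana$stratified` describes co-occurrence before row cleaning: per stratum
of symptoms-per-narrative, how many narratives mention the index symptom —
for this seed, 619 of 10,933 overall (5.66%), concentrated in the ≥4
stratum.

A thin command-line wrapper with the same functionality ships at
`inst/cli/symptomics.R` (subcommands `simulate` and `analyze`).

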