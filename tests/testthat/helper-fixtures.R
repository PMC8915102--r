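# Lazily built, session-cached fixtures shared across test files. Everything
# is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# The study-sized separable phantom cohort: 80 cases, 43 benign / 37
# malignant, default class-conditional parameters.
cohort80 <- function() {
  fixture("cohort80", function() {
    generate_cohort(phantom_config(n_cases = 80, seed = 424242))
  })
}

features80 <- function() {
  fixture("features80", function() extract_feature_table(cohort80()))
}

# A small cohort for cheap unit tests.
cohort_small <- function() {
  fixture("cohort_small", function() {
    generate_cohort(phantom_config(n_cases = 6, seed = 99))
  })
}

# Noise-free single-ADC phantom configuration.
noiseless_config <- function(n_cases = 1, adc = 1.0e-3, seed = 1) {
  phantom_config(n_cases = n_cases, class_balance = 0,
                 adc_benign_mean = adc, adc_malignant_mean = adc / 2,
                 adc_sd = 0, noise_sd = 0, seed = seed)
}

# Feature table of pure noise: p standard-normal features, balanced labels.
noise_table <- function(n, p, seed) {
  set.seed(seed)
  mat <- matrix(rnorm(n * p), n, p,
                dimnames = list(sprintf("case_%03d", seq_len(n)),
                                sprintf("x%03d", seq_len(p))))
  structure(list(case_ids = rownames(mat), feature_names = colnames(mat),
                 matrix = mat,
                 labels = rep(c("benign", "malignant"), length.out = n),
                 provenance = rep("texture", p)),
            class = "feature_table")
}
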