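# heavyweight fixtures built once per test run and shared across files
.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

control_recording <- function(seed = 1) {
  cached(paste0("rec_", seed), simulate_oocyte(seed = seed))
}

control_analysis <- function(seed = 1) {
  cached(paste0("an_", seed), analyze_oocyte(control_recording(seed)))
}

# the full wild-type training cohort (10 oocytes x 20 chromosomes)
control_cohort <- function() {
  cached("cohort", simulate_cohort(10, condition = "control", seeds = 1:10))
}

cohort_analyses <- function() {
  cached("analyses", lapply(control_cohort(), analyze_oocyte))
}

cohort_seqs <- function() {
  cached("seqs", cohort_sequences(cohort_analyses()))
}

cohort_split <- function() {
  cached("split", split_train_test(cohort_seqs()$sequences, 0.9, seed = 7))
}

# full-size classifier used by the acceptance checks
trained_full_model <- function() {
  cached("model_full",
         train_classifier(cohort_split()$train, gru_spec(seed = 1)))
}

# reduced classifier for unit tests that only need a working model
small_gru_spec <- function(seed = 3) {
  gru_spec(hidden_size = 12, head_size = 12, epochs = 80, patience = 80,
           seed = seed)
}

# random-walk aligned trajectory for property tests
random_walk_aligned <- function(n = 30, seed = 1, oocyte = "rw") {
  withr::with_seed(seed, {
    tibble::tibble(
      oocyte_id = oocyte, chromosome_id = 1L,
      frame = 0:(n - 1), t_min = 10 * (0:(n - 1)),
      x_um = cumsum(rnorm(n)), y_um = cumsum(rnorm(n)),
      z_um = cumsum(rnorm(n)))
  })
}
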