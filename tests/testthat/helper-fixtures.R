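# Shared fixtures, built once per test run and cached. The encoder training
# and cohort extraction are the expensive pieces; every test that needs them
# reuses the same objects.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 500-patch degradation dataset (25 synthetic patients x 20 patches).
get_pretext_data <- function() {
  fixture("pretext_data", function()
    build_pretext_dataset(n_patients = 25L, patches_per_patient = 20L, seed = 7L))
}

# Encoder trained on the 500-patch corpus, at most 30 epochs.
get_trained_encoder <- function() {
  fixture("encoder", function()
    train_pretext(build_encoder(seed = 7L), get_pretext_data(),
                  epochs = 30L, seed = 7L))
}

# Small-canvas phantom geometry used throughout the suite (0.5 mm grid, so
# resampling is the identity and extraction stays fast).
test_phantom_spec <- function(...) {
  phantom_spec(image_size = c(96L, 96L), pixel_spacing = 0.5, ...)
}

# Default 18/34 cohort with the planted texture effects.
get_default_cohort <- function() {
  fixture("cohort", function()
    build_cohort(n = 52L, n_benefit = 18L, base_spec = test_phantom_spec(),
                 seed = 11L))
}

# Its full 194-feature tables for both regions.
get_cohort_features <- function() {
  fixture("features", function()
    extract_features_cohort(get_default_cohort(), get_trained_encoder()))
}

# One preprocessed case of that cohort.
get_test_study <- function() {
  fixture("study", function() preprocess_case(get_default_cohort()$cases[[1]]))
}

make_labels <- function(n_pos = 18, n_neg = 34) {
  factor(rep(c("non-benefit", "benefit"), c(n_neg, n_pos)),
         levels = c("non-benefit", "benefit"))
}
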