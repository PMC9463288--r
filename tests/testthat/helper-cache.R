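# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; the heavier cohorts are cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small fast cohort for unit tests (4 participants, one exercise,
# short attempts)
small_config <- function(seed = 7) {
  cohort_config(n_participants = 4, n_excluded = 0, exercises = 1,
                group_split = c("2D" = 2, "3D" = 2),
                attempt_duration_s = list(meanlog = log(18), sdlog = 0.25,
                                          cap = 90),
                seed = seed)
}

small_cohort <- function() {
  cache_get("small_cohort", function() simulate_cohort(small_config()))
}

small_tables <- function() {
  cache_get("small_tables", function() build_feature_tables(small_cohort()))
}

# the study-condition cohort: 15 participants, 3 exercises, strong effects
# (effect_amplitude 1.5, effect_trend 0.05), 3 exclusions
default_cohort <- function() {
  cache_get("default_cohort", function()
    exclude_participants(simulate_cohort(cohort_config(seed = 42))))
}

default_tables <- function() {
  cache_get("default_tables", function() build_feature_tables(default_cohort()))
}

default_map_ex1 <- function() {
  cache_get("default_map_ex1", function()
    build_distance_maps(default_tables()[[1]], "euclidean"))
}

# single-exercise cohorts (15 participants, 3 exclusions) for replicate
# and null checks; statistically identical to one exercise of the full
# cohort
one_exercise_tables <- function(seed, effect_amplitude = 1.5,
                                effect_trend = 0.05) {
  co <- exclude_participants(simulate_cohort(
    cohort_config(exercises = 1L, effect_amplitude = effect_amplitude,
                  effect_trend = effect_trend, seed = seed)))
  build_feature_tables(co)[[1]]
}

null_table <- function() {
  cache_get("null_table", function()
    one_exercise_tables(5, effect_amplitude = 1, effect_trend = 0))
}
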