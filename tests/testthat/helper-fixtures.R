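# Small in-code fixtures shared across test files.

# A ranking object directly from a P vector (already ascending).
make_ranking <- function(p, ids = sprintf("G%03d", seq_along(p))) {
  mlrldacp:::new_ranking(ids, p)
}

# A small strong-signal cohort for end-to-end tests: every causal
# transcript is ultra-significant in the screen and carries a large
# survival coefficient relative to the noise.
strong_cohort <- function(seed = 7, ...) {
  args <- utils::modifyList(
    list(n_normal = 40, n_tumor = 120, n_transcripts = 150,
         n_differential = 30, n_causal = 5, effect_size = 5,
         noise_sd = 10, seed = seed),
    list(...))
  generate_cohort(do.call(cohort_spec, args))
}

# Run screen -> Led/La construction on a cohort.
prepare_training <- function(cohort, alpha = 0.001) {
  ranking <- differential_screen(cohort$normal, cohort$tumor, alpha = alpha)
  led <- build_led(cohort$tumor, ranking)
  la <- build_survival_vector(cohort$clinical, rownames(led))
  list(ranking = ranking, led = led, la = la)
}

# Exhaustive best-subset AIC over all subsets of `candidates`.
exhaustive_best_aic <- function(candidates, led, la) {
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(candidates)))
  aics <- apply(subsets, 1, function(inc) {
    set <- candidates[as.logical(inc)]
    suppressWarnings(model_aic(led[, set, drop = FALSE], la))
  })
  min(aics)
}
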