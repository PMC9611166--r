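# The end-to-end synthetic study used by the learnability, interpretation
# and screening tests: a 100-molecule library, 1300 + 1300 planted-rule
# pairs at 5 % label noise, split 2000 / 200 / 400, and three trained
# models (full, covalent-only, noncovalent-only). Built once per test run.

study_conditions <- function() {
  list(spec = synthetic_spec(n_molecules = 100L, n_pos = 1300L,
                             n_neg = 1300L, label_noise = 0.05, seed = 11L),
       split_seed = 5L, train_seed = 42L,
       ratios = c(2000, 200, 400) / 2600)
}

acceptance_study <- function() {
  if (!is.null(.test_cache$study)) return(.test_cache$study)
  cond <- study_conditions()
  ds <- generate_dataset(cond$spec)
  sets <- split_dataset(ds, cond$ratios, seed = cond$split_seed)
  fits <- list(
    full = cocrystal_gcn(sets$train, sets$val, control = gcn_control(),
                         seed = cond$train_seed),
    covalent_only = cocrystal_gcn(sets$train, sets$val,
                                  control = gcn_control(use_noncovalent = FALSE),
                                  seed = cond$train_seed),
    noncovalent_only = cocrystal_gcn(sets$train, sets$val,
                                     control = gcn_control(use_covalent = FALSE),
                                     seed = cond$train_seed))
  .test_cache$study <- list(ds = ds, sets = sets, fits = fits,
                            metrics = lapply(fits, evaluate_model,
                                             ds = sets$test))
  .test_cache$study
}
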