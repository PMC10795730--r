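# Desk-scale study bundle: the synthetic cohort and the trained default
# U-net shared by the predictor, experiment and acceptance tests. Built
# once per test run (training dominates the suite's runtime). The study
# conditions: 24 torso phantoms of 192 px at 0.8 mm (18 train / 6
# validation), dose fractions 25/50/75%, two (z, s) pairs per case per
# dose, default architecture, 96-px patches, 6 epochs.

.bundle_env <- new.env(parent = emptyenv())

desk_bundle <- function() {
  if (!is.null(.bundle_env$bundle)) return(.bundle_env$bundle)
  spec <- phantom_spec(image_size = 192, spacing_mm = 0.8)
  cohort <- generate_cohort(24, spec, seed = 101)
  trainset <- build_training_set(cohort, per_case_samples = 2, seed = 202)
  model <- train_predictor(build_model(model_config(epochs = 6, seed = 7)),
                           trainset)
  .bundle_env$bundle <- list(
    cohort = cohort, trainset = trainset, model = model,
    val = cohort[attr(cohort, "split") == "val"])
  .bundle_env$bundle
}
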