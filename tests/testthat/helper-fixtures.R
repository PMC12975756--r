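# Shared fixtures, built once per test run and memoized. All randomness is
# seeded through the cohort/pipeline specs themselves.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# planted complete-data cohort for the selection pipeline (n = 1000)
fx_planted <- function() memo("planted", function() {
  spec <- cohortSpec(nSubjects = 1000L, missingRate = 0, outlierRate = 0,
                     seed = 42L)
  co <- generateCohort(spec, volumes = FALSE)
  st <- fitPreprocess(co$clinical)
  list(cohort = co, M = scaleAndEncode(co$clinical, st),
       labels = co$labels)
})

fx_audit <- function() memo("audit", function() {
  p <- fx_planted()
  selectFeatures(p$M, p$labels, profile = "paper-4.2", seed = 1L)
})

# small volumetric cohort for encoder / saliency plumbing tests
fx_volcohort <- function() memo("volcohort", function() {
  generateCohort(cohortSpec(nSubjects = 12L,
                            gridShape = c(24L, 24L, 24L), seed = 7L))
})

# a briefly trained tiny multimodal model on a small cohort (shared by
# interpretability and training-behaviour tests)
fx_tinyfit <- function() memo("tinyfit", function() {
  spec <- cohortSpec(nSubjects = 60L, gridShape = c(24L, 24L, 24L),
                     seed = 21L)
  co <- generateCohort(spec)
  imp <- imputeTable(co$clinical)
  model <- buildMultimodalModel(seed = 3L)
  subs <- prepareSubjects(co, imp, model)
  plan <- makeSplit(co$subjectIds, co$labels, seed = 2L)
  fit <- trainModel(model, subs, plan,
                    trainConfig(epochs = 12L, seed = 5L, lr = 5e-4,
                                augment = FALSE, mixup = FALSE),
                    lossConfig())
  list(cohort = co, subs = subs, plan = plan, fit = fit)
})

informative5 <- c("UPDRS", "Age", "MoCA", "HY_stage", "Weight")
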