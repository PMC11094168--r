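# Shared simulation-study objects for the end-to-end suites. Everything is
# memoised so the expensive classifier trainings run once per test session
# and are reused across test blocks.

.study <- new.env(parent = emptyenv())

study_get <- function(name, build) {
  if (!exists(name, envir = .study, inherits = FALSE)) {
    assign(name, build(), envir = .study)
  }
  get(name, envir = .study, inherits = FALSE)
}

STUDY_SEED <- 1L

# 4 transcripts x 220 bases: ~210 usable target (C) sites in total, ~52 on
# the transcript used for the mixture study
study_ref <- function() study_get("ref", function() {
  synthetic_reference(4, 220, seed = STUDY_SEED)
})

study_pore <- function() make_pore_model(seed = STUDY_SEED)

# main task: m5C-like, strong mean shift (the separable study condition)
eff_main <- function() mod_effect(mean_shift = 2.0)
# second-modification task for transfer: hm5C-like on the same base
eff_new <- function() mod_effect(mean_shift = 1.5, sd_factor = 1.15,
                                 dwell_factor = 1.6, quality_shift = -3)

study_make_instances <- function(refs, eff, base, s1, s2, n_reads) {
  pore <- study_pore()
  sm <- simulate_reads(refs, n_reads, base, 1, pore, eff, seed = s1)
  su <- simulate_reads(refs, n_reads, base, 0, pore, eff, seed = s2)
  combine_instances(
    extract_features(sm$events, refs, labels = "modified", center_base = base),
    extract_features(su$events, refs, labels = "unmodified", center_base = base))
}

# labeled pool of the main task, split into the 4000-instance training set
# and the held-back remainder used as an independent test set
study_pool <- function() study_get("pool", function() {
  pool <- study_make_instances(study_ref(), eff_main(), "C",
                               STUDY_SEED + 11L, STUDY_SEED + 12L, 50)
  set.seed(STUDY_SEED + 7L)
  pick <- sample(nrow(pool$meta), 4000)
  list(train = subset_instances(pool, pick),
       heldback = subset_instances(pool, setdiff(seq_len(nrow(pool$meta)), pick)),
       pool = pool, pick = pick)
})

study_instances <- function() study_pool()$train

study_train_config <- function(seed = STUDY_SEED) {
  train_config(seed = seed, max_epochs = 90L, early_stop_patience = 20L)
}

study_model <- function() study_get("model", function() {
  train_model(study_instances(), config = study_train_config())
})

# no-signal control: labels permuted across the whole pool, model trained on
# the usual 4000-instance subset and evaluated on the held-back windows
# against their own (permuted) labels — an unbiased null, free of the
# optimism of argmax checkpoint selection
study_permuted_auc <- function() study_get("permuted_auc", function() {
  sp <- study_pool()
  pool <- sp$pool
  set.seed(STUDY_SEED + 5L)
  pool$meta$label <- sample(pool$meta$label)
  fit <- train_model(subset_instances(pool, sp$pick),
                     config = train_config(seed = STUDY_SEED))
  rest <- subset_instances(pool, setdiff(seq_len(nrow(pool$meta)), sp$pick))
  p <- predict(fit, rest)[, "modified"]
  roc_pr_auc(p, rest$meta$label == "modified")$roc_auc
})

# site-level calls on read mixtures with known stoichiometry (main task)
study_mixtures <- function() study_get("mixtures", function() {
  fit <- study_model()
  ref <- study_ref()
  levels <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  called <- numeric(0)
  truth <- numeric(0)
  for (i in seq_along(levels)) {
    sim <- simulate_reads(ref["tx1"], 200, "C", levels[i], study_pore(),
                          eff_main(), seed = STUDY_SEED + 100L + i)
    inst <- extract_features(sim$events, ref, center_base = "C")
    sites <- call_sites(predict_reads(fit, inst))
    called <- c(called, sites$rate)
    truth <- c(truth, rep(levels[i], nrow(sites)))
  }
  list(called = called, truth = truth)
})

# transfer study: scratch on 3000 new-task instances vs transfer on 1500
study_transfer <- function() study_get("transfer", function() {
  instB <- study_make_instances(study_ref(), eff_new(), "C",
                                STUDY_SEED + 21L, STUDY_SEED + 22L, 50)
  set.seed(STUDY_SEED + 8L)
  idx <- sample(nrow(instB$meta))
  scratch <- train_model(subset_instances(instB, idx[1:3000]),
                         config = train_config(seed = STUDY_SEED + 2L))
  transfer <- transfer_model(study_model(), subset_instances(instB, idx[1:1500]),
                             config = train_config(seed = STUDY_SEED + 2L,
                                                   mode = "transfer",
                                                   max_epochs = 25L))
  list(scratch = scratch, transfer = transfer)
})
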