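#' Configuration for the end-to-end weak-supervision experiment
#'
#' Describes the full synthetic experiment: an "external" labelled cohort
#' emulating a clean diagnostic-ECG source on which the surrogate (label
#' generation) model is trained; an unlabelled "target" pool and a labelled
#' test set emulating noisier ICU telemetry in a shifted domain; training
#' settings shared by all models; the confident-learning cleaning schedule;
#' and the grid of uncertainty modes. Defaults are desk-scale: cohorts of a
#' few thousand 10-s, 4-lead segments at 240 Hz, a width-reduced network,
#' and shortened epoch budgets, with the target-domain class mix and noise
#' structure mirroring an ICU telemetry test population (14% AF among
#' in-distribution segments, 27% noisy, 9% OOD).
#'
#' @param external_size,target_size,test_size Approximate cohort sizes
#'   (segments), realised as patients x segments-per-patient.
#' @param segments_per_patient Segments per patient in every cohort.
#' @param shift A [domain_shift()] applied to the target-domain cohorts
#'   (pool and test) relative to the external source domain.
#' @param class_mix In-distribution class proportions for all cohorts.
#' @param noise_rate_external,noise_rate_target Noisy-segment rates in the
#'   source and target domains.
#' @param ood_rate_pool,ood_rate_test OOD (abstain-analog) rates in the
#'   unlabelled pool and the test set.
#' @param network A [network_config()].
#' @param train A [train_config()]; the surrogate uses the same settings
#'   with a 30% stratified validation split.
#' @param cleaner A [confident_cleaner()] used by the confident-learning
#'   model.
#' @param n_passes Stochastic passes T for every uncertainty mode.
#' @param mask_fraction Mask fraction for the aleatoric modes.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(external_size = 2000, target_size = 2400,
                              test_size = 500, segments_per_patient = 10,
                              shift = domain_shift(amplitude_scale = 0.75,
                                                   noise_floor = 0.04,
                                                   hr_shift = 8),
                              class_mix = c(sinus = 0.86, af = 0.14),
                              noise_rate_external = 0.05,
                              noise_rate_target = 0.27,
                              ood_rate_pool = 0.05, ood_rate_test = 0.09,
                              network = network_config(scale = 0.25),
                              train = train_config(max_epochs = 20, patience = 4),
                              cleaner = confident_cleaner(interval = 3, warmup = 9),
                              n_passes = 30, mask_fraction = 0.10,
                              seed = 1) {
  structure(
    list(external_size = external_size, target_size = target_size,
         test_size = test_size, segments_per_patient = segments_per_patient,
         shift = shift, class_mix = class_mix,
         noise_rate_external = noise_rate_external,
         noise_rate_target = noise_rate_target,
         ood_rate_pool = ood_rate_pool, ood_rate_test = ood_rate_test,
         network = network, train = train, cleaner = cleaner,
         n_passes = as.integer(n_passes), mask_fraction = mask_fraction,
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

exp_cohort <- function(size, per_patient, ...) {
  n_pat <- max(1L, ceiling(size / per_patient))
  generate_cohort(n_patients = n_pat, segments_per_patient = per_patient, ...)
}

#' Run the full weak-supervision experiment on synthetic cohorts
#'
#' Executes the pipeline end to end: (1) simulate the external, target-pool
#' and test cohorts; (2) train the surrogate (label generation) model on
#' the external cohort with a 70/30 stratified split; (3) curate the target
#' pool and weak-label it with the surrogate; (4) train a "weak labels
#' only" model (plain supervision on the weak labels) and a "confident
#' learning" model (same labels, with iterative label cleaning every 3
#' epochs after a warm-up); (5) evaluate all three models under the four uncertainty modes
#' (always-confident, epistemic, aleatoric, combined) on the labelled test
#' set; (6) compare uncertainty distributions between clean/noisy and
#' in-distribution/OOD groups with Holm-corrected Mann-Whitney tests. The
#' whole experiment is reproducible from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @param verbose Print per-stage progress.
#' @return An `af_experiment` object with elements `metrics` (3 models x 4
#'   uncertainty modes), `predictions` (per-segment prediction sets for
#'   every configuration), `comparisons`, `models`, `weak_labels`,
#'   `histories` and `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Experiment stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "afuq_pipeline_error", parent = e)
    })
  }

  say("simulating cohorts")
  external <- stage("simulate_external", exp_cohort(
    config$external_size, config$segments_per_patient,
    class_mix = config$class_mix, noise_rate = config$noise_rate_external,
    ood_rate = 0, seed = derive_seed(seed, 1)
  ))
  pool <- stage("simulate_pool", exp_cohort(
    config$target_size, config$segments_per_patient,
    class_mix = config$class_mix, noise_rate = config$noise_rate_target,
    ood_rate = config$ood_rate_pool, shift = config$shift,
    seed = derive_seed(seed, 2)
  ))
  test <- stage("simulate_test", exp_cohort(
    config$test_size, config$segments_per_patient,
    class_mix = config$class_mix, noise_rate = config$noise_rate_target,
    ood_rate = config$ood_rate_test, shift = config$shift,
    seed = derive_seed(seed, 3)
  ))

  say("training surrogate on %d external segments", nrow(external))
  surrogate_cfg <- config$train
  surrogate_cfg$val_fraction <- 0.3 # 70/30 stratified source-domain split
  surrogate_cfg$seed <- derive_seed(seed, 5)
  external$label <- external$y_true
  surrogate <- stage("train_surrogate", train_classifier(
    build_classifier(config$network, seed = derive_seed(seed, 4)),
    external, surrogate_cfg
  ))

  say("curating and weak-labelling target pool")
  pool_curated <- stage("curate", curate_segments(pool))
  weak <- stage("weak_label", assign_weak_labels(pool_curated, surrogate))

  say("training weak-labels-only model on %d segments", nrow(weak))
  weak_cfg <- config$train
  weak_cfg$seed <- derive_seed(seed, 7)
  weak_only <- stage("train_weak_only", train_classifier(
    build_classifier(config$network, seed = derive_seed(seed, 6)),
    weak, weak_cfg
  ))

  say("training confident-learning model")
  # common random numbers: same initialisation and batch stream as the
  # weak-labels-only model, so the two arms differ only through cleaning
  # (the paired design isolates the treatment effect of label cleaning
  # from initialisation and batch-order variance)
  cl_model <- stage("train_confident", train_classifier(
    build_classifier(config$network, seed = derive_seed(seed, 6)),
    weak, weak_cfg, cleaner = config$cleaner
  ))

  models <- list(label_generation = surrogate,
                 weak_labels_only = weak_only,
                 confident_learning = cl_model)
  modes <- c("none", "epistemic", "aleatoric", "combined")

  say("evaluating %d model x mode configurations on %d test segments",
      length(models) * length(modes), nrow(test))
  predictions <- list()
  metric_rows <- list()
  comp_rows <- list()
  tag <- 10L
  for (m in names(models)) {
    for (mode in modes) {
      tag <- tag + 1L
      ucfg <- uncertainty_config(mode, n_passes = config$n_passes,
                                 mask_fraction = config$mask_fraction,
                                 seed = derive_seed(seed, tag))
      preds <- stage(paste0("uncertainty_", m, "_", mode),
                     batch_uncertainty(models[[m]], test, ucfg))
      predictions[[paste(m, mode, sep = ".")]] <- preds
      cm <- classification_metrics(preds)
      cal <- ece(preds)
      metric_rows[[paste(m, mode)]] <- tibble(
        model = m, uncertainty = mode,
        f1 = cm$f1, ppv = cm$ppv, sensitivity = cm$sensitivity,
        specificity = cm$specificity,
        ece = cal$ece, brier = brier(preds), nll = nll(preds)
      )
      if (mode != "none") {
        cc <- compare_uncertainty_groups(
          preds, groupings = c("clean_vs_noisy", "id_vs_ood"))
        if (nrow(cc)) {
          cc$model <- m
          cc$uncertainty <- mode
          comp_rows[[paste(m, mode)]] <- cc
        }
      }
    }
  }

  structure(
    list(
      metrics = bind_rows(metric_rows),
      predictions = predictions,
      comparisons = bind_rows(comp_rows),
      models = models,
      weak_labels = weak,
      cleaning_report = cl_model$cleaning_report,
      histories = lapply(models, tidy),
      test = test,
      config = config
    ),
    class = "af_experiment"
  )
}

#' @export
print.af_experiment <- function(x, ...) {
  cat(sprintf("<af_experiment> %d model x uncertainty configurations, seed %d\n",
              nrow(x$metrics), x$config$seed))
  print(as.data.frame(x$metrics), digits = 3)
  invisible(x)
}

#' Tidy the metrics grid of an experiment
#'
#' @param x An `af_experiment`.
#' @param ... Unused.
#' @return The metrics tibble: one row per model x uncertainty mode with
#'   F1, PPV, sensitivity, specificity, ECE, Brier and NLL.
#' @method tidy af_experiment
#' @export
tidy.af_experiment <- function(x, ...) x$metrics

#' One-row experiment summary
#'
#' @param x An `af_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with cohort sizes, the best F1 and best
#'   (lowest) ECE configurations, and the number of Holm-corrected group
#'   separations detected.
#' @method glance af_experiment
#' @export
glance.af_experiment <- function(x, ...) {
  m <- x$metrics
  tibble(
    n_test = nrow(x$test),
    n_weak = nrow(x$weak_labels),
    best_f1 = max(m$f1),
    best_f1_config = paste(m$model[which.max(m$f1)],
                           m$uncertainty[which.max(m$f1)]),
    best_ece = min(m$ece),
    best_ece_config = paste(m$model[which.min(m$ece)],
                            m$uncertainty[which.min(m$ece)]),
    n_rejections = if (nrow(x$comparisons)) sum(x$comparisons$reject) else 0L
  )
}
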