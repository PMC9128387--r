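#' Pipeline run configuration
#'
#' Bundles every knob of a pipeline run so that a run is a pure function of
#' (configuration, inputs): the event filter, MI estimator configuration,
#' graph conventions, classifier profile, seed, and optional output
#' directory. The configuration is fully serializable to JSON and its
#' serialized form is embedded in every run manifest.
#'
#' @param event_filter An [fr_filter()]; default fast ripples > 350 Hz.
#' @param mi_cfg An [mi_config()].
#' @param radius_definition `"shortest_path"` or `"adjacency"`.
#' @param normalize_strength_diff Normalize the MI strength difference by
#'   node counts (non-default variant).
#' @param classifier_profile `"svm1"` or `"svm2"`.
#' @param impute_strategy Imputation strategy for missing MI features.
#' @param exclude_zero_fr Exclude zero-FR patients from SVM training.
#' @param threshold Non-responder probability threshold.
#' @param n_boot Bootstrap replicates for AUC CIs.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(event_filter = fr_filter(), mi_cfg = mi_config(),
                       radius_definition = "shortest_path",
                       normalize_strength_diff = FALSE,
                       classifier_profile = "svm1",
                       impute_strategy = "median_of_training",
                       exclude_zero_fr = FALSE,
                       threshold = 0.5, n_boot = 1000, seed = 1L,
                       out_dir = NULL) {
  structure(list(event_filter = event_filter, mi_cfg = mi_cfg,
                 radius_definition = radius_definition,
                 normalize_strength_diff = normalize_strength_diff,
                 classifier_profile = classifier_profile,
                 impute_strategy = impute_strategy,
                 exclude_zero_fr = exclude_zero_fr,
                 threshold = threshold, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_json <- function(config) {
  ser <- config
  ser$out_dir <- NULL
  as.character(jsonlite::toJSON(unclass(lapply(ser, unclass)),
                                auto_unbox = TRUE, digits = NA))
}

write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(list(package = "frnet",
                     version = as.character(utils::packageVersion("frnet")),
                     seed = config$seed,
                     config = config_json(config)),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the per-patient network analysis
#'
#' Builds the SOZ distance, FR distance, FR rate-distance (all nodes and
#' non-SOZ only) and FR mutual-information networks for one patient and
#' computes the global measures. With an output directory set, writes the
#' network edge lists, a one-row measures CSV (missing markers as empty
#' fields), and a JSON manifest embedding the serialized configuration and
#' seed; reruns with identical config and inputs are byte-identical.
#'
#' A patient with no events passing the filter is handled per the radius
#' conventions: radii 0, MI measures missing, and the run succeeds.
#'
#' @param record A [patient_record()].
#' @param config A [run_config()].
#' @return List with `networks` (named list; `mi` may be `NULL`) and
#'   `measures` (one-row data frame).
#' @export
run_patient <- function(record, config = run_config()) {
  res <- tryCatch({
    flt <- config$event_filter
    rates <- compute_rates(record, flt)
    nets <- list(
      soz_distance = distance_network(
        record$contacts[record$contacts$is_soz, , drop = FALSE]),
      fr_distance = distance_network(select_nodes(record, flt)),
      fr_rate_distance = rate_distance_network(select_nodes(record, flt), rates),
      fr_rate_distance_nonsoz = rate_distance_network(
        select_nodes(record, flt, nonsoz_only = TRUE), rates),
      mi = mi_network(record, flt, config$mi_cfg))
    measures <- global_measures(record, flt, config$mi_cfg,
                                config$radius_definition,
                                config$normalize_strength_diff)
    list(networks = nets, measures = measures)
  }, error = function(e) {
    stop("patient ", record$patient_id, ": ", conditionMessage(e), call. = FALSE)
  })
  if (!is.null(config$out_dir)) {
    dir <- file.path(config$out_dir, record$patient_id)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(res$networks))
      if (!is.null(res$networks[[nm]]))
        write_network(res$networks[[nm]], file.path(dir, nm))
    write.csv(res$measures, file.path(dir, "measures.csv"),
              row.names = FALSE, quote = FALSE, na = "")
    write_manifest(dir, config, list(patient_id = record$patient_id))
  }
  res
}

#' Run the full cohort analysis
#'
#' Orchestrates the pipeline end to end over a list of patient records (or
#' a [cohort_spec()], which is generated first): per-patient networks and
#' global measures; SOZ-classification ROC of filtered-event rates per
#' outcome group with bootstrap CIs; outcome classification ROC of the
#' non-SOZ rate-distance radius; the log-frequency mixed model per outcome
#' group; PCA of the three MI measures with rank-sum tests on the PC
#' scores (Holm-corrected); and -- when a train/test split is given -- the
#' SVM trained on the training patients and scored on the test patients.
#' Every patient excluded from a stage (non-constructible MI network,
#' missing measures) is listed in `exclusions` with the reason.
#'
#' @param cohort List of [patient_record()]s, or a [cohort_spec()].
#' @param config A [run_config()].
#' @param train_ids Patient ids forming the classifier training set;
#'   `NULL` trains and evaluates on all patients (training metrics).
#' @return List of class `cohort_result` with elements `measures`,
#'   `soz_roc`, `radius_roc`, `mixed_models`, `pca`, `pc_tests`,
#'   `classifier`, `exclusions`.
#' @export
run_cohort <- function(cohort, config = run_config(), train_ids = NULL) {
  if (inherits(cohort, "cohort_spec")) cohort <- generate_cohort(cohort)
  stopifnot(length(cohort) >= 2L)
  flt <- config$event_filter
  exclusions <- list()

  per_patient <- lapply(cohort, run_patient, config = config)
  measures <- do.call(rbind, lapply(per_patient, `[[`, "measures"))
  for (i in seq_along(cohort))
    if (!measures$mi_constructible[i])
      exclusions[[length(exclusions) + 1L]] <-
        list(patient_id = measures$patient_id[i], stage = "mi_network",
             reason = "fewer than 2 contacts with enough filtered events")

  # contact-level SOZ classification from filtered-event rates, per group
  soz_roc <- lapply(split(cohort, outcome_group(cohort)), function(recs) {
    rates <- do.call(rbind, lapply(recs, function(r)
      cbind(compute_rates(r, flt), is_soz = r$contacts$is_soz)))
    if (length(unique(rates$is_soz)) < 2L) return(NULL)
    ci <- bootstrap_auc_ci(rates$rate, rates$is_soz, config$n_boot,
                           seed = config$seed)
    list(auc = ci$auc, lo = ci$lo, hi = ci$hi,
         n_contacts = nrow(rates))
  })

  # patient-level outcome classification by non-SOZ rate-distance radius
  cls <- outcome_to_class(measures$outcome)
  radius_roc <- if (length(unique(cls)) == 2L) {
    ci <- bootstrap_auc_ci(measures$fr_rate_distance_radius_nonsoz,
                           cls == 1L, config$n_boot, seed = config$seed)
    list(auc = ci$auc, lo = ci$lo, hi = ci$hi)
  }

  mixed_models <- lapply(split(cohort, outcome_group(cohort)), function(recs) {
    ev <- do.call(rbind, lapply(recs, fr_event_table))
    if (is.null(ev) || length(unique(ev$patient_id)) < 2L ||
        length(unique(ev$is_soz)) < 2L) return(NULL)
    fit_feature_lmm(ev)
  })

  mi_cols <- c("mi_charpath", "mi_mean_local_eff_nonsoz", "mi_strength_diff")
  mi_mat <- as.matrix(measures[, mi_cols])
  rownames(mi_mat) <- measures$patient_id
  pca <- pc_tests <- NULL
  if (sum(complete.cases(mi_mat)) >= 3L) {
    pca <- pca_measures(mi_mat)
    for (pid in pca$excluded)
      exclusions[[length(exclusions) + 1L]] <-
        list(patient_id = pid, stage = "pca", reason = "missing MI measures")
    grp <- outcome_to_class(
      measures$outcome[match(rownames(pca$scores), measures$patient_id)])
    if (length(unique(grp)) == 2L) {
      pc_groups <- lapply(1:3, function(k)
        list(responder = pca$scores[grp == 0L, k],
             non_responder = pca$scores[grp == 1L, k]))
      p <- vapply(pc_groups, function(g)
        suppressWarnings(wilcox.test(g$responder, g$non_responder)$p.value),
        numeric(1))
      adj <- p.adjust(p, "holm")
      pc_tests <- data.frame(component = paste0("PC", 1:3), p_raw = p,
                             p_holm = adj, reject = adj < 0.05)
    }
  }

  classifier <- NULL
  if (!is.null(train_ids)) {
    train <- measures[measures$patient_id %in% train_ids, , drop = FALSE]
    test <- measures[!measures$patient_id %in% train_ids, , drop = FALSE]
  } else if (length(unique(cls)) == 2L && min(table(cls)) >= 3L) {
    train <- measures
    test <- measures[0, , drop = FALSE]
  } else {
    train <- NULL
  }
  if (!is.null(train)) {
    strategy <- config$impute_strategy
    # an entirely missing MI feature cannot be median-imputed: fall back to
    # the sentinel so classification degrades to the radius features
    if (any(vapply(svm_feature_names(),
                   function(cl) all(is.na(train[[cl]])), TRUE)))
      strategy <- "constant_sentinel"
    model <- train_outcome_svm(train, profile = config$classifier_profile,
                               impute_strategy = strategy,
                               exclude_zero_fr = config$exclude_zero_fr,
                               seed = config$seed)
    classifier <- list(model = model,
                       train = predict_outcome(model, train, config$threshold),
                       test = if (nrow(test))
                         predict_outcome(model, test, config$threshold))
  }

  result <- structure(list(measures = measures, soz_roc = soz_roc,
                           radius_roc = radius_roc,
                           mixed_models = mixed_models,
                           pca = pca, pc_tests = pc_tests,
                           classifier = classifier,
                           exclusions = exclusions),
                      class = "cohort_result")
  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write.csv(measures, file.path(dir, "measures.csv"), row.names = FALSE,
              quote = FALSE, na = "")
    if (!is.null(pca))
      write.csv(data.frame(patient_id = rownames(pca$scores),
                           round(pca$scores, 10)),
                file.path(dir, "pca_scores.csv"), row.names = FALSE,
                quote = FALSE)
    if (!is.null(classifier) && !is.null(classifier$test))
      write.csv(classifier$test$predictions,
                file.path(dir, "test_predictions.csv"), row.names = FALSE,
                quote = FALSE)
    write_manifest(dir, config,
                   list(n_patients = length(cohort),
                        exclusions = exclusions))
  }
  result
}

outcome_group <- function(cohort) {
  vapply(cohort, function(r)
    if (r$outcome == "responder") "responder" else "non_responder", "")
}

#' Fast-ripple event table for the spectral-feature mixed model
#'
#' Collects every fRonO/fRonS event of a patient (all frequencies, as the
#' spectral-feature model uses every fast ripple) together with the
#' contact's SOZ flag and numeric location code, in the layout
#' [fit_feature_lmm()] expects. Tables from several patients can be
#' row-bound directly.
#'
#' @param record A [patient_record()].
#' @return Data frame with `patient_id`, `is_soz`, `location_code`,
#'   `peak_freq_hz`, or `NULL` when the patient has no fast ripples.
#' @export
fr_event_table <- function(record) {
  ev <- filter_events(record, fr_filter(c("fRonO", "fRonS"),
                                        min_freq_hz = NULL))
  if (!nrow(ev)) return(NULL)
  ct <- record$contacts
  idx <- match(ev$contact_id, ct$contact_id)
  data.frame(patient_id = record$patient_id,
             is_soz = ct$is_soz[idx],
             location_code = region_codes()$code[
               match(ct$region[idx], region_codes()$region)],
             peak_freq_hz = ev$peak_freq_hz)
}
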