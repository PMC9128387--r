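#' Predictor columns used by the outcome classifier
#' @return Character vector of the six feature names.
#' @export
svm_feature_names <- function() {
  c("soz_radius", "fr_distance_radius", "fr_rate_distance_radius",
    "mi_charpath", "mi_mean_local_eff_nonsoz", "mi_strength_diff")
}

#' Impute missing MI features
#'
#' Patients without a constructible MI network carry `NA` in the three MI
#' features. `"median_of_training"` fills each missing value with the
#' per-column median computed on the training rows (pass the training
#' statistics when transforming a test set so test patients never influence
#' them); `"constant_sentinel"` fills with 0. The imputation mask is
#' attached as attribute `"imputed"`.
#'
#' @param features Data frame containing [svm_feature_names()] columns.
#' @param strategy `"median_of_training"` or `"constant_sentinel"`.
#' @param training_stats Named numeric vector of column medians from
#'   training data; computed from `features` itself when `NULL`.
#' @return The features with missings filled, plus attributes `"imputed"`
#'   (logical mask) and `"training_stats"`.
#' @export
impute_features <- function(features,
                            strategy = c("median_of_training",
                                         "constant_sentinel"),
                            training_stats = NULL) {
  strategy <- match.arg(strategy)
  cols <- svm_feature_names()
  miss <- setdiff(cols, names(features))
  if (length(miss)) stop_schema("features missing column(s): ",
                                paste(miss, collapse = ", "))
  mask <- is.na(as.matrix(features[, cols]))
  if (strategy == "median_of_training") {
    if (is.null(training_stats)) {
      training_stats <- vapply(features[cols], median, numeric(1), na.rm = TRUE)
      if (anyNA(training_stats))
        stop("feature column entirely missing; cannot impute")
    }
    for (cl in cols)
      features[[cl]][is.na(features[[cl]])] <- training_stats[[cl]]
  } else {
    training_stats <- setNames(numeric(length(cols)), cols)
    for (cl in cols) features[[cl]][is.na(features[[cl]])] <- 0
  }
  attr(features, "imputed") <- mask
  attr(features, "training_stats") <- training_stats
  features
}

# Platt sigmoid: fit P(positive | d) = 1 / (1 + exp(A d + B)) by
# regularized maximum likelihood with the usual smoothed targets.
fit_platt <- function(decision, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  t <- ifelse(positive, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(par) {
    z <- par[1] * decision + par[2]
    p <- 1 / (1 + exp(z))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  fit <- optim(c(-1, 0), nll, method = "BFGS")
  c(A = fit$par[1], B = fit$par[2])
}

platt_prob <- function(params, decision) {
  1 / (1 + exp(params["A"] * decision + params["B"]))
}

#' Train the non-responder SVM
#'
#' Radial-basis-function support-vector classifier of surgical
#' non-responders from the six per-patient network features. Features are
#' z-scored with training-set statistics; the kernel bandwidth is set
#' automatically by the median heuristic (sigma = median pairwise Euclidean
#' distance between standardized training rows, gamma = 1 / (2 sigma^2));
#' and a Platt sigmoid is fitted to the training decision values so that a
#' probability threshold of 0.5 is meaningful. Missing MI features are
#' imputed with training statistics only.
#'
#' Two training profiles are provided: `"svm1"` trains on all
#' patients; `"svm2"` excludes patients treated with responsive
#' neurostimulation alone (outcome `no_resection_rns`) from the training
#' set. For classification, `no_resection_rns` patients count as
#' non-responders (they are non-responders a priori). `exclude_zero_fr`
#' drops training patients whose FR distance radius is 0 (no fast ripples
#' above threshold).
#'
#' @param features Data frame with `patient_id`, `outcome`, and the
#'   [svm_feature_names()] columns.
#' @param profile `"svm1"` or `"svm2"`.
#' @param impute_strategy Passed to [impute_features()].
#' @param exclude_zero_fr Drop zero-FR training patients (default FALSE).
#' @param cost SVM cost parameter (default 1).
#' @param seed Integer seed (the fit is deterministic; the seed is recorded
#'   in the manifest for reproducibility bookkeeping).
#' @return List of class `outcome_svm`: standardization parameters, kernel
#'   bandwidth, the fitted libsvm object, Platt parameters, imputation
#'   statistics, and a training-set manifest.
#' @export
train_outcome_svm <- function(features, profile = c("svm1", "svm2"),
                              impute_strategy = "median_of_training",
                              exclude_zero_fr = FALSE, cost = 1, seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(all(c("patient_id", "outcome") %in% names(features)))
  train <- features
  if (profile == "svm2")
    train <- train[train$outcome != "no_resection_rns", , drop = FALSE]
  if (exclude_zero_fr)
    train <- train[train$fr_distance_radius > 0, , drop = FALSE]
  label <- outcome_to_class(train$outcome)
  if (length(unique(label)) < 2L) stop("training set must contain both classes")
  if (min(table(label)) < 3L) stop("need >= 3 training patients per class")

  train_imp <- impute_features(train, impute_strategy)
  x <- as.matrix(train_imp[, svm_feature_names()])
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sds, `/`)
  pd <- as.numeric(stats::dist(z))
  sigma <- median(pd[pd > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  gamma <- 1 / (2 * sigma^2)

  y <- factor(ifelse(label == 1L, "non_responder", "responder"),
              levels = c("responder", "non_responder"))
  model <- with_seed(seed, e1071::svm(x = z, y = y, kernel = "radial",
                                      gamma = gamma, cost = cost,
                                      scale = FALSE))
  dec <- decision_nonresponder(model, z)
  platt <- fit_platt(dec, label == 1L)

  structure(list(center = mu, scale = sds, gamma = gamma, sigma = sigma,
                 cost = cost, model = model, platt = platt,
                 impute_strategy = impute_strategy,
                 impute_stats = attr(train_imp, "training_stats"),
                 profile = profile, seed = as.integer(seed),
                 manifest = list(train_ids = train$patient_id,
                                 n_responder = sum(label == 0L),
                                 n_nonresponder = sum(label == 1L))),
            class = "outcome_svm")
}

# Map outcome labels to the binary classification target (1 = non-responder;
# no-resection/RNS patients are non-responders a priori).
outcome_to_class <- function(outcome) {
  if (any(!outcome %in% outcome_levels()))
    stop_schema("unknown outcome label")
  as.integer(outcome %in% c("non_responder", "no_resection_rns"))
}

# Signed decision value oriented so that larger = more non-responder-like.
decision_nonresponder <- function(model, z) {
  pr <- predict(model, z, decision.values = TRUE)
  dec <- drop(attr(pr, "decision.values"))
  if (grepl("^non_responder", colnames(attr(pr, "decision.values"))[1]))
    dec else -dec
}

#' Classify patients and summarize performance
#'
#' Applies a trained [train_outcome_svm()] model: features are imputed and
#' standardized with the model's training statistics, decision values are
#' mapped to probabilities through the trained Platt sigmoid, and patients
#' with probability above the threshold are called non-responders (the
#' positive class: a true positive is a correctly identified
#' non-responder). When outcomes are present, sensitivity, specificity,
#' positive and negative predictive value and accuracy are reported at the
#' threshold, each with an exact binomial 95% CI, together with the full
#' threshold-sweep ROC of the probabilities.
#'
#' @param model An `outcome_svm`.
#' @param features Data frame with [svm_feature_names()] columns (plus
#'   `patient_id`, and `outcome` for scoring).
#' @param threshold Probability threshold for the non-responder call.
#' @return List of class `svm_prediction`: `predictions` (per-patient
#'   probability and class), and -- when outcomes are available --
#'   `metrics` (one row per metric with CI), `confusion`, `roc`.
#' @export
predict_outcome <- function(model, features, threshold = 0.5) {
  stopifnot(inherits(model, "outcome_svm"))
  miss <- setdiff(svm_feature_names(), names(features))
  if (length(miss)) stop_schema("features missing column(s): ",
                                paste(miss, collapse = ", "))
  imp <- impute_features(features, model$impute_strategy,
                         training_stats = model$impute_stats)
  x <- as.matrix(imp[, svm_feature_names()])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  dec <- decision_nonresponder(model$model, z)
  prob <- unname(platt_prob(model$platt, dec))
  pred <- data.frame(patient_id = features$patient_id %||%
                       seq_len(nrow(features)),
                     prob_nonresponder = prob,
                     predicted = ifelse(prob > threshold,
                                        "non_responder", "responder"))
  out <- list(predictions = pred, threshold = threshold)
  if ("outcome" %in% names(features)) {
    truth <- outcome_to_class(features$outcome) == 1L
    call <- prob > threshold
    tp <- sum(call & truth); fn <- sum(!call & truth)
    tn <- sum(!call & !truth); fp <- sum(call & !truth)
    metric_row <- function(name, k, n) {
      if (n == 0)
        return(data.frame(metric = name, estimate = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_, n = 0L))
      ci <- binom_ci(k, n)
      data.frame(metric = name, estimate = k / n, ci_lo = ci[[1]],
                 ci_hi = ci[[2]], n = n)
    }
    out$confusion <- c(tp = tp, fn = fn, tn = tn, fp = fp)
    out$metrics <- rbind(
      metric_row("sensitivity", tp, tp + fn),
      metric_row("specificity", tn, tn + fp),
      metric_row("ppv", tp, tp + fp),
      metric_row("npv", tn, tn + fn),
      metric_row("accuracy", tp + tn, length(truth)))
    out$roc <- roc_auc(prob, truth)
  }
  class(out) <- "svm_prediction"
  out
}
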