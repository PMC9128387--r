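#' Mixed-effects model of a log-transformed event feature
#'
#' Fits a Gaussian linear mixed model to the log of an HFO event feature
#' (peak spectral frequency, peak power, or duration) with a random
#' intercept per patient and fixed effects for SOZ membership and a numeric
#' anatomical location code (see [region_codes()]):
#' `log(y) ~ soz + location + (1 | patient)`. Intercepts near 5.5 log-Hz
#' correspond to the 250-600 Hz fast-ripple band. Returns Wald 95%
#' confidence intervals and the residual degrees of freedom. A singular
#' random-effect fit falls back to ordinary least squares with a warning
#' and is flagged.
#'
#' @param events Data frame with columns `patient_id`, `is_soz`,
#'   `location_code`, and the response column.
#' @param response Name of the (positive) response column; default
#'   `"peak_freq_hz"`.
#' @param log_transform Model the natural log of the response (default).
#' @return List of class `mixed_model_result` with `coefficients` (data
#'   frame: term, estimate, ci_lo, ci_hi), `df`, `singular`, `model`.
#' @export
fit_feature_lmm <- function(events, response = "peak_freq_hz",
                            log_transform = TRUE) {
  need <- c("patient_id", "is_soz", "location_code", response)
  miss <- setdiff(need, names(events))
  if (length(miss)) stop_schema("events missing column(s): ",
                                paste(miss, collapse = ", "))
  if (length(unique(events$patient_id)) < 2L)
    stop("need >= 2 patients for a random patient intercept")
  if (length(unique(events$is_soz)) < 2L)
    stop("both SOZ classes must be represented")
  d <- data.frame(y = events[[response]],
                  soz = as.numeric(events$is_soz),
                  location = as.numeric(events$location_code),
                  patient = factor(events$patient_id))
  if (log_transform) d$y <- log(d$y)
  fit <- lme4::lmer(y ~ soz + location + (1 | patient), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-effect fit; falling back to fixed effects only")
    fit_fe <- stats::lm(y ~ soz + location, data = d)
    est <- coef(fit_fe)
    se <- sqrt(diag(vcov(fit_fe)))
    df <- fit_fe$df.residual
    model <- fit_fe
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(vcov(fit))))
    df <- nrow(d) - length(est)
    model <- fit
  }
  z <- qnorm(0.975)
  coefs <- data.frame(term = c("intercept", "soz", "location"),
                      estimate = unname(est),
                      ci_lo = unname(est - z * se),
                      ci_hi = unname(est + z * se))
  structure(list(coefficients = coefs, df = df, singular = singular,
                 model = model),
            class = "mixed_model_result")
}

#' Rank-sum tests with Bonferroni-Holm correction
#'
#' Runs a two-sided Wilcoxon rank-sum test for each requested group
#' comparison and applies the Holm step-down adjustment across the family,
#' with rejection flags at the requested family-wise error rate.
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons List of length-2 character vectors naming group pairs;
#'   default: all pairwise comparisons.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame: `group_a`, `group_b`, `p_raw`, `p_holm`, `reject`.
#' @export
ranksum_holm <- function(groups, comparisons = NULL, alpha = 0.05) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (any(!vapply(groups, length, 1L)))
    stop("every group needs at least one value")
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  p <- vapply(comparisons, function(cmp) {
    a <- groups[[cmp[1]]]; b <- groups[[cmp[2]]]
    if (is.null(a) || is.null(b)) stop("unknown group in comparison")
    suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
  }, numeric(1))
  adj <- p.adjust(p, method = "holm")
  data.frame(group_a = vapply(comparisons, `[`, "", 1),
             group_b = vapply(comparisons, `[`, "", 2),
             p_raw = p, p_holm = adj, reject = adj < alpha)
}

#' PCA of the three global MI network measures
#'
#' Standardizes the columns of the measures matrix and extracts principal
#' axes. Patients with any missing measure are excluded (and reported).
#' Each component's sign is fixed so that its largest-magnitude loading is
#' positive, making the decomposition deterministic.
#'
#' @param measures Numeric matrix or data frame (patients x measures), with
#'   patient ids as row names if available.
#' @return List of class `pca_result`: `loadings` (orthonormal columns),
#'   `scores`, `explained` (variance fractions summing to 1),
#'   `excluded` (row identifiers dropped for missingness).
#' @export
pca_measures <- function(measures) {
  m <- as.matrix(measures)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  ok <- complete.cases(m)
  excluded <- rownames(m)[!ok]
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 3L) stop("need >= 3 patients with complete measures")
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(loadings = loadings, scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 excluded = excluded),
            class = "pca_result")
}
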