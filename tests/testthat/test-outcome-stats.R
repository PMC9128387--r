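test_that("AUC handles separation, ties, and partial concordance", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.5)
  # SOZ {3,1} vs non-SOZ {2,0}: 3 concordant of 4 pairs
  expect_equal(roc_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_true(is.na(roc_auc(c(1, 2), c(TRUE, TRUE))$auc))
})

test_that("threshold-sweep AUC equals the Mann-Whitney pair statistic", {
  set.seed(301)
  for (i in 1:30) {
    n <- sample(5:40, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # force ties often
    labels <- runif(n) < 0.5
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, auc_pairs_oracle(scores, labels), tolerance = 1e-12)
    # curve endpoints
    expect_equal(r$sensitivity[1], 0)
    expect_equal(tail(r$sensitivity, 1), 1)
    expect_equal(tail(r$specificity, 1), 0)
  }
})

test_that("bootstrap CI is deterministic, stratified, and sane", {
  set.seed(302)
  scores <- c(rnorm(100, 2), rnorm(100))
  labels <- rep(c(TRUE, FALSE), each = 100)
  a <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = 5)
  b <- bootstrap_auc_ci(scores, labels, n_boot = 300, seed = 5)
  expect_identical(a$lo, b$lo)
  expect_identical(a$hi, b$hi)
  expect_lte(a$lo, a$auc)
  expect_gte(a$hi, a$auc)
  expect_equal(a$n_redraws, 0L)
  # perfect separation: upper bound pinned at 1
  sep <- bootstrap_auc_ci(c(10, 9, 8, 1, 2, 3),
                          c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                          n_boot = 200, seed = 1)
  expect_equal(sep$hi, 1.0)
  expect_gt(sep$lo, 0.9)
})

test_that("paired AUC-difference test separates unequal classifiers", {
  set.seed(303)
  labels <- rep(c(TRUE, FALSE), each = 80)
  good <- ifelse(labels, rnorm(160, 2), rnorm(160))
  noise <- rnorm(160)
  d <- auc_diff_test(good, noise, labels, n_boot = 400, seed = 2)
  expect_lt(d$p_value, 0.05)
  same <- auc_diff_test(noise, noise + 0, labels, n_boot = 400, seed = 2)
  expect_gte(same$p_value, 0.05)
})

test_that("mixed model on a single-cluster fit matches OLS", {
  set.seed(304)
  n <- 400
  d <- data.frame(patient_id = "P1",
                  is_soz = rep(c(TRUE, FALSE), each = n / 2),
                  location_code = sample(1:5, n, TRUE))
  d$peak_freq_hz <- exp(5.5 + 0.2 * d$is_soz + 0.01 * d$location_code +
                          rnorm(n, 0, 0.15))
  d2 <- d
  d2$patient_id <- rep(c("P1", "P2"), n / 2)  # two patients, no true RE
  fit <- suppressWarnings(fit_feature_lmm(d2))
  ols <- lm(log(peak_freq_hz) ~ I(as.numeric(is_soz)) + location_code,
            data = d2)
  # with (near-)zero random-effect variance the fixed effects match OLS
  expect_equal(fit$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-3)
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$estimate))
  expect_true(all(fit$coefficients$ci_hi >= fit$coefficients$estimate))
})

test_that("mixed model recovers a planted SOZ shift", {
  set.seed(305)
  pts <- sprintf("P%d", 1:8)
  rows <- do.call(rbind, lapply(pts, function(p) {
    n <- 600
    data.frame(patient_id = p,
               is_soz = runif(n) < 0.3,
               location_code = sample(1:8, n, TRUE))
  }))
  pint <- setNames(rnorm(8, 0, 0.05), pts)
  rows$peak_freq_hz <- exp(5.47 + 0.178 * rows$is_soz +
                             pint[rows$patient_id] + rnorm(nrow(rows), 0, 0.15))
  fit <- fit_feature_lmm(rows)
  soz <- fit$coefficients[fit$coefficients$term == "soz", ]
  expect_equal(soz$estimate, 0.178, tolerance = 0.05)
  expect_true(soz$ci_lo < 0.178 && soz$ci_hi > 0.178)
  expect_false(fit$singular)
})

test_that("rank-sum p-values and Holm adjustment match hand computations", {
  # exhaustive 3v3 extreme allocation: two-sided exact p = 2/20 = 0.1
  out <- ranksum_holm(list(a = c(1, 2, 3), b = c(10, 11, 12)),
                      list(c("a", "b")))
  expect_equal(out$p_raw, 0.1)
  # identical groups: p = 1, nothing rejected
  same <- ranksum_holm(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                       list(c("a", "b")))
  expect_equal(same$p_raw, 1)
  expect_false(same$reject)
  # Holm step-down on p = {0.01, 0.04, 0.2}: adjusted {0.03, 0.08, 0.2}
  expect_equal(p.adjust(c(0.01, 0.04, 0.2), "holm"), c(0.03, 0.08, 0.2))
  # monotone and never below raw
  set.seed(306)
  p <- runif(6)
  adj <- p.adjust(p, "holm")
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("PCA of global measures is standardized and sign-deterministic", {
  set.seed(307)
  # variation along one axis only: PC1 explains everything
  base <- rnorm(20)
  m <- cbind(a = base, b = 2 * base, c = -base) +
    matrix(rnorm(60, 0, 1e-9), 20)
  pc <- pca_measures(m)
  expect_gt(pc$explained[1], 0.999)
  expect_equal(sum(pc$explained), 1)
  # orthonormal loadings, diagonal score covariance
  expect_equal(crossprod(pc$loadings), diag(3), ignore_attr = TRUE,
               tolerance = 1e-9)
  mm <- matrix(rnorm(90), 30)
  colnames(mm) <- c("a", "b", "c")
  pc2 <- pca_measures(mm)
  cv <- cov(pc2$scores)
  expect_equal(cv, diag(diag(cv)), ignore_attr = TRUE, tolerance = 1e-9)
  # deterministic sign: largest loading positive
  expect_true(all(apply(pc2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # planted dominant direction recovered within 5 degrees
  dir <- c(1, 2, -1) / sqrt(6)
  scores <- rnorm(40, 0, 5)
  planted <- outer(scores, dir) + matrix(rnorm(120, 0, 0.2), 40)
  colnames(planted) <- c("a", "b", "c")
  # standardization rescales axes; compare in the standardized frame
  zs <- scale(planted)
  pcz <- prcomp(zs)
  pc3 <- pca_measures(planted)
  ang <- acos(abs(sum(pc3$loadings[, 1] * pcz$rotation[, 1]))) * 180 / pi
  expect_lt(ang, 5)
  # missing rows excluded and reported
  withmiss <- planted
  withmiss[3, 2] <- NA
  rownames(withmiss) <- sprintf("P%d", 1:40)
  pc4 <- pca_measures(withmiss)
  expect_equal(pc4$excluded, "P3")
  expect_equal(nrow(pc4$scores), 39)
})

test_that("exact binomial CI matches the Clopper-Pearson bounds", {
  ci <- binom_ci(0, 10)
  expect_equal(ci[["lo"]], 0)
  expect_equal(ci[["hi"]], 0.3085, tolerance = 1e-4)
  expect_equal(binom_ci(10, 10)[["hi"]], 1.0)
  ci5 <- binom_ci(5, 10)
  expect_equal(ci5[["lo"]], 1 - ci5[["hi"]], tolerance = 1e-12)
})
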