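test_that("logistic fits reproduce closed forms and the score equations", {
  # intercept-only: beta0 = log odds of the event rate
  y <- rep(c(1, 0), c(30, 70))
  fit0 <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(unname(coef(fit0)[1]), log(0.3 / 0.7), tolerance = 1e-8)
  # single binary covariate: slope = log odds ratio ln(ad/bc)
  a <- 20; b <- 30; c_ <- 10; d <- 40
  y2 <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
  x2 <- c(rep(1, a + b), rep(0, c_ + d))
  fit2 <- fit_logistic(y2, data.frame(x = x2))
  expect_equal(unname(coef(fit2)["x"]), log(a * d / (b * c_)),
               tolerance = 1e-8)
  # score equations X'(y - p) ~ 0 at convergence
  set.seed(5)
  X <- data.frame(x1 = stats::rnorm(300), x2 = stats::rbinom(300, 1, 0.4))
  y3 <- stats::rbinom(300, 1, stats::plogis(-1 + X$x1 - 0.5 * X$x2))
  fit3 <- fit_logistic(y3, X)
  resid <- y3 - fit3$fitted
  grad <- crossprod(cbind(1, as.matrix(X)), resid)
  expect_lt(max(abs(grad)), 1e-6)
  expect_true(fit3$converged)
  # covariance symmetric positive semi-definite
  expect_equal(fit3$vcov, t(fit3$vcov))
  expect_true(all(eigen(fit3$vcov, symmetric = TRUE)$values > -1e-12))
  # degenerate inputs rejected
  expect_error(fit_logistic(rep(1, 50), data.frame(x = stats::rnorm(50))),
               "identical")
})

test_that("perfect separation is detected and reported, not masked", {
  y <- rep(c(0, 1), each = 25)
  x <- c(stats::rnorm(25, -3), stats::rnorm(25, 3))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_true(fit$separation)
})

test_that("stepwise keeps signal, drops noise, and terminates", {
  set.seed(101)
  n <- 800
  signal <- stats::rnorm(n)
  noise <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * signal))
  sel <- stepwise_select(y, data.frame(signal = signal, noise = noise))
  expect_identical(sel$terms, "signal")
  # all-noise candidates: empty model with high probability; check the
  # family-wise entry rate over replicates stays near the nominal level
  set.seed(202)
  kept <- vapply(1:40, function(i) {
    yy <- stats::rbinom(300, 1, 0.2)
    Xn <- data.frame(a = stats::rnorm(300), b = stats::rnorm(300))
    length(stepwise_select(yy, Xn)$terms) > 0
  }, logical(1))
  # family-wise type-I ~ 1 - (1 - 0.05)^2 ~ 0.0975; allow 3 binomial SEs
  expect_lt(mean(kept), 0.0975 + 3 * sqrt(0.0975 * 0.9025 / 40))
})

test_that("stepwise over the MSI covariates recovers the generating terms", {
  cases <- generate_severe_cases(6000, simulation_config(), seed = 31)
  cov <- derive_covariates(cases)
  sel <- stepwise_select(as.integer(cases$died),
                         as.data.frame(cov[paste0("x", 1:7)]))
  # the dominant generating covariates must be retained at this n
  expect_true(all(c("x1", "x5", "x6") %in% sel$terms))
  expect_true(length(sel$steps) <= 50)
})

test_that("Hosmer-Lemeshow behaves at its closed-form anchors", {
  # perfectly calibrated groups: chi2 = 0
  p <- rep(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.85, 0.9), each = 20)
  y <- unlist(lapply(unique(p), function(q) {
    rep(c(1, 0), c(round(20 * q), 20 - round(20 * q)))
  }))
  out <- hosmer_lemeshow(y, p, groups = 10)
  expect_equal(out$chi2, 0, tolerance = 1e-9)
  expect_equal(out$df, 8L) # groups - 2
  expect_equal(out$p_value, 1)
  expect_error(hosmer_lemeshow(c(0, 1), c(0.1, 0.9), groups = 10), "at least")
})

test_that("Nagelkerke R2 matches a brute-force likelihood oracle", {
  set.seed(9)
  x <- stats::rnorm(120)
  y <- stats::rbinom(120, 1, stats::plogis(0.8 * x))
  fit <- fit_logistic(y, data.frame(x = x))
  # oracle: likelihoods recomputed directly from probabilities
  p_hat <- fit$fitted
  ll <- sum(log(ifelse(y == 1, p_hat, 1 - p_hat)))
  p0 <- mean(y)
  ll0 <- sum(log(ifelse(y == 1, p0, 1 - p0)))
  n <- length(y)
  oracle <- (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(fit), oracle, tolerance = 1e-10)
  expect_gte(nagelkerke_r2(fit), 0)
  expect_lte(nagelkerke_r2(fit), 1)
  # null model: exactly zero
  fit0 <- fit_logistic(y, data.frame(row.names = seq_along(y)))
  expect_equal(nagelkerke_r2(fit0), 0, tolerance = 1e-12)
  # near-separation: approaches 1
  ys <- rep(c(0, 1), each = 30)
  xs <- c(stats::rnorm(30, -4), stats::rnorm(30, 4))
  fits <- fit_logistic(ys, data.frame(x = xs))
  expect_gt(nagelkerke_r2(fits), 0.95)
})

test_that("auroc equals the O(n^2) concordance oracle and matches pROC", {
  set.seed(13)
  n <- 300
  y <- stats::rbinom(n, 1, 0.3)
  p <- stats::plogis(stats::rnorm(n) + 2 * y) # informative with ties unlikely
  p <- round(p, 2) # force some ties
  got <- auroc(y, p)
  # brute force over all death/survivor pairs
  pos <- p[y == 1]; neg <- p[y == 0]
  conc <- 0
  for (i in seq_along(pos)) {
    for (j in seq_along(neg)) {
      conc <- conc + (pos[i] > neg[j]) + 0.5 * (pos[i] == neg[j])
    }
  }
  expect_equal(got$point, conc / (length(pos) * length(neg)),
               tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::roc(y, p, quiet = TRUE, direction = "<")
  expect_equal(got$point, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(got$lo, got$hi), ci[c(1, 3)], tolerance = 1e-6)
})

test_that("auroc endpoints: perfect separation and uninformative scores", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(auroc(y, y * 1.0)$point, 1.0)
  set.seed(21)
  big_y <- stats::rbinom(20000, 1, 0.3)
  null_auc <- auroc(big_y, stats::runif(20000))$point
  expect_equal(null_auc, 0.5, tolerance = 0.02)
  expect_error(auroc(rep(1, 10), stats::runif(10)), "both")
})

test_that("the development/testing split is seeded, sized and exclusive", {
  cohort <- make_cases(rep(list("shock"), 1000))
  sp <- split_cohort(cohort, 0.8, seed = 17)
  expect_equal(nrow(sp$a), 800L)
  expect_equal(nrow(sp$b), 200L)
  expect_length(intersect(sp$a$case_id, sp$b$case_id), 0L)
  sp2 <- split_cohort(cohort, 0.8, seed = 17)
  expect_identical(sp$a$case_id, sp2$a$case_id)
  expect_error(split_cohort(cohort, 1), "between 0 and 1")
  expect_error(split_cohort(cohort, 0.8), "seed")
  # n = 9555 at 80%: the allocation the published study drew from
  big <- make_cases(rep(list(character(0)), 9555))
  expect_equal(nrow(split_cohort(big, 0.8, seed = 1)$a), round(0.8 * 9555))
})

test_that("AUROC sample size scales as the normal approximation predicts", {
  # balanced design at the published alpha/beta/AUCs: 14 deaths, 28 in total
  n1 <- auroc_sample_size(neg_pos_ratio = 1)
  expect_equal(n1, 14L)
  expect_equal(2L * n1, 28L)
  # vanishing effect: requirement blows up
  expect_gt(auroc_sample_size(auc_alt = 0.52, neg_pos_ratio = 1), 2000)
  # doubling the AUC difference cuts n by roughly 4x
  n_small <- auroc_sample_size(auc_alt = 0.575, neg_pos_ratio = 5)
  n_big <- auroc_sample_size(auc_alt = 0.65, neg_pos_ratio = 5)
  expect_gt(n_small / n_big, 3)
  expect_lt(n_small / n_big, 5)
  expect_error(auroc_sample_size(auc_alt = 0.4, neg_pos_ratio = 1), "Require")
})

test_that("fit_msi_model exposes tidy/glance and model variants", {
  cases <- generate_severe_cases(2500, simulation_config(), seed = 77)
  fit1 <- fit_msi_model(cases, "score_only")
  expect_identical(fit1$terms, "x1")
  fit2 <- fit_msi_model(cases, "full")
  expect_identical(fit2$terms, paste0("x", 1:7))
  td <- tidy(fit2)
  expect_equal(td$term, c("(Intercept)", paste0("x", 1:7)))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit2)
  expect_equal(gl$n, 2500L)
  expect_gte(gl$nagelkerke_r2, 0)
  expect_lte(gl$nagelkerke_r2, 1)
  expect_true(gl$auroc >= 0 && gl$auroc <= 1)
  # both models discriminate strongly; the full covariate set cannot do
  # worse than the score alone under the generating model
  a1 <- glance(fit1)$auroc
  expect_gt(a1, 0.85)
  expect_gte(gl$auroc, a1)
  expect_true(gl$auroc > 0.90 && gl$auroc < 0.99)
  # predictions on new data use the fitted coefficients
  p <- predict(fit2, cases[1:10, ])
  expect_equal(p, fit2$fitted[1:10], tolerance = 1e-10)
  # round-trip into a coefficient set
  coef_set <- as_msi_coefficients(fit2)
  expect_equal(unname(coef_set["beta1"]),
               unname(coef(fit2)["x1"]))
  expect_equal(msi_probability(cases[1:5, ], coef_set), p[1:5],
               tolerance = 1e-10)
})
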