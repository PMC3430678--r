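#' Fit a logistic death-probability model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, via [stats::glm()]) of a binary death outcome on a covariate
#' matrix. This is the engine behind [fit_msi_model()] and
#' [stepwise_select()].
#'
#' Perfect or quasi-perfect separation is detected (diverging standardized
#' coefficients together with degenerate fitted probabilities) and reported
#' in the `separation` field rather than silently returned; non-convergence
#' is reported with the iteration count.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param X A data frame or matrix of covariates (no intercept column; an
#'   intercept is always included).
#' @return An object of class `msi_fit`: a list with `coefficients`, `vcov`,
#'   `loglik`, `null_loglik`, `n`, `converged`, `iterations`, `separation`,
#'   `fitted`, `y`, `terms`.
#' @examples
#' y <- rep(c(0, 1), c(70, 30))
#' fit_logistic(y, data.frame(x = seq_along(y) * 0)) # intercept-only-like
#' @export
fit_logistic <- function(y, X) {
  y <- as.integer(parse_bool(y, "y"))
  X <- as.data.frame(X)
  n <- length(y)
  if (nrow(X) != n) stop("`y` and `X` sizes differ.", call. = FALSE)
  if (n <= ncol(X) + 1L) stop("Need n > number of parameters.", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("Outcomes are all identical; the model is not estimable.",
         call. = FALSE)
  }
  dat <- cbind(.y = y, X)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      # both conditions are surfaced as structured fields on the fit
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("algorithm did not converge", msg)) {
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- stats::coef(fit)
  # standardized magnitude check for (quasi-)separation
  sds <- c(1, vapply(X, function(col) max(stats::sd(as.numeric(col)), 1e-12),
                     numeric(1)))
  separation <- sep_warn && any(abs(beta * sds) > 15, na.rm = TRUE)
  null_ll <- null_loglik_binary(y)
  structure(
    list(
      coefficients = beta,
      vcov = stats::vcov(fit),
      loglik = as.numeric(stats::logLik(fit)),
      null_loglik = null_ll,
      n = n,
      converged = fit$converged,
      iterations = fit$iter,
      separation = separation,
      fitted = as.numeric(stats::fitted(fit)),
      y = y,
      terms = names(X),
      glm = fit
    ),
    class = "msi_fit"
  )
}

null_loglik_binary <- function(y) {
  p <- mean(y)
  if (p == 0 || p == 1) return(0)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

#' Fit an MSI-style model to a cohort
#'
#' Re-derives a death-probability model from line-listed case records using
#' the MSI covariate scheme: model `"score_only"` regresses death on the
#' maternal severity score alone (model I); `"full"` uses the complete MSI
#' covariate set x1...x7 (the model II covariates); `"stepwise"` runs
#' forward-stepwise selection with likelihood-ratio tests over the same
#' candidates (entry p < 0.05, removal p > 0.10 by default).
#'
#' @param cases A case-record data frame including `died`.
#' @param model `"score_only"`, `"full"` or `"stepwise"`.
#' @param p_entry,p_removal Stepwise thresholds (used when
#'   `model = "stepwise"`).
#' @return An `msi_fit` object (see [fit_logistic()]); [generics::tidy()] and
#'   [generics::glance()] methods summarize coefficients and diagnostics.
#' @export
fit_msi_model <- function(cases, model = c("full", "score_only", "stepwise"),
                          p_entry = 0.05, p_removal = 0.10) {
  model <- match.arg(model)
  cov <- derive_covariates(cases)
  y <- parse_bool(cases$died, "died")
  X <- as.data.frame(cov[paste0("x", 1:7)])
  fit <- switch(model,
    score_only = fit_logistic(y, X["x1"]),
    full = fit_logistic(y, X),
    stepwise = stepwise_select(y, X, p_entry = p_entry,
                               p_removal = p_removal)
  )
  fit$model_name <- model
  fit
}

#' Forward-stepwise logistic selection with likelihood-ratio tests
#'
#' At each step, the candidate whose addition gives the smallest
#' likelihood-ratio p-value is entered if that p-value is below `p_entry`;
#' retained terms whose removal LR p-value exceeds `p_removal` are then
#' dropped. Iteration is capped to guarantee termination.
#'
#' @param y Binary outcome.
#' @param X Data frame of candidate covariates.
#' @param p_entry Entry threshold (default 0.05).
#' @param p_removal Removal threshold (default 0.10).
#' @param max_steps Hard cap on add/remove cycles.
#' @return An `msi_fit` for the selected model (intercept-only fits carry an
#'   empty `terms`), with the selection trace in `$steps`.
#' @export
stepwise_select <- function(y, X, p_entry = 0.05, p_removal = 0.10,
                            max_steps = 50L) {
  y <- as.integer(parse_bool(y, "y"))
  X <- as.data.frame(X)
  if (ncol(X) < 1L) stop("Need at least one candidate covariate.", call. = FALSE)
  current <- character(0)
  steps <- list()

  ll_of <- function(terms) {
    if (length(terms) == 0L) {
      list(ll = null_loglik_binary(y), fit = NULL)
    } else {
      f <- fit_logistic(y, X[terms])
      list(ll = f$loglik, fit = f)
    }
  }

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    base <- ll_of(current)
    # entry: most significant LR addition below p_entry
    pool <- setdiff(names(X), current)
    if (length(pool) > 0L) {
      p_add <- vapply(pool, function(v) {
        cand <- ll_of(c(current, v))
        stats::pchisq(2 * (cand$ll - base$ll), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (min(p_add) < p_entry) {
        add <- pool[which.min(p_add)]
        current <- c(current, add)
        steps[[length(steps) + 1L]] <- list(action = "add", term = add,
                                            p = min(p_add))
        changed <- TRUE
        base <- ll_of(current)
      }
    }
    # removal: any retained term whose LR p exceeds p_removal
    if (length(current) > 0L) {
      p_drop <- vapply(current, function(v) {
        red <- ll_of(setdiff(current, v))
        stats::pchisq(2 * (base$ll - red$ll), df = 1, lower.tail = FALSE)
      }, numeric(1))
      if (max(p_drop) > p_removal) {
        drop <- current[which.max(p_drop)]
        current <- setdiff(current, drop)
        steps[[length(steps) + 1L]] <- list(action = "remove", term = drop,
                                            p = max(p_drop))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- if (length(current) == 0L) {
    f <- stats::glm(y ~ 1, family = stats::binomial())
    structure(
      list(coefficients = stats::coef(f), vcov = stats::vcov(f),
           loglik = as.numeric(stats::logLik(f)),
           null_loglik = null_loglik_binary(y), n = length(y),
           converged = f$converged, iterations = f$iter, separation = FALSE,
           fitted = as.numeric(stats::fitted(f)), y = y,
           terms = character(0), glm = f),
      class = "msi_fit"
    )
  } else {
    fit_logistic(y, X[current])
  }
  fit$steps <- steps
  fit$model_name <- "stepwise"
  fit
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups cases into `groups` bins of predicted risk (deciles by default,
#' ties broken by a stable sort on predicted probability then case order,
#' keeping group sizes as equal as possible) and compares observed with
#' expected deaths: `chi2 = sum (O - E)^2 / (n_g * pbar * (1 - pbar))`,
#' `df = groups - 2`. A p-value below 0.05 indicates poor calibration.
#'
#' @param y Binary outcomes.
#' @param p_hat Predicted probabilities.
#' @param groups Number of risk groups (default 10).
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `groups_used`.
#' @export
hosmer_lemeshow <- function(y, p_hat, groups = 10) {
  y <- as.integer(parse_bool(y, "y"))
  n <- length(y)
  stopifnot(length(p_hat) == n)
  if (n < groups) stop("Need at least `groups` observations.", call. = FALSE)
  ord <- order(p_hat, seq_len(n))
  g <- ceiling(seq_len(n) / (n / groups))
  g <- pmin(g, groups)
  grp <- integer(n)
  grp[ord] <- g
  used <- sort(unique(grp))
  if (length(used) < groups) {
    message("Hosmer-Lemeshow: reduced to ", length(used),
            " non-empty groups.")
  }
  chi2 <- 0
  for (k in used) {
    idx <- grp == k
    ng <- sum(idx)
    O <- sum(y[idx])
    E <- sum(p_hat[idx])
    denom <- E * (1 - E / ng)
    if (denom <= 0) {
      if (abs(O - E) > 1e-12) {
        warning("Degenerate Hosmer-Lemeshow group with O != E.", call. = FALSE)
        chi2 <- Inf
      }
      next
    }
    chi2 <- chi2 + (O - E)^2 / denom
  }
  df <- length(used) - 2L
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 groups_used = length(used))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R-squared rescaled by its attainable maximum:
#' `(1 - exp(2 * (LL0 - LL) / n)) / (1 - exp(2 * LL0 / n))`.
#'
#' @param fit An `msi_fit` object.
#' @return A number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  stopifnot(inherits(fit, "msi_fit"))
  n <- fit$n
  cs <- 1 - exp(2 * (fit$null_loglik - fit$loglik) / n)
  max_cs <- 1 - exp(2 * fit$null_loglik / n)
  if (max_cs == 0) return(0)
  cs / max_cs
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' AUROC via the Mann-Whitney identity (proportion of death/survivor pairs
#' in which the death has the higher predicted risk, ties counted one half),
#' with a confidence interval by DeLong's placement-variance method.
#'
#' @param y Binary outcomes; both classes must be present.
#' @param p_hat Predicted risks or any monotone score.
#' @param level Confidence level.
#' @return A one-row tibble: `point`, `lo`, `hi`, `level`, `method`.
#' @export
auroc <- function(y, p_hat, level = 0.95) {
  y <- as.integer(parse_bool(y, "y"))
  stopifnot(length(p_hat) == length(y))
  pos <- p_hat[y == 1]
  neg <- p_hat[y == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  if (n1 == 0L || n0 == 0L) {
    stop("AUROC needs both deaths and survivors.", call. = FALSE)
  }
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), numeric(1))
  v <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(point = auc, lo = max(0, auc - z * sqrt(v)),
                 hi = min(1, auc + z * sqrt(v)), level = level,
                 method = "delong")
}

#' Random development/testing split of a cohort
#'
#' Allocates `round(fraction_a * n)` rows to subpopulation A (model
#' development) by seeded simple random sampling without stratification; the
#' remainder forms subpopulation B (model testing).
#'
#' @param cases A case-record data frame.
#' @param fraction_a Fraction allocated to A, strictly between 0 and 1
#'   (default 0.80).
#' @param seed Integer seed (mandatory; the split must be reproducible).
#' @return A list with tibbles `a` and `b`.
#' @export
split_cohort <- function(cases, fraction_a = 0.8, seed) {
  if (!(fraction_a > 0 && fraction_a < 1)) {
    stop("`fraction_a` must be strictly between 0 and 1.", call. = FALSE)
  }
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  n <- nrow(cases)
  idx <- with_seed(seed, sample.int(n, size = round(fraction_a * n)))
  list(a = tibble::as_tibble(cases[idx, , drop = FALSE]),
       b = tibble::as_tibble(cases[-idx, , drop = FALSE]))
}

#' Required positives for AUROC testing (Hanley-McNeil)
#'
#' Smallest number of positive cases (deaths) such that a two-sided test of
#' the AUROC against `auc_null` attains power `1 - beta` when the true AUROC
#' is `auc_alt`, with `neg_pos_ratio` negatives per positive. Variances are
#' the Hanley-McNeil binormal-free approximations evaluated under the null
#' and the alternative.
#'
#' @param alpha Type-I error probability (two-sided; default 0.05).
#' @param beta Type-II error probability (default 0.20).
#' @param auc_null Null AUROC (default 0.5).
#' @param auc_alt Smallest AUROC worth detecting (default 0.8).
#' @param neg_pos_ratio Negatives per positive in the testing sample.
#' @param max_pos Search cap.
#' @return Integer: required number of positives.
#' @export
auroc_sample_size <- function(alpha = 0.05, beta = 0.20, auc_null = 0.5,
                              auc_alt = 0.8, neg_pos_ratio, max_pos = 1e6) {
  if (!(auc_null >= 0.5 && auc_null < auc_alt && auc_alt < 1)) {
    stop("Require 0.5 <= auc_null < auc_alt < 1.", call. = FALSE)
  }
  if (neg_pos_ratio <= 0) stop("`neg_pos_ratio` must be positive.", call. = FALSE)
  hm_var <- function(a, n1, n0) {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    (a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) / (n1 * n0)
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(1 - beta)
  delta <- auc_alt - auc_null
  for (n1 in 2:max_pos) {
    n0 <- max(1, round(neg_pos_ratio * n1))
    se0 <- sqrt(hm_var(auc_null, n1, n0))
    se1 <- sqrt(hm_var(auc_alt, n1, n0))
    if (za * se0 + zb * se1 <= delta) return(n1)
  }
  stop("No solution below `max_pos`; the effect is too small.", call. = FALSE)
}

# run code with a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
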