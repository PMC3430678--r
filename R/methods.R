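#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
coef.msi_fit <- function(object, ...) object$coefficients

#' @export
print.msi_fit <- function(x, ...) {
  cat("<msi_fit>", if (!is.null(x$model_name)) paste0("model: ", x$model_name),
      "\n")
  cat("  n =", x$n, " deaths =", sum(x$y), "\n")
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = ", ")
      else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  if (!x$converged) cat("  WARNING: IRLS did not converge after",
                        x$iterations, "iterations\n")
  if (isTRUE(x$separation)) {
    cat("  WARNING: (quasi-)perfect separation detected;",
        "coefficients are unreliable\n")
  }
  invisible(x)
}

#' Tidy a fitted MSI-style model
#'
#' @param x An `msi_fit` object.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `conf_low`, `conf_high`.
#' @method tidy msi_fit
#' @export
tidy.msi_fit <- function(x, conf_level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(est - q * se), conf_high = unname(est + q * se)
  )
}

#' One-row fit diagnostics for an MSI-style model
#'
#' @param x An `msi_fit` object.
#' @param hl_groups Number of Hosmer-Lemeshow risk groups.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_deaths`, `loglik`, `null_loglik`,
#'   `nagelkerke_r2`, `hl_chi2`, `hl_p`, `auroc`, `auroc_lo`, `auroc_hi`,
#'   `pct_deaths_pred_gt_half`, `converged`, `separation`.
#' @method glance msi_fit
#' @export
glance.msi_fit <- function(x, hl_groups = 10, ...) {
  hl <- hosmer_lemeshow(x$y, x$fitted, groups = hl_groups)
  roc <- auroc(x$y, x$fitted)
  tibble::tibble(
    n = x$n, n_deaths = sum(x$y), loglik = x$loglik,
    null_loglik = x$null_loglik,
    nagelkerke_r2 = nagelkerke_r2(x),
    hl_chi2 = hl$chi2, hl_p = hl$p_value,
    auroc = roc$point, auroc_lo = roc$lo, auroc_hi = roc$hi,
    pct_deaths_pred_gt_half = mean(x$fitted[x$y == 1] > 0.5),
    converged = x$converged, separation = x$separation
  )
}

#' Predict death probabilities from a fitted MSI-style model
#'
#' @param object An `msi_fit` fitted by [fit_msi_model()] or on MSI
#'   covariates.
#' @param newdata Either a case-record data frame (covariates are derived
#'   with [derive_covariates()]) or a data frame already holding the model's
#'   covariate columns.
#' @param ... Unused.
#' @return Numeric vector of predicted probabilities.
#' @export
predict.msi_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  X <- if (all(object$terms %in% names(newdata))) {
    as.data.frame(newdata)[object$terms]
  } else {
    as.data.frame(derive_covariates(newdata))[object$terms]
  }
  eta <- object$coefficients[["(Intercept)"]]
  for (v in object$terms) {
    eta <- eta + object$coefficients[[v]] * as.numeric(X[[v]])
  }
  stats::plogis(eta)
}

#' Export a fitted model as an MSI coefficient set
#'
#' Maps a fit over the x1...x7 covariates (or a subset; absent terms get a
#' zero coefficient) onto the `beta0` ... `beta7` layout accepted by
#' [msi_coefficients()], so refitted models can drive [add_msi()] and the
#' benchmarking functions.
#'
#' @param fit An `msi_fit` whose terms are among x1...x7.
#' @return A named numeric vector `beta0` ... `beta7`.
#' @export
as_msi_coefficients <- function(fit) {
  stopifnot(inherits(fit, "msi_fit"))
  bad <- setdiff(fit$terms, paste0("x", 1:7))
  if (length(bad) > 0L) {
    stop("Fit has terms outside the MSI covariate scheme: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- c(beta0 = unname(fit$coefficients[["(Intercept)"]]),
           stats::setNames(rep(0, 7), paste0("beta", 1:7)))
  for (v in fit$terms) {
    out[[sub("^x", "beta", v)]] <- unname(fit$coefficients[[v]])
  }
  attr(out, "set_name") <- "refit"
  out
}
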