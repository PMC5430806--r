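#' Age-residualized fertility via Poisson regression
#'
#' Living-offspring counts confound fertility with maternal age, so the
#' analysis removes the age effect first: a Poisson regression with log
#' link and linear predictor `intercept + b1*age + b2*age^2` captures the
#' quadratic age-fertility curve, and response-scale residuals
#' (observed minus fitted counts) carry the age-adjusted reproductive
#' success. A residual of 0 is a mother with the average number of living
#' offspring for her age; the model is fitted once per population.
#'
#' Fitting is maximum likelihood by iteratively reweighted least squares,
#' followed by Newton polishing of the score equations to below `1e-10`, so
#' the score identities `sum(r) = sum(r*age) = sum(r*age^2) = 0` hold to
#' numerical precision in the residuals (this is what makes the residuals
#' exactly age-orthogonal).
#'
#' @param mothers data frame with columns `id`, `age` and
#'   `n_living_offspring`; at least 10 mothers spanning at least 3 distinct
#'   ages.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter IRLS iteration cap; non-convergence is an error carrying
#'   the deviance trace.
#' @return object of class `age_fertility_fit` with components
#'   `coefficients` (intercept, age, age2), `fitted` (named by mother id),
#'   `deviance`, `trace` (per-iteration deviance), `converged`, `n`.
#' @examples
#' m <- data.frame(id = as.character(1:40), age = rep(18:37, 2),
#'                 n_living_offspring = rpois(40, 3))
#' fit <- fit_age_fertility(m)
#' coef(fit)
#' @export
fit_age_fertility <- function(mothers, tol = 1e-8, max_iter = 50) {
  need <- c("id", "age", "n_living_offspring")
  if (!all(need %in% names(mothers)))
    stop("mothers table needs columns: ", paste(need, collapse = ", "))
  y <- mothers$n_living_offspring
  age <- mothers$age
  if (length(y) < 10) stop("need at least 10 mothers to fit the age curve")
  if (length(unique(age)) < 3) stop("need at least 3 distinct ages")
  if (any(is.na(y)) || any(y < 0)) stop("offspring counts must be nonnegative")

  X <- cbind(intercept = 1, age = age, age2 = age^2)
  beta <- c(log(mean(y) + 0.1), 0, 0)
  dev_fun <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  trace <- numeric(0)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    fit <- lm.wfit(X, z, w = mu)
    beta <- fit$coefficients
    mu <- exp(drop(X %*% beta))
    dev <- dev_fun(mu)
    trace <- c(trace, dev)
    if (is.finite(dev_old) && abs(dev - dev_old) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter, " iterations; deviance trace: ",
         paste(sprintf("%.6g", trace), collapse = " -> "))
  }
  # Newton polish: drive the score X'(y - mu) to ~machine zero so the
  # residual orthogonality identities are exact
  for (it in seq_len(25)) {
    mu <- exp(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < 1e-10) break
    info <- crossprod(X, X * mu)
    beta <- beta + solve(info, score)
  }
  mu <- exp(drop(X %*% beta))

  out <- list(
    coefficients = setNames(as.numeric(beta), c("intercept", "age", "age2")),
    fitted = setNames(mu, mothers$id),
    ids = as.character(mothers$id),
    age = age,
    y = y,
    deviance = dev_fun(mu),
    trace = trace,
    converged = TRUE,
    n = length(y)
  )
  class(out) <- "age_fertility_fit"
  out
}

#' @export
print.age_fertility_fit <- function(x, ...) {
  cat("Poisson age-fertility curve (log link):\n")
  cat(sprintf("  log E[offspring] = %.4f + %.4f*age + %.6f*age^2\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  n = %d mothers, deviance %.3f, %d IRLS iteration(s)\n",
              x$n, x$deviance, length(x$trace)))
  invisible(x)
}

#' @export
coef.age_fertility_fit <- function(object, ...) object$coefficients

#' @export
fitted.age_fertility_fit <- function(object, ...) object$fitted

#' @export
residuals.age_fertility_fit <- function(object, ...) {
  setNames(object$y - object$fitted, object$ids)
}

#' @export
predict.age_fertility_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  b <- object$coefficients
  exp(b[1] + b[2] * newdata$age + b[3] * newdata$age^2)
}

#' Response-scale fertility residuals
#'
#' `residual_i = observed_i - fitted_i` on the count scale: positive values
#' are above-average reproductive success for one's age. By the Poisson
#' score equations the residuals sum to zero and are exactly orthogonal to
#' age and age squared.
#'
#' @param mothers mothers data frame (same population as `fit`).
#' @param fit an [fit_age_fertility()] result.
#' @return data frame `id, residual`.
#' @export
fertility_residuals <- function(mothers, fit) {
  stopifnot(inherits(fit, "age_fertility_fit"))
  idx <- match(as.character(mothers$id), fit$ids)
  if (anyNA(idx)) {
    stop("mother(s) absent from fit: ",
         paste(mothers$id[is.na(idx)], collapse = ", "))
  }
  data.frame(id = as.character(mothers$id),
             residual = mothers$n_living_offspring - unname(fit$fitted[idx]),
             stringsAsFactors = FALSE)
}
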