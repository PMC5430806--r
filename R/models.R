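# Standardized regression suite: single-centrality fertility models with
# age-interaction pruning, VIF-guarded joint models, and sickness models
# with a dependent-count mediation check.

.is_binary <- function(x) all(x %in% c(0, 1) | is.na(x))

#' Two-standard-deviation predictor standardization
#'
#' Continuous predictors are centered at their in-sample mean and divided
#' by twice their sample SD; binary predictors are left untransformed. A
#' one-unit change in a standardized continuous predictor then spans two
#' SDs, which puts its coefficient on the same footing as a 0/1 binary
#' predictor, so all betas in a model are directly comparable. Interaction
#' columns must be built from the standardized mains.
#'
#' @param data data frame.
#' @param cols columns to standardize (binary columns among them are
#'   passed through).
#' @return `data` with the named columns transformed; centers and scales
#'   are attached as attributes `centers` and `scales`.
#' @export
two_sd_standardize <- function(data, cols) {
  centers <- scales <- setNames(numeric(0), character(0))
  for (cl in cols) {
    x <- data[[cl]]
    if (is.null(x)) stop("no such column: ", cl)
    if (.is_binary(x)) next
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("zero-variance continuous predictor: ", cl)
    centers[cl] <- mean(x)
    scales[cl] <- 2 * s
    data[[cl]] <- (x - mean(x)) / (2 * s)
  }
  attr(data, "centers") <- centers
  attr(data, "scales") <- scales
  data
}

# Fit an OLS model from a prepared model frame and wrap it.
.fit_ols <- function(frame, formula, spec) {
  fit <- lm(formula, data = frame)
  mm <- stats::model.matrix(fit)
  if (fit$rank < ncol(mm)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  tab <- data.frame(
    term = rownames(sm$coefficients),
    beta = sm$coefficients[, 1],
    ci_lo = ci[, 1],
    ci_hi = ci[, 2],
    p = sm$coefficients[, 4],
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  out <- list(
    fit = fit,
    terms = tab,
    adj_r2 = sm$adj.r.squared,
    n = nrow(frame),
    spec = spec,
    vif = NULL,
    interaction_retained = NA
  )
  class(out) <- "centrality_fit"
  out
}

.term_row <- function(object, term) {
  i <- match(term, object$terms$term)
  if (is.na(i)) stop("no term '", term, "' in model")
  object$terms[i, , drop = FALSE]
}

#' Single-centrality fertility model
#'
#' OLS regression of age-residualized living-offspring counts on one
#' two-SD standardized camp-z centrality measure, with camp indicator
#' variables absorbing camp-level mean differences and, optionally, a
#' centrality-by-age interaction (age mean-centered and two-SD
#' standardized; the age main effect is included whenever the interaction
#' is). Returns standardized coefficients with analytic 95% CIs, p-values
#' from the t distribution on residual degrees of freedom, and adjusted
#' R-squared.
#'
#' @param data analysis table with columns `residual`, `age`, `camp` and
#'   `z_<measure>` (see [mother_table()]).
#' @param measure one of `"degree"`, `"strength"`, `"ec"`,
#'   `"betweenness"`, `"closeness"`.
#' @param interaction include the centrality-by-age interaction?
#' @return an object of class `centrality_fit`; see [summary.centrality_fit()].
#' @seealso [prune_interaction()], [fit_joint_model()]
#' @export
fit_fertility_model <- function(data, measure, interaction = FALSE) {
  zcol <- paste0("z_", measure)
  need <- c("residual", "age", "camp", zcol)
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  if (nrow(data) < 4 + interaction) stop("too few rows to fit")
  frame <- data.frame(.outcome = data$residual,
                      m = data[[zcol]],
                      age = data$age,
                      camp = factor(data$camp))
  names(frame)[names(frame) == "m"] <- measure
  frame <- two_sd_standardize(frame, c(measure, "age"))
  rhs <- measure
  if (interaction) rhs <- c(rhs, "age", paste0(measure, ":age"))
  if (nlevels(frame$camp) > 1) rhs <- c(rhs, "camp")
  f <- stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  out <- .fit_ols(frame, f, spec = list(
    type = "fertility", data = data, measure = measure,
    interaction = interaction
  ))
  if (interaction) out$interaction_retained <- TRUE
  out
}

#' Drop an insignificant centrality-by-age interaction
#'
#' If the interaction term's p-value exceeds `threshold` (default 0.05) the
#' model is refitted without it and returned with
#' `interaction_retained = FALSE`; otherwise the original model is returned
#' flagged `TRUE`. Only the pruned (reported) model should be interpreted.
#'
#' @param model a `centrality_fit` fitted with an interaction.
#' @param threshold pruning p-value threshold.
#' @return a `centrality_fit`.
#' @export
prune_interaction <- function(model, threshold = 0.05) {
  stopifnot(inherits(model, "centrality_fit"))
  if (!isTRUE(model$spec$interaction))
    stop("model was not fitted with an interaction")
  int_term <- grep(":", model$terms$term, value = TRUE)
  p_int <- .term_row(model, int_term[1])$p
  if (p_int > threshold) {
    refit <- switch(model$spec$type,
      fertility = fit_fertility_model(model$spec$data, model$spec$measure,
                                      interaction = FALSE),
      sickness = fit_sickness_model(model$spec$data, model$spec$measure,
                                    include_dependents = model$spec$include_dependents,
                                    interaction = FALSE),
      stop("cannot refit model type ", model$spec$type))
    refit$interaction_retained <- FALSE
    refit
  } else {
    model$interaction_retained <- TRUE
    model
  }
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all the others (with intercept). A VIF of 1 means the predictor
#' is orthogonal to the rest in-sample; values above 2.5 flag collinearity
#' strong enough to destabilize coefficient estimates in these small
#' samples.
#'
#' @param design data frame or matrix of predictor columns (include camp
#'   indicator columns as regressors via `assess` if desired).
#' @param assess columns to report VIFs for (default all); the auxiliary
#'   regressions always use every column.
#' @return named numeric vector of VIFs (`Inf`, with a warning, under
#'   perfect collinearity).
#' @export
compute_vif <- function(design, assess = NULL) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("VIF needs at least 2 predictors")
  if (is.null(assess)) assess <- colnames(X)
  out <- setNames(numeric(length(assess)), assess)
  for (j in assess) {
    y <- X[, j]
    others <- X[, setdiff(colnames(X), j), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) {
      warning("perfect collinearity: VIF for '", j, "' is infinite")
      out[j] <- Inf
    } else {
      out[j] <- 1 / (1 - r2)
    }
  }
  out
}

#' Joint degree + betweenness + closeness fertility model
#'
#' Because the centrality measures co-vary, they are first modelled one at
#' a time; the joint model then pits degree, betweenness and closeness
#' against each other, guarded by a variance-inflation-factor check so the
#' joint betas are not collinearity artefacts. With `vif_mode = "abort"`
#' any VIF above `vif_limit` (default 2.5) is an error; with `"warn"` the
#' model is fitted and flagged.
#'
#' @param data analysis table (see [fit_fertility_model()]).
#' @param measures centrality measures entered jointly.
#' @param vif_mode `"warn"` or `"abort"`.
#' @param vif_limit collinearity ceiling.
#' @return a `centrality_fit` with a `vif` component.
#' @export
fit_joint_model <- function(data, measures = c("degree", "betweenness", "closeness"),
                            vif_mode = c("warn", "abort"), vif_limit = 2.5) {
  vif_mode <- match.arg(vif_mode)
  zcols <- paste0("z_", measures)
  need <- c("residual", "camp", zcols)
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  frame <- data.frame(.outcome = data$residual, camp = factor(data$camp))
  for (k in seq_along(measures)) frame[[measures[k]]] <- data[[zcols[k]]]
  frame <- two_sd_standardize(frame, measures)

  pred <- frame[, measures, drop = FALSE]
  if (nlevels(frame$camp) > 1) {
    cm <- stats::model.matrix(~camp, frame)[, -1, drop = FALSE]
    pred <- cbind(pred, cm)
  }
  vif <- compute_vif(pred, assess = measures)
  if (any(vif > vif_limit)) {
    msg <- paste0("VIF above ", vif_limit, ": ",
                  paste(sprintf("%s=%.2f", names(vif)[vif > vif_limit],
                                vif[vif > vif_limit]), collapse = ", "))
    if (vif_mode == "abort") stop("collinearity check failed; ", msg)
    warning(msg)
  }
  rhs <- measures
  if (nlevels(frame$camp) > 1) rhs <- c(rhs, "camp")
  f <- stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  out <- .fit_ols(frame, f, spec = list(
    type = "joint", data = data, measures = measures
  ))
  out$vif <- vif
  out
}

#' Sickness model for mothers
#'
#' OLS regression of the reported sickness count (0--2 instances over two
#' weeks) on one two-SD standardized centrality measure, controlling for
#' maternal age, whether the camp is settled, individual mobility and
#' household belongings -- covariates with known links to health in these
#' populations. Setting `include_dependents = TRUE` adds the number of
#' living dependents, which tests whether a centrality association is
#' carried by family size ([mediation_check()]). The 0--2 count is
#' modelled by OLS so betas, like the fertility models', are standardized
#' linear coefficients with symmetric CIs; `family = "poisson"` fits a
#' log-link count model instead for sensitivity analysis.
#'
#' @param data mothers analysis table with `sickness_count`, `age`,
#'   `settled`, `mobile`, `belongings`, `n_dependents` and `z_<measure>`.
#' @param measure centrality measure.
#' @param include_dependents add the living-dependents control?
#' @param interaction include a centrality-by-age interaction?
#' @param family `"gaussian"` (OLS, default) or `"poisson"`.
#' @return a `centrality_fit`.
#' @export
fit_sickness_model <- function(data, measure, include_dependents = FALSE,
                               interaction = FALSE,
                               family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  zcol <- paste0("z_", measure)
  need <- c("sickness_count", "age", "settled", "mobile", "belongings",
            "n_dependents", zcol)
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  if (all(data$sickness_count == 0) || sd(data$sickness_count) == 0)
    stop("degenerate outcome: sickness counts have no variance")
  frame <- data.frame(.outcome = data$sickness_count,
                      m = data[[zcol]],
                      age = data$age,
                      settled = data$settled,
                      mobile = data$mobile,
                      belongings = data$belongings)
  names(frame)[names(frame) == "m"] <- measure
  std_cols <- c(measure, "age", "belongings")
  if (include_dependents) {
    frame$dependents <- data$n_dependents
    std_cols <- c(std_cols, "dependents")
  }
  frame <- two_sd_standardize(frame, std_cols)
  rhs <- c(measure, "age", "settled", "mobile", "belongings")
  if (include_dependents) rhs <- c(rhs, "dependents")
  if (interaction) rhs <- c(rhs, paste0(measure, ":age"))
  f <- stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")))
  if (family == "poisson") {
    fit <- stats::glm(f, data = frame, family = stats::poisson())
    sm <- summary(fit)
    ci <- suppressMessages(suppressWarnings(stats::confint.default(fit)))
    tab <- data.frame(term = rownames(sm$coefficients),
                      beta = sm$coefficients[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm$coefficients[, 4], stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    out <- list(fit = fit, terms = tab, adj_r2 = NA_real_, n = nrow(frame),
                spec = list(type = "sickness", data = data, measure = measure,
                            include_dependents = include_dependents,
                            interaction = interaction, family = family),
                vif = NULL, interaction_retained = NA)
    class(out) <- "centrality_fit"
  } else {
    out <- .fit_ols(frame, f, spec = list(
      type = "sickness", data = data, measure = measure,
      include_dependents = include_dependents, interaction = interaction,
      family = family
    ))
  }
  if (interaction) out$interaction_retained <- TRUE
  out
}

#' Mediation-by-attenuation check
#'
#' Compares a centrality coefficient before and after adding the
#' living-dependents term: `attenuation = 1 - beta_with / beta_without`.
#' An attenuation near 1 with a post-inclusion p above 0.05 indicates the
#' centrality association is carried by family size; attenuation near 0
#' indicates an association independent of it. This is covariate-adjustment
#' attenuation, not a causal indirect-effect estimate.
#'
#' @param model_without,model_with `centrality_fit`s on the same data and
#'   measure, differing only by the dependents term.
#' @return object of class `mediation_check`.
#' @export
mediation_check <- function(model_without, model_with) {
  stopifnot(inherits(model_without, "centrality_fit"),
            inherits(model_with, "centrality_fit"))
  if (model_without$n != model_with$n)
    stop("models were fitted on different samples (n = ",
         model_without$n, " vs ", model_with$n, ")")
  m1 <- model_without$spec$measure
  m2 <- model_with$spec$measure
  if (!identical(m1, m2))
    stop("models use different centrality measures: ", m1, " vs ", m2)
  b0 <- .term_row(model_without, m1)
  b1 <- .term_row(model_with, m2)
  out <- list(
    measure = m1,
    beta_without = b0$beta, p_without = b0$p,
    beta_with = b1$beta, p_with = b1$p,
    attenuation = 1 - b1$beta / b0$beta,
    significant_before = b0$p < 0.05,
    significant_after = b1$p < 0.05
  )
  class(out) <- "mediation_check"
  out
}

#' @export
print.mediation_check <- function(x, ...) {
  cat(sprintf("Mediation check for %s:\n", x$measure))
  cat(sprintf("  without dependents: beta = %.3f (p = %.3g)%s\n",
              x$beta_without, x$p_without,
              if (x$significant_before) " *" else ""))
  cat(sprintf("  with dependents:    beta = %.3f (p = %.3g)%s\n",
              x$beta_with, x$p_with,
              if (x$significant_after) " *" else ""))
  cat(sprintf("  proportional attenuation: %.1f%%\n", 100 * x$attenuation))
  invisible(x)
}

# ---- centrality_fit methods -------------------------------------------------

#' @export
print.centrality_fit <- function(x, ...) {
  type <- x$spec$type
  cat(sprintf("Standardized %s model (n = %d)\n", type, x$n))
  tab <- x$terms[!grepl("^camp", x$terms$term) & x$terms$term != "(Intercept)", ,
                 drop = FALSE]
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-22s beta %8.3f  [%.3f, %.3f]  p %s\n",
                tab$term[i], tab$beta[i], tab$ci_lo[i], tab$ci_hi[i],
                format.pval(tab$p[i], digits = 3, eps = 1e-4)))
  }
  if (!is.na(x$adj_r2)) cat(sprintf("  adjusted R^2 %.3f\n", x$adj_r2))
  if (!is.null(x$vif)) {
    cat("  VIF: ", paste(sprintf("%s %.2f", names(x$vif), x$vif),
                         collapse = ", "), "\n")
  }
  if (!is.na(x$interaction_retained)) {
    cat("  age interaction", if (x$interaction_retained) "retained" else "pruned (p > 0.05)", "\n")
  }
  invisible(x)
}

#' Summarize a standardized centrality model
#'
#' @param object a `centrality_fit`.
#' @param ... unused.
#' @return the full term table with adjusted R-squared, VIFs and the
#'   interaction flag as attributes.
#' @export
summary.centrality_fit <- function(object, ...) {
  out <- object$terms
  attr(out, "adj_r2") <- object$adj_r2
  attr(out, "n") <- object$n
  attr(out, "vif") <- object$vif
  attr(out, "interaction_retained") <- object$interaction_retained
  class(out) <- c("summary.centrality_fit", "data.frame")
  out
}

#' @export
print.summary.centrality_fit <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (!is.na(attr(x, "adj_r2")))
    cat(sprintf("adjusted R^2 %.3f, n = %d\n", attr(x, "adj_r2"), attr(x, "n")))
  invisible(x)
}

#' @export
coef.centrality_fit <- function(object, ...) {
  setNames(object$terms$beta, object$terms$term)
}

#' @export
confint.centrality_fit <- function(object, parm, level = 0.95, ...) {
  if (missing(parm)) confint(object$fit, level = level)
  else confint(object$fit, parm = parm, level = level)
}

#' @export
residuals.centrality_fit <- function(object, ...) residuals(object$fit)

#' @export
predict.centrality_fit <- function(object, ...) predict(object$fit, ...)

#' @export
plot.centrality_fit <- function(x, ...) {
  m <- x$spec$measure
  if (is.null(m)) m <- x$spec$measures[1]
  frame <- stats::model.frame(x$fit)
  xx <- frame[[m]]
  yy <- frame$.outcome
  plot(xx, yy, xlab = paste(m, "(two-SD standardized camp z-score)"),
       ylab = if (x$spec$type == "sickness") "sickness count"
              else "age-residualized living offspring",
       pch = 19, col = "grey35", ...)
  b <- coef(x$fit)
  graphics::abline(a = b["(Intercept)"], b = b[m], lwd = 2)
  invisible(x)
}

#' Write tidy model coefficients
#'
#' One row per term:
#' `population,model,term,beta,ci_lo,ci_hi,p,adj_r2,vif,interaction_retained`.
#'
#' @param fits named list of `centrality_fit`s.
#' @param path output CSV path.
#' @param population population label.
#' @export
write_model_results <- function(fits, path, population = "A") {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(population = population, model = nm, f$terms,
               adj_r2 = f$adj_r2,
               vif = if (is.null(f$vif)) NA_real_
                     else f$vif[match(f$terms$term, names(f$vif))],
               interaction_retained = f$interaction_retained,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
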