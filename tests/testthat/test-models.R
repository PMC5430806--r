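# analysis-table fixture with controllable structure
fixture_mothers <- function(n = 60, camps = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    id = sprintf("m%03d", seq_len(n)),
    camp = rep(sprintf("c%d", seq_len(camps)), length.out = n),
    age = runif(n, 18, 55),
    residual = rnorm(n, 0, 2),
    z_degree = rnorm(n), z_strength = rnorm(n), z_ec = rnorm(n),
    z_betweenness = rnorm(n), z_closeness = rnorm(n),
    sickness_count = rbinom(n, 2, 0.4),
    n_dependents = rpois(n, 3),
    settled = rbinom(n, 1, 0.5), mobile = rbinom(n, 1, 0.3),
    belongings = rlnorm(n), stringsAsFactors = FALSE
  )
}

test_that("two-SD standardization transforms continuous, spares binary", {
  d <- data.frame(x = c(6, 8, 10, 12, 14), b = c(0, 1, 0, 1, 1))
  out <- two_sd_standardize(d, c("x", "b"))
  # mean 10, SD ~3.16: value 14 maps to (14-10)/(2*sd)
  expect_equal(out$x, (d$x - 10) / (2 * sd(d$x)))
  expect_equal(out$b, d$b)
  # the worked example: a column with mean 10 and SD 2 maps 14 to 1.0
  d2 <- data.frame(x = c(8, 10, 12)) # mean 10, sample SD exactly 2
  out2 <- two_sd_standardize(d2, "x")
  expect_equal(out2$x, c(-0.5, 0, 0.5))
  expect_equal(unname((14 - attr(out2, "centers")["x"]) /
                        attr(out2, "scales")["x"]), 1.0)
  expect_error(two_sd_standardize(data.frame(x = rep(2, 5)), "x"),
               "zero-variance")
  expect_error(two_sd_standardize(d, "nope"), "no such column")
})

test_that("standardized betas equal 2*SD times raw-scale betas", {
  m <- fixture_mothers(50, camps = 1, seed = 4)
  fit <- fit_fertility_model(m, "betweenness")
  raw <- lm(residual ~ z_betweenness, data = m)
  expect_equal(unname(coef(fit)["betweenness"]),
               unname(2 * sd(m$z_betweenness) * coef(raw)["z_betweenness"]),
               tolerance = 1e-10)
  ci_raw <- confint(raw)["z_betweenness", ] * 2 * sd(m$z_betweenness)
  row <- summary(fit)[summary(fit)$term == "betweenness", ]
  expect_equal(unname(c(row$ci_lo, row$ci_hi)), unname(ci_raw),
               tolerance = 1e-10)
})

test_that("shifting the outcome only moves the intercept", {
  m <- fixture_mothers(45, seed = 5)
  f1 <- fit_fertility_model(m, "closeness")
  m2 <- m
  m2$residual <- m$residual + 7
  f2 <- fit_fertility_model(m2, "closeness")
  b1 <- coef(f1)
  b2 <- coef(f2)
  expect_equal(b1[names(b1) != "(Intercept)"], b2[names(b2) != "(Intercept)"],
               tolerance = 1e-10)
  expect_equal(unname(b2["(Intercept)"] - b1["(Intercept)"]), 7,
               tolerance = 1e-10)
})

test_that("camp fixed effects absorb camp-level mean shifts exactly", {
  m <- fixture_mothers(60, camps = 3, seed = 6)
  f1 <- fit_fertility_model(m, "degree")
  m2 <- m
  shift <- c(c1 = 5, c2 = -2, c3 = 11)
  m2$residual <- m$residual + shift[m$camp]
  f2 <- fit_fertility_model(m2, "degree")
  expect_equal(unname(coef(f1)["degree"]), unname(coef(f2)["degree"]),
               tolerance = 1e-10)
})

test_that("interaction pruning follows the p > 0.05 rule", {
  m <- fixture_mothers(80, seed = 8)
  fit <- fit_fertility_model(m, "strength", interaction = TRUE)
  pruned <- prune_interaction(fit)
  p_int <- fit$terms$p[grepl(":", fit$terms$term)]
  if (p_int > 0.05) {
    expect_false(pruned$interaction_retained)
    expect_false(any(grepl(":", pruned$terms$term)))
  } else {
    expect_true(pruned$interaction_retained)
  }
  # threshold 1 never prunes
  keep <- prune_interaction(fit, threshold = 1)
  expect_true(keep$interaction_retained)
  expect_true(any(grepl(":", keep$terms$term)))
  expect_error(prune_interaction(fit_fertility_model(m, "strength")),
               "interaction")
})

test_that("a strongly planted age interaction is retained nearly always", {
  retained <- logical(60)
  for (r in seq_len(60)) {
    cfg <- sim_config(n_camps = 25, camp_size_range = c(24, 24),
                      beta_centrality_fertility = 0.5,
                      beta_age_interaction = 2.5,
                      fertility_measure = "betweenness",
                      seed = 40000 + r)
    study <- simulate_study(cfg)
    fit <- prune_interaction(fit_fertility_model(study$mothers, "betweenness",
                                                 interaction = TRUE))
    retained[r] <- fit$interaction_retained
  }
  expect_gte(mean(retained), 0.95)
})

test_that("variance inflation factors match their defining identity", {
  set.seed(10)
  X <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  X[, 2] <- X[, 1] * 0.8 + rnorm(200, 0, 0.5)
  vif <- compute_vif(X)
  # independent route: diagonal of the inverse correlation matrix
  expect_equal(unname(vif), unname(diag(solve(cor(X)))), tolerance = 1e-10)
  # columns orthogonal to each other and to the intercept give VIF 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
  colnames(Q) <- paste0("q", 1:3)
  expect_equal(unname(compute_vif(Q)), rep(1, 3), tolerance = 1e-10)
  # exact duplication is flagged as infinite (one warning per column)
  X2 <- cbind(a = X[, 1], b = X[, 1])
  w <- capture_warnings(v2 <- compute_vif(X2))
  expect_true(all(grepl("perfect collinearity", w)))
  expect_true(all(is.infinite(v2)))
  expect_error(compute_vif(X[, 1, drop = FALSE]), "at least 2")
})

test_that("VIFs agree with car on a fitted model", {
  skip_if_not_installed("car")
  m <- fixture_mothers(100, camps = 1, seed = 11)
  d <- two_sd_standardize(m, c("z_degree", "z_betweenness", "z_closeness"))
  lmfit <- lm(residual ~ z_degree + z_betweenness + z_closeness, data = d)
  mine <- compute_vif(d[, c("z_degree", "z_betweenness", "z_closeness")])
  expect_equal(unname(mine), unname(car::vif(lmfit)), tolerance = 1e-8)
})

test_that("joint models reduce to single models for orthogonal predictors", {
  set.seed(12)
  n <- 90
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  m <- fixture_mothers(n, camps = 1, seed = 12)
  m$z_degree <- Q[, 1]
  m$z_betweenness <- Q[, 2]
  m$z_closeness <- Q[, 3]
  joint <- fit_joint_model(m)
  for (meas in c("degree", "betweenness", "closeness")) {
    single <- fit_fertility_model(m, meas)
    expect_equal(unname(coef(joint)[meas]), unname(coef(single)[meas]),
                 tolerance = 1e-10)
  }
  expect_true(all(joint$vif < 1.05))
})

test_that("collinearity above the VIF ceiling aborts or warns as configured", {
  m <- fixture_mothers(80, camps = 1, seed = 13)
  m$z_betweenness <- m$z_closeness * 0.95 + rnorm(80, 0, 0.25)
  vif <- compute_vif(m[, c("z_degree", "z_betweenness", "z_closeness")])
  expect_gt(max(vif), 2.5) # fixture is built to breach the ceiling
  expect_error(fit_joint_model(m, vif_mode = "abort"), "collinearity")
  expect_warning(fit <- fit_joint_model(m, vif_mode = "warn"), "VIF")
  expect_false(is.null(fit$vif))
})

test_that("rank-deficient designs are refused with the collinear term named", {
  m <- fixture_mothers(40, camps = 1, seed = 14)
  m$z_betweenness <- m$z_closeness
  expect_error(suppressWarnings(fit_joint_model(m, vif_mode = "warn")),
               "rank-deficient")
})

test_that("sickness models control as specified and reject degenerate outcomes", {
  m <- fixture_mothers(70, seed = 15)
  fit <- fit_sickness_model(m, "closeness")
  terms <- fit$terms$term
  expect_true(all(c("closeness", "age", "settled", "mobile", "belongings")
                  %in% terms))
  expect_false("dependents" %in% terms)
  fit_d <- fit_sickness_model(m, "closeness", include_dependents = TRUE)
  expect_true("dependents" %in% fit_d$terms$term)
  m0 <- m
  m0$sickness_count <- 0L
  expect_error(fit_sickness_model(m0, "closeness"), "degenerate")
  # Poisson sensitivity mode runs and reports the same terms
  fit_p <- fit_sickness_model(m, "closeness", family = "poisson")
  expect_true("closeness" %in% fit_p$terms$term)
})

test_that("mediation check reports attenuation and enforces comparability", {
  m <- fixture_mothers(70, seed = 16)
  f1 <- fit_sickness_model(m, "betweenness")
  f2 <- fit_sickness_model(m, "betweenness", include_dependents = TRUE)
  med <- mediation_check(f1, f2)
  expect_equal(med$attenuation, 1 - med$beta_with / med$beta_without)
  # identical models: zero attenuation by definition
  med0 <- mediation_check(f1, f1)
  expect_equal(med0$attenuation, 0)
  # different measures or different samples are refused
  f3 <- fit_sickness_model(m, "closeness")
  expect_error(mediation_check(f1, f3), "different centrality measures")
  f4 <- fit_sickness_model(m[1:50, ], "betweenness")
  expect_error(mediation_check(f1, f4), "different samples")
})

test_that("model objects expose the standard S3 surface", {
  m <- fixture_mothers(50, seed = 17)
  fit <- fit_fertility_model(m, "ec", interaction = TRUE)
  expect_output(print(fit), "ec")
  expect_s3_class(summary(fit), "summary.centrality_fit")
  expect_true("ec:age" %in% names(coef(fit)))
  expect_equal(nrow(confint(fit)), length(coef(fit)))
  expect_length(residuals(fit), 50)
  f <- tempfile(fileext = ".csv")
  write_model_results(list(ec = fit), f)
  tab <- read.csv(f, stringsAsFactors = FALSE)
  expect_true(all(c("population", "model", "term", "beta", "ci_lo", "ci_hi",
                    "p", "adj_r2", "vif", "interaction_retained")
                  %in% names(tab)))
  pfile <- tempfile(fileext = ".pdf")
  grDevices::pdf(pfile)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(pfile))
})
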