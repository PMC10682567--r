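no_predictors <- function(n) matrix(numeric(0), n, 0)

test_that("intercept-only MLEs match the closed forms", {
  y <- c(rep(1, 25), rep(0, 75))
  fit <- fit_glm(list(response = y, X = no_predictors(100)), "binomial")
  expect_equal(unname(fit$coefficients), log(25 / 75), tolerance = 1e-8)

  counts <- c(rep(2, 30), rep(4, 30))   # mean 3.0
  fitp <- fit_glm(list(response = counts, X = no_predictors(60)), "poisson")
  expect_equal(unname(fitp$coefficients), log(3), tolerance = 1e-8)
})

test_that("a 2x2 binomial slope equals the closed-form log odds ratio", {
  # x = 0: 30 successes / 20 failures; x = 1: 10 successes / 40 failures
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  x <- matrix(c(rep(0, 50), rep(1, 50)), dimnames = list(NULL, "x"))
  fit <- fit_glm(list(response = y, X = x), "binomial")
  expect_equal(unname(fit$coefficients["x"]), log(1 / 6), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(30 / 20),
               tolerance = 1e-8)
})

test_that("IRLS agrees with a derivative-free likelihood maximizer and stats::glm", {
  set.seed(42)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- -0.5 + 0.8 * X[, 1] - 0.4 * X[, 2]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_glm(list(response = y, X = X), "binomial")
  oracle <- neldermead_glm(y, X, "binomial")
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)
  ref <- glm(y ~ X, family = binomial, control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)

  yc <- rpois(n, exp(0.5 + 0.3 * X[, 1]))
  fitc <- fit_glm(list(response = yc, X = X), "poisson")
  expect_equal(unname(fitc$coefficients), neldermead_glm(yc, X, "poisson"),
               tolerance = 1e-6)
  refc <- glm(yc ~ X, family = poisson)
  expect_equal(unname(fitc$coefficients), unname(coef(refc)), tolerance = 1e-8)
})

test_that("score equations hold: fitted means reproduce sample summaries", {
  set.seed(14)
  n <- 150
  X <- cbind(x = rnorm(n))
  y <- rbinom(n, 1, plogis(0.3 - 0.5 * X[, 1]))
  fit <- fit_glm(list(response = y, X = X), "binomial")
  expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-10)

  yc <- rpois(n, exp(0.4 + 0.2 * X[, 1]))
  fitc <- fit_glm(list(response = yc, X = X), "poisson")
  expect_equal(sum(fitc$fitted) / sum(yc), 1, tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with guidance", {
  y <- c(rep(0, 20), rep(1, 20))
  sep <- matrix(c(rep(0, 20), rep(1, 20)), dimnames = list(NULL, "x"))
  expect_error(fit_glm(list(response = y, X = sep), "binomial"),
               "separation")
  dup <- cbind(a = rnorm(40), b = 0)
  dup <- cbind(dup, c = dup[, "a"])
  expect_error(fit_glm(list(response = y, X = dup), "binomial"),
               "rank")
  expect_error(fit_glm(list(response = c(0.5, 1, 0), X = no_predictors(3)),
                       "binomial"), "0/1")
  expect_error(fit_glm(list(response = c(-1, 2, 0), X = no_predictors(3)),
                       "poisson"), "non-negative")
})

test_that("Wald table maps estimates to two-sided normal p values in design order", {
  set.seed(3)
  X <- cbind(a = rnorm(80), b = rnorm(80))
  y <- rbinom(80, 1, 0.4)
  fit <- fit_glm(list(response = y, X = X), "binomial")
  tab <- wald_table(fit)
  expect_equal(tab$term, c("(Intercept)", "a", "b"))
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * pnorm(-abs(tab$z)))
  expect_equal(tab$p[tab$estimate == 0], numeric(0))  # no exact zeros expected
  # beta = 1.96 SE corresponds to p ~ 0.05
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

sim_design_fit <- function(n = 300, seed = 8) {
  set.seed(seed)
  rec <- make_records(n,
                      latitude = runif(n, 35, 48),
                      longitude = runif(n, -95, -65),
                      elevation = runif(n, 0, 800),
                      observation_date = as.Date("2020-06-01") + sample(0:120, n, TRUE),
                      fruit_present = sample(c("yes", "no"), n, TRUE))
  marg <- runif(n)
  rec$exsertion_score <- ifelse(runif(n) < plogis(-0.5 - 0.6 * scale(rec$latitude)[, 1]),
                                "present", "absent")
  rec$n_exserted_flowers <- ifelse(rec$exsertion_score == "present", 1L, 0L)
  design <- build_design(rec, "geo_binary", marginalities = marg)
  list(design = design, fit = fit_glm(design, "binomial"))
}

test_that("prediction surfaces hold covariates at fitting-time means", {
  sf <- sim_design_fit()
  grid <- seq(36, 47, length.out = 5)
  surf <- predict_surface(sf$fit, "z_latitude", grid)
  expect_true(all(surf$mean > 0 & surf$mean < 1))
  expect_true(all(surf$lower <= surf$mean & surf$mean <= surf$upper))
  expect_false(any(surf$extrapolated))
  # grid beyond the observed range is allowed but flagged
  wide <- predict_surface(sf$fit, "z_latitude", c(20, 40))
  expect_equal(wide$extrapolated, c(TRUE, FALSE))
  # SE(eta) equals the quadratic form x' Sigma x computed by hand
  params <- sf$fit$params
  x <- matrix(0, 1, length(sf$fit$terms), dimnames = list(NULL, sf$fit$terms))
  x[1, "(Intercept)"] <- 1
  x[1, "fruit_indicator"] <- params$fruit_mean
  x[1, "z_latitude"] <- (grid[3] - params$z_latitude$mean) / params$z_latitude$sd
  expect_equal(surf$se_eta[3], sqrt(drop(x %*% sf$fit$vcov %*% t(x))),
               tolerance = 1e-12)
})

test_that("intercept-only predictions invert the link exactly", {
  y <- rep(c(0, 1), 50)
  fit <- fit_glm(list(response = y, X = no_predictors(100)), "binomial")
  fit$params <- list(fruit_mean = 0)
  surf <- predict_surface(fit, "(Intercept)", 1)
  expect_equal(surf$mean, 0.5, tolerance = 1e-8)
  expect_equal(surf$upper - 0.5, 0.5 - surf$lower, tolerance = 1e-8)

  counts <- rep(c(1, 3), 50)   # mean 2
  fitp <- fit_glm(list(response = counts, X = no_predictors(100)), "poisson")
  expect_equal(unname(exp(fitp$coefficients)), 2, tolerance = 1e-8)
})

test_that("prediction intervals cover the true mean at nominal-ish rates", {
  set.seed(77)
  n <- 250
  X <- cbind(x = rnorm(n))
  beta <- c(-0.4, 0.7)
  truth_at_zero <- plogis(beta[1])
  hits <- vapply(1:150, function(i) {
    y <- rbinom(n, 1, plogis(beta[1] + beta[2] * X[, 1]))
    fit <- fit_glm(list(response = y, X = X), "binomial")
    fit$params <- list(fruit_mean = 0, z_x = list(mean = 0, sd = 1))
    eta <- fit$coefficients["(Intercept)"]
    se <- sqrt(fit$vcov[1, 1])
    truth_at_zero >= plogis(eta - 1.96 * se) && truth_at_zero <= plogis(eta + 1.96 * se)
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.99)
})

species_fit <- function(effects = c(inflata = -1.4, cardinalis = 0.9,
                                    kalmii = 0.4, siphilitica = 0.9,
                                    spicata = 0.2), n_per = 150, seed = 12) {
  set.seed(seed)
  rec <- do.call(rbind, lapply(names(effects), function(sp) {
    r <- make_records(n_per, species = sp,
                      observation_date = as.Date("2020-06-01") + sample(0:120, n_per, TRUE),
                      fruit_present = sample(c("yes", "no"), n_per, TRUE))
    eta <- effects[["inflata"]] + if (sp == "inflata") 0 else effects[[sp]]
    r$exsertion_score <- ifelse(runif(n_per) < plogis(eta), "present", "absent")
    r$n_exserted_flowers <- ifelse(r$exsertion_score == "present", 1L, 0L)
    r
  }))
  design <- build_design(rec, "species_binary")
  list(fit = fit_glm(design, "binomial"), design = design)
}

test_that("marginal means follow the reference coding and balanced-data ordering", {
  fit <- species_fit()$fit
  em <- marginal_means(fit)
  expect_equal(em$species[1], "inflata")
  # reference species mean = inverse link of intercept + fruit offset
  eta_ref <- fit$coefficients["(Intercept)"] +
    fit$coefficients["fruit_indicator"] * fit$params$fruit_mean
  expect_equal(em$mean[1], unname(plogis(eta_ref)), tolerance = 1e-10)
  expect_true(all(em$lower < em$mean & em$mean < em$upper))
  # strong positive species effects push marginal means above the reference
  expect_gt(em$mean[em$species == "cardinalis"], em$mean[em$species == "inflata"])
})

test_that("tukey contrasts respect the raw-p / bonferroni envelope", {
  fit <- species_fit()$fit
  ct <- tukey_contrasts(fit, seed = 99)
  m <- nrow(ct)
  expect_equal(m, choose(5, 2))
  expect_true(all(ct$p_adjusted >= ct$p_raw - 1e-12))
  expect_true(all(ct$p_adjusted <= pmin(1, m * ct$p_raw) + 0.002))
  expect_true(all(ct$p_adjusted >= 0 & ct$p_adjusted <= 1))
  bon <- tukey_contrasts(fit, adjust = "bonferroni")
  expect_equal(bon$p_adjusted, pmin(1, m * bon$p_raw))
})

test_that("contrasts of two identical groups are null; k = 2 matches the raw p", {
  set.seed(21)
  n_per <- 120
  rec <- do.call(rbind, lapply(c("inflata", "kalmii"), function(sp) {
    r <- make_records(n_per, species = sp,
                      observation_date = as.Date("2020-06-01") + sample(0:60, n_per, TRUE))
    r$exsertion_score <- rep(c("present", "absent"), n_per / 2)
    r$n_exserted_flowers <- ifelse(r$exsertion_score == "present", 1L, 0L)
    r$fruit_present <- rep(c("yes", "no"), each = n_per / 2)
    r
  }))
  fit <- fit_glm(build_design(rec, "species_binary"), "binomial")
  ct <- tukey_contrasts(fit)
  expect_equal(nrow(ct), 1)
  expect_equal(ct$estimate, 0, tolerance = 1e-5)
  expect_equal(ct$p_adjusted, ct$p_raw, tolerance = 0.002)
  expect_gt(ct$p_adjusted, 0.99)
})

test_that("mvn-adjusted p values agree with the multcomp single-step reference", {
  skip_if_not_installed("multcomp")
  sf <- species_fit(effects = c(inflata = -1.0, cardinalis = 0.5, kalmii = 0.2,
                                siphilitica = -0.2, spicata = 0.35),
                    n_per = 120, seed = 33)
  fit <- sf$fit
  ct <- tukey_contrasts(fit, seed = 1234)
  # same model refit with stats::glm, same contrast rows, multcomp's
  # multivariate-t/normal machinery as the independent adjustment oracle
  d <- data.frame(y = sf$design$response, sf$design$X, check.names = FALSE)
  ref_fit <- glm(y ~ ., data = d, family = binomial)
  levels <- fit$params$species_levels
  rows <- t(vapply(levels, function(sp) {
    x <- setNames(numeric(length(fit$terms)), fit$terms)
    x["(Intercept)"] <- 1
    x["fruit_indicator"] <- fit$params$fruit_mean
    ind <- paste0("species_", sp)
    if (ind %in% names(x)) x[ind] <- 1
    x
  }, numeric(length(fit$terms))))
  pairs <- combn(seq_along(levels), 2)
  L <- t(apply(pairs, 2, function(ij) rows[ij[1], ] - rows[ij[2], ]))
  colnames(L) <- names(coef(ref_fit))
  ref <- summary(multcomp::glht(ref_fit, linfct = L))
  expect_equal(ct$estimate, unname(ref$test$coefficients), tolerance = 1e-6)
  expect_equal(ct$p_adjusted, unname(as.numeric(ref$test$pvalues)),
               tolerance = 0.01)
})
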