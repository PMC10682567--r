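# GLM fitting by iteratively reweighted least squares, Wald inference,
# inverse-link prediction surfaces, estimated marginal means and
# multiplicity-adjusted pairwise species contrasts.
#
# Dispersion is fixed at 1 for both families (plain binomial / Poisson);
# a Pearson chi-square / df overdispersion diagnostic is reported but not
# modeled. All intervals are 95%.

glm_families <- c("binomial", "poisson")

#' Fit a binomial or Poisson GLM by iteratively reweighted least squares
#'
#' Canonical links only (logit for binomial, log for Poisson). An
#' intercept column is always prepended. Convergence is declared when the
#' maximum absolute coefficient change falls below `1e-8` or the deviance
#' change below `1e-10`; non-convergence within `maxit` iterations is an
#' error, as is quasi-separation: a linear predictor beyond `|eta| > 30`
#' at convergence, or binomial fitted probabilities within `1e-10` of 0
#' or 1 (there the MLE diverges and IRLS merely stalls).
#'
#' @param design A `design_matrix` from [build_design()], or a list with
#'   elements `response` and `X` (predictor matrix without intercept).
#' @param family `"binomial"` or `"poisson"`.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `glm_fit`: coefficients, standard errors,
#'   `z` and two-sided normal `p` values, coefficient covariance
#'   (inverse Fisher information), log-likelihood, deviance, a Pearson
#'   chi-square/df overdispersion diagnostic, fitted values, and fit
#'   metadata (`converged`, `iterations`, `n`). The originating design's
#'   standardization parameters travel with the fit for prediction.
#' @export
fit_glm <- function(design, family = glm_families, maxit = 50) {
  family <- match.arg(family)
  y <- design$response
  X <- cbind(`(Intercept)` = 1, design$X)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  if (family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial family requires a 0/1 response", call. = FALSE)
  }
  if (family == "poisson" && (any(y < 0) || any(y != floor(y)))) {
    stop("poisson family requires non-negative integer responses", call. = FALSE)
  }

  if (family == "binomial") {
    linkinv <- stats::plogis
    mu <- (y + 0.5) / 2
    eta <- stats::qlogis(mu)
    variance <- function(mu) mu * (1 - mu)
    dev_fun <- function(mu) {
      -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    }
    loglik_fun <- function(mu) sum(stats::dbinom(y, 1, mu, log = TRUE))
  } else {
    linkinv <- exp
    mu <- y + 0.1
    eta <- log(mu)
    variance <- function(mu) mu
    dev_fun <- function(mu) {
      2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    }
    loglik_fun <- function(mu) sum(stats::dpois(y, mu, log = TRUE))
  }

  beta <- rep(0, p)
  dev <- dev_fun(mu)
  converged <- FALSE
  iter <- 0
  while (iter < maxit) {
    iter <- iter + 1
    w <- variance(mu)               # canonical link: W = V(mu)
    z <- eta + (y - mu) / w
    wls <- stats::lm.wfit(X, z, w)
    beta_new <- wls$coefficients
    eta <- drop(X %*% beta_new)
    mu <- linkinv(eta)
    dev_new <- dev_fun(mu)
    delta_beta <- max(abs(beta_new - beta))
    delta_dev <- abs(dev_new - dev)
    beta <- beta_new
    dev <- dev_new
    if (delta_beta < 1e-8 || delta_dev < 1e-10) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("IRLS failed to converge in ", maxit, " iterations", call. = FALSE)
  }
  separated <- any(abs(eta) > 30) ||
    (family == "binomial" && any(mu < 1e-10 | mu > 1 - 1e-10))
  if (separated) {
    stop("quasi-separation detected (fitted values numerically at the ",
         "boundary): a predictor perfectly separates the response; remove ",
         "or coarsen it", call. = FALSE)
  }

  w <- variance(mu)
  xtwx <- crossprod(X, X * w)
  vcov <- chol2inv(chol(xtwx))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(vcov))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  pearson <- sum((y - mu)^2 / variance(mu))

  structure(list(
    family = family,
    coefficients = beta,
    se = se,
    z = zval,
    p = pval,
    vcov = vcov,
    loglik = loglik_fun(mu),
    deviance = dev,
    dispersion_pearson = pearson / (n - p),
    n = n,
    converged = converged,
    iterations = iter,
    eta = eta,
    fitted = mu,
    terms = colnames(X),
    model = design$model %||% NA_character_,
    params = design$params %||% NULL
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("GLM (%s, %s link), n = %d, converged in %d iterations\n",
              x$family, if (x$family == "binomial") "logit" else "log",
              x$n, x$iterations))
  print(wald_table(x))
  cat(sprintf("Pearson chi-square / df: %.3f\n", x$dispersion_pearson))
  invisible(x)
}

#' Wald coefficient table
#'
#' Per-coefficient estimate, standard error, `z = beta/SE` and two-sided
#' normal p value, in design column order.
#'
#' @param fit A `glm_fit`.
#' @return Tibble with `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_table <- function(fit) {
  tibble::tibble(term = fit$terms, estimate = unname(fit$coefficients),
                 se = unname(fit$se), z = unname(fit$z), p = unname(fit$p))
}

link_row <- function(fit, x) {
  eta <- drop(x %*% fit$coefficients)
  se <- sqrt(rowSums((x %*% fit$vcov) * x))
  linkinv <- if (fit$family == "binomial") stats::plogis else exp
  tibble::tibble(eta = eta, se_eta = se,
                 mean = linkinv(eta),
                 lower = linkinv(eta - 1.96 * se),
                 upper = linkinv(eta + 1.96 * se))
}

#' Prediction surface over one focal predictor
#'
#' Predicted probabilities (binomial) or counts (Poisson) across a grid
#' of raw-scale values of one focal predictor, with all other model
#' variables held constant: numeric predictors at their fitting-subset
#' means (z = 0) and the fruit indicator at the fitting-subset mean
#' fruiting proportion. Confidence bounds are computed on the linear
#' predictor (`eta +/- 1.96 SE(eta)`, SE from the coefficient
#' covariance) and then inverse-linked, so they are asymmetric on the
#' response scale. Grid values outside the observed range of the focal
#' predictor are allowed but flagged `extrapolated`.
#'
#' @param fit A `glm_fit` carrying standardization parameters (from a
#'   [build_design()] design).
#' @param focal Name of the focal design column (e.g. `"z_latitude"`).
#' @param grid Numeric vector of raw-scale focal values.
#' @param params Standardization parameter set; defaults to the one
#'   stored in the fit.
#' @return Tibble with the raw grid value, its z-score, `eta`, `se_eta`,
#'   predicted `mean`, `lower`, `upper`, `extrapolated`.
#' @export
predict_surface <- function(fit, focal, grid, params = fit$params) {
  if (is.null(params)) stop("fit carries no standardization parameters", call. = FALSE)
  if (!focal %in% fit$terms) stop("unknown focal predictor: ", focal, call. = FALSE)
  base <- baseline_row(fit, params)
  x <- base[rep(1L, length(grid)), , drop = FALSE]
  if (focal == "(Intercept)") {
    zvals <- rep(1, length(grid))
    extrapolated <- rep(FALSE, length(grid))
  } else if (focal == "fruit_indicator") {
    zvals <- grid
    extrapolated <- grid < 0 | grid > 1
  } else {
    fp <- params[[focal]]
    if (is.null(fp)) stop("no standardization parameters for ", focal, call. = FALSE)
    zvals <- (grid - fp$mean) / fp$sd
    extrapolated <- if (!is.null(fp$min)) grid < fp$min | grid > fp$max else
      rep(FALSE, length(grid))
  }
  x[, focal] <- zvals
  out <- link_row(fit, x)
  tibble::tibble(value = grid, z = zvals, out, extrapolated = extrapolated)
}

# Reference row: intercept 1, all z columns 0, fruit at its mean,
# species indicators 0 (reference species).
baseline_row <- function(fit, params) {
  x <- matrix(0, 1, length(fit$terms), dimnames = list(NULL, fit$terms))
  x[1, "(Intercept)"] <- 1
  if ("fruit_indicator" %in% fit$terms) {
    x[1, "fruit_indicator"] <- params$fruit_mean %||% 0
  }
  x
}

#' Estimated marginal means by species
#'
#' Model-based predicted probability (binomial) or count (Poisson) for
#' each species, evaluated at the average observation date (group-
#' centered day of year = 0), the pooled mean fruiting proportion, and —
#' for count models — the average total number of visible flowers
#' (z = 0), with 95% confidence bounds inverse-linked from the linear
#' predictor scale.
#'
#' @param fit A `glm_fit` of a species model.
#' @param params Standardization parameters; defaults to those in the fit.
#' @return Tibble with one row per species: `species`, `eta`, `se_eta`,
#'   `mean`, `lower`, `upper`.
#' @export
marginal_means <- function(fit, params = fit$params) {
  levels <- params$species_levels
  if (is.null(levels)) stop("fit is not a species model", call. = FALSE)
  x <- do.call(rbind, lapply(levels, function(sp) {
    row <- baseline_row(fit, params)
    ind <- paste0("species_", sp)
    if (ind %in% fit$terms) row[1, ind] <- 1
    row
  }))
  tibble::tibble(species = levels, link_row(fit, x))
}

#' Multiplicity-adjusted pairwise species contrasts
#'
#' All pairwise differences in estimated marginal means between species,
#' on the link scale, with standard errors from the coefficient
#' covariance. The default single-step adjustment uses the
#' equicoordinate multivariate-normal reference distribution of the
#' contrast statistics (the GLM analogue of the Tukey test): the
#' adjusted p value of contrast *i* is the probability that the maximum
#' absolute component of a correlated standard-normal vector — with the
#' contrasts' correlation matrix — exceeds `|z_i|`, estimated by seeded
#' Monte Carlo. A deterministic Bonferroni fallback is available.
#'
#' @param fit A `glm_fit` of a species model.
#' @param adjust `"mvn"` (single-step multivariate normal, default) or
#'   `"bonferroni"`.
#' @param seed Seed for the Monte-Carlo quantile estimate.
#' @param draws Number of Monte-Carlo draws.
#' @return Tibble with `contrast`, `estimate` (link scale), `se`, `z`,
#'   `p_raw`, `p_adjusted`, `method`.
#' @export
tukey_contrasts <- function(fit, adjust = c("mvn", "bonferroni"),
                            seed = 20231127, draws = 1e5) {
  adjust <- match.arg(adjust)
  levels <- fit$params$species_levels
  if (is.null(levels) || length(levels) < 2) {
    stop("need a species model with at least 2 species levels", call. = FALSE)
  }
  rows <- lapply(levels, function(sp) {
    row <- baseline_row(fit, fit$params)
    ind <- paste0("species_", sp)
    if (ind %in% fit$terms) row[1, ind] <- 1
    row
  })
  pairs <- utils::combn(seq_along(levels), 2)
  L <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    rows[[pairs[1, k]]] - rows[[pairs[2, k]]]
  }))
  labels <- apply(pairs, 2, function(ij) paste(levels[ij[1]], "-", levels[ij[2]]))
  est <- drop(L %*% fit$coefficients)
  V <- L %*% fit$vcov %*% t(L)
  if (any(!is.finite(diag(V))) || any(diag(V) <= 0)) {
    stop("singular contrast covariance", call. = FALSE)
  }
  se <- sqrt(diag(V))
  zstat <- est / se
  p_raw <- 2 * stats::pnorm(-abs(zstat))
  m <- length(est)
  if (adjust == "bonferroni" || m == 1) {
    p_adj <- pmin(1, m * p_raw)
    method <- if (m == 1) "single contrast (no adjustment)" else "bonferroni"
  } else {
    # The m pairwise contrasts are linearly dependent (rank k - 1), so the
    # reference vector is sampled through the full-rank coefficient
    # covariance: z* = L b* / se with b* ~ N(0, vcov).
    p_adj <- with_local_seed(seed, {
      Lc <- chol(fit$vcov)
      B <- matrix(stats::rnorm(draws * ncol(Lc)), draws) %*% Lc %*% t(L)
      Z <- sweep(B, 2, se, "/")
      maxabs <- apply(abs(Z), 1, max)
      vapply(abs(zstat), function(t) mean(maxabs >= t), numeric(1))
    })
    method <- sprintf("single-step mvn (monte carlo, %d draws, seed %d)",
                      as.integer(draws), as.integer(seed))
  }
  p_adj <- pmax(p_adj, p_raw)
  tibble::tibble(contrast = labels, estimate = est, se = se, z = zstat,
                 p_raw = p_raw, p_adjusted = pmin(1, p_adj), method = method)
}

# Evaluate expr under a temporary RNG state, restoring the caller's.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
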