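# Twin linear mixed model (lme4-style nested random effects).
#
# Per family the phenotype is multivariate normal with mean
# beta_0 + beta_age * age. Three variance components: sigma2_pair (random
# intercept shared by any co-twin pair), sigma2_mz_extra (an additional
# random effect whose level is shared by MZ co-twins but unique to each
# DZ twin or singleton) and sigma2_resid (unique-environment noise).
# Every individual therefore has marginal variance
# sigma2_pair + sigma2_mz_extra + sigma2_resid, while
# cov(DZ pair) = sigma2_pair and cov(MZ pair) = sigma2_pair +
# sigma2_mz_extra. Equal marginal variances make covariance contrasts
# equal correlation contrasts, so the genetic variance is
# 2 * sigma2_mz_extra = twice the additional MZ correlation (times the
# total variance).

# Exact block log-likelihood. Co-twins share age, so each pair's two design
# rows coincide and the pair factorizes into a sum component with variance
# diag + cov and a difference component with variance diag - cov.
.twin_ll_core <- function(y, mu, blocks, s2p, s2m, s2r) {
  ll <- 0
  dg <- s2p + s2m + s2r
  if (length(blocks$i1)) {
    cv <- s2p + s2m * blocks$mz
    su <- dg + cv                 # var of (y1 + y2)/sqrt(2)
    sd2 <- dg - cv                # var of (y1 - y2)/sqrt(2)
    r1 <- y[blocks$i1] - mu[blocks$i1]
    r2 <- y[blocks$i2] - mu[blocks$i2]
    qs <- (r1 + r2)^2 / (2 * su) + (r1 - r2)^2 / (2 * sd2)
    ll <- ll - 0.5 * sum(log(su) + log(sd2) + qs) -
      length(blocks$i1) * log(2 * pi)
  }
  if (length(blocks$singles)) {
    r <- y[blocks$singles] - mu[blocks$singles]
    ll <- ll - 0.5 * sum(log(2 * pi * dg) + r^2 / dg)
  }
  ll
}

#' Twin mixed-model log-likelihood
#'
#' Exact Gaussian log-likelihood of a phenotype under the twin linear mixed
#' model, computed family block by family block: singletons are univariate
#' normals; pairs are bivariate normals with covariance `sigma2_pair`
#' (plus `sigma2_mz_extra` for MZ pairs). Every individual's marginal
#' variance is `sigma2_pair + sigma2_mz_extra + sigma2_resid` (the nested
#' random-effects convention: DZ twins and singletons carry their own
#' level of the MZ-extra effect). The mean is `beta_0 + beta_age * age`.
#'
#' @param phenotype Numeric vector, one value per cohort row.
#' @param cohort A `twin_cohort`.
#' @param params Named list with `beta_0`, `beta_age`, `sigma2_pair`,
#'   `sigma2_mz_extra`, `sigma2_resid` (variances must be nonnegative,
#'   `sigma2_resid` strictly positive).
#' @return The log-likelihood (a single number).
#' @export
twin_loglik <- function(phenotype, cohort, params) {
  validate_cohort(cohort)
  if (length(phenotype) != nrow(cohort))
    stop("phenotype length must match cohort size")
  if (any(!is.finite(phenotype))) stop("phenotype contains non-finite values")
  need <- c("beta_0", "beta_age", "sigma2_pair", "sigma2_mz_extra",
            "sigma2_resid")
  if (!all(need %in% names(params)))
    stop("params must name: ", paste(need, collapse = ", "))
  s2p <- params$sigma2_pair; s2m <- params$sigma2_mz_extra
  s2r <- params$sigma2_resid
  if (min(s2p, s2m) < 0 || s2r <= 0)
    stop("variances must be nonnegative and sigma2_resid > 0")
  blocks <- .cohort_blocks(cohort)
  mu <- params$beta_0 + params$beta_age * cohort$age
  .twin_ll_core(phenotype, mu, blocks, s2p, s2m, s2r)
}

# Profile log-likelihood: GLS fixed effects in closed form for given
# variance components (exploits equal ages within pairs).
.twin_profile <- function(v, y, age, blocks, include_age) {
  s2p <- v[1]; s2m <- v[2]; s2r <- max(v[3], 1e-12)
  dg <- s2p + s2m + s2r
  p <- if (include_age) 2L else 1L
  A <- matrix(0, p, p); b <- numeric(p)
  if (length(blocks$i1)) {
    su <- dg + s2p + s2m * blocks$mz
    x1 <- age[blocks$i1]
    ysum <- y[blocks$i1] + y[blocks$i2]
    w <- 2 / su
    A[1, 1] <- A[1, 1] + sum(w)
    b[1] <- b[1] + sum(ysum / su)
    if (include_age) {
      A[1, 2] <- A[1, 2] + sum(w * x1)
      A[2, 2] <- A[2, 2] + sum(w * x1^2)
      b[2] <- b[2] + sum(ysum * x1 / su)
    }
  }
  if (length(blocks$singles)) {
    s0 <- dg
    xs <- age[blocks$singles]
    ys <- y[blocks$singles]
    A[1, 1] <- A[1, 1] + length(xs) / s0
    b[1] <- b[1] + sum(ys) / s0
    if (include_age) {
      A[1, 2] <- A[1, 2] + sum(xs) / s0
      A[2, 2] <- A[2, 2] + sum(xs^2) / s0
      b[2] <- b[2] + sum(ys * xs) / s0
    }
  }
  if (include_age) A[2, 1] <- A[1, 2]
  beta <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, p))
  if (any(!is.finite(beta))) return(list(ll = -Inf, beta = beta))
  mu <- if (include_age) beta[1] + beta[2] * age else
    rep(beta[1], length(y))
  list(ll = .twin_ll_core(y, mu, blocks, s2p, s2m, s2r), beta = beta)
}

#' Fit the twin mixed model by maximum likelihood
#'
#' Maximum-likelihood (not REML) estimates of the twin model: the fixed
#' effects are profiled out in closed form (generalized least squares) and
#' the three variance components are maximized with bounded quasi-Newton
#' (L-BFGS-B, variances bounded at zero) from three deterministic starting
#' points (method of moments, equal split, residual-only); the best
#' optimum is kept. ML is used throughout because the likelihood-ratio
#' test compares models differing in a fixed effect.
#'
#' @param phenotype Numeric vector aligned with the cohort rows.
#' @param cohort A `twin_cohort` with at least 10 families.
#' @param include_age Include the fixed age effect? `FALSE` forces
#'   `beta_age = 0` (the null model of the age test).
#' @return A `twin_fit`: `beta_0`, `beta_age`, `sigma2_pair`,
#'   `sigma2_mz_extra`, `sigma2_resid`, `loglik`, `converged`,
#'   `n_individuals`, `n_families`, `include_age`.
#' @export
fit_twin_model <- function(phenotype, cohort, include_age = TRUE) {
  validate_cohort(cohort)
  if (length(phenotype) != nrow(cohort))
    stop("phenotype length must match cohort size")
  if (any(!is.finite(phenotype))) stop("phenotype contains non-finite values")
  blocks <- .cohort_blocks(cohort)
  if (blocks$n_families < 10)
    stop("need at least 10 families to fit the twin model")
  vy <- stats::var(phenotype)
  if (!is.finite(vy) || vy <= 0)
    stop("phenotype has zero variance; twin model is degenerate")
  age <- cohort$age
  if (include_age && stats::var(age) <= 0)
    stop("age effect not identifiable: all ages identical")

  sdy <- sqrt(vy)
  ys <- phenotype / sdy

  # method-of-moments start from co-twin cross-products of the
  # age-adjusted, centered phenotype
  res <- if (include_age) stats::lm.fit(cbind(1, age), ys)$residuals
  else ys - mean(ys)
  v0 <- mean(res^2)
  cov_mz <- if (any(blocks$mz))
    mean(res[blocks$i1[blocks$mz]] * res[blocks$i2[blocks$mz]]) else 0
  cov_dz <- if (any(!blocks$mz))
    mean(res[blocks$i1[!blocks$mz]] * res[blocks$i2[!blocks$mz]]) else 0
  s2p0 <- min(max(cov_dz, 0), 0.95 * v0)
  s2m0 <- min(max(cov_mz - cov_dz, 0), 0.95 * (v0 - s2p0))
  starts <- list(
    c(s2p0, s2m0, max(v0 - s2p0 - s2m0, 0.05 * v0)),
    c(v0 / 3, v0 / 3, v0 / 3),
    c(0, 0, v0)
  )

  nll <- function(v) -.twin_profile(v, ys, age, blocks, include_age)$ll
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(0, 0, 1e-9), upper = rep(50, 3),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("twin model optimization failed")

  prof <- .twin_profile(best$par, ys, age, blocks, include_age)
  beta <- prof$beta * sdy
  v <- best$par * vy
  n <- nrow(cohort)
  # log-likelihood on the original scale: ll(y) = ll(y/s) - n log s
  fit <- list(
    beta_0 = beta[1],
    beta_age = if (include_age) beta[2] else 0,
    sigma2_pair = v[1], sigma2_mz_extra = v[2], sigma2_resid = v[3],
    loglik = prof$ll - n * log(sdy),
    converged = best$convergence == 0,
    n_individuals = n, n_families = blocks$n_families,
    include_age = include_age
  )
  class(fit) <- "twin_fit"
  fit
}

#' Likelihood-ratio test for an age effect
#'
#' Fits the full twin model (with the fixed age term) and the null model
#' (without it) by maximum likelihood and compares them:
#' `statistic = 2 * (loglik_full - loglik_null)`, floored at zero, with the
#' p-value from the upper tail of a chi-square with 1 degree of freedom.
#'
#' @param phenotype Numeric vector aligned with the cohort rows.
#' @param cohort A `twin_cohort`.
#' @return List with `lrt_stat`, `p_value`, `beta_age`, `fit_full`,
#'   `fit_null`, `converged` (both fits converged; a warning is issued
#'   when not).
#' @export
lrt_age <- function(phenotype, cohort) {
  fit_full <- fit_twin_model(phenotype, cohort, include_age = TRUE)
  fit_null <- fit_twin_model(phenotype, cohort, include_age = FALSE)
  stat <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  conv <- fit_full$converged && fit_null$converged
  if (!conv)
    warning("twin model fit did not converge; p-value may be unreliable")
  list(lrt_stat = stat, p_value = p, beta_age = fit_full$beta_age,
       fit_full = fit_full, fit_null = fit_null, converged = conv)
}

#' ACE + age variance decomposition of a twin fit
#'
#' Decomposes the model-implied phenotype variance into additive-genetic,
#' shared-environment, unique-environment and fixed-age components. The
#' genetic variance is twice the additional covariance of MZ over DZ
#' co-twins (`2 * sigma2_mz_extra`); shared environment is
#' `sigma2_pair - sigma2_mz_extra`; unique environment is `sigma2_resid`;
#' the age component is the population variance of `beta_age * age` over
#' the analyzed cohort. Shares are each divided by the total, negative
#' implied shares are clipped at zero and the four shares renormalized to
#' sum to one, so every output lies in `[0, 1]`. Because the shares are
#' scale-free, covariance contrasts equal correlation contrasts on the
#' standardized phenotype.
#'
#' @param fit_full A converged `twin_fit` with the age term.
#' @param cohort The `twin_cohort` the fit used.
#' @return List with `h2`, `c2`, `e2`, `age_share_total`,
#'   `age_share_env` (= age share of the environmental, i.e. non-genetic,
#'   variance).
#' @export
decompose_variance <- function(fit_full, cohort) {
  if (!inherits(fit_full, "twin_fit")) stop("'fit_full' must be a twin_fit")
  if (!fit_full$converged)
    warning("decomposing a non-converged fit")
  validate_cohort(cohort)
  age <- cohort$age
  n <- length(age)
  v_age <- fit_full$beta_age^2 * (stats::var(age) * (n - 1) / n)
  v_gen <- 2 * fit_full$sigma2_mz_extra
  v_shared <- fit_full$sigma2_pair - fit_full$sigma2_mz_extra
  v_uniq <- fit_full$sigma2_resid
  V <- v_age + fit_full$sigma2_pair + fit_full$sigma2_mz_extra + v_uniq
  if (V <= 0) stop("total model-implied variance is zero")
  shares <- c(h2 = v_gen, c2 = v_shared, e2 = v_uniq,
              age_share_total = v_age) / V
  shares <- pmax(shares, 0)
  shares <- shares / sum(shares)
  h2 <- shares[["h2"]]
  age_total <- shares[["age_share_total"]]
  age_env <- if (h2 < 1) min(age_total / (1 - h2), 1) else 0
  list(h2 = h2, c2 = shares[["c2"]], e2 = shares[["e2"]],
       age_share_total = age_total, age_share_env = age_env)
}

#' Simulate a phenotype from the twin mixed model
#'
#' Draws one phenotype vector directly from the twin model's covariance:
#' each pair is bivariate normal with covariance `sigma2_pair`
#' (+ `sigma2_mz_extra` for MZ) and every individual's marginal variance
#' is `sigma2_pair + sigma2_mz_extra + sigma2_resid`; singletons are
#' univariate. Used for calibration and parameter-recovery studies where
#' the generating process must coincide with the fitted model.
#'
#' @param cohort A `twin_cohort`.
#' @param beta_0,beta_age Fixed effects (mean `beta_0 + beta_age * age`).
#' @param sigma2_pair,sigma2_mz_extra,sigma2_resid Variance components.
#' @param seed Optional integer seed (uses the current RNG state if NULL).
#' @return Numeric phenotype vector aligned with the cohort rows.
#' @export
simulate_twin_phenotype <- function(cohort, beta_0 = 0, beta_age = 0,
                                    sigma2_pair = 0.3,
                                    sigma2_mz_extra = 0.2,
                                    sigma2_resid = 0.5, seed = NULL) {
  validate_cohort(cohort)
  if (!is.null(seed)) set.seed(.stream_seed(seed, "expression"))
  blocks <- .cohort_blocks(cohort)
  dg <- sigma2_pair + sigma2_mz_extra + sigma2_resid
  y <- numeric(nrow(cohort))
  if (length(blocks$i1)) {
    cv <- sigma2_pair + sigma2_mz_extra * blocks$mz
    zs <- stats::rnorm(length(blocks$i1), 0, sqrt((dg + cv) / 2))
    zd <- stats::rnorm(length(blocks$i1), 0, sqrt((dg - cv) / 2))
    y[blocks$i1] <- zs + zd
    y[blocks$i2] <- zs - zd
  }
  if (length(blocks$singles))
    y[blocks$singles] <- stats::rnorm(length(blocks$singles), 0, sqrt(dg))
  beta_0 + beta_age * cohort$age + y
}
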