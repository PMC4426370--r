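test_that("singleton log-likelihood equals the standard normal density", {
  co <- tiny_cohort(0, 0, 1, ages = 50)
  ll <- twin_loglik(0.7, co, list(beta_0 = 0.7, beta_age = 0,
                                  sigma2_pair = 0, sigma2_mz_extra = 0,
                                  sigma2_resid = 1))
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("block likelihood matches the dense multivariate-normal oracle", {
  co <- tiny_cohort(1, 1, 1, ages = c(45, 60, 72))
  params <- list(beta_0 = 0.3, beta_age = 0.01, sigma2_pair = 0.5,
                 sigma2_mz_extra = 0.25, sigma2_resid = 0.4)
  set.seed(1)
  y <- rnorm(5)
  expect_equal(twin_loglik(y, co, params), dense_twin_loglik(y, co, params),
               tolerance = 1e-10)
})

test_that("likelihood equals dense oracle over random draws on small cohorts", {
  set.seed(2)
  for (rep in 1:250) {
    n_mz <- sample(0:3, 1); n_dz <- sample(0:3, 1)
    n_s <- sample(0:3, 1)
    if (n_mz + n_dz + n_s == 0) n_s <- 1
    co <- tiny_cohort(n_mz, n_dz, n_s,
                      ages = runif(n_mz + n_dz + n_s, 39, 85))
    params <- list(beta_0 = rnorm(1), beta_age = rnorm(1, 0, 0.05),
                   sigma2_pair = runif(1, 0, 2),
                   sigma2_mz_extra = runif(1, 0, 2),
                   sigma2_resid = runif(1, 0.05, 2))
    y <- rnorm(nrow(co), 0, 2)
    expect_equal(twin_loglik(y, co, params),
                 dense_twin_loglik(y, co, params), tolerance = 1e-8)
  }
})

test_that("zero pair variances reduce to independent normals", {
  co <- tiny_cohort(1, 1, 1, ages = c(40, 55, 70))
  params <- list(beta_0 = 0.1, beta_age = 0.02, sigma2_pair = 0,
                 sigma2_mz_extra = 0, sigma2_resid = 0.8)
  set.seed(3)
  y <- rnorm(5)
  mu <- params$beta_0 + params$beta_age * co$age
  expect_equal(twin_loglik(y, co, params),
               sum(dnorm(y, mu, sqrt(0.8), log = TRUE)), tolerance = 1e-12)
})

test_that("singleton-only fit reproduces ordinary least squares", {
  set.seed(4)
  co <- tiny_cohort(0, 0, 40, ages = runif(40, 39, 85))
  y <- 1.5 + 0.03 * co$age + rnorm(40, 0, 0.5)
  fit <- fit_twin_model(y, co, include_age = TRUE)
  ols <- lm(y ~ co$age)
  expect_equal(fit$beta_age, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(fit$sigma2_pair + fit$sigma2_mz_extra + fit$sigma2_resid,
               mean(resid(ols)^2), tolerance = 1e-6)
})

test_that("variance components are recovered from model-simulated pairs", {
  co <- generate_cohort(cohort_spec(500, 500, seed = 5))
  est <- rowMeans(vapply(1:8, function(i) {
    y <- simulate_twin_phenotype(co, 0, 0, 0.5, 0.25, 0.25, seed = 100 + i)
    f <- fit_twin_model(y, co)
    c(f$sigma2_pair, f$sigma2_mz_extra, f$sigma2_resid)
  }, numeric(3)))
  expect_lt(abs(est[1] - 0.5), 0.05)
  expect_lt(abs(est[2] - 0.25), 0.05)
  expect_lt(abs(est[3] - 0.25), 0.05)
})

test_that("fitted likelihood beats the generating parameters (ML optimality)", {
  co <- generate_cohort(cohort_spec(100, 100, seed = 6))
  truth <- list(beta_0 = 0, beta_age = 0.01, sigma2_pair = 0.4,
                sigma2_mz_extra = 0.2, sigma2_resid = 0.4)
  for (i in 1:5) {
    y <- simulate_twin_phenotype(co, 0, 0.01, 0.4, 0.2, 0.4, seed = 200 + i)
    f <- fit_twin_model(y, co)
    expect_gte(f$loglik + 1e-6, twin_loglik(y, co, truth))
  }
})

test_that("twin model fit agrees with the lme4 nested random-effects fit", {
  skip_if_not_installed("lme4")
  # the model is y ~ age + (1 | family) + (1 | mz_unit) where the mz_unit
  # level is shared by MZ co-twins and unique to everyone else
  co <- generate_cohort(cohort_spec(60, 60, 10, seed = 7))
  y <- simulate_twin_phenotype(co, 1, 0.02, 0.3, 0.25, 0.45, seed = 8)
  dat <- cbind(co, y = y)
  dat$mz_unit <- ifelse(dat$zygosity == "MZ", dat$family_id,
                        dat$sample_id)
  fit <- fit_twin_model(y, co)
  lfit <- suppressMessages(
    lme4::lmer(y ~ age + (1 | family_id) + (1 | mz_unit), data = dat,
               REML = FALSE))
  expect_equal(fit$loglik, as.numeric(logLik(lfit)), tolerance = 1e-5)
  expect_equal(fit$beta_age, unname(lme4::fixef(lfit)[2]), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma2_pair,
               vc$vcov[vc$grp == "family_id"], tolerance = 1e-3)
  expect_equal(fit$sigma2_mz_extra,
               vc$vcov[vc$grp == "mz_unit"], tolerance = 1e-3)
})

test_that("degenerate inputs are rejected", {
  co <- tiny_cohort(5, 5, 2)
  expect_error(fit_twin_model(rep(1, nrow(co)), co), "zero variance")
  co_same <- tiny_cohort(5, 5, 2, ages = rep(50, 12))
  y <- rnorm(nrow(co_same))
  expect_error(fit_twin_model(y, co_same, include_age = TRUE),
               "identifiable")
  expect_error(fit_twin_model(rnorm(4), co), "length")
  co2 <- tiny_cohort(2, 2, 0)
  expect_error(fit_twin_model(rnorm(nrow(co2)), co2), "10 families")
})

test_that("LRT statistic, p-value and chi-square reference behave", {
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  co <- generate_cohort(cohort_spec(150, 150, seed = 9))
  # planted age effect is detected
  y <- simulate_twin_phenotype(co, 0, 0.05, 0.3, 0.2, 0.5, seed = 10)
  t1 <- lrt_age(y, co)
  expect_lt(t1$p_value, 1e-6)
  expect_gte(t1$lrt_stat, 0)
  # null phenotype gives an unremarkable statistic
  y0 <- simulate_twin_phenotype(co, 0, 0, 0.3, 0.2, 0.5, seed = 11)
  t0 <- lrt_age(y0, co)
  expect_gt(t0$p_value, 1e-4)
})

test_that("variance decomposition follows the MZ/DZ contrast arithmetic", {
  co <- generate_cohort(cohort_spec(50, 50, seed = 12))
  fit <- structure(list(beta_0 = 0, beta_age = 0, sigma2_pair = 0.5,
                        sigma2_mz_extra = 0.25, sigma2_resid = 0.25,
                        loglik = 0, converged = TRUE,
                        n_individuals = nrow(co), n_families = 100,
                        include_age = TRUE), class = "twin_fit")
  d <- decompose_variance(fit, co)
  expect_equal(d$h2, 0.5, tolerance = 1e-12)
  expect_equal(d$c2, 0.25, tolerance = 1e-12)
  expect_equal(d$e2, 0.25, tolerance = 1e-12)
  expect_equal(d$age_share_total, 0)
  expect_equal(d$age_share_env, 0)

  # rMZ = rDZ means no heritability
  fit$sigma2_mz_extra <- 0
  expect_equal(decompose_variance(fit, co)$h2, 0)

  # negative implied shared environment is clipped and renormalized
  fit2 <- fit
  fit2$sigma2_pair <- 0.1
  fit2$sigma2_mz_extra <- 0.4  # c2 = 0.1 - 0.4 < 0
  d2 <- decompose_variance(fit2, co)
  expect_equal(d2$c2, 0)
  expect_true(all(unlist(d2) >= 0 & unlist(d2) <= 1))
  expect_equal(d2$h2 + d2$c2 + d2$e2 + d2$age_share_total, 1,
               tolerance = 1e-8)

  # age share: fixed-effect variance over the cohort enters the total
  fit3 <- fit
  fit3$sigma2_mz_extra <- 0.25
  fit3$beta_age <- 0.05
  d3 <- decompose_variance(fit3, co)
  n <- nrow(co)
  v_age <- 0.05^2 * var(co$age) * (n - 1) / n
  expect_equal(d3$age_share_total, v_age / (v_age + 1), tolerance = 1e-10)
  expect_equal(d3$age_share_env, d3$age_share_total / (1 - d3$h2),
               tolerance = 1e-10)
})

test_that("heritability recovery is unbiased away from the zero boundary", {
  co <- generate_cohort(cohort_spec(250, 250, seed = 13))
  for (h2_true in c(0.3, 0.6)) {
    s2m <- h2_true / 2
    s2p <- s2m + 0.15            # shared environment 0.15
    s2r <- 1 - s2p - s2m
    est <- vapply(1:25, function(i) {
      y <- simulate_twin_phenotype(co, 0, 0, s2p, s2m, s2r,
                                   seed = 1000 * h2_true + i)
      decompose_variance(fit_twin_model(y, co), co)$h2
    }, numeric(1))
    expect_lt(abs(mean(est) - h2_true), 0.06)
  }
  # at h2 = 0 the [0, 1] constraint folds the sampling noise upward; the
  # typical (median) estimate stays at or near the boundary
  est0 <- vapply(1:25, function(i) {
    y <- simulate_twin_phenotype(co, 0, 0, 0.15, 0, 0.85, seed = 40000 + i)
    decompose_variance(fit_twin_model(y, co), co)$h2
  }, numeric(1))
  expect_lt(median(est0), 0.05)
  expect_lt(mean(est0), 0.15)
})
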