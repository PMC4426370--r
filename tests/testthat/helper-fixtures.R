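# Shared fixtures and independent oracles for the test suite.

# Hand-built tiny roster: n_mz + n_dz pairs and n_s singletons with fixed ages.
tiny_cohort <- function(n_mz = 1, n_dz = 1, n_s = 1, ages = NULL) {
  n_units <- n_mz + n_dz + n_s
  zyg <- c(rep("MZ", n_mz), rep("DZ", n_dz), rep("singleton", n_s))
  sizes <- ifelse(zyg == "singleton", 1L, 2L)
  if (is.null(ages)) ages <- seq(40, 80, length.out = n_units)
  fam <- sprintf("f%02d", seq_len(n_units))
  row_unit <- rep(seq_len(n_units), sizes)
  ids <- sprintf("%s_%d", fam[row_unit], sequence(sizes))
  co <- data.frame(sample_id = ids, individual_id = ids,
                   family_id = fam[row_unit], zygosity = zyg[row_unit],
                   age = ages[row_unit], batch = "b1",
                   rna_quality = 8, rna_concentration = 100,
                   stringsAsFactors = FALSE)
  validate_cohort(co)
}

# Dense multivariate-normal log-likelihood over the full cohort covariance:
# the brute-force oracle for the block twin likelihood.
dense_twin_loglik <- function(y, cohort, params) {
  n <- nrow(cohort)
  S <- matrix(0, n, n)
  dg <- params$sigma2_pair + params$sigma2_mz_extra + params$sigma2_resid
  for (f in unique(cohort$family_id)) {
    ix <- which(cohort$family_id == f)
    mz <- cohort$zygosity[ix[1]] == "MZ"
    cv <- params$sigma2_pair + if (mz) params$sigma2_mz_extra else 0
    if (length(ix) == 2) S[ix[1], ix[2]] <- S[ix[2], ix[1]] <- cv
    for (i in ix) S[i, i] <- dg
  }
  mu <- params$beta_0 + params$beta_age * cohort$age
  r <- y - mu
  ch <- chol(S)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, r, transpose = TRUE)^2))
}

# Upper-tail hypergeometric sum by direct enumeration: Fisher oracle.
hyper_tail_p <- function(k, n_set, n_sig, n_univ) {
  kmax <- min(n_set, n_sig)
  sum(stats::dhyper(k:kmax, n_sig, n_univ - n_sig, n_set))
}

# One-sample Kolmogorov-Smirnov statistic against Uniform(0, 1).
ks_uniform_stat <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(pmax(abs((1:n) / n - s), abs(s - (0:(n - 1)) / n)))
}

# Small expression matrix with named dims.
rand_expr <- function(n, g, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * g, 0, sd), n, g)
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("g%03d", seq_len(g)))
  m
}
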