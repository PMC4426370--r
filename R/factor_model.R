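#' Bayesian factor analysis with observed covariates
#'
#' Fits `Y ~ C B + X W' + e` by expectation-maximization: the factor scores
#' X are the latent variables, the weights W carry a per-factor automatic
#' relevance determination (ARD) precision with a Gamma(1e-3, 1e-3)
#' hyperprior that shrinks uninformative factors, noise is per-gene (or
#' optionally isotropic), and the observed covariates C are unpenalized
#' fixed effects re-estimated each iteration. The maximized objective is
#' the observed-data log-likelihood plus the log prior on W and the ARD
#' precisions; it is non-decreasing across iterations.
#'
#' Initialization is deterministic: scores start at the top-K left singular
#' vectors of the covariate-adjusted matrix, so fits are reproducible
#' without a seed. After convergence each score vector is standardized to
#' unit variance (the weights absorb the scale) and signs are fixed so the
#' gene with the largest absolute weight on each factor has positive
#' weight.
#'
#' Variance accounting is by sequential orthogonal projection of the
#' covariate-adjusted data onto the factor scores: `per_factor_variance`
#' are incremental fractions that sum exactly to `variance_explained_total`
#' and all lie in `[0, 1]`.
#'
#' @param Y Samples x genes numeric matrix.
#' @param covariates Samples x p design matrix of observed covariates, or
#'   `NULL` for an intercept-only design. Pass a zero-column matrix for no
#'   covariates at all.
#' @param K Number of factors (`K = 0` collapses to covariate regression).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @param ard Use ARD precisions on the weights (`FALSE` gives a flat
#'   prior, the maximum-likelihood factor model).
#' @param noise `"per_gene"` (factor analysis) or `"isotropic"`
#'   (probabilistic PCA).
#' @return A `factor_fit` with elements `K`, `weights` (genes x K),
#'   `scores` (samples x K, unit variance), `covariate_effects`,
#'   `gene_noise_variances`, `ard_precisions`, `log_marginal_trace`,
#'   `variance_explained_total`, `per_factor_variance`, `converged`.
#' @export
fit_factor_model <- function(Y, covariates = NULL, K = 5,
                             max_iter = 1000, tol = 1e-6,
                             ard = TRUE,
                             noise = c("per_gene", "isotropic")) {
  noise <- match.arg(noise)
  if (!is.matrix(Y) || !is.numeric(Y)) stop("Y must be a numeric matrix")
  if (any(!is.finite(Y))) stop("Y must be complete (finite values only)")
  K <- .assert_scalar_count(K, "K")
  n <- nrow(Y); G <- ncol(Y)
  C <- .design_matrix(covariates, n)
  p <- ncol(C)
  if (K > min(n, G)) stop("K exceeds the feasible rank min(samples, genes)")
  if (n < K + p + 2)
    stop("need at least K + covariates + 2 samples")

  fitB <- function(Ytarget) {
    if (p == 0) matrix(0, 0, G) else qr.coef(qr(C), Ytarget)
  }
  B <- fitB(Y)
  Yr <- Y - C %*% B

  if (K == 0) {
    fit <- list(K = 0L, weights = matrix(0, G, 0), scores = matrix(0, n, 0),
                covariate_effects = B,
                gene_noise_variances = colMeans(Yr^2),
                ard_precisions = numeric(0),
                log_marginal_trace = numeric(0),
                variance_explained_total = 0,
                per_factor_variance = numeric(0),
                converged = TRUE, covariates = C,
                sample_ids = rownames(Y), gene_ids = colnames(Y))
    class(fit) <- "factor_fit"
    return(fit)
  }

  sv <- svd(Yr, nu = K, nv = K)
  d <- sv$d[seq_len(K)]
  EX <- sv$u * sqrt(n)
  W <- sv$v * rep(d / sqrt(n), each = G)
  resid0 <- Yr - EX %*% t(W)
  psi <- pmax(colMeans(resid0^2), 1e-8)
  if (noise == "isotropic") psi <- rep(mean(psi), G)
  alpha <- G / pmax(colSums(W^2), 1e-12)
  a0 <- 1e-3; b0 <- 1e-3

  objective <- function(Yr, W, psi, alpha) {
    iw <- W / psi
    M <- diag(K) + crossprod(W, iw)
    ch <- chol(M)
    logdet <- sum(log(psi)) + 2 * sum(log(diag(ch)))
    T1 <- Yr %*% iw
    T2 <- T1 %*% chol2inv(ch)
    quad <- sum(Yr^2 / rep(psi, each = n)) - sum(T2 * T1)
    ll <- -0.5 * (n * G * log(2 * pi) + n * logdet + quad)
    if (ard) {
      lp <- sum(0.5 * G * log(alpha / (2 * pi)) -
                  0.5 * alpha * colSums(W^2)) +
        sum((a0 - 1) * log(alpha) - b0 * alpha)
      ll <- ll + lp
    }
    ll
  }

  trace <- numeric(0)
  converged <- FALSE
  obj_prev <- -Inf
  for (it in seq_len(max_iter)) {
    # E-step
    iw <- W / psi
    M <- diag(K) + crossprod(W, iw)
    Sig <- chol2inv(chol(M))
    EX <- Yr %*% iw %*% Sig
    EXX <- n * Sig + crossprod(EX)

    # M-step: weights
    XtY <- crossprod(EX, Yr)                      # K x G
    if (ard && noise == "per_gene") {
      Wt <- vapply(seq_len(G), function(g)
        solve(EXX + psi[g] * diag(alpha, K), XtY[, g]),
        numeric(K))
      W <- t(matrix(Wt, K, G))
    } else if (ard) {
      W <- t(solve(EXX + psi[1] * diag(alpha, K), XtY))
    } else {
      W <- t(solve(EXX, XtY))
    }

    # M-step: noise
    ss <- colSums(Yr^2) - 2 * rowSums(W * t(XtY)) +
      rowSums((W %*% EXX) * W)
    psi <- pmax(ss / n, 1e-10)
    if (noise == "isotropic") psi <- rep(mean(psi), G)

    # M-step: ARD precisions
    if (ard)
      alpha <- pmin((G + 2 * (a0 - 1)) / (colSums(W^2) + 2 * b0), 1e8)

    # M-step: covariates (subtract current factor reconstruction)
    if (p > 0) {
      B <- fitB(Y - EX %*% t(W))
      Yr <- Y - C %*% B
    }

    obj <- objective(Yr, W, psi, alpha)
    trace <- c(trace, obj)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) < tol * (abs(obj_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged)
    warning("factor model did not converge in ", max_iter, " iterations")

  # final E-step so scores match the returned weights
  iw <- W / psi
  Sig <- chol2inv(chol(diag(K) + crossprod(W, iw)))
  EX <- Yr %*% iw %*% Sig

  # identifiability: unit-variance scores, dominant weight positive
  sdx <- apply(EX, 2, stats::sd)
  sdx[sdx < 1e-12] <- 1
  X <- EX / rep(sdx, each = n)
  W <- W * rep(sdx, each = G)
  for (k in seq_len(K)) {
    g <- which.max(abs(W[, k]))
    if (W[g, k] < 0) {
      W[, k] <- -W[, k]
      X[, k] <- -X[, k]
    }
  }

  ve <- .variance_ledger(Yr, X)
  fit <- list(K = K, weights = W, scores = X, covariate_effects = B,
              gene_noise_variances = psi, ard_precisions = alpha,
              log_marginal_trace = trace,
              variance_explained_total = ve$total,
              per_factor_variance = ve$per_factor,
              converged = converged, covariates = C,
              sample_ids = rownames(Y), gene_ids = colnames(Y))
  rownames(fit$weights) <- colnames(Y)
  rownames(fit$scores) <- rownames(Y)
  class(fit) <- "factor_fit"
  fit
}

# Intercept-only default design; NULL -> intercept, 0-column matrix allowed.
.design_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1,
                                         dimnames = list(NULL, "intercept")))
  C <- as.matrix(covariates)
  if (nrow(C) != n && ncol(C) > 0)
    stop("covariates must have one row per sample")
  if (ncol(C) == 0) return(matrix(0, n, 0))
  storage.mode(C) <- "double"
  if (any(!is.finite(C))) stop("covariates must be finite")
  C
}

# Incremental variance fractions from sequential orthogonal projection of
# the (covariate-adjusted) data onto the score columns.
.variance_ledger <- function(Yadj, X) {
  Yc <- sweep(Yadj, 2, colMeans(Yadj))
  ss_tot <- sum(Yc^2)
  if (ss_tot <= 0) stop("zero total variance")
  K <- ncol(X)
  if (K == 0) return(list(total = 0, per_factor = numeric(0)))
  Xc <- sweep(X, 2, colMeans(X))
  # collapsed (near-constant) score columns explain nothing by definition
  live <- which(apply(Xc, 2, stats::sd) > 1e-10)
  per <- numeric(K)
  if (length(live)) {
    qrX <- qr(Xc[, live, drop = FALSE])
    Q <- qr.Q(qrX)
    for (j in seq_len(min(length(live), qrX$rank))) {
      proj <- crossprod(Q[, j, drop = FALSE], Yc)
      per[live[j]] <- sum(proj^2) / ss_tot
    }
  }
  list(total = sum(per), per_factor = per)
}

#' Remove covariate and factor signal from an expression matrix
#'
#' Regresses every gene on the fit's covariates and factor scores jointly
#' (ordinary least squares) and returns the residuals, so each residual
#' gene vector is numerically orthogonal to every factor score and
#' covariate column. This is the "regress the global factors out as
#' nuisance covariates" step that precedes pathway factor analysis.
#'
#' @param Y The samples x genes matrix the fit was produced from (or any
#'   matrix over the same samples).
#' @param fit A `factor_fit`.
#' @return Residual matrix with the same dimnames as `Y`.
#' @export
residualize <- function(Y, fit) {
  if (!inherits(fit, "factor_fit")) stop("'fit' must be a factor_fit")
  if (nrow(Y) != nrow(fit$scores) && fit$K > 0)
    stop("sample mismatch between Y and fit")
  if (nrow(Y) != nrow(fit$covariates) && ncol(fit$covariates) > 0)
    stop("sample mismatch between Y and fit covariates")
  D <- cbind(fit$covariates, fit$scores)
  if (ncol(D) == 0) return(Y)
  res <- stats::lm.fit(D, Y)$residuals
  dimnames(res) <- dimnames(Y)
  res
}

#' Fraction of variance explained by a factor fit
#'
#' Computes `1 - SS_residual / SS_total` after covariate adjustment, where
#' the factor contribution is the orthogonal projection of the adjusted
#' data onto the fitted scores. Always in `[0, 1]`.
#'
#' @param fit A `factor_fit`.
#' @param Y The matrix the fit was produced from.
#' @return A single fraction.
#' @export
variance_explained <- function(fit, Y) {
  if (!inherits(fit, "factor_fit")) stop("'fit' must be a factor_fit")
  if (nrow(Y) != nrow(fit$covariates) && ncol(fit$covariates) > 0)
    stop("sample mismatch")
  Yadj <- if (ncol(fit$covariates) > 0)
    Y - fit$covariates %*% fit$covariate_effects else Y
  .variance_ledger(Yadj, fit$scores)$total
}

#' Serialize a factor fit to a JSON + TSV bundle
#'
#' Writes `<stem>.json` (dimensions, diagnostics, ARD precisions, objective
#' trace) plus `<stem>_weights.tsv` and `<stem>_scores.tsv`.
#'
#' @param fit A `factor_fit`.
#' @param stem Output path stem.
#' @return The JSON path, invisibly.
#' @export
write_factor_fit <- function(fit, stem) {
  if (!inherits(fit, "factor_fit")) stop("'fit' must be a factor_fit")
  meta <- list(K = fit$K,
               variance_explained_total = fit$variance_explained_total,
               per_factor_variance = fit$per_factor_variance,
               ard_precisions = fit$ard_precisions,
               gene_noise_variances = fit$gene_noise_variances,
               log_marginal_trace = fit$log_marginal_trace,
               converged = fit$converged)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  wt <- data.frame(gene_id = rownames(fit$weights), fit$weights,
                   check.names = FALSE)
  utils::write.table(wt, paste0(stem, "_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sc <- data.frame(sample_id = rownames(fit$scores), fit$scores,
                   check.names = FALSE)
  utils::write.table(sc, paste0(stem, "_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(stem, ".json"))
}
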