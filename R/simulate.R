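#' Ground truth for a synthetic expression study
#'
#' Builds the `simulation_truth` object that [generate_expression()] turns
#' into a log2-scale expression matrix for a given cohort. The generator
#' emulates a post-QC twin expression study: low-rank global confounders
#' loading on every gene, one latent co-expression module per pathway
#' loading on a fraction of its member genes, per-gene additive-genetic (A),
#' shared-environment (C) and unique-environment (E) variance, and linear
#' age effects planted on the module genes of a subset of pathways. The
#' module latent score itself carries an A/C/E decomposition so planted
#' modules are heritable phenotypes that pathway factor analysis can
#' recover.
#'
#' Per-gene variance fractions `v_a + v_c + v_e` must not exceed 1; the
#' remainder of the unit budget is taken up by the factor, module and age
#' signal.
#'
#' @param cohort A `twin_cohort` (the global factor scores are drawn per
#'   sample, so the truth is tied to this cohort).
#' @param pathway_sizes Integer vector of member-gene counts, one entry per
#'   pathway. Default: 20 pathways of 10 genes.
#' @param n_genes Total gene universe size; must be at least
#'   `sum(pathway_sizes)`. Genes beyond the pathway members are background
#'   genes in no pathway.
#' @param k_global Number of global confounding factors.
#' @param global_weight_sd Standard deviation of global factor weights; with
#'   unit-variance scores, the expected global variance per gene is
#'   `k_global * global_weight_sd^2`.
#' @param module_variance Variance contributed by the pathway module latent
#'   to each loaded gene.
#' @param module_loading_fraction Fraction of a pathway's member genes that
#'   load on its module latent.
#' @param module_ace Length-3 vector of A/C/E fractions (summing to 1) for
#'   the module latent score itself.
#' @param n_age_pathways Number of pathways whose module genes receive an
#'   age effect (the first pathways in order).
#' @param age_effect Age slope for responsive genes, expression units/year.
#' @param v_a,v_c,v_e Per-gene additive-genetic, shared-environment and
#'   unique-environment variance fractions (applied to every gene).
#' @param baseline_mean Mean baseline log2 expression.
#' @param seed Integer seed for all truth- and expression-level randomness.
#' @return A `simulation_truth` object.
#' @export
simulate_truth <- function(cohort,
                           pathway_sizes = rep(10L, 20L),
                           n_genes = sum(pathway_sizes),
                           k_global = 5,
                           global_weight_sd = sqrt(0.06),
                           module_variance = 0.3,
                           module_loading_fraction = 0.3,
                           module_ace = c(0.6, 0.1, 0.3),
                           n_age_pathways = min(3L, length(pathway_sizes)),
                           age_effect = 0.02,
                           v_a = 0.15, v_c = 0.05, v_e = 0.5,
                           baseline_mean = 8,
                           seed = 1) {
  validate_cohort(cohort)
  .assert_scalar_count(k_global, "k_global")
  .assert_scalar_count(n_age_pathways, "n_age_pathways")
  if (n_genes < sum(pathway_sizes))
    stop("n_genes must cover all pathway members")
  if (any(pathway_sizes < 1)) stop("pathway sizes must be >= 1")
  if (n_age_pathways > length(pathway_sizes))
    stop("n_age_pathways exceeds the number of pathways")
  if (length(module_ace) != 3 || any(module_ace < 0) ||
      abs(sum(module_ace) - 1) > 1e-8)
    stop("module_ace must be 3 nonnegative fractions summing to 1")
  if (min(v_a, v_c, v_e) < 0 || v_a + v_c + v_e > 1)
    stop("per-gene variance fractions must be nonnegative with sum <= 1")

  n <- nrow(cohort)
  genes <- sprintf("g%05d", seq_len(n_genes))
  n_pw <- length(pathway_sizes)
  pw_ids <- sprintf("pw%03d", seq_len(n_pw))
  stops <- cumsum(pathway_sizes)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  pathways <- stats::setNames(
    lapply(seq_len(n_pw), function(j) genes[starts[j]:stops[j]]), pw_ids)

  set.seed(.stream_seed(seed, "truth"))
  scores <- matrix(stats::rnorm(n * k_global), n, k_global,
                   dimnames = list(cohort$sample_id,
                                   paste0("gf", seq_len(max(k_global, 1)))[seq_len(k_global)]))
  weights <- matrix(stats::rnorm(n_genes * k_global, 0, global_weight_sd),
                    n_genes, k_global, dimnames = list(genes, colnames(scores)))
  baseline <- stats::setNames(stats::rnorm(n_genes, baseline_mean, 0.5), genes)

  # which member genes carry the module latent (at least one per pathway);
  # the same selection receives the age effect in age-responsive pathways,
  # independent of the loading magnitude
  loadings <- stats::setNames(vector("list", n_pw), pw_ids)
  selected <- vector("list", n_pw)
  for (j in seq_len(n_pw)) {
    mem <- pathways[[j]]
    k <- max(1L, round(module_loading_fraction * length(mem)))
    hit <- sort(sample(length(mem), k))
    lo <- stats::setNames(numeric(length(mem)), mem)
    lo[hit] <- sqrt(module_variance)
    loadings[[j]] <- lo
    selected[[j]] <- mem[hit]
  }

  age_beta <- stats::setNames(numeric(n_genes), genes)
  if (n_age_pathways > 0)
    for (j in seq_len(n_age_pathways))
      age_beta[selected[[j]]] <- age_effect

  vf <- cbind(v_a = rep(v_a, n_genes), v_c = rep(v_c, n_genes),
              v_e = rep(v_e, n_genes))
  rownames(vf) <- genes

  structure(
    list(genes = genes,
         pathway_module_assignments = pathways,
         module_loadings = loadings,
         module_ace = stats::setNames(module_ace, c("a", "c", "e")),
         global_factor_scores = scores,
         global_weights = weights,
         baseline = baseline,
         age_effect_sizes = age_beta,
         variance_fractions = vf,
         seed = seed),
    class = "simulation_truth"
  )
}

#' Simulate a log2 expression matrix for a twin cohort
#'
#' Assembles `Y[i, g] = baseline_g + global + module + age_effect_g * age_i
#' + A_ig + C_ig + E_ig`. The additive-genetic component A is shared exactly
#' between MZ co-twins and correlated 0.5 between DZ co-twins; the shared
#' environment C is identical within any twin pair; E is independent noise.
#' Component variances follow `truth$variance_fractions`. Random draws are
#' keyed to gene and pathway identifiers in sorted order, so permuting the
#' gene order in the truth permutes the matrix columns identically.
#' Deterministic given `truth$seed`.
#'
#' @param cohort The `twin_cohort` the truth was built for.
#' @param truth A `simulation_truth` from [simulate_truth()].
#' @return Samples x genes numeric matrix with sample ids as row names and
#'   gene ids as column names.
#' @export
generate_expression <- function(cohort, truth) {
  validate_cohort(cohort)
  if (!inherits(truth, "simulation_truth"))
    stop("'truth' must be a simulation_truth")
  n <- nrow(cohort)
  if (nrow(truth$global_factor_scores) != n)
    stop("cohort size does not match truth global factor scores")
  genes <- truth$genes
  if (length(genes) == 0) stop("truth gene universe is empty")
  gs <- sort(genes)
  G <- length(gs)

  fam_ids <- unique(cohort$family_id)
  u <- match(cohort$family_id, fam_ids)
  n_units <- length(fam_ids)
  is_mz <- cohort$zygosity == "MZ"
  is_dz <- cohort$zygosity == "DZ"
  # family-share vs individual coefficients for the additive component
  coef_f <- ifelse(is_mz, 1, ifelse(is_dz, sqrt(0.5), 0))
  coef_i <- ifelse(is_mz, 0, ifelse(is_dz, sqrt(0.5), 1))

  set.seed(.stream_seed(truth$seed, "expression"))
  zfA <- matrix(stats::rnorm(n_units * G), n_units, G)
  ziA <- matrix(stats::rnorm(n * G), n, G)
  zfC <- matrix(stats::rnorm(n_units * G), n_units, G)
  zE <- matrix(stats::rnorm(n * G), n, G)

  pw_sorted <- sort(names(truth$pathway_module_assignments))
  P <- length(pw_sorted)
  if (P > 0) {
    zmF <- matrix(stats::rnorm(n_units * P), n_units, P)
    zmI <- matrix(stats::rnorm(n * P), n, P)
    zmC <- matrix(stats::rnorm(n_units * P), n_units, P)
    zmE <- matrix(stats::rnorm(n * P), n, P)
    ac <- truth$module_ace
    module_scores <- sqrt(ac[["a"]]) * (coef_f * zmF[u, , drop = FALSE] +
                                          coef_i * zmI) +
      sqrt(ac[["c"]]) * ((is_mz | is_dz) * zmC[u, , drop = FALSE]) +
      sqrt(ac[["e"]]) * zmE
    colnames(module_scores) <- pw_sorted
  }

  vf <- truth$variance_fractions[gs, , drop = FALSE]
  sA <- rep(sqrt(vf[, "v_a"]), each = n)
  sC <- rep(sqrt(vf[, "v_c"]), each = n)
  sE <- rep(sqrt(vf[, "v_e"]), each = n)

  A <- (coef_f * zfA[u, , drop = FALSE] + coef_i * ziA) * sA
  C <- ((is_mz | is_dz) * zfC[u, , drop = FALSE]) * sC
  E <- zE * sE

  W <- truth$global_weights[gs, , drop = FALSE]
  Y <- truth$global_factor_scores %*% t(W) + A + C + E
  Y <- Y + rep(truth$baseline[gs], each = n)
  Y <- Y + outer(cohort$age, truth$age_effect_sizes[gs])

  if (P > 0) {
    for (pw in pw_sorted) {
      lo <- truth$module_loadings[[pw]]
      lo <- lo[lo != 0]
      if (length(lo))
        Y[, names(lo)] <- Y[, names(lo), drop = FALSE] +
          module_scores[, pw] %o% unname(lo)
    }
  }

  dimnames(Y) <- list(cohort$sample_id, gs)
  Y[, genes, drop = FALSE]
}

#' Gene sets implied by a simulation truth
#'
#' @param truth A `simulation_truth`.
#' @return A `gene_set_collection` of the pathway membership lists.
#' @export
truth_gene_sets <- function(truth) {
  if (!inherits(truth, "simulation_truth"))
    stop("'truth' must be a simulation_truth")
  sets <- truth$pathway_module_assignments
  new_gene_set_collection(sets,
                          descriptions = rep("synthetic pathway",
                                             length(sets)))
}

#' Serialize a simulation truth to JSON and back
#'
#' The truth object is written as a JSON sidecar next to the expression and
#' metadata tables so a simulated study is fully reconstructable from text
#' files.
#'
#' @param truth A `simulation_truth`.
#' @param path File path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the object.
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "simulation_truth"))
    stop("'truth' must be a simulation_truth")
  payload <- list(
    genes = truth$genes,
    pathway_module_assignments = truth$pathway_module_assignments,
    module_loadings = lapply(truth$module_loadings, as.list),
    module_ace = as.list(truth$module_ace),
    global_factor_scores = truth$global_factor_scores,
    global_weights = truth$global_weights,
    sample_ids = rownames(truth$global_factor_scores),
    baseline = as.list(truth$baseline),
    age_effect_sizes = as.list(truth$age_effect_sizes),
    variance_fractions = apply(truth$variance_fractions, 1, as.list,
                               simplify = FALSE),
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vf <- do.call(rbind, lapply(p$variance_fractions, function(x)
    unlist(x)[c("v_a", "v_c", "v_e")]))
  rownames(vf) <- names(p$variance_fractions)
  scores <- as.matrix(p$global_factor_scores)
  rownames(scores) <- p$sample_ids
  weights <- as.matrix(p$global_weights)
  rownames(weights) <- p$genes
  structure(
    list(genes = p$genes,
         pathway_module_assignments = lapply(p$pathway_module_assignments,
                                             as.character),
         module_loadings = lapply(p$module_loadings, unlist),
         module_ace = unlist(p$module_ace)[c("a", "c", "e")],
         global_factor_scores = scores,
         global_weights = weights,
         baseline = unlist(p$baseline),
         age_effect_sizes = unlist(p$age_effect_sizes),
         variance_fractions = vf,
         seed = p$seed),
    class = "simulation_truth"
  )
}
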