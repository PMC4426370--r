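#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (!.is_number(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  n_tests <- .assert_scalar_count(n_tests, "n_tests", min = 1L)
  alpha / n_tests
}

#' Test every pathway phenotype for an age effect
#'
#' Runs the twin likelihood-ratio age test ([lrt_age()]) on each pathway
#' factor phenotype and flags significance at the Bonferroni threshold over
#' the total phenotype count. Rows are ordered by pathway id then factor
#' index.
#'
#' @param phenotypes A `pathway_phenotypes` object.
#' @param cohort A `twin_cohort` whose samples align with the phenotype
#'   scores.
#' @param alpha Family-wise error rate (default 0.05).
#' @return An association table: data frame with `pathway_id`,
#'   `factor_index`, `beta_age`, `lrt_stat`, `p_value`,
#'   `significant_bonferroni`, `converged`; the Bonferroni threshold is
#'   attached as attribute `threshold`.
#' @export
test_all_phenotypes <- function(phenotypes, cohort, alpha = 0.05) {
  if (!inherits(phenotypes, "pathway_phenotypes"))
    stop("'phenotypes' must be a pathway_phenotypes object")
  validate_cohort(cohort)
  if (!identical(phenotypes$sample_ids, cohort$sample_id))
    stop("phenotype samples and cohort samples are misaligned")
  info <- phenotypes$info
  ord <- order(info$pathway_id, info$factor_index)
  info <- info[ord, , drop = FALSE]
  n_tests <- nrow(info)
  thr <- bonferroni_threshold(alpha, n_tests)
  out <- lapply(seq_len(n_tests), function(r) {
    cn <- sprintf("%s.f%d", info$pathway_id[r], info$factor_index[r])
    t <- lrt_age(phenotypes$scores[, cn], cohort)
    data.frame(pathway_id = info$pathway_id[r],
               factor_index = info$factor_index[r],
               beta_age = t$beta_age, lrt_stat = t$lrt_stat,
               p_value = t$p_value,
               significant_bonferroni = t$p_value < thr,
               converged = t$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "threshold") <- thr
  attr(tab, "alpha") <- alpha
  tab
}

#' Twin-structure-preserving cohort permutation
#'
#' Builds a permuted cohort for empirical null analyses by reassigning the
#' family-level attributes (family id and shared age) among family units
#' within each stratum: MZ pairs exchange with MZ pairs, DZ pairs with DZ
#' pairs, singletons with singletons, and twin pairs are always kept
#' together. Zygosity labels, pair memberships and the multiset of ages
#' are unchanged; only the phenotype-to-(age, family) assignment moves.
#'
#' @param cohort A `twin_cohort`.
#' @param seed Integer seed; deterministic.
#' @return A permuted `twin_cohort` with the same row (sample) order.
#' @export
permute_cohort <- function(cohort, seed = 1) {
  validate_cohort(cohort)
  set.seed(.stream_seed(seed, "permutation"))
  fam_ids <- unique(cohort$family_id)
  first <- match(fam_ids, cohort$family_id)
  unit_zyg <- cohort$zygosity[first]
  unit_age <- cohort$age[first]
  new_fam <- fam_ids
  new_age <- unit_age
  for (z in unique(unit_zyg)) {
    ix <- which(unit_zyg == z)
    perm <- if (length(ix) > 1) sample(ix) else ix
    new_fam[ix] <- fam_ids[perm]
    new_age[ix] <- unit_age[perm]
  }
  u <- match(cohort$family_id, fam_ids)
  out <- cohort
  out$family_id <- new_fam[u]
  out$age <- new_age[u]
  validate_cohort(out)
  out
}

#' Permutation null distribution of the age tests
#'
#' Re-runs [test_all_phenotypes()] on `n_perm` independently permuted
#' cohorts; the pooled p-values form the empirical null used for Q-Q
#' comparison (the customary display pools 10 permuted analyses).
#'
#' @param phenotypes A `pathway_phenotypes` object.
#' @param cohort A `twin_cohort`.
#' @param n_perm Number of permutations (default 10).
#' @param seed Integer master seed; permutation `i` uses `seed + i`.
#' @param alpha Passed through to [test_all_phenotypes()].
#' @return List of length `n_perm`; element `i` is the p-value vector of
#'   permutation `i` (named by phenotype).
#' @export
permutation_null_run <- function(phenotypes, cohort, n_perm = 10, seed = 1,
                                 alpha = 0.05) {
  n_perm <- .assert_scalar_count(n_perm, "n_perm", min = 1L)
  lapply(seq_len(n_perm), function(i) {
    perm <- permute_cohort(cohort, seed = seed + i)
    tab <- test_all_phenotypes(phenotypes, perm, alpha = alpha)
    stats::setNames(tab$p_value,
                    sprintf("%s.f%d", tab$pathway_id, tab$factor_index))
  })
}

#' Single-gene age tests with multiple-testing control
#'
#' Runs the twin LRT age test on every gene of the (residualized)
#' expression matrix, flags Bonferroni significance at `alpha / n_genes`
#' and attaches Benjamini-Hochberg q-values across all genes.
#'
#' @param residuals Samples x genes residual matrix.
#' @param cohort A `twin_cohort` aligned with the matrix rows.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Data frame with `gene_id`, `beta_age`, `lrt_stat`, `p_value`,
#'   `q_value`, `significant_bonferroni`, `converged`.
#' @export
single_gene_tests <- function(residuals, cohort, alpha = 0.05) {
  validate_cohort(cohort)
  if (nrow(residuals) != nrow(cohort))
    stop("expression samples and cohort samples are misaligned")
  genes <- colnames(residuals)
  thr <- bonferroni_threshold(alpha, length(genes))
  out <- lapply(genes, function(g) {
    t <- lrt_age(residuals[, g], cohort)
    data.frame(gene_id = g, beta_age = t$beta_age, lrt_stat = t$lrt_stat,
               p_value = t$p_value, converged = t$converged,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant_bonferroni <- tab$p_value < thr
  rownames(tab) <- NULL
  attr(tab, "threshold") <- thr
  tab[, c("gene_id", "beta_age", "lrt_stat", "p_value", "q_value",
          "significant_bonferroni", "converged")]
}

#' Per-pathway follow-up of member genes
#'
#' Within one pathway, flags member genes whose age-test p-value passes a
#' within-pathway Bonferroni threshold (`alpha` divided by the number of
#' genes in the pathway).
#'
#' @param gene_table Output of [single_gene_tests()].
#' @param members Character vector of the pathway's member gene ids.
#' @param alpha Family-wise error rate (default 0.05).
#' @return The member-gene rows of `gene_table` with a
#'   `significant_in_pathway` flag.
#' @export
pathway_gene_followup <- function(gene_table, members, alpha = 0.05) {
  sub <- gene_table[gene_table$gene_id %in% members, , drop = FALSE]
  if (nrow(sub) == 0) return(cbind(sub, significant_in_pathway = logical(0)))
  thr <- bonferroni_threshold(alpha, nrow(sub))
  sub$significant_in_pathway <- sub$p_value < thr
  sub
}

#' Fisher exact gene-set enrichment
#'
#' One-sided (greater) Fisher exact test per pathway on the 2x2 table of
#' in-set vs out-of-set by significant vs non-significant genes, against a
#' stated gene universe. Set members are intersected with the universe.
#'
#' @param sig_genes Character vector of significant gene ids (must be a
#'   subset of `universe`).
#' @param sets A `gene_set_collection`.
#' @param universe Character vector of all tested gene ids.
#' @return Data frame with `pathway_id`, `n_genes`, `n_significant_genes`,
#'   `n_universe`, `n_sig_universe`, `fisher_p`.
#' @export
fisher_enrichment <- function(sig_genes, sets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  if (!all(sig_genes %in% universe))
    stop("sig_genes must be a subset of the universe")
  n_u <- length(universe)
  n_s <- length(unique(sig_genes))
  rows <- lapply(names(sets), function(pw) {
    mem <- intersect(sets[[pw]], universe)
    k <- sum(mem %in% sig_genes)
    tab <- matrix(c(k, length(mem) - k,
                    n_s - k, n_u - length(mem) - (n_s - k)), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(pathway_id = pw, n_genes = length(mem),
               n_significant_genes = k, n_universe = n_u,
               n_sig_universe = n_s, fisher_p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concordance between factor-based and enrichment-based pathway p-values
#'
#' Spearman rank correlation (midrank ties) with its asymptotic p-value,
#' between the per-pathway summary p-value of the factor analysis
#' (by default the minimum over the pathway's K factor p-values) and the
#' Fisher enrichment p-value.
#'
#' @param pathway_factor_p Named numeric vector: per-pathway factor-based
#'   p-value (e.g. from [pathway_min_p()]).
#' @param enrichment_p Named numeric vector: per-pathway enrichment
#'   p-value; names must cover the same pathways.
#' @return List with `rho` and `p_value`.
#' @export
compare_methods <- function(pathway_factor_p, enrichment_p) {
  common <- intersect(names(pathway_factor_p), names(enrichment_p))
  if (length(common) < 3)
    stop("need at least 3 shared pathways to compare methods")
  ct <- suppressWarnings(
    stats::cor.test(pathway_factor_p[common], enrichment_p[common],
                    method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_pathways = length(common))
}

#' Reduce factor-level p-values to one per pathway
#'
#' @param assoc_table Output of [test_all_phenotypes()].
#' @param method `"min"` (raw minimum over the pathway's factors) or
#'   `"sidak"` (Sidak-adjusted minimum, `1 - (1 - p_min)^K`).
#' @return Named numeric vector, one p-value per pathway.
#' @export
pathway_min_p <- function(assoc_table, method = c("min", "sidak")) {
  method <- match.arg(method)
  sp <- split(assoc_table$p_value, assoc_table$pathway_id)
  p <- vapply(sp, min, numeric(1))
  if (method == "sidak") {
    k <- vapply(sp, length, integer(1))
    p <- 1 - (1 - p)^k
  }
  p
}

#' Q-Q coordinates for a set of p-values
#'
#' Pairs the sorted observed p-values with uniform-order-statistic
#' expectations `i / (n + 1)`, both on the -log10 scale, for quantile-
#' quantile display of test calibration.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Data frame with `expected` and `observed` (-log10 scale),
#'   sorted by `expected` (stable with respect to duplicates).
#' @export
qq_data <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  n <- length(p_values)
  obs <- sort(p_values, decreasing = TRUE)
  exp_p <- (n:1) / (n + 1)
  data.frame(expected = -log10(exp_p), observed = -log10(obs))
}
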