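test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 930), 3), 5.38e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 9300), 0.05 / 9300)
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("structure-preserving permutation keeps the twin design intact", {
  co <- generate_cohort(cohort_spec(20, 30, 10, seed = 1))
  perm <- permute_cohort(co, seed = 7)
  expect_identical(perm, permute_cohort(co, seed = 7))  # deterministic
  expect_identical(perm$sample_id, co$sample_id)
  expect_identical(perm$zygosity, co$zygosity)
  expect_identical(sort(perm$age), sort(co$age))        # age multiset
  validate_cohort(perm)                                  # pairs intact
  # co-twins still share one age
  expect_true(all(tapply(perm$age, perm$family_id,
                         function(a) length(unique(a)) == 1)))
  # ages move only within zygosity strata
  for (z in c("MZ", "DZ", "singleton")) {
    expect_identical(sort(perm$age[perm$zygosity == z]),
                     sort(co$age[co$zygosity == z]))
  }
  # one singleton: nothing to permute
  one <- generate_cohort(cohort_spec(0, 0, 1, seed = 2))
  expect_identical(permute_cohort(one, seed = 3)$age, one$age)
})

test_that("tiny-cohort permutations enumerate the within-stratum group", {
  co <- tiny_cohort(2, 2, 0, ages = c(40, 50, 60, 70))
  seen <- unique(vapply(1:200, function(s)
    paste(permute_cohort(co, seed = s)$age, collapse = ","),
    character(1)))
  # 2 MZ x 2 DZ orders = 4 reachable assignments, all stratum-respecting
  expect_equal(length(seen), 4)
  mz_ages <- c(40, 50); dz_ages <- c(60, 70)
  for (s in seen) {
    a <- as.numeric(strsplit(s, ",")[[1]])
    expect_setequal(a[1:4][c(1, 3)], mz_ages)
    expect_setequal(a[5:8][c(1, 3)], dz_ages)
  }
})

test_that("phenotype age scan flags planted pathways and is deterministic", {
  co <- generate_cohort(cohort_spec(100, 100, seed = 3))
  tr <- simulate_truth(co, pathway_sizes = rep(12L, 8L),
                       n_age_pathways = 2, age_effect = 0.025, seed = 4)
  Y <- generate_expression(co, tr)
  res <- residualize(Y, fit_factor_model(Y, K = 5))
  sets <- filter_pathways(truth_gene_sets(tr), res)
  ph <- build_pathway_phenotypes(res, sets, K = 5)
  tab <- test_all_phenotypes(ph, co)
  expect_equal(nrow(tab), 40)
  expect_identical(tab, test_all_phenotypes(ph, co))
  planted <- c("pw001", "pw002")
  for (pw in planted)
    expect_true(any(tab$significant_bonferroni[tab$pathway_id == pw]))
  # flags agree with the threshold definition
  thr <- attr(tab, "threshold")
  expect_equal(tab$significant_bonferroni, tab$p_value < thr)
  # misaligned cohort is rejected
  expect_error(test_all_phenotypes(ph, co[rev(seq_len(nrow(co))), ]),
               "misaligned")
})

test_that("permuted runs destroy a planted age signal", {
  co <- generate_cohort(cohort_spec(80, 80, seed = 5))
  tr <- simulate_truth(co, pathway_sizes = rep(12L, 4L),
                       n_age_pathways = 1, age_effect = 0.03, seed = 6)
  Y <- generate_expression(co, tr)
  res <- residualize(Y, fit_factor_model(Y, K = 5))
  sets <- filter_pathways(truth_gene_sets(tr), res)
  ph <- build_pathway_phenotypes(res, sets, K = 5)
  real <- test_all_phenotypes(ph, co)
  expect_true(any(real$significant_bonferroni))
  perms <- permutation_null_run(ph, co, n_perm = 5, seed = 10)
  expect_identical(perms, permutation_null_run(ph, co, n_perm = 5,
                                               seed = 10))
  thr <- bonferroni_threshold(0.05, nrow(real))
  lost <- vapply(perms, function(p) min(p) > thr, logical(1))
  expect_gte(sum(lost), 4)
})

test_that("single-gene tests apply BH and Bonferroni correctly", {
  # hand-applied BH step-up oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))

  co <- generate_cohort(cohort_spec(60, 60, seed = 7))
  tr <- simulate_truth(co, pathway_sizes = integer(0), n_genes = 12,
                       k_global = 0, n_age_pathways = 0, seed = 8)
  Y <- generate_expression(co, tr)
  Y <- cbind(Y, dup = Y[, 1])
  colnames(Y)[ncol(Y)] <- "dup001"
  tab <- single_gene_tests(Y, co)
  expect_equal(nrow(tab), 13)
  # duplicated gene gets an identical p-value
  expect_equal(tab$p_value[tab$gene_id == "dup001"],
               tab$p_value[tab$gene_id == "g00001"])
  expect_equal(tab$q_value, p.adjust(tab$p_value, "BH"))
  expect_equal(tab$significant_bonferroni,
               tab$p_value < 0.05 / nrow(tab))
})

test_that("within-pathway follow-up uses a pathway-sized Bonferroni", {
  gt <- data.frame(gene_id = sprintf("g%02d", 1:10),
                   p_value = c(0.004, 0.02, seq(0.2, 0.9, length.out = 8)))
  sub <- pathway_gene_followup(gt, sprintf("g%02d", 1:5), alpha = 0.05)
  expect_equal(nrow(sub), 5)
  expect_equal(sub$significant_in_pathway, sub$p_value < 0.05 / 5)
})

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  genes <- sprintf("g%04d", 1:1000)
  sig <- genes[1:100]
  sets <- twinfact:::new_gene_set_collection(list(
    enriched = c(genes[1:5], genes[101:115]),   # 5 of 20 significant
    whole = genes
  ))
  res <- fisher_enrichment(sig, sets, genes)
  expect_equal(res$fisher_p[res$pathway_id == "enriched"],
               hyper_tail_p(5, 20, 100, 1000), tolerance = 1e-12)
  # pathway = universe and zero significant genes are degenerate p = 1
  expect_equal(res$fisher_p[res$pathway_id == "whole"], 1)
  res0 <- fisher_enrichment(character(0), sets, genes)
  expect_true(all(res0$fisher_p == 1))
  expect_error(fisher_enrichment(sig, sets, character(0)), "universe")
  expect_error(fisher_enrichment("absent", sets, genes), "subset")
})

test_that("Fisher p matches brute-force enumeration on random tables", {
  set.seed(9)
  for (i in 1:100) {
    n_univ <- sample(50:500, 1)
    n_sig <- sample(1:(n_univ / 2), 1)
    n_set <- sample(2:(n_univ / 2), 1)
    k <- sample(0:min(n_set, n_sig), 1)
    tab <- matrix(c(k, n_set - k, n_sig - k,
                    n_univ - n_set - n_sig + k), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p, hyper_tail_p(k, n_set, n_sig, n_univ),
                 tolerance = 1e-12)
  }
})

test_that("method comparison computes Spearman rho with midrank ties", {
  a <- c(p1 = 1, p2 = 2, p3 = 3, p4 = 4, p5 = 5)
  expect_equal(compare_methods(a, a)$rho, 1)
  b <- a; b[] <- rev(unname(a))
  expect_equal(compare_methods(a, b)$rho, -1)
  d <- a; d[] <- c(2, 1, 4, 3, 5)
  expect_equal(compare_methods(a, d)$rho, 0.8, tolerance = 1e-12)
  expect_error(compare_methods(a[1:2], a[1:2]), "at least 3")
})

test_that("pathway-level p reduction supports min and Sidak", {
  tab <- data.frame(pathway_id = rep(c("pA", "pB"), each = 2),
                    factor_index = c(1, 2, 1, 2),
                    p_value = c(0.01, 0.5, 0.2, 0.3))
  expect_equal(unname(pathway_min_p(tab)["pA"]), 0.01)
  expect_equal(unname(pathway_min_p(tab, "sidak")["pA"]),
               1 - (1 - 0.01)^2)
})

test_that("Q-Q coordinates pair sorted observations with uniform quantiles", {
  qq <- qq_data(0.5)
  expect_equal(qq$expected, -log10(0.5))
  expect_equal(qq$observed, -log10(0.5))
  set.seed(10)
  p <- runif(1000)
  qq2 <- qq_data(p)
  expect_equal(qq2$observed, sort(-log10(p)))
  # uniform p-values track the diagonal
  expect_lt(max(abs(10^(-qq2$observed) - 10^(-qq2$expected))), 0.05)
  expect_identical(qq_data(c(p, p))$observed[1:2],
                   rep(qq_data(p)$observed[1], 2))
  expect_error(qq_data(c(0.5, 0)), "0, 1")
  expect_error(qq_data(numeric(0)), "no p-values")
})
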