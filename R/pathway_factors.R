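#' Filter gene sets against an expression matrix
#'
#' Keeps the sets with strictly more than `min_genes` members present among
#' the matrix gene ids (the standard ">10 genes with probes" pathway
#' filter) and trims each membership list to the genes actually present.
#' Set order is preserved.
#'
#' @param sets A `gene_set_collection`.
#' @param matrix Samples x genes expression matrix.
#' @param min_genes Retention is strict: a set needs `> min_genes` present
#'   members. Default 10.
#' @return The filtered `gene_set_collection` (possibly empty, with a
#'   message).
#' @export
filter_pathways <- function(sets, matrix, min_genes = 10) {
  if (!inherits(sets, "gene_set_collection"))
    stop("'sets' must be a gene_set_collection")
  genes <- colnames(matrix)
  trimmed <- lapply(sets, function(m) m[m %in% genes])
  keep <- lengths(trimmed) > min_genes
  if (!any(keep)) {
    message("no gene set retains more than ", min_genes, " present genes")
    return(structure(list(),
                     descriptions = character(0),
                     class = "gene_set_collection"))
  }
  out <- trimmed[keep]
  desc <- attr(sets, "descriptions")[names(out)]
  new_gene_set_collection(out, descriptions = desc)
}

#' Build per-pathway factor phenotypes
#'
#' For each (pre-filtered) pathway, fits the factor model to the member-
#' gene submatrix of the residualized expression — no covariates, since
#' global confounders were already regressed out — and returns the K factor
#' score vectors as derived phenotypes. Within a pathway, factors are
#' ordered by variance explained (descending, ties by original factor
#' index). Each pathway is fitted in isolation, so batch results equal
#' single-pathway results.
#'
#' Automatic relevance determination can shrink a factor to numerically
#' zero when a small pathway holds less structure than K factors; because
#' every pathway contributes exactly K tested phenotypes, such collapsed
#' factors are completed deterministically with the leading principal
#' directions of the pathway submatrix residual (after removing the
#' surviving factors), standardized to unit variance.
#'
#' @param residuals Samples x genes residual matrix (output of
#'   [residualize()] after the global-factor stage).
#' @param sets A filtered `gene_set_collection`.
#' @param K Factors per pathway (default 5).
#' @param ... Passed to [fit_factor_model()] (e.g. `tol`, `max_iter`).
#' @return A `pathway_phenotypes` object: `scores` (samples x
#'   `K * n_pathways` matrix, columns named `<pathway>.f<k>`), `info`
#'   (data frame with `pathway_id`, `factor_index`, `var_explained_factor`,
#'   `n_genes_present`, `var_explained_pathway`), `weights` (per-pathway
#'   gene-weight matrices), `K`, `sample_ids`.
#' @export
build_pathway_phenotypes <- function(residuals, sets, K = 5, ...) {
  if (!inherits(sets, "gene_set_collection"))
    stop("'sets' must be a gene_set_collection")
  K <- .assert_scalar_count(K, "K", min = 1L)
  n <- nrow(residuals)
  if (n < K + 2)
    stop("fewer samples than K + 2; cannot fit pathway factors")
  ids <- names(sets)
  score_list <- vector("list", length(ids))
  weight_list <- stats::setNames(vector("list", length(ids)), ids)
  info <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    pw <- ids[j]
    mem <- intersect(sets[[pw]], colnames(residuals))
    sub <- residuals[, mem, drop = FALSE]
    fit <- fit_factor_model(sub, covariates = NULL, K = K, ...)
    sc <- fit$scores
    wt <- fit$weights
    dead <- which(apply(sc, 2, stats::sd) < 1e-8)
    if (length(dead)) {
      live <- setdiff(seq_len(K), dead)
      sub_c <- sweep(sub, 2, colMeans(sub))
      resid_sub <- if (length(live))
        stats::lm.fit(cbind(1, sc[, live, drop = FALSE]), sub)$residuals
      else sub_c
      sv <- svd(resid_sub, nu = length(dead), nv = length(dead))
      for (d in seq_along(dead)) {
        u <- sv$u[, d]
        u <- u / stats::sd(u)
        g <- which.max(abs(sv$v[, d]))
        if (sv$v[g, d] < 0) u <- -u
        sc[, dead[d]] <- u
        wt[, dead[d]] <- crossprod(sub_c, u) / (n - 1)
      }
    }
    pfv <- .variance_ledger(sub, sc)
    ord <- order(-pfv$per_factor, seq_len(K))
    sc <- sc[, ord, drop = FALSE]
    colnames(sc) <- sprintf("%s.f%d", pw, seq_len(K))
    score_list[[j]] <- sc
    weight_list[[pw]] <- wt[, ord, drop = FALSE]
    info[[j]] <- data.frame(
      pathway_id = pw,
      factor_index = seq_len(K),
      var_explained_factor = pfv$per_factor[ord],
      n_genes_present = length(mem),
      var_explained_pathway = pfv$total,
      stringsAsFactors = FALSE
    )
  }
  scores <- do.call(cbind, score_list)
  if (is.null(scores)) scores <- matrix(0, n, 0)
  rownames(scores) <- rownames(residuals)
  structure(
    list(scores = scores, info = do.call(rbind, info),
         weights = weight_list, K = K,
         sample_ids = rownames(residuals)),
    class = "pathway_phenotypes"
  )
}

#' Write pathway phenotypes as long-format TSV tables
#'
#' Writes `<stem>_scores.tsv` (`pathway_id`, `factor_index`, `sample_id`,
#' `score`) and `<stem>_summary.tsv` (per-pathway gene counts and variance
#' explained).
#'
#' @param phen A `pathway_phenotypes` object.
#' @param stem Output path stem.
#' @return The scores path, invisibly.
#' @export
write_pathway_phenotypes <- function(phen, stem) {
  if (!inherits(phen, "pathway_phenotypes"))
    stop("'phen' must be a pathway_phenotypes object")
  info <- phen$info
  long <- do.call(rbind, lapply(seq_len(nrow(info)), function(r) {
    cn <- sprintf("%s.f%d", info$pathway_id[r], info$factor_index[r])
    data.frame(pathway_id = info$pathway_id[r],
               factor_index = info$factor_index[r],
               sample_id = phen$sample_ids,
               score = phen$scores[, cn],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, paste0(stem, "_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- unique(info[, c("pathway_id", "n_genes_present",
                          "var_explained_pathway")])
  utils::write.table(summ, paste0(stem, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(stem, "_scores.tsv"))
}
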