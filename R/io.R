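#' Read and write expression matrices
#'
#' Tab-separated layout: header row of gene ids, one row per sample with the
#' sample id in the first column, log2 expression values in the rest. The
#' reader enforces the modelling-matrix invariants: unique sample and gene
#' ids, rectangular rows, all cells numeric and finite (missing values are
#' rejected; see [drop_incomplete_genes()] for the documented pre-filter).
#'
#' @param path File path.
#' @param matrix Samples x genes numeric matrix with dimnames.
#' @return `read_expression` returns the samples x genes matrix;
#'   `write_expression` returns `path` invisibly. Round-tripping reproduces
#'   values to full printed precision (17 significant digits).
#' @export
read_expression <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("expression file needs a header and >= 1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  genes <- header[-1]
  if (anyDuplicated(genes))
    stop("duplicate gene id(s) in expression header: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  ncol_expect <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncol_expect))
    stop("ragged expression row(s): ",
         paste(which(widths != ncol_expect), collapse = ", "))
  samples <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1]), numeric(length(genes))))
  vals <- if (length(genes) == 1L) matrix(vals, ncol = 1L) else t(vals)
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing cell at row '%s', column '%s'",
                 samples[bad[1, 1]], genes[bad[1, 2]]))
  dimnames(vals) <- list(samples, genes)
  vals
}

#' @rdname read_expression
#' @export
write_expression <- function(matrix, path) {
  .check_expression(matrix)
  header <- paste(c("sample_id", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i],
            formatC(matrix[i, ], format = "g", digits = 17)),
          collapse = "\t"), character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

.check_expression <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression must be a numeric matrix (samples x genes)")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs sample and gene id dimnames")
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(m))) stop("duplicate gene ids")
  invisible(m)
}

#' Drop genes with missing values
#'
#' The modelling matrix must be complete; this documented pre-filter removes
#' any gene (column) containing a non-finite entry, with a message.
#'
#' @param matrix Samples x genes matrix.
#' @return The matrix restricted to complete genes.
#' @export
drop_incomplete_genes <- function(matrix) {
  bad <- colSums(!is.finite(matrix)) > 0
  if (any(bad))
    message("dropping ", sum(bad), " gene(s) with missing values")
  matrix[, !bad, drop = FALSE]
}

#' Collapse duplicate-named expression columns by mean
#'
#' Utility for matrices whose column ids repeat (e.g. several probes mapped
#' to one gene symbol): duplicate-named columns are averaged, with a
#' message listing how many ids were collapsed.
#'
#' @param matrix Samples x genes matrix (duplicate column names allowed).
#' @return Matrix with unique column names.
#' @export
collapse_duplicate_genes <- function(matrix) {
  ids <- colnames(matrix)
  if (!anyDuplicated(ids)) return(matrix)
  uid <- unique(ids)
  message("collapsing ", length(ids) - length(uid),
          " duplicate column(s) by mean")
  out <- vapply(uid, function(g)
    rowMeans(matrix[, ids == g, drop = FALSE]), numeric(nrow(matrix)))
  dimnames(out) <- list(rownames(matrix), uid)
  out
}

# ---- gene sets ------------------------------------------------------------

new_gene_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("duplicate gene set ids")
  if (any(lengths(sets) == 0)) stop("empty gene set member list")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(lapply(sets, as.character),
            descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids. File order is preserved; duplicated
#' members within a line are stored once with a warning.
#'
#' @param path File path.
#' @return A `gene_set_collection`: a named list of member-gene character
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(fields, `[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  ndup <- sum(vapply(members, anyDuplicated, integer(1)) > 0)
  if (ndup > 0) {
    warning(ndup, " gene set(s) contained duplicated members; deduplicated")
    members <- lapply(members, unique)
  }
  names(members) <- ids
  new_gene_set_collection(members, descriptions = desc)
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set_collection`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- quantile normalization ----------------------------------------------

#' Two-stage quantile normalization
#'
#' Stage 1: within each replicate group (the samples of one individual),
#' samples are quantile-normalized to the group's mean quantile profile and
#' collapsed to a single profile per individual by averaging the normalized
#' replicates. Stage 2: the per-individual profiles are quantile-normalized
#' across individuals. After stage 2, every individual's sorted value
#' vector is identical (ties receive the mean of the reference quantiles
#' they span, the midrank convention). When `replicate_groups` is `NULL`
#' or every group has one sample, stage 1 is the identity.
#'
#' @param matrix Samples x genes matrix.
#' @param replicate_groups Optional named list mapping individual id to the
#'   sample ids of its technical replicates; every sample must belong to
#'   exactly one group.
#' @return Individuals x genes matrix (row names are individual ids when
#'   `replicate_groups` is given, sample ids otherwise).
#' @export
quantile_normalize <- function(matrix, replicate_groups = NULL) {
  .check_expression(matrix)
  if (!is.null(replicate_groups)) {
    all_samp <- unlist(replicate_groups, use.names = FALSE)
    unknown <- setdiff(all_samp, rownames(matrix))
    if (length(unknown))
      stop("replicate group references unknown sample(s): ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(all_samp) ||
        !setequal(all_samp, rownames(matrix)))
      stop("every sample must be assigned to exactly one replicate group")
    profiles <- t(vapply(replicate_groups, function(samp) {
      sub <- matrix[samp, , drop = FALSE]
      if (length(samp) > 1L)
        sub <- t(limma::normalizeQuantiles(t(sub), ties = TRUE))
      colMeans(sub)
    }, numeric(ncol(matrix))))
    rownames(profiles) <- names(replicate_groups)
  } else {
    profiles <- matrix
  }
  out <- t(limma::normalizeQuantiles(t(profiles), ties = TRUE))
  dimnames(out) <- dimnames(profiles)
  out
}
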