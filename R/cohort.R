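#' Specify a synthetic twin cohort
#'
#' A cohort specification describes a female twin registry sample: numbers of
#' monozygotic (MZ) pairs, dizygotic (DZ) pairs and unpaired singletons, the
#' age range and the target mean age. Defaults mirror a cohort of 336 MZ and
#' 520 DZ twins aged 39--85 years with mean age 59.
#'
#' @param n_mz_pairs Number of MZ twin pairs.
#' @param n_dz_pairs Number of DZ twin pairs.
#' @param n_singletons Number of unpaired individuals.
#' @param age_min,age_max Age range in years.
#' @param age_mean Target mean age in years; ages are drawn from a normal
#'   distribution truncated to `[age_min, age_max]` whose location is tuned
#'   so the truncated mean equals this target.
#' @param age_sd Scale of the untruncated age distribution, in years.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_mz_pairs = 168, n_dz_pairs = 260, n_singletons = 0,
                        age_min = 39, age_max = 85, age_mean = 59,
                        age_sd = 12, seed = 1) {
  .assert_scalar_count(n_mz_pairs, "n_mz_pairs")
  .assert_scalar_count(n_dz_pairs, "n_dz_pairs")
  .assert_scalar_count(n_singletons, "n_singletons")
  if (!.is_number(age_min) || !.is_number(age_max) || !.is_number(age_mean))
    stop("age_min, age_max and age_mean must be finite numbers")
  if (!(age_min <= age_mean && age_mean <= age_max))
    stop("require age_min <= age_mean <= age_max")
  if (!.is_number(age_sd) || age_sd <= 0) stop("age_sd must be > 0")
  if (n_mz_pairs + n_dz_pairs + n_singletons < 1)
    stop("cohort must contain at least one individual")
  structure(
    list(n_mz_pairs = as.integer(n_mz_pairs),
         n_dz_pairs = as.integer(n_dz_pairs),
         n_singletons = as.integer(n_singletons),
         age_min = age_min, age_max = age_max, age_mean = age_mean,
         age_sd = age_sd, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a twin cohort roster
#'
#' Draws a sample roster from a [cohort_spec()]: each twin pair shares one
#' family id and one age (twins are sampled together); ages come from a
#' truncated normal on `[age_min, age_max]` whose location is steered so the
#' truncated mean equals the target mean. Technical covariates (batch, RNA
#' quality, RNA concentration) are attached for use as fixed effects in the
#' factor model. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `twin_cohort`: a data frame with one row per sample and columns
#'   `sample_id`, `individual_id`, `family_id`,
#'   `zygosity` (`"MZ"`, `"DZ"` or `"singleton"`), `age`, `batch`,
#'   `rna_quality`, `rna_concentration`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  n_units <- spec$n_mz_pairs + spec$n_dz_pairs + spec$n_singletons
  unit_sizes <- c(rep(2L, spec$n_mz_pairs + spec$n_dz_pairs),
                  rep(1L, spec$n_singletons))
  unit_zyg <- c(rep("MZ", spec$n_mz_pairs), rep("DZ", spec$n_dz_pairs),
                rep("singleton", spec$n_singletons))

  set.seed(.stream_seed(spec$seed, "ages"))
  mu <- if (spec$age_min == spec$age_max) spec$age_min else
    .truncnorm_location(spec$age_mean, spec$age_sd, spec$age_min, spec$age_max)
  unit_age <- .rtruncnorm(n_units, mu, spec$age_sd, spec$age_min, spec$age_max)

  fam <- sprintf("fam%04d", seq_len(n_units))
  n <- sum(unit_sizes)
  row_unit <- rep(seq_len(n_units), unit_sizes)
  twin_ix <- sequence(unit_sizes)
  ind <- sprintf("%s_%d", fam[row_unit], twin_ix)

  set.seed(.stream_seed(spec$seed, "covariates"))
  batch <- sample(paste0("b", 1:4), n, replace = TRUE)
  rna_quality <- round(stats::rnorm(n, 8, 0.6), 3)
  rna_concentration <- round(stats::rnorm(n, 100, 12), 3)

  cohort <- data.frame(
    sample_id = ind,
    individual_id = ind,
    family_id = fam[row_unit],
    zygosity = unit_zyg[row_unit],
    age = round(unit_age[row_unit], 2),
    batch = batch,
    rna_quality = rna_quality,
    rna_concentration = rna_concentration,
    stringsAsFactors = FALSE
  )
  class(cohort) <- c("twin_cohort", "data.frame")
  validate_cohort(cohort)
  cohort
}

#' Validate a twin cohort roster
#'
#' Checks the structural invariants a twin roster must satisfy: each family
#' id appears once or twice; co-twins share zygosity and age; zygosity labels
#' are `MZ`, `DZ` or `singleton`; paired samples are never labelled
#' `singleton` and singleton families never hold two samples; sample ids are
#' unique and ages finite.
#'
#' @param cohort A data frame with the `twin_cohort` columns.
#' @return The cohort, invisibly, with class `twin_cohort`; errors on any
#'   violated invariant.
#' @export
validate_cohort <- function(cohort) {
  req <- c("sample_id", "individual_id", "family_id", "zygosity", "age")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$sample_id))
    stop("duplicate sample ids in cohort")
  if (!all(cohort$zygosity %in% c("MZ", "DZ", "singleton")))
    stop("zygosity must be one of MZ, DZ, singleton")
  if (!is.numeric(cohort$age) || !all(is.finite(cohort$age)))
    stop("ages must be finite numbers")
  sizes <- table(cohort$family_id)
  if (any(sizes > 2)) stop("a family id appears more than twice")
  by_fam <- split(seq_len(nrow(cohort)), cohort$family_id)
  for (ix in by_fam) {
    if (length(ix) == 2L) {
      if (cohort$zygosity[ix[1]] != cohort$zygosity[ix[2]])
        stop("co-twins disagree on zygosity in family ",
             cohort$family_id[ix[1]])
      if (cohort$zygosity[ix[1]] == "singleton")
        stop("two samples labelled singleton share family ",
             cohort$family_id[ix[1]])
      if (abs(cohort$age[ix[1]] - cohort$age[ix[2]]) > 1e-8)
        stop("co-twins disagree on age in family ", cohort$family_id[ix[1]])
    } else if (cohort$zygosity[ix[1]] != "singleton") {
      stop("unpaired sample not labelled singleton in family ",
           cohort$family_id[ix[1]])
    }
  }
  if (!inherits(cohort, "twin_cohort"))
    class(cohort) <- c("twin_cohort", class(cohort))
  invisible(cohort)
}

#' Read and write cohort metadata tables
#'
#' Tab-separated metadata layout: one row per sample with columns
#' `sample_id`, `individual_id`, `family_id`, `zygosity`, `age`, `batch`,
#' `rna_quality`, `rna_concentration`.
#'
#' @param path File path.
#' @param cohort A `twin_cohort` data frame.
#' @return `read_cohort` returns a validated `twin_cohort`;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  validate_cohort(tab)
  class(tab) <- c("twin_cohort", "data.frame")
  tab
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Family-block index used by the twin likelihood: pair row indices,
# MZ indicator per pair, singleton row indices.
.cohort_blocks <- function(cohort) {
  by_fam <- split(seq_len(nrow(cohort)), cohort$family_id)
  sizes <- lengths(by_fam)
  pair_ix <- by_fam[sizes == 2L]
  i1 <- vapply(pair_ix, `[`, integer(1), 1L)
  i2 <- vapply(pair_ix, `[`, integer(1), 2L)
  list(
    i1 = unname(i1), i2 = unname(i2),
    mz = unname(cohort$zygosity[i1] == "MZ"),
    singles = unname(unlist(by_fam[sizes == 1L], use.names = FALSE)),
    n_families = length(by_fam)
  )
}
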