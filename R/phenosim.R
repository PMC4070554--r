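#' Define a planted QTL architecture
#'
#' Holds additive and epistatic loci with family-specific effects and
#' per-stage scalings. A family's effect may be 0, meaning the QTL does not
#' segregate functionally in that family. Stage profiles model temporal
#' dynamics: a locus whose profile falls to ~0 at a stage contributes nothing
#' there, producing stage-specific QTL; correlation between stages arises from
#' loci shared across stages, not from an explicit correlation matrix.
#'
#' @param additive data frame with columns `group`, `pos` (one row per QTL).
#' @param add_effects numeric matrix, QTL x family: allele-substitution effect
#'   in trait units per parent-A allele (genetic contribution is
#'   `effect * (count - 1)`, i.e. +/- effect in a DH line).
#' @param epistatic optional data frame with columns `group1`, `pos1`,
#'   `group2`, `pos2`.
#' @param epi_effects numeric matrix, pair x family: interaction effect; the
#'   contribution is `effect * (count1 - 1) * (count2 - 1)`.
#' @param stages character vector of stage labels.
#' @param add_profiles,epi_profiles matrices (locus x stage) scaling each
#'   effect per stage; default all 1.
#' @param family_means matrix family x stage of family mean genetic values;
#'   default 0.
#' @param families character vector of family ids (column order of the effect
#'   matrices).
#' @return A `qtl_architecture` object. `$loci` lists additive loci followed
#'   by the (distinct) epistatic loci, the order used by
#'   [simulate_dh_population]'s `qtl_geno`.
#' @export
qtl_architecture <- function(additive, add_effects, families,
                             stages = "trait",
                             add_profiles = NULL,
                             epistatic = NULL, epi_effects = NULL,
                             epi_profiles = NULL,
                             family_means = NULL) {
  additive <- as.data.frame(additive)
  n_add <- nrow(additive)
  add_effects <- matrix(add_effects, nrow = n_add)
  stopifnot(ncol(add_effects) == length(families))
  if (is.null(add_profiles)) {
    add_profiles <- matrix(1, n_add, length(stages))
  }
  add_profiles <- matrix(add_profiles, nrow = n_add)
  stopifnot(ncol(add_profiles) == length(stages))
  n_epi <- if (is.null(epistatic)) 0L else nrow(epistatic)
  if (n_epi) {
    epistatic <- as.data.frame(epistatic)
    epi_effects <- matrix(epi_effects, nrow = n_epi)
    stopifnot(ncol(epi_effects) == length(families))
    if (is.null(epi_profiles)) epi_profiles <- matrix(1, n_epi, length(stages))
    epi_profiles <- matrix(epi_profiles, nrow = n_epi)
  }
  if (is.null(family_means)) {
    family_means <- matrix(0, length(families), length(stages))
  }
  family_means <- matrix(family_means, nrow = length(families))
  # distinct loci table: additive loci then epistatic member loci
  loci <- additive[, c("group", "pos")]
  if (n_epi) {
    loci <- rbind(loci,
                  data.frame(group = epistatic$group1, pos = epistatic$pos1),
                  data.frame(group = epistatic$group2, pos = epistatic$pos2))
  }
  key <- paste0(loci$group, "@", loci$pos)
  keep <- !duplicated(key)
  loci <- loci[keep, , drop = FALSE]
  rownames(loci) <- NULL
  idx <- match(key, key[keep])
  add_idx <- idx[seq_len(n_add)]
  epi_idx <- if (n_epi) {
    cbind(idx[n_add + seq_len(n_epi)], idx[n_add + n_epi + seq_len(n_epi)])
  } else NULL
  structure(list(additive = additive, add_effects = add_effects,
                 add_profiles = add_profiles,
                 epistatic = epistatic, epi_effects = epi_effects,
                 epi_profiles = epi_profiles,
                 family_means = family_means,
                 families = families, stages = stages,
                 loci = loci, add_idx = add_idx, epi_idx = epi_idx),
            class = "qtl_architecture")
}

#' True genetic values of a simulated population
#'
#' `g_i = family mean + sum_q profile_qs * a_qf * (x_iq - 1) +
#'  sum_e profile_es * w_ef * (x1 - 1)(x2 - 1)` using the true (hidden) QTL
#' genotypes of the population.
#'
#' @param pop a [dh_population] simulated with the architecture.
#' @param arch the [qtl_architecture].
#' @param stage stage label (must be in `arch$stages`).
#' @return Named numeric vector of genetic values per line.
#' @export
genetic_values <- function(pop, arch, stage) {
  stopifnot(inherits(pop, "dh_population"), inherits(arch, "qtl_architecture"))
  s <- match(stage, arch$stages)
  if (is.na(s)) stop_param("unknown stage ", stage)
  if (is.null(pop$qtl_geno)) stop_param("population carries no QTL genotypes")
  fam_idx <- match(pop$line_family, arch$families)
  g <- arch$family_means[fam_idx, s]
  Xc <- pop$qtl_geno - 1          # +/- 1 coding
  for (q in seq_len(nrow(arch$additive))) {
    a <- arch$add_effects[q, fam_idx] * arch$add_profiles[q, s]
    g <- g + a * Xc[, arch$add_idx[q]]
  }
  if (!is.null(arch$epi_idx)) {
    for (e in seq_len(nrow(arch$epistatic))) {
      w <- arch$epi_effects[e, fam_idx] * arch$epi_profiles[e, s]
      g <- g + w * Xc[, arch$epi_idx[e, 1L]] * Xc[, arch$epi_idx[e, 2L]]
    }
  }
  names(g) <- rownames(pop$geno)
  g
}

#' Simulate multi-environment phenotypes for one stage
#'
#' Adds genotype-by-environment deviations and plot errors around the true
#' genetic values. The error variances are solved from the targeted entry-mean
#' heritability `h2 = s2G / (s2G + s2GE/E + s2e/(E*r))` together with the
#' requested genotypic-to-GxE variance ratio, with `s2G` taken as the realized
#' variance of the genetic values.
#'
#' @param pop a [dh_population] with QTL genotypes.
#' @param arch the [qtl_architecture].
#' @param stage stage label.
#' @param h2_target targeted entry-mean heritability in `(0, 1]`; `1` requires
#'   `ge_ratio = Inf` and yields noiseless data.
#' @param ge_ratio `s2G / s2GE` (`> 0`, may be `Inf`).
#' @param n_env number of environments (`>= 2`), labelled as location x year.
#' @param reps_per_env replicates per environment.
#' @param seed RNG seed.
#' @return A `pheno_set`: list with `stage`, `values` (long data frame
#'   `line, env, rep, value`), `environments`, `reps_per_env`, `entry_means`
#'   (named vector), `g` (true genetic values) and the realized variance
#'   components used for simulation.
#' @export
simulate_phenotypes <- function(pop, arch, stage, h2_target = 0.85,
                                ge_ratio = 5, n_env = 4, reps_per_env = 2,
                                seed = NULL) {
  if (h2_target <= 0 || h2_target > 1) stop_param("h2_target must be in (0, 1]")
  if (ge_ratio <= 0) stop_param("ge_ratio must be > 0")
  if (n_env < 2) stop_param("n_env must be >= 2")
  g <- genetic_values(pop, arch, stage)
  n <- length(g)
  s2G <- stats::var(g)
  s2GE <- if (is.infinite(ge_ratio)) 0 else s2G / ge_ratio
  s2e <- n_env * reps_per_env * (s2G / h2_target - s2G - s2GE / n_env)
  if (s2e < -1e-8 * max(s2G, 1)) {
    stop_param("h2_target ", h2_target, " unattainable with ge_ratio ",
               ge_ratio, " at n_env = ", n_env)
  }
  s2e <- max(s2e, 0)
  envs <- data.frame(
    env = paste0("E", seq_len(n_env)),
    location = paste0("LOC", rep(seq_len(ceiling(n_env / 2)), each = 2)[seq_len(n_env)]),
    year = 2000 + rep(seq_len(2), length.out = n_env),
    stringsAsFactors = FALSE)
  with_seed(seed, {
    ge <- matrix(stats::rnorm(n * n_env, 0, sqrt(s2GE)), n, n_env)
    values <- expand.grid(rep = seq_len(reps_per_env), env = envs$env,
                          line = names(g), KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)[, c("line", "env", "rep")]
    li <- match(values$line, names(g))
    ei <- match(values$env, envs$env)
    values$value <- g[li] + ge[cbind(li, ei)] +
      stats::rnorm(nrow(values), 0, sqrt(s2e))
    em <- c(tapply(values$value, values$line, mean))[names(g)]
    structure(list(stage = stage, values = values, environments = envs,
                   reps_per_env = reps_per_env, entry_means = em, g = g,
                   sim_components = c(s2G = s2G, s2GE = s2GE, s2e = s2e)),
              class = "pheno_set")
  })
}

#' @export
print.pheno_set <- function(x, ...) {
  cat(sprintf("Phenotypes [%s]: %d lines x %d environments x %d rep(s)\n",
              x$stage, length(x$entry_means), nrow(x$environments),
              x$reps_per_env))
  invisible(x)
}
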