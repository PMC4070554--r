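#' One-stage QTL analysis: cofactors, threshold, scan, declaration, pG
#'
#' Convenience wrapper running the full composite-interval-mapping analysis
#' for one stage: cofactor selection, permutation threshold, genome scan with
#' the cofactor-exclusion rule, QTL declaration with support intervals, and
#' the proportion of genotypic variance explained.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param h2 entry-mean heritability of `y`.
#' @param step_cM scan-grid step.
#' @param n_perm permutations for the threshold; set `threshold` to skip.
#' @param alpha experiment-wise error rate.
#' @param max_cofactors cofactor limit.
#' @param threshold optional fixed LOD threshold (skips permutations).
#' @param seed RNG seed (permutations).
#' @return List with `cofactors`, `threshold`, `scan`, `qtl` (with
#'   `pG_single` column when any QTL was declared), `pG_combined`.
#' @export
scan_stage <- function(y, pop, h2, step_cM = 1, n_perm = 200, alpha = 0.10,
                       max_cofactors = 10, threshold = NULL, seed = NULL) {
  grid <- scan_grid(pop$map, step_cM)
  cof <- select_cofactors(y, pop, max_cofactors)
  if (is.null(threshold)) {
    threshold <- permutation_threshold(y, pop, grid, n_perm = n_perm,
                                       alpha = alpha, seed = seed,
                                       max_cofactors = max_cofactors)
  }
  scan <- genome_scan(y, pop, grid, cof)
  qtl <- declare_qtl(scan, threshold)
  pg_combined <- NA_real_
  if (nrow(qtl)) {
    pg <- proportion_genotypic_variance(qtl, y, pop, h2)
    qtl$pG_single <- pg$pG_single
    pg_combined <- pg$pG_combined
  }
  list(cofactors = cof, threshold = threshold, scan = scan, qtl = qtl,
       pG_combined = pg_combined)
}

#' Locus x stage matrix of explained genotypic variance
#'
#' For every locus detected at any stage (clustered across stages with the
#' overlap window, represented by its highest-LOD peak), the drop-one `pG`
#' contribution is evaluated at every stage from a simultaneous model holding
#' all loci -- the temporal-dynamics view of the QTL set.
#'
#' @param qtl_by_stage named list of QTL tables.
#' @param y_by_stage named list of entry-mean vectors.
#' @param h2_by_stage named numeric vector of heritabilities.
#' @param pop a [dh_population].
#' @param window_cM cross-stage clustering window.
#' @return Data frame: `group`, `pos`, one `pG_<stage>` column per stage.
#' @export
pg_by_stage <- function(qtl_by_stage, y_by_stage, h2_by_stage, pop,
                        window_cM = 10) {
  ov <- classify_overlap(qtl_by_stage, window_cM)
  cl <- ov$clusters
  if (nrow(cl) == 0L) {
    return(data.frame(group = character(), pos = numeric()))
  }
  lods <- unlist(lapply(names(qtl_by_stage), function(st) {
    q <- qtl_by_stage[[st]]
    if (is.null(q) || !nrow(q)) numeric() else q$lod
  }))
  cl$lod <- lods
  reps <- do.call(rbind, lapply(split(cl, cl$cluster), function(cc) {
    cc[which.max(cc$lod), c("group", "peak_pos")]
  }))
  loci <- data.frame(group = reps$group, peak_pos = reps$peak_pos,
                     stringsAsFactors = FALSE)
  out <- data.frame(group = loci$group, pos = loci$peak_pos,
                    stringsAsFactors = FALSE)
  for (st in names(y_by_stage)) {
    pg <- proportion_genotypic_variance(loci, y_by_stage[[st]], pop,
                                        h2_by_stage[[st]])
    out[[paste0("pG_", st)]] <- pg$pG_single
  }
  out[order(out$group, out$pos), , drop = FALSE]
}

#' Run the full pipeline from a configuration list
#'
#' Executes the study emulation end to end: simulate (or read) the
#' population and phenotypes, estimate variance components and heritability
#' per stage, scan each stage with a permutation threshold, cross-validate,
#' run the epistasis scan, and write the report files.
#'
#' @param config named list (or path to a YAML file when the `yaml` package
#'   is available) with optional blocks: `seed`; `out_dir`; `simulate`
#'   (`TRUE` or a list overriding [simulate_study] arguments); `files`
#'   (`map`, `genotypes`, `families`, `phenotypes` paths when not
#'   simulating); `scan` (`step_cM`, `n_perm`, `alpha`, `max_cofactors`);
#'   `cv` (`enabled`, `k`, `n_replicates`); `epistasis` (`enabled`,
#'   `step_cM`, `alpha`).
#' @return Invisibly, a list with all intermediate results; report files are
#'   written under `config$out_dir`.
#' @export
run_all <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_param("reading a config file requires the yaml package")
    }
    config <- yaml::yaml.load_file(config)
  }
  seed <- config$seed %||% 1
  out_dir <- config$out_dir %||% "mlcqtl_report"
  scan_cfg <- config$scan %||% list()
  n_perm <- scan_cfg$n_perm %||% 200
  if (n_perm < 100) stop_param("scan n_perm must be >= 100")
  step_cM <- scan_cfg$step_cM %||% 1
  alpha <- scan_cfg$alpha %||% 0.10
  max_cof <- scan_cfg$max_cofactors %||% 10
  log_lines <- c(paste0("mlcqtl ", as.character(utils::packageVersion("mlcqtl"))),
                 paste0("seed: ", seed),
                 paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  if (!is.null(config$files)) {
    pop <- read_population(config$files$map, config$files$genotypes,
                           config$files$families)
    pheno_tabs <- read_phenotypes(config$files$phenotypes)
    stages <- names(pheno_tabs)
    values_by_stage <- pheno_tabs
  } else {
    sim_args <- if (is.list(config$simulate)) config$simulate else list()
    sim_args$seed <- seed
    sim <- do.call(simulate_study, sim_args)
    pop <- sim$pop
    stages <- sim$arch$stages
    values_by_stage <- lapply(sim$pheno, `[[`, "values")
    names(values_by_stage) <- stages
  }
  vc <- lapply(values_by_stage, variance_components)
  h2 <- vapply(vc, heritability, 0)
  blues <- lapply(values_by_stage, compute_blues)
  corr <- if (length(blues) >= 2) stage_correlations(blues) else NULL
  results <- list(qtl = list(), cv = NULL, log = log_lines)
  y_by_stage <- list()
  for (s in seq_along(stages)) {
    st <- stages[s]
    y <- blues[[st]]
    y_by_stage[[st]] <- y
    res <- scan_stage(y, pop, h2[[st]], step_cM = step_cM, n_perm = n_perm,
                      alpha = alpha, max_cofactors = max_cof,
                      seed = child_seed(seed, 200 + s))
    results$qtl[[st]] <- res$qtl
    results$log <- c(results$log,
                     sprintf("[%s] h2 = %.3f, LOD threshold = %.2f, %d QTL, pG = %.1f",
                             st, h2[[st]], .as_threshold(res$threshold),
                             nrow(res$qtl), res$pG_combined),
                     sprintf("[%s] cofactors: %s", st,
                             paste(res$cofactors$marker, collapse = ", ")))
    cv_cfg <- config$cv %||% list()
    if (isTRUE(cv_cfg$enabled %||% TRUE)) {
      cv <- run_cv(y, pop, h2[[st]], res$threshold, k = cv_cfg$k %||% 5,
                   n_replicates = cv_cfg$n_replicates %||% 20,
                   grid = scan_grid(pop$map, step_cM),
                   max_cofactors = max_cof,
                   seed = child_seed(seed, 300 + s))
      results$cv[[st]] <- cv
    }
    epi_cfg <- config$epistasis %||% list()
    if (isTRUE(epi_cfg$enabled %||% FALSE)) {
      thr <- region_threshold(length(unique(pop$map$group)),
                              epi_cfg$alpha %||% 0.05)
      results$epistasis[[st]] <- epistasis_scan(
        y, pop, step_cM = epi_cfg$step_cM %||% 5, threshold = thr,
        h2 = h2[[st]], cofactors = res$cofactors)
    }
  }
  if (length(stages) >= 2) {
    results$overlap <- classify_overlap(results$qtl)
    results$pg_matrix <- pg_by_stage(results$qtl, y_by_stage, as.list(h2), pop)
  }
  results$h2 <- h2
  results$variance_components <- vc
  results$correlations <- corr
  write_report(results, out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
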