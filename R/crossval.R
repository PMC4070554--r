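#' Family-stratified cross-validation folds
#'
#' Splits lines into `k` disjoint folds, stratified within family so that
#' every fold carries about `1/k` of each family.
#'
#' @param line_ids character vector of line ids.
#' @param line_family named family assignment (as in a [dh_population]).
#' @param k number of folds (`>= 2`).
#' @param seed RNG seed.
#' @return List of `k` character vectors partitioning `line_ids`.
#' @export
cv_split <- function(line_ids, line_family, k = 5, seed = NULL) {
  if (k < 2) stop_param("k must be >= 2")
  line_family <- line_family[line_ids]
  with_seed(seed, {
    folds <- vector("list", k)
    totals <- integer(k)
    for (f in unique(line_family)) {
      ids <- base::sample(line_ids[line_family == f])
      n <- length(ids)
      sizes <- rep(n %/% k, k)
      if (n %% k) {
        # leftovers go to the currently smallest folds (random tie-break),
        # keeping overall fold sizes within one line of each other
        ord <- order(totals + stats::runif(k))
        sizes[ord[seq_len(n %% k)]] <- sizes[ord[seq_len(n %% k)]] + 1L
      }
      assign_to <- rep(seq_len(k), times = sizes)
      for (j in seq_len(k)) {
        folds[[j]] <- c(folds[[j]], ids[assign_to == j])
      }
      totals <- totals + sizes
    }
    folds
  })
}

#' Relative bias of cross-validated explained genotypic variance
#'
#' `100 * (pG_ES - pG_TS) / pG_ES`: how much the estimation-set estimate of
#' the explained genotypic variance exceeds its test-set validation, in
#' percent of the estimation-set value.
#'
#' @param pG_ES,pG_TS proportions of genotypic variance (percent) in the
#'   estimation and test sets.
#' @return Relative bias in percent.
#' @export
relative_bias <- function(pG_ES, pG_TS) {
  if (any(pG_ES <= 0)) stop_param("pG_ES must be > 0")
  100 * (pG_ES - pG_TS) / pG_ES
}

#' Fivefold cross-validation of the QTL scan
#'
#' For each of `n_replicates` random fold partitions and each of the `k`
#' folds: cofactors are selected and the genome scanned on the estimation set
#' (the other `k - 1` folds), QTL are declared at the fixed full-data
#' threshold, `pG` is estimated on the estimation set, and test-set lines are
#' predicted from the estimation-set family means and QTL effects. The
#' test-set `pG` is `100 * r^2(yhat, y_TS) / h2` (0 when the correlation is
#' negative). Detection frequencies are accumulated in 10 cM bins.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param h2 entry-mean heritability used to scale `pG`.
#' @param threshold fixed LOD threshold (numeric or `perm_threshold`),
#'   normally the full-data permutation threshold.
#' @param grid scan grid; defaults to a 1 cM grid.
#' @param k folds (default 5).
#' @param n_replicates independent fold partitions (default 20, giving
#'   `k * n_replicates` runs).
#' @param max_cofactors passed to [select_cofactors].
#' @param bin_cM width of the QTL-frequency bins.
#' @param seed RNG seed.
#' @return A `cv_result`: `runs` (per-run data frame with `n_qtl`, `pG_ES`,
#'   `pG_TS`), summary means `qtl_ES_mean`, `pG_ES_mean`, `pG_TS_mean`,
#'   `relative_bias`, and `frequency` (data frame `group`, `bin_start`,
#'   `count`, `n_runs`).
#' @export
run_cv <- function(y, pop, h2, threshold, grid = NULL, k = 5,
                   n_replicates = 20, max_cofactors = 10, bin_cM = 10,
                   seed = NULL) {
  threshold <- .as_threshold(threshold)
  if (is.null(grid)) grid <- scan_grid(pop$map, 1)
  counts <- expected_counts(pop, grid, quiet = TRUE)
  mcounts <- expected_counts(pop, pop$map, quiet = TRUE)
  line_ids <- rownames(pop$geno)
  runs <- list()
  freq <- list()
  for (rep_i in seq_len(n_replicates)) {
    folds <- cv_split(line_ids, pop$line_family, k = k,
                      seed = child_seed(seed, 1000 + rep_i))
    for (fold_i in seq_len(k)) {
      ts_ids <- folds[[fold_i]]
      es_ids <- setdiff(line_ids, ts_ids)
      es_pop <- subset_population(pop, es_ids)
      small <- pop$families$family[
        table(factor(es_pop$line_family,
                     levels = pop$families$family)) < 10]
      if (length(small)) {
        warning("estimation set leaves family ",
                paste(small, collapse = ", "), " with < 10 lines",
                call. = FALSE)
      }
      es_rows <- match(es_ids, line_ids)
      y_es <- y[es_ids]
      cof <- select_cofactors(y_es, es_pop, max_cofactors,
                              counts = mcounts[es_rows, , drop = FALSE])
      scan <- genome_scan(y_es, es_pop, grid, cof,
                          counts = counts[es_rows, , drop = FALSE])
      qtl <- declare_qtl(scan, threshold)
      if (nrow(qtl)) {
        pg <- proportion_genotypic_variance(qtl, y_es, es_pop, h2)
        pg_es <- pg$pG_combined
        yhat <- predict_mlc(pg$model, pop, ts_ids,
                            data.frame(group = qtl$group, pos = qtl$peak_pos))
        r <- suppressWarnings(stats::cor(yhat, y[ts_ids]))
        pg_ts <- if (is.na(r) || r < 0) 0 else 100 * r^2 / h2
        b <- floor(qtl$peak_pos / bin_cM) * bin_cM
        freq[[length(freq) + 1L]] <- data.frame(group = qtl$group,
                                                bin_start = b,
                                                stringsAsFactors = FALSE)
      } else {
        pg_es <- 0
        pg_ts <- 0
      }
      runs[[length(runs) + 1L]] <- data.frame(
        replicate = rep_i, fold = fold_i, n_qtl = nrow(qtl),
        pG_ES = pg_es, pG_TS = pg_ts)
    }
  }
  runs <- do.call(rbind, runs)
  n_runs <- nrow(runs)
  freq <- if (length(freq)) {
    fr <- do.call(rbind, freq)
    agg <- stats::aggregate(list(count = rep(1L, nrow(fr))),
                            by = fr[c("group", "bin_start")], FUN = sum)
    agg$n_runs <- n_runs
    agg[order(agg$group, agg$bin_start), ]
  } else {
    data.frame(group = character(), bin_start = numeric(), count = integer(),
               n_runs = integer())
  }
  pg_es_mean <- mean(runs$pG_ES)
  pg_ts_mean <- mean(runs$pG_TS)
  structure(list(runs = runs, n_runs = n_runs,
                 qtl_ES_mean = mean(runs$n_qtl),
                 pG_ES_mean = pg_es_mean, pG_TS_mean = pg_ts_mean,
                 relative_bias = if (pg_es_mean > 0) {
                   relative_bias(pg_es_mean, pg_ts_mean)
                 } else NA_real_,
                 frequency = freq),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Fivefold cross-validation, %d runs\n", x$n_runs))
  cat(sprintf("  QTL_ES  = %.1f\n  pG_ES   = %.1f\n  pG_TS   = %.1f\n",
              x$qtl_ES_mean, x$pG_ES_mean, x$pG_TS_mean))
  cat(sprintf("  relative bias = %.1f%%\n", x$relative_bias))
  invisible(x)
}

#' Restrict a population to a subset of lines
#'
#' @param pop a [dh_population].
#' @param line_ids lines to keep.
#' @return A [dh_population] over the subset (family table unchanged).
#' @export
subset_population <- function(pop, line_ids) {
  stopifnot(all(line_ids %in% rownames(pop$geno)))
  dh_population(pop$map, pop$families,
                pop$geno[line_ids, , drop = FALSE],
                pop$line_family[line_ids],
                qtl_geno = if (!is.null(pop$qtl_geno)) {
                  pop$qtl_geno[line_ids, , drop = FALSE]
                })
}

# Predict entry means for new lines from a fitted multi-QTL model
# (estimation-set family means + family-specific QTL slopes).
predict_mlc <- function(model, pop, line_ids, qtl_pos) {
  sub <- subset_population(pop, line_ids)
  counts <- if (nrow(qtl_pos)) {
    expected_counts(sub, qtl_pos, quiet = TRUE)
  } else NULL
  fam <- sub$line_family
  yhat <- numeric(length(line_ids))
  for (f in names(model$coefs)) {
    idx <- which(fam == f)
    if (!length(idx)) next
    cf <- model$coefs[[f]]
    b <- cf[-1L]
    b[is.na(b)] <- 0
    yhat[idx] <- cf[1L] + if (length(b)) {
      as.vector(counts[idx, , drop = FALSE] %*% b)
    } else 0
  }
  names(yhat) <- line_ids
  yhat
}
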