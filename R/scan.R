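# Core multiple-line cross scan engine.
#
# The disconnected model  Y = J M + X_q B_q + sum_c X_c B_c + eps  has a
# family-block-diagonal design: the columns of J, X_q and X_c are each nonzero
# inside exactly one family. OLS therefore decomposes into independent
# per-family regressions whose residual sums of squares add up; all scan
# statistics below exploit this, with Frisch-Waugh partialling to test many
# positions against a common base model at once.

.seg_tol <- 1e-7

fam_rows <- function(pop) {
  lapply(pop$families$family, function(f) which(pop$line_family == f))
}

# Orthonormal basis of a design's column space; residualising against Q via
# two BLAS products is much faster than qr.resid for wide right-hand sides.
.proj_base <- function(X0) {
  q0 <- qr(X0)
  list(Q = qr.Q(q0)[, seq_len(q0$rank), drop = FALSE], rank = q0$rank)
}

.resid_Q <- function(Q, M) {
  M - Q %*% crossprod(Q, M)
}

# residual sums of squares and residual maker per family for the base model
# (intercept + included cofactor count columns)
.base_fit <- function(y, rows, cof_cols) {
  lapply(seq_along(rows), function(f) {
    idx <- rows[[f]]
    X0 <- if (is.null(cof_cols) || ncol(cof_cols) == 0L) {
      matrix(1, length(idx), 1L)
    } else {
      cbind(1, cof_cols[idx, , drop = FALSE])
    }
    pb <- .proj_base(X0)
    e <- as.vector(.resid_Q(pb$Q, matrix(y[idx])))
    list(Q = pb$Q, rank = pb$rank, e = e, rss0 = sum(e^2), idx = idx)
  })
}

#' Likelihood-ratio test of a putative QTL at one position
#'
#' Fits family means plus family-specific allele-substitution effects at the
#' tested position (plus any cofactor columns) by ordinary least squares, and
#' compares against the same model without the tested locus:
#' `LR = N * ln(RSS0 / RSS1)`, `LOD = (N / 2) * log10(RSS0 / RSS1)`.
#' Families in which the tested counts do not segregate are dropped from the
#' tested term (their effect is `NA`) with the degrees of freedom reduced
#' accordingly.
#'
#' @param y named numeric vector of entry means (BLUEs) per line.
#' @param pop a [dh_population].
#' @param xq numeric vector of expected allele counts at the tested position
#'   (one per line, same order as `y`).
#' @param cof_counts optional matrix of expected counts at the included
#'   cofactor markers (lines x cofactors).
#' @return List with `lod`, `lr`, `rss0`, `rss1`, `effects` (named per-family
#'   allele-substitution estimates, `NA` where dropped) and `df` (number of
#'   segregating family terms).
#' @export
position_test <- function(y, pop, xq, cof_counts = NULL) {
  stopifnot(length(xq) == length(y))
  rows <- fam_rows(pop)
  N <- length(y)
  base <- .base_fit(y, rows, cof_cols = cof_counts)
  rss0 <- sum(vapply(base, `[[`, 0, "rss0"))
  red <- 0
  effects <- rep(NA_real_, length(rows))
  names(effects) <- pop$families$family
  df <- 0L
  for (f in seq_along(rows)) {
    b <- base[[f]]
    z <- as.vector(.resid_Q(b$Q, matrix(xq[b$idx])))
    den <- sum(z^2)
    if (den > .seg_tol * length(b$idx)) {
      num <- sum(b$e * z)
      red <- red + num^2 / den
      effects[f] <- num / den
      df <- df + 1L
    }
  }
  rss1 <- rss0 - red
  if (rss1 <= 0) {
    warning("saturated model (RSS1 = 0); LOD capped", call. = FALSE)
    rss1 <- max(rss1, rss0 * 1e-12, .Machine$double.eps)
  }
  lod <- (N / 2) * log10(rss0 / rss1)
  list(lod = lod, lr = N * log(rss0 / rss1), rss0 = rss0, rss1 = rss1,
       effects = effects, df = df)
}

# excluded-cofactor subset per grid position under the proximity rule
.cof_exclusion <- function(grid, cofactors, excl_cM) {
  if (is.null(cofactors) || nrow(cofactors) == 0L) {
    return(rep("", nrow(grid)))
  }
  vapply(seq_len(nrow(grid)), function(j) {
    excl <- which(cofactors$group == grid$group[j] &
                    abs(cofactors$pos - grid$pos[j]) < excl_cM)
    paste(excl, collapse = ",")
  }, "")
}

#' Genome scan with the disconnected multiple-line cross model
#'
#' Runs [position_test] at every grid position. Cofactors within
#' `cof_exclude_cM` of the tested position (same linkage group) are excluded
#' from the model for that position, composite-interval-mapping style.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param grid scan grid (see [scan_grid]); defaults to a 1 cM grid.
#' @param cofactors data frame `group`, `pos` of cofactor markers (typically
#'   from [select_cofactors]); `NULL` for plain interval mapping.
#' @param cof_exclude_cM exclusion window around the tested position (cM).
#' @param counts optional precomputed [expected_counts] for `grid` (reused
#'   across permutations).
#' @return A `scan_result` data frame: `group`, `pos`, `lod`, `df`, one
#'   `eff_<family>` column per family.
#' @export
genome_scan <- function(y, pop, grid = NULL, cofactors = NULL,
                        cof_exclude_cM = 10, counts = NULL) {
  if (is.null(grid)) grid <- scan_grid(pop$map, 1)
  if (is.null(counts)) counts <- expected_counts(pop, grid, quiet = TRUE)
  rows <- fam_rows(pop)
  N <- length(y)
  P <- length(rows)
  fams <- pop$families$family
  cof_cols <- if (!is.null(cofactors) && nrow(cofactors)) {
    cof_grid <- cofactors[, c("group", "pos")]
    expected_counts(pop, cof_grid, quiet = TRUE)
  } else NULL
  keys <- .cof_exclusion(grid, cofactors, cof_exclude_cM)
  lod <- numeric(nrow(grid))
  df <- integer(nrow(grid))
  eff <- matrix(NA_real_, nrow(grid), P, dimnames = list(NULL, fams))
  for (key in unique(keys)) {
    jj <- which(keys == key)
    excl <- if (nzchar(key)) as.integer(strsplit(key, ",")[[1L]]) else integer()
    incl_cols <- if (!is.null(cof_cols)) {
      cof_cols[, setdiff(seq_len(ncol(cof_cols)), excl), drop = FALSE]
    } else NULL
    base <- .base_fit(y, rows, incl_cols)
    rss0 <- sum(vapply(base, `[[`, 0, "rss0"))
    red <- numeric(length(jj))
    for (f in seq_along(rows)) {
      b <- base[[f]]
      Z <- .resid_Q(b$Q, counts[b$idx, jj, drop = FALSE])
      num <- colSums(Z * b$e)
      den <- colSums(Z^2)
      seg <- den > .seg_tol * length(b$idx)
      red <- red + ifelse(seg, num^2 / den, 0)
      eff[jj, f] <- ifelse(seg, num / den, NA_real_)
      df[jj] <- df[jj] + as.integer(seg)
    }
    rss1 <- pmax(rss0 - red, rss0 * 1e-12)
    lod[jj] <- (N / 2) * log10(rss0 / rss1)
  }
  out <- data.frame(group = grid$group, pos = grid$pos, lod = lod, df = df,
                    stringsAsFactors = FALSE)
  colnames(eff) <- paste0("eff_", fams)
  out <- cbind(out, eff)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Forward cofactor selection by the Schwarz criterion
#'
#' Starting from the family-means model, markers enter one at a time as
#' family-specific blocks (one allele-count column per family, skipping
#' families where the marker does not segregate). At each step the marker
#' giving the lowest Schwarz Bayesian criterion
#' `SBC = N ln(RSS/N) + k ln(N)` is added; selection stops when no marker
#' improves the criterion or `max_cofactors` is reached. Deterministic given
#' the input.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param max_cofactors maximum number of cofactor markers.
#' @param counts optional precomputed [expected_counts] at the map's markers.
#' @return Data frame `marker`, `group`, `pos` of the selected markers, in
#'   selection order (zero rows if none improves the criterion).
#' @export
select_cofactors <- function(y, pop, max_cofactors = 10, counts = NULL) {
  map <- pop$map
  if (is.null(counts)) counts <- expected_counts(pop, map, quiet = TRUE)
  rows <- fam_rows(pop)
  N <- length(y)
  P <- length(rows)
  if (max_cofactors == 0) {
    return(data.frame(marker = character(), group = character(),
                      pos = numeric(), stringsAsFactors = FALSE))
  }
  if (N <= P + max_cofactors * P) {
    stop_param("too few lines for ", max_cofactors,
               " family-specific cofactor blocks")
  }
  M <- ncol(counts)
  selected <- integer()
  # per-family design starts as the intercept
  X_f <- lapply(rows, function(idx) matrix(1, length(idx), 1L))
  k_cur <- P
  rss_cur <- sum(vapply(seq_along(rows), function(f) {
    yf <- y[rows[[f]]]
    sum((yf - mean(yf))^2)
  }, 0))
  sbc_cur <- N * log(rss_cur / N) + k_cur * log(N)
  repeat {
    red <- matrix(0, M, 1L)
    dfm <- integer(M)
    for (f in seq_along(rows)) {
      idx <- rows[[f]]
      pb <- .proj_base(X_f[[f]])
      e <- as.vector(.resid_Q(pb$Q, matrix(y[idx])))
      Z <- .resid_Q(pb$Q, counts[idx, , drop = FALSE])
      num <- colSums(Z * e)
      den <- colSums(Z^2)
      seg <- den > .seg_tol * length(idx)
      red <- red + ifelse(seg, num^2 / den, 0)
      dfm <- dfm + as.integer(seg)
    }
    rss_new <- rss_cur - red
    sbc <- N * log(pmax(rss_new, .Machine$double.eps) / N) +
      (k_cur + dfm) * log(N)
    sbc[selected] <- Inf
    sbc[dfm == 0L] <- Inf
    best <- which.min(sbc)
    if (!is.finite(sbc[best]) || sbc[best] >= sbc_cur - 1e-9) break
    selected <- c(selected, best)
    for (f in seq_along(rows)) {
      X_f[[f]] <- cbind(X_f[[f]], counts[rows[[f]], best])
    }
    rss_cur <- rss_new[best]
    k_cur <- k_cur + dfm[best]
    sbc_cur <- sbc[best]
    if (length(selected) >= max_cofactors) break
  }
  data.frame(marker = map$marker[selected], group = map$group[selected],
             pos = map$pos[selected], stringsAsFactors = FALSE)
}

#' Permutation-based genome-wide LOD threshold
#'
#' Phenotypes are permuted within each family (preserving family structure),
#' cofactors are re-selected on each permuted phenotype, the genome is
#' re-scanned, and the maximum LOD recorded. The threshold is the empirical
#' `1 - alpha` quantile (type-7 interpolation) of the max-LOD distribution,
#' giving an experiment-wise type-I error of `alpha`.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param grid scan grid; defaults to a 1 cM grid.
#' @param n_perm number of permutations (`>= 100`; 2000 for publication-grade
#'   thresholds, 200 as a fast default).
#' @param alpha experiment-wise error rate in `(0, 1]`.
#' @param seed RNG seed.
#' @param max_cofactors passed to [select_cofactors].
#' @param reselect_cofactors re-select cofactors inside every permutation
#'   replicate (default; honest but slower). If `FALSE`, `cofactors` is used
#'   unchanged.
#' @param cofactors fixed cofactors when `reselect_cofactors = FALSE`.
#' @return A `perm_threshold` list: `threshold`, `max_lods`, `alpha`,
#'   `n_perm`.
#' @export
permutation_threshold <- function(y, pop, grid = NULL, n_perm = 200,
                                  alpha = 0.10, seed = NULL,
                                  max_cofactors = 10,
                                  reselect_cofactors = TRUE,
                                  cofactors = NULL) {
  if (alpha <= 0 || alpha > 1) stop_param("alpha must be in (0, 1]")
  if (n_perm < 100) stop_param("n_perm must be >= 100")
  if (is.null(grid)) grid <- scan_grid(pop$map, 1)
  counts <- expected_counts(pop, grid, quiet = TRUE)
  mcounts <- expected_counts(pop, pop$map, quiet = TRUE)
  rows <- fam_rows(pop)
  max_lods <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- y
      for (idx in rows) yp[idx] <- y[idx][sample.int(length(idx))]
      cof <- if (reselect_cofactors) {
        select_cofactors(yp, pop, max_cofactors, counts = mcounts)
      } else cofactors
      max(genome_scan(yp, pop, grid, cof, counts = counts)$lod)
    }, 0)
  })
  structure(list(threshold = unname(stats::quantile(max_lods, 1 - alpha,
                                                    type = 7)),
                 max_lods = max_lods, alpha = alpha, n_perm = n_perm),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("Genome-wide LOD threshold %.2f (alpha = %.2f, %d permutations)\n",
              x$threshold, x$alpha, x$n_perm))
  invisible(x)
}

.as_threshold <- function(threshold) {
  if (inherits(threshold, "perm_threshold")) threshold$threshold else threshold
}

#' Declare QTL from a scan profile
#'
#' Local LOD maxima above the threshold become QTL. Two peaks on one group
#' are distinct QTL only if they are more than `peak_sep_cM` apart and the
#' profile between them drops by at least `fall_off` LOD below both peaks;
#' otherwise they merge into the higher peak. The support interval is the
#' contiguous region around the peak where the LOD stays within `fall_off` of
#' the peak value.
#'
#' @param scan a `scan_result` from [genome_scan].
#' @param threshold numeric LOD threshold or a `perm_threshold`.
#' @param fall_off LOD fall-off for support intervals (and valley depth).
#' @param peak_sep_cM minimum separation of distinct peaks on one group.
#' @return Data frame of QTL records: `group`, `peak_pos`, `support_lo`,
#'   `support_hi`, `lod`, `df`, per-family `eff_*` columns.
#' @export
declare_qtl <- function(scan, threshold, fall_off = 1.0, peak_sep_cM = 20) {
  threshold <- .as_threshold(threshold)
  eff_cols <- grep("^eff_", names(scan), value = TRUE)
  recs <- list()
  for (g in unique(scan$group)) {
    s <- scan[scan$group == g, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    lod <- s$lod
    n <- length(lod)
    if (n == 0L || max(lod) < threshold) next
    left <- c(-Inf, lod[-n])
    right <- c(lod[-1L], -Inf)
    is_peak <- lod >= left & lod >= right & lod >= threshold
    # de-duplicate flat-topped runs: keep the first index of each run
    cand <- which(is_peak)
    if (length(cand) > 1L) {
      keep <- c(TRUE, !(diff(cand) == 1L & abs(diff(lod[cand])) < 1e-12))
      cand <- cand[keep]
    }
    cand <- cand[order(-lod[cand])]
    accepted <- integer()
    for (ci in cand) {
      ok <- TRUE
      for (ai in accepted) {
        rng <- sort(c(ci, ai))
        valley <- min(lod[rng[1L]:rng[2L]])
        sep <- abs(s$pos[ci] - s$pos[ai])
        if (sep <= peak_sep_cM ||
            valley > min(lod[ci], lod[ai]) - fall_off) {
          ok <- FALSE
          break
        }
      }
      if (ok) accepted <- c(accepted, ci)
    }
    for (ai in accepted) {
      lo <- ai
      while (lo > 1L && lod[lo - 1L] >= lod[ai] - fall_off) lo <- lo - 1L
      hi <- ai
      while (hi < n && lod[hi + 1L] >= lod[ai] - fall_off) hi <- hi + 1L
      recs[[length(recs) + 1L]] <- cbind(
        data.frame(group = g, peak_pos = s$pos[ai], support_lo = s$pos[lo],
                   support_hi = s$pos[hi], lod = lod[ai], df = s$df[ai],
                   stringsAsFactors = FALSE),
        s[ai, eff_cols, drop = FALSE])
    }
  }
  if (!length(recs)) {
    out <- data.frame(group = character(), peak_pos = numeric(),
                      support_lo = numeric(), support_hi = numeric(),
                      lod = numeric(), df = integer(),
                      stringsAsFactors = FALSE)
    for (cc in eff_cols) out[[cc]] <- numeric()
    return(out)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out[order(match(out$group, unique(scan$group)), out$peak_pos), ,
      drop = FALSE]
}

# Fit the simultaneous family-means + multi-QTL model; returns per-family
# coefficients (intercept + one slope per QTL, NA where non-segregating),
# total RSS and total rank.
fit_mlc_model <- function(y, pop, qtl_pos, counts = NULL) {
  rows <- fam_rows(pop)
  Q <- if (is.null(qtl_pos)) 0L else nrow(qtl_pos)
  if (Q > 0L && is.null(counts)) {
    counts <- expected_counts(pop, qtl_pos[, c("group", "pos")], quiet = TRUE)
  }
  coefs <- vector("list", length(rows))
  rss <- 0
  rank <- 0L
  for (f in seq_along(rows)) {
    idx <- rows[[f]]
    X <- cbind(rep(1, length(idx)),
               if (Q > 0L) counts[idx, , drop = FALSE])
    fit <- stats::lm.fit(X, y[idx])
    rss <- rss + sum(fit$residuals^2)
    rank <- rank + fit$rank
    cf <- fit$coefficients
    cf[is.na(cf)] <- NA_real_
    coefs[[f]] <- cf
  }
  names(coefs) <- pop$families$family
  list(coefs = coefs, rss = rss, rank = rank)
}

#' Proportion of genotypic variance explained by a set of QTL
#'
#' Fits the simultaneous model with family means plus all QTL blocks, takes
#' the adjusted coefficient of determination
#' `R2adj = 1 - (1 - R2) (N - 1) / (N - k - 1)` (with `k` the number of
#' fitted non-intercept parameters) and divides by the entry-mean
#' heritability: `pG = 100 * R2adj / h2`. Each QTL's single contribution is
#' the drop-one partial: `pG_combined` minus the same quantity with that QTL
#' removed, floored at 0.
#'
#' @param qtl QTL table from [declare_qtl] (needs `group`, `peak_pos`).
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param h2 entry-mean heritability in `(0, 1]`.
#' @return List with `pG_combined`, `pG_single` (one per QTL row), `R2adj`
#'   and the fitted `model` (see `fit_mlc_model`).
#' @export
proportion_genotypic_variance <- function(qtl, y, pop, h2) {
  if (h2 <= 0 || h2 > 1) stop_param("h2 must be in (0, 1]")
  if (is.null(qtl) || nrow(qtl) == 0L) stop_param("empty QTL set")
  qtl_pos <- data.frame(group = qtl$group, pos = qtl$peak_pos,
                        stringsAsFactors = FALSE)
  counts <- expected_counts(pop, qtl_pos, quiet = TRUE)
  N <- length(y)
  tss <- sum((y - mean(y))^2)
  pg_of <- function(cols) {
    Q <- length(cols)
    fit <- fit_mlc_model(y, pop,
                         if (Q) qtl_pos[cols, , drop = FALSE] else NULL,
                         counts = if (Q) counts[, cols, drop = FALSE])
    k <- fit$rank - 1L
    if (N <= k + 1L) stop_param("model over-parameterized: N <= k + 1")
    r2 <- 1 - fit$rss / tss
    r2adj <- 1 - (1 - r2) * (N - 1) / (N - k - 1)
    list(pg = 100 * r2adj / h2, fit = fit, r2adj = r2adj)
  }
  full <- pg_of(seq_len(nrow(qtl)))
  single <- vapply(seq_len(nrow(qtl)), function(q) {
    rest <- setdiff(seq_len(nrow(qtl)), q)
    drop <- if (length(rest)) pg_of(rest)$pg else {
      # family-means-only model: R2adj of J alone
      pg_of(integer())$pg
    }
    max(full$pg - drop, 0)
  }, 0)
  list(pG_combined = full$pg, pG_single = single, R2adj = full$r2adj,
       model = full$fit)
}

#' Classify QTL overlap across developmental stages
#'
#' Two QTL overlap if they sit on the same linkage group with peaks at most
#' `window_cM` apart (boundary inclusive); overlap is closed transitively
#' into clusters, and each cluster is labelled by the set of stages in which
#' its members were detected (the Venn classification).
#'
#' @param qtl_by_stage named list of QTL tables (one per stage, from
#'   [declare_qtl]).
#' @param window_cM overlap window in cM.
#' @return List with `clusters` (data frame `cluster`, `stage`, `group`,
#'   `peak_pos`) and `counts` (named integer vector per stage combination,
#'   labels like `"BM1+BM3"`).
#' @export
classify_overlap <- function(qtl_by_stage, window_cM = 10) {
  stages <- names(qtl_by_stage)
  peaks <- do.call(rbind, lapply(stages, function(st) {
    q <- qtl_by_stage[[st]]
    if (is.null(q) || nrow(q) == 0L) return(NULL)
    data.frame(stage = st, group = q$group, peak_pos = q$peak_pos,
               stringsAsFactors = FALSE)
  }))
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(list(clusters = data.frame(cluster = integer(), stage = character(),
                                      group = character(),
                                      peak_pos = numeric()),
                counts = integer()))
  }
  n <- nrow(peaks)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (peaks$group[i] == peaks$group[j] &&
          abs(peaks$peak_pos[i] - peaks$peak_pos[j]) <= window_cM) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  peaks$cluster <- match(root, unique(root))
  combos <- vapply(split(peaks$stage, peaks$cluster), function(ss) {
    paste(stages[stages %in% ss], collapse = "+")
  }, "")
  counts <- table(combos)
  list(clusters = peaks[, c("cluster", "stage", "group", "peak_pos")],
       counts = stats::setNames(as.integer(counts), names(counts)))
}
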