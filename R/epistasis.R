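# Two-dimensional epistasis scan.
#
# The scan model is extended by a second-locus block and an interaction block
# whose within-family columns are products of within-family centered allele
# counts (centering keeps the product term close to orthogonal to the main
# effects). The interaction block is tested with an F test, equivalent to the
# likelihood ratio under Gaussian OLS but numerically stabler.

#' Region-based significance threshold for the epistasis scan
#'
#' Bonferroni correction over the number of possible independent pairwise
#' interactions between chromosome regions, assuming two separate regions per
#' chromosome: `threshold = alpha / choose(2 * n_groups, 2)`.
#'
#' @param n_groups number of linkage groups (`>= 1`).
#' @param alpha nominal error rate.
#' @return P-value threshold.
#' @export
region_threshold <- function(n_groups, alpha = 0.05) {
  if (n_groups < 1) stop_param("n_groups must be >= 1")
  alpha / choose(2 * n_groups, 2)
}

# Vectorised interaction tests of locus i against candidate columns jj of
# `counts`; `base_cols` holds optional extra base-model columns (cofactor
# counts). Returns P values, interaction df and model ranks per candidate.
.pair_tests_vec <- function(y, rows, counts, i, jj, base_cols = NULL) {
  N <- length(y)
  m <- length(jj)
  rss_base <- 0
  red_main <- numeric(m)
  red_full <- numeric(m)
  seg2 <- integer(m)
  segw <- integer(m)
  rank_base <- 0L
  for (f in seq_along(rows)) {
    idx <- rows[[f]]
    nf <- length(idx)
    x1 <- counts[idx, i]
    X0 <- cbind(1, x1, if (!is.null(base_cols)) {
      base_cols[idx, , drop = FALSE]
    })
    pb <- .proj_base(X0)
    rank_base <- rank_base + pb$rank
    e <- as.vector(.resid_Q(pb$Q, matrix(y[idx])))
    rss_base <- rss_base + sum(e^2)
    X2 <- counts[idx, jj, drop = FALSE]
    X2r <- .resid_Q(pb$Q, X2)
    x1c <- x1 - mean(x1)
    W <- x1c * sweep(X2, 2L, colMeans(X2))
    Wr <- .resid_Q(pb$Q, W)
    a <- colSums(X2r^2)
    cc <- colSums(Wr^2)
    b <- colSums(X2r * Wr)
    u <- colSums(X2r * e)
    v <- colSums(Wr * e)
    s2 <- a > .seg_tol * nf
    det <- a * cc - b^2
    sw <- s2 & cc > .seg_tol * nf & det > 1e-10 * pmax(a * cc, 1e-300)
    red_main <- red_main + ifelse(s2, u^2 / pmax(a, 1e-300), 0)
    red_full <- red_full + ifelse(
      sw,
      (cc * u^2 - 2 * b * u * v + a * v^2) / pmax(det, 1e-300),
      ifelse(s2, u^2 / pmax(a, 1e-300), 0))
    seg2 <- seg2 + as.integer(s2)
    segw <- segw + as.integer(sw)
  }
  rss_main <- pmax(rss_base - red_main, 0)
  rss_full <- pmax(rss_base - red_full, 0)
  rank_full <- rank_base + seg2 + segw
  df2 <- N - rank_full
  dd <- rss_main - rss_full
  Fstat <- (dd / pmax(segw, 1L)) / (rss_full / pmax(df2, 1L))
  P <- ifelse(segw == 0L | df2 <= 0L | dd <= 0 | rss_full <= 0,
              1, stats::pf(Fstat, segw, df2, lower.tail = FALSE))
  list(P = P, df_int = segw, rank_full = rank_full)
}

#' Test the interaction between two loci
#'
#' F test of the family-specific interaction block, comparing the model with
#' family means, both main-effect blocks and the interaction block against
#' the same model without the interaction block. Families where the
#' interaction column is non-segregating or collinear with the main effects
#' are dropped from the tested block.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param x1,x2 expected allele counts of the two loci (one value per line).
#' @param cof_counts optional matrix of expected counts at cofactor markers
#'   included in both models (callers exclude cofactors near the tested
#'   loci).
#' @return List with `P`, `F`, `df_int`, `df_resid` and `effects` (named
#'   per-family interaction coefficients, `NA` where dropped).
#' @export
pair_test <- function(y, pop, x1, x2, cof_counts = NULL) {
  rows <- fam_rows(pop)
  N <- length(y)
  effects0 <- stats::setNames(rep(NA_real_, length(rows)),
                              pop$families$family)
  if (sum((y - mean(y))^2) <= .Machine$double.eps * N) {
    return(list(P = 1, F = 0, df_int = 0L, df_resid = N - 3L * length(rows),
                effects = effects0))
  }
  rss_main <- 0
  rss_full <- 0
  rank_main <- 0L
  rank_full <- 0L
  effects <- rep(NA_real_, length(rows))
  names(effects) <- pop$families$family
  for (f in seq_along(rows)) {
    idx <- rows[[f]]
    x1f <- x1[idx]; x2f <- x2[idx]
    w <- (x1f - mean(x1f)) * (x2f - mean(x2f))
    Xm <- cbind(1, x1f, x2f,
                if (!is.null(cof_counts)) cof_counts[idx, , drop = FALSE])
    Xf <- cbind(Xm[, 1:3, drop = FALSE], w,
                if (!is.null(cof_counts)) cof_counts[idx, , drop = FALSE])
    qm <- qr(Xm)
    qf <- qr(Xf)
    rss_main <- rss_main + sum(qr.resid(qm, y[idx])^2)
    rss_full <- rss_full + sum(qr.resid(qf, y[idx])^2)
    rank_main <- rank_main + qm$rank
    rank_full <- rank_full + qf$rank
    if (qf$rank > qm$rank) {
      effects[f] <- qr.coef(qf, y[idx])[4L]
    }
  }
  df_int <- rank_full - rank_main
  df_resid <- N - rank_full
  dd <- rss_main - rss_full
  if (df_int == 0L || df_resid <= 0L || dd <= 1e-12 * max(rss_main, 1e-300) ||
      rss_full <= 0) {
    return(list(P = 1, F = 0, df_int = df_int, df_resid = df_resid,
                effects = effects))
  }
  Fstat <- (dd / df_int) / (rss_full / df_resid)
  list(P = stats::pf(Fstat, df_int, df_resid, lower.tail = FALSE),
       F = Fstat, df_int = df_int, df_resid = df_resid, effects = effects)
}

# pG of the interaction block via drop-one partial adjusted R^2 / h2.
.pg_interaction <- function(y, pop, x1, x2, h2, cof_counts = NULL) {
  rows <- fam_rows(pop)
  N <- length(y)
  tss <- sum((y - mean(y))^2)
  r2adj_of <- function(with_w) {
    rss <- 0; rank <- 0L
    for (f in seq_along(rows)) {
      idx <- rows[[f]]
      x1f <- x1[idx]; x2f <- x2[idx]
      X <- cbind(1, x1f, x2f,
                 if (!is.null(cof_counts)) cof_counts[idx, , drop = FALSE])
      if (with_w) X <- cbind(X, (x1f - mean(x1f)) * (x2f - mean(x2f)))
      q <- qr(X)
      rss <- rss + sum(qr.resid(q, y[idx])^2)
      rank <- rank + q$rank
    }
    k <- rank - 1L
    1 - (1 - (1 - rss / tss)) * (N - 1) / (N - k - 1)
  }
  max(100 * (r2adj_of(TRUE) - r2adj_of(FALSE)) / h2, 0)
}

#' Full two-dimensional epistasis scan
#'
#' Tests all grid-position pairs on different linkage groups, plus pairs at
#' least `same_group_min_cM` apart on the same group (closely linked pairs
#' are skipped as their interaction column is collinear with the main
#' effects). Significant pairs are clustered -- two pairs join a cluster when
#' both loci lie within `cluster_cM` -- and each cluster is reported at its
#' best (smallest-P) pair.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param step_cM grid step for both dimensions (default 5 cM; the 2-D scan
#'   grows quadratically in grid size).
#' @param threshold P-value threshold, typically
#'   `region_threshold(n_groups)`.
#' @param h2 entry-mean heritability; when given, `pG_epi` is reported per
#'   cluster.
#' @param cofactors optional cofactor table (`group`, `pos`, from
#'   [select_cofactors]) added to the base model to absorb main-effect QTL
#'   elsewhere in the genome; cofactors within `cof_exclude_cM` of either
#'   tested locus are excluded for that pair. Without them, a strong
#'   unmodelled additive QTL leaves a non-Gaussian within-family residual
#'   that inflates the tails of the interaction F test.
#' @param cof_exclude_cM exclusion window around tested loci.
#' @param same_group_min_cM minimum separation of tested same-group pairs.
#' @param cluster_cM clustering window for significant pairs.
#' @return List with `records` (data frame `group1`, `pos1`, `group2`,
#'   `pos2`, `P`, `neglog10P`, `df_int`, `pG_epi`, per-family `effect_*`
#'   columns; one row per significant cluster), `n_tested`, `min_P` and
#'   `threshold`.
#' @export
epistasis_scan <- function(y, pop, step_cM = 5, threshold = NULL, h2 = NULL,
                           cofactors = NULL, cof_exclude_cM = 10,
                           same_group_min_cM = 20, cluster_cM = 10) {
  grid <- scan_grid(pop$map, step_cM)
  counts <- expected_counts(pop, grid, quiet = TRUE)
  rows <- fam_rows(pop)
  if (is.null(threshold)) {
    threshold <- region_threshold(length(unique(pop$map$group)))
  }
  have_cof <- !is.null(cofactors) && nrow(cofactors) > 0
  cof_cols <- if (have_cof) {
    expected_counts(pop, cofactors[, c("group", "pos")], quiet = TRUE)
  } else NULL
  keys <- if (have_cof) {
    .cof_exclusion(grid, cofactors, cof_exclude_cM)
  } else rep("", nrow(grid))
  G <- nrow(grid)
  n_tested <- 0L
  min_p <- 1
  hits <- list()
  for (i in seq_len(G - 1L)) {
    jj_all <- which(seq_len(G) > i &
                      (grid$group != grid$group[i] |
                         abs(grid$pos - grid$pos[i]) >= same_group_min_cM))
    if (!length(jj_all)) next
    # candidates grouped by the cofactors their pair must exclude
    for (key in unique(keys[jj_all])) {
      jj <- jj_all[keys[jj_all] == key]
      base_cols <- NULL
      if (have_cof) {
        excl <- unique(c(
          if (nzchar(keys[i])) as.integer(strsplit(keys[i], ",")[[1L]]),
          if (nzchar(key)) as.integer(strsplit(key, ",")[[1L]])))
        base_cols <- cof_cols[, setdiff(seq_len(ncol(cof_cols)), excl),
                              drop = FALSE]
      }
      res <- .pair_tests_vec(y, rows, counts, i, jj, base_cols)
      n_tested <- n_tested + length(jj)
      min_p <- min(min_p, min(res$P))
      sig <- which(res$P < threshold)
      if (length(sig)) {
        hits[[length(hits) + 1L]] <- data.frame(
          i = i, j = jj[sig], P = res$P[sig], df_int = res$df_int[sig])
      }
    }
  }
  records <- .cluster_pairs(do.call(rbind, hits), grid, cluster_cM)
  if (nrow(records)) {
    eff <- matrix(NA_real_, nrow(records), nrow(pop$families),
                  dimnames = list(NULL,
                                  paste0("effect_", pop$families$family)))
    records$pG_epi <- NA_real_
    for (r in seq_len(nrow(records))) {
      i <- records$i[r]; j <- records$j[r]
      cof_ij <- NULL
      if (have_cof) {
        keep <- !(
          (cofactors$group == grid$group[i] &
             abs(cofactors$pos - grid$pos[i]) < cof_exclude_cM) |
            (cofactors$group == grid$group[j] &
               abs(cofactors$pos - grid$pos[j]) < cof_exclude_cM))
        cof_ij <- cof_cols[, keep, drop = FALSE]
        if (ncol(cof_ij) == 0L) cof_ij <- NULL
      }
      pt <- pair_test(y, pop, counts[, i], counts[, j], cof_counts = cof_ij)
      eff[r, ] <- pt$effects
      records$P[r] <- pt$P
      records$neglog10P[r] <- -log10(max(pt$P, .Machine$double.xmin))
      if (!is.null(h2)) {
        records$pG_epi[r] <- .pg_interaction(y, pop, counts[, i],
                                             counts[, j], h2,
                                             cof_counts = cof_ij)
      }
    }
    records <- cbind(records[, c("group1", "pos1", "group2", "pos2", "P",
                                 "neglog10P", "df_int", "pG_epi")], eff)
  }
  list(records = records, n_tested = n_tested, min_P = min_p,
       threshold = threshold)
}

# Cluster significant pairs: same cluster when both loci are within
# cluster_cM (on matching groups); keep the best pair per cluster.
.cluster_pairs <- function(hits, grid, cluster_cM) {
  empty <- data.frame(group1 = character(), pos1 = numeric(),
                      group2 = character(), pos2 = numeric(), P = numeric(),
                      neglog10P = numeric(), df_int = integer(),
                      i = integer(), j = integer())
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  h <- data.frame(group1 = grid$group[hits$i], pos1 = grid$pos[hits$i],
                  group2 = grid$group[hits$j], pos2 = grid$pos[hits$j],
                  P = hits$P, df_int = hits$df_int, i = hits$i, j = hits$j,
                  stringsAsFactors = FALSE)
  n <- nrow(h)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  near <- function(ga, pa, gb, pb) ga == gb && abs(pa - pb) <= cluster_cM
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if ((near(h$group1[a], h$pos1[a], h$group1[b], h$pos1[b]) &&
             near(h$group2[a], h$pos2[a], h$group2[b], h$pos2[b])) ||
            (near(h$group1[a], h$pos1[a], h$group2[b], h$pos2[b]) &&
             near(h$group2[a], h$pos2[a], h$group1[b], h$pos1[b]))) {
          parent[find(b)] <- find(a)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  best <- vapply(split(seq_len(n), root), function(ii) {
    ii[which.min(h$P[ii])]
  }, 0L)
  out <- h[sort(best), , drop = FALSE]
  out$neglog10P <- -log10(pmax(out$P, .Machine$double.xmin))
  # canonical locus order within each pair
  swap <- out$group1 > out$group2 |
    (out$group1 == out$group2 & out$pos1 > out$pos2)
  if (any(swap)) {
    tmp_g <- out$group1[swap]; tmp_p <- out$pos1[swap]
    out$group1[swap] <- out$group2[swap]; out$pos1[swap] <- out$pos2[swap]
    out$group2[swap] <- tmp_g; out$pos2[swap] <- tmp_p
  }
  rownames(out) <- NULL
  out
}

#' Interaction landscape for one pair of linkage groups
#'
#' Dense matrix of `-log10(P)` of the interaction test for every grid
#' position of `group_a` against every grid position of `group_b`, plus a
#' significance mask -- the tabular stand-in for a 3-D interaction-landscape
#' plot.
#'
#' @param y named entry means per line.
#' @param pop a [dh_population].
#' @param group_a,group_b the two linkage groups (must differ).
#' @param step_cM grid step.
#' @param threshold P-value threshold for the mask; defaults to
#'   [region_threshold] of the whole map.
#' @return List with `neglog10P` (matrix, rows = `group_a` positions),
#'   `significant` (logical matrix), `pos_a`, `pos_b`, `threshold`.
#' @export
landscape <- function(y, pop, group_a, group_b, step_cM = 5,
                      threshold = NULL, cofactors = NULL,
                      cof_exclude_cM = 10) {
  if (group_a == group_b) stop_param("landscape needs two distinct groups")
  if (is.null(threshold)) {
    threshold <- region_threshold(length(unique(pop$map$group)))
  }
  grid <- scan_grid(pop$map, step_cM)
  keep <- grid$group %in% c(group_a, group_b)
  grid <- grid[keep, , drop = FALSE]
  counts <- expected_counts(pop, grid, quiet = TRUE)
  rows <- fam_rows(pop)
  ia <- which(grid$group == group_a)
  ib <- which(grid$group == group_b)
  have_cof <- !is.null(cofactors) && nrow(cofactors) > 0
  cof_cols <- if (have_cof) {
    # cofactors on the two plotted groups are dropped wholesale: the whole
    # group is "near" some tested locus of the landscape
    keep <- !(cofactors$group %in% c(group_a, group_b))
    cc <- expected_counts(pop, cofactors[keep, c("group", "pos"),
                                         drop = FALSE], quiet = TRUE)
    if (ncol(cc)) cc else NULL
  } else NULL
  mat <- matrix(NA_real_, length(ia), length(ib),
                dimnames = list(paste0(group_a, "@", grid$pos[ia]),
                                paste0(group_b, "@", grid$pos[ib])))
  for (k in seq_along(ia)) {
    res <- .pair_tests_vec(y, rows, counts, ia[k], ib, cof_cols)
    mat[k, ] <- -log10(pmax(res$P, .Machine$double.xmin))
  }
  list(neglog10P = mat, significant = mat > -log10(threshold),
       pos_a = grid$pos[ia], pos_b = grid$pos[ib], threshold = threshold)
}
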