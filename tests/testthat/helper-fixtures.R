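# Fixtures and small independent oracles shared across test files.
# Everything is generated in code; no data files.

# Small two-family population on a compact map.
tiny_pop <- function(n1 = 60, n2 = 60, n_groups = 2, length_cM = 60,
                     spacing_cM = 10, seed = 42, arch = NULL) {
  map <- make_map(n_groups, length_cM, spacing_cM)
  fams <- family_spec(c("FAM1", "FAM2"), c(n1, n2))
  simulate_dh_population(map, fams, arch = arch, seed = seed)
}

# Population built by hand from an explicit genotype matrix (one family
# unless line_family says otherwise).
manual_pop <- function(map, geno, line_family = NULL) {
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("L%02d", seq_len(nrow(geno)))
  }
  colnames(geno) <- map$marker
  if (is.null(line_family)) {
    line_family <- stats::setNames(rep("FAM1", nrow(geno)), rownames(geno))
  }
  fam_ids <- unique(line_family)
  fams <- family_spec(fam_ids, as.integer(table(factor(line_family,
                                                       levels = fam_ids))))
  dh_population(map, fams, geno, line_family)
}

# Brute-force conditional expected count at position p on a group, given the
# observed marker codes of one line, by exhaustive enumeration of DH gamete
# classes under Haldane transition probabilities. Independent of the
# package's flanking-marker shortcut.
enum_expected_count <- function(marker_pos, codes, p) {
  obs <- which(!is.na(codes))
  loci <- sort(unique(c(marker_pos, p)))
  p_idx <- match(p, loci)
  r <- 0.5 * (1 - exp(-2 * diff(loci) / 100))
  k <- length(loci)
  num <- 0
  den <- 0
  for (cls in 0:(2^k - 1)) {
    alle <- as.integer(intToBits(cls))[seq_len(k)]   # 1 = parent A
    pr <- 0.5
    if (k > 1) {
      sw <- abs(diff(alle))
      pr <- pr * prod(ifelse(sw == 1, r, 1 - r))
    }
    m_idx <- match(marker_pos[obs], loci)
    if (all(alle[m_idx] == codes[obs] / 2)) {
      den <- den + pr
      num <- num + pr * alle[p_idx]
    }
  }
  2 * num / den
}

# OLS likelihood-ratio LOD for the disconnected model, solved directly from
# the normal equations (independent of the package's QR path).
oracle_lod <- function(y, fam, xq) {
  fam <- as.character(fam)
  fams <- unique(fam)
  N <- length(y)
  J <- sapply(fams, function(f) as.numeric(fam == f))
  X1 <- cbind(J, sapply(fams, function(f) xq * (fam == f)))
  rss <- function(X) {
    # least-norm OLS through an eigen pseudo-inverse (handles collinear
    # columns from non-segregating families), fully independent of QR
    XtX <- t(X) %*% X
    ev <- eigen(XtX, symmetric = TRUE)
    pos <- ev$values > 1e-10 * max(ev$values)
    XtXinv <- ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
    b <- XtXinv %*% (t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  rss0 <- rss(J)
  rss1 <- rss(X1)
  list(rss0 = rss0, rss1 = rss1, lod = (N / 2) * log10(rss0 / rss1),
       lr = N * log(rss0 / rss1))
}

# Kernel-density mode count with a minimum-valley prominence rule.
count_modes <- function(x, prominence = 0.05) {
  d <- stats::density(x)
  yy <- d$y / max(d$y)
  pk <- which(diff(sign(diff(yy))) == -2) + 1L
  pk <- pk[yy[pk] > 0.1]
  if (length(pk) < 2) return(length(pk))
  n <- 1L
  for (k in 2:length(pk)) {
    v <- min(yy[pk[k - 1L]:pk[k]])
    if (v < min(yy[pk[k - 1L]], yy[pk[k]]) - prominence) n <- n + 1L
  }
  n
}

# Depth of the valley between the outermost density modes (0 = unimodal).
valley_depth <- function(x) {
  d <- stats::density(x)
  yy <- d$y / max(d$y)
  pk <- which(diff(sign(diff(yy))) == -2) + 1L
  pk <- pk[yy[pk] > 0.1]
  if (length(pk) < 2) return(0)
  max(0, min(yy[pk[1L]], yy[pk[length(pk)]]) -
        min(yy[pk[1L]:pk[length(pk)]]))
}
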