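#' Haldane map function
#'
#' Converts a map distance in cM to a recombination fraction assuming no
#' crossover interference: `r = 0.5 * (1 - exp(-2 d / 100))`.
#'
#' @param d_cM map distance in cM (`>= 0`); vectorised.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_r <- function(d_cM) {
  if (any(!is.finite(d_cM) | d_cM < 0)) {
    if (any(is.infinite(d_cM) & d_cM > 0)) {
      # allow the d -> Inf asymptote
      return(ifelse(is.infinite(d_cM), 0.5, haldane_r(pmax(d_cM, 0))))
    }
    stop_param("d_cM must be >= 0")
  }
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Conditional probability of the A allele in a DH line
#'
#' Probability that a doubled-haploid line carries the parent-A allele at a
#' position flanked by markers with observed alleles `left` and `right`, given
#' recombination fractions `r_left` / `r_right` between the position and each
#' flank. Under no interference the crossover process is Markov, so flanking
#' markers carry all the information of the chromosome.
#'
#' @param left,right observed flank alleles: `"A"`, `"B"` or `NA` (missing).
#' @param r_left,r_right recombination fractions in `[0, 0.5]`.
#' @return `P(A)` at the position.
#' @export
dh_prob <- function(left, right, r_left, r_right) {
  if (any(c(r_left, r_right) < 0 | c(r_left, r_right) > 0.5, na.rm = TRUE)) {
    stop_param("recombination fractions must lie in [0, 0.5]")
  }
  l_miss <- is.na(left)
  r_miss <- is.na(right)
  if (l_miss && r_miss) return(0.5)
  if (r_miss) return(if (left == "A") 1 - r_left else r_left)
  if (l_miss) return(if (right == "A") 1 - r_right else r_right)
  pl <- if (left == "A") 1 - r_left else r_left    # P(no switch to here | left)
  pr <- if (right == "A") 1 - r_right else r_right
  ql <- 1 - pl
  qr <- 1 - pr
  pl * pr / (pl * pr + ql * qr)
}

# Vectorised core used by expected_counts: g_left/g_right are 0/2 codes (may be
# NA handled upstream), d_* distances in cM. Returns P(A).
.dh_prob_codes <- function(a_left, a_right, r_l, r_r) {
  # a_* in {1 (A), 0 (B)}; probability allele at position is A
  pl <- ifelse(a_left == 1, 1 - r_l, r_l)
  pr <- ifelse(a_right == 1, 1 - r_r, r_r)
  pl * pr / (pl * pr + (1 - pl) * (1 - pr))
}

#' Expected allele counts on a scan grid
#'
#' For every line and every grid position, the expected number (0 to 2) of
#' parent-A alleles given the nearest non-missing flanking markers on the same
#' linkage group. At a genotyped, non-missing marker the expected count equals
#' the observed 0/2 code. Lines with no genotyped marker on a group get the
#' uninformative value 1 there.
#'
#' @param pop a [dh_population].
#' @param grid data frame with columns `group`, `pos` (see [scan_grid]), or a
#'   [genmap] to use marker positions.
#' @param quiet suppress the warning about fully missing group/line pairs.
#' @return Numeric matrix, lines x grid positions; column names
#'   `"<group>@<pos>"`, attribute `grid` carries the grid.
#' @export
expected_counts <- function(pop, grid = NULL, quiet = FALSE) {
  stopifnot(inherits(pop, "dh_population"))
  if (is.null(grid)) grid <- pop$map[, c("group", "pos")]
  if (inherits(grid, "genmap")) grid <- grid[, c("group", "pos")]
  map <- pop$map
  geno <- pop$geno
  n <- nrow(geno)
  out <- matrix(NA_real_, n, nrow(grid),
                dimnames = list(rownames(geno),
                                paste0(grid$group, "@", grid$pos)))
  n_uninformative <- 0L
  for (g in unique(grid$group)) {
    gsel <- which(grid$group == g)
    gpos <- grid$pos[gsel]
    msel <- which(map$group == g)
    if (!length(msel)) stop_param("grid group ", g, " not on the map")
    mpos <- map$pos[msel]
    G <- geno[, msel, drop = FALSE]          # n x k codes 0/2/NA
    A <- G / 2                               # 1 = parent A allele
    res <- matrix(0.5, n, length(gsel))
    for (i in seq_len(n)) {
      obs <- which(!is.na(A[i, ]))
      if (!length(obs)) {
        n_uninformative <- n_uninformative + 1L
        next
      }
      opos <- mpos[obs]
      oall <- A[i, obs]
      # index of nearest informative marker at or left of each grid position
      li <- findInterval(gpos, opos)
      ri <- length(opos) - findInterval(-gpos, rev(-opos)) + 1L
      has_l <- li >= 1L
      has_r <- ri <= length(opos)
      p <- rep(0.5, length(gpos))
      both <- has_l & has_r
      if (any(both)) {
        rl <- haldane_r(gpos[both] - opos[li[both]])
        rr <- haldane_r(opos[ri[both]] - gpos[both])
        p[both] <- .dh_prob_codes(oall[li[both]], oall[ri[both]], rl, rr)
      }
      only_l <- has_l & !has_r
      if (any(only_l)) {
        rl <- haldane_r(gpos[only_l] - opos[li[only_l]])
        p[only_l] <- ifelse(oall[li[only_l]] == 1, 1 - rl, rl)
      }
      only_r <- has_r & !has_l
      if (any(only_r)) {
        rr <- haldane_r(opos[ri[only_r]] - gpos[only_r])
        p[only_r] <- ifelse(oall[ri[only_r]] == 1, 1 - rr, rr)
      }
      res[i, ] <- p
    }
    out[, gsel] <- 2 * res
  }
  if (n_uninformative > 0L && !quiet) {
    msg_log(n_uninformative,
            " line/group combinations had no genotyped marker; expected ",
            "count set to the uninformative value 1")
  }
  attr(out, "grid") <- grid
  out
}
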