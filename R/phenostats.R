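#' Variance components of a balanced multi-environment trial
#'
#' Two-way (line x environment) analysis of variance with `r` replicates,
#' solved by the expected-mean-squares method for a balanced design (under
#' balance this coincides with REML for the full random model):
#' `s2e = MS_error`, `s2GE = (MS_GxE - MS_error) / r`,
#' `s2G = (MS_G - MS_GxE) / (r * E)`, with negative solutions truncated at 0.
#' With a single replicate the error and interaction variances are confounded;
#' the pooled term is reported as `s2GE` and `s2e` as 0 with a warning.
#'
#' @param values long data frame with columns `line`, `env`, `rep`, `value`
#'   (a `pheno_set$values` table), or a `pheno_set`.
#' @return A `variance_components` object: list with `sigma2_G`, `sigma2_GE`,
#'   `sigma2_e`, `n_env`, `reps`, `n_lines` and the underlying mean squares.
#' @export
variance_components <- function(values) {
  if (inherits(values, "pheno_set")) values <- values$values
  stopifnot(all(c("line", "env", "value") %in% names(values)))
  if (is.null(values$rep)) values$rep <- 1L
  lines <- unique(values$line)
  envs <- unique(values$env)
  L <- length(lines); E <- length(envs)
  if (L < 2 || E < 2) stop_param("need >= 2 lines and >= 2 environments")
  tab <- table(values$line, values$env)
  r <- tab[1L]
  if (any(tab != r) || anyNA(values$value)) {
    stop_param("unbalanced or incomplete table: the balanced-design solver ",
               "requires every line in every environment with equal ",
               "replication (simulate balanced data or complete the table)")
  }
  r <- as.integer(r)
  y <- values$value
  lf <- factor(values$line, levels = lines)
  ef <- factor(values$env, levels = envs)
  li <- as.integer(lf)
  ei <- as.integer(ef)
  m <- mean(y)
  m_l <- as.vector(tapply(y, lf, mean))
  m_e <- as.vector(tapply(y, ef, mean))
  m_c <- tapply(y, list(lf, ef), mean)
  ss_l <- E * r * sum((m_l - m)^2)
  ss_e <- L * r * sum((m_e - m)^2)
  ss_c <- r * sum((sweep(sweep(m_c, 1, m_l), 2, m_e) + m)^2)
  ms_g <- ss_l / (L - 1)
  ms_ge <- ss_c / ((L - 1) * (E - 1))
  if (r > 1L) {
    ss_err <- sum((y - m_c[cbind(li, ei)])^2)
    ms_err <- ss_err / (L * E * (r - 1))
    s2e <- ms_err
    s2ge <- max((ms_ge - ms_err) / r, 0)
  } else {
    msg_log("single replicate: residual and GxE variance are confounded; ",
            "reporting the pooled term as sigma2_GE and sigma2_e = 0")
    ms_err <- NA_real_
    s2e <- 0
    s2ge <- ms_ge
  }
  s2g <- max((ms_g - ms_ge) / (r * E), 0)
  structure(list(sigma2_G = s2g, sigma2_GE = s2ge, sigma2_e = s2e,
                 n_env = E, reps = r, n_lines = L,
                 mean_squares = c(MS_G = ms_g, MS_GE = ms_ge, MS_err = ms_err)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%d lines, %d env x %d rep):\n",
              x$n_lines, x$n_env, x$reps))
  cat(sprintf("  sigma2_G  = %.4f\n  sigma2_GE = %.4f\n  sigma2_e  = %.4f\n",
              x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  if (x$sigma2_GE > 0) {
    cat(sprintf("  sigma2_G : sigma2_GE = %.1f : 1\n", x$sigma2_G / x$sigma2_GE))
  }
  invisible(x)
}

#' Entry-mean heritability
#'
#' `h2 = s2G / (s2G + s2GE/E + s2e/(E*r))`: the genotypic share of the
#' variance of a line's mean over the whole trial design.
#'
#' @param vc a [variance_components] object, or a list with the same fields.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  denom <- vc$sigma2_G + vc$sigma2_GE / vc$n_env +
    vc$sigma2_e / (vc$n_env * vc$reps)
  if (denom <= 0) stop_param("all variance components are zero; h2 undefined")
  vc$sigma2_G / denom
}

#' Entry means (BLUEs) across environments
#'
#' Under a balanced design with fixed genotype effects the best linear
#' unbiased estimate of a line's value is its arithmetic mean over all plots.
#' Missing cells are averaged over the available cells (count reported); lines
#' with no data are dropped with a warning.
#'
#' @param values long phenotype table or `pheno_set` (see
#'   [variance_components]).
#' @return Named numeric vector of per-line means.
#' @export
compute_blues <- function(values) {
  if (inherits(values, "pheno_set")) values <- values$values
  stopifnot(all(c("line", "value") %in% names(values)))
  ok <- !is.na(values$value)
  n_miss <- sum(!ok)
  if (n_miss > 0) {
    msg_log(n_miss, " missing cells averaged over available cells")
  }
  lines <- unique(values$line)
  em <- c(tapply(values$value[ok], factor(values$line[ok], levels = lines),
             mean))
  dropped <- names(em)[is.na(em)]
  if (length(dropped)) {
    warning("lines with no phenotype data excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    em <- em[!is.na(em)]
  }
  em
}

#' Correlations between developmental stages
#'
#' Pearson correlations of entry means between stages, with two-sided
#' P values.
#'
#' @param blues named list of entry-mean vectors, one per stage, over the same
#'   lines.
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `P` (P-value matrix, `NA` diagonal).
#' @export
stage_correlations <- function(blues) {
  stopifnot(is.list(blues), length(blues) >= 2)
  lines <- names(blues[[1L]])
  mat <- vapply(blues, function(b) unname(b[lines]), numeric(length(lines)))
  r <- stats::cor(mat)
  P <- matrix(NA_real_, ncol(mat), ncol(mat), dimnames = dimnames(r))
  for (i in seq_len(ncol(mat) - 1L)) {
    for (j in (i + 1L):ncol(mat)) {
      P[i, j] <- P[j, i] <- stats::cor.test(mat[, i], mat[, j])$p.value
    }
  }
  list(r = r, P = P)
}

#' Orthogonal contrast of a family mean against its midparent
#'
#' Tests whether the family mean deviates from the mean of its two parents --
#' a significant deviation indicates non-additive (epistatic) inheritance.
#' Parent values are treated as known constants (in the field trial they are
#' replicated checks with comparatively negligible error).
#'
#' @param family_blues entry means of the family's DH lines (`>= 3`).
#' @param parent_a_blue,parent_b_blue parent entry means.
#' @return List with `contrast` (`mean(family) - midparent`), `t`, `df`, `P`
#'   (two-sided; `NA` with a flag if the family variance is zero).
#' @export
parent_family_contrast <- function(family_blues, parent_a_blue, parent_b_blue) {
  n <- length(family_blues)
  if (n < 3) stop_param("need at least 3 lines in the family")
  contrast <- mean(family_blues) - (parent_a_blue + parent_b_blue) / 2
  s <- stats::sd(family_blues)
  if (s == 0) {
    warning("zero within-family variance; P undefined", call. = FALSE)
    return(list(contrast = contrast, t = NA_real_, df = n - 1L, P = NA_real_,
                degenerate = TRUE))
  }
  t <- contrast / (s / sqrt(n))
  P <- 2 * stats::pt(abs(t), df = n - 1L, lower.tail = FALSE)
  list(contrast = contrast, t = t, df = n - 1L, P = P, degenerate = FALSE)
}
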