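make_long <- function(vals, lines, envs, reps) {
  d <- expand.grid(rep = seq_len(reps), env = envs, line = lines,
                   stringsAsFactors = FALSE)[, c("line", "env", "rep")]
  d$value <- vals
  d
}

test_that("variance components match the closed-form EMS solution on a hand-built table", {
  # 3 lines x 2 env x 2 reps; cell means chosen so that all mean squares are
  # simple: line effects (-1, 0, 1), env effects (-2, 2), interaction
  # (+0.5 pattern), residuals (+/- 0.25) -- worked through by hand below.
  lines <- c("A", "B", "C"); envs <- c("E1", "E2")
  cell <- matrix(c(-3.5, 1.5,   # A in E1, E2  (line -1, env -2/ +2, int -0.5/+0.5)
                   -2.0, 2.0,   # B
                   -0.5, 2.5),  # C (int +0.5/-0.5)
                 nrow = 3, byrow = TRUE)
  d <- expand.grid(rep = 1:2, env = envs, line = lines,
                   stringsAsFactors = FALSE)[, c("line", "env", "rep")]
  d$value <- cell[cbind(match(d$line, lines), match(d$env, envs))] +
    ifelse(d$rep == 1, 0.25, -0.25)
  vc <- variance_components(d)
  # independent oracle: aov mean squares + EMS arithmetic
  fit <- summary(stats::aov(value ~ factor(line) * factor(env), data = d))[[1]]
  ms <- fit[["Mean Sq"]]
  expect_equal(vc$sigma2_e, ms[4], tolerance = 1e-12)
  expect_equal(vc$sigma2_GE, max((ms[3] - ms[4]) / 2, 0), tolerance = 1e-12)
  expect_equal(vc$sigma2_G, max((ms[1] - ms[3]) / (2 * 2), 0),
               tolerance = 1e-12)
})

test_that("no line-to-line differences gives zero genotypic variance", {
  d <- make_long(rep(c(1, 1, 5, 5), each = 3), lines = c("A", "B", "C"),
                 envs = c("E1", "E2"), reps = 2)
  # value depends only on env/rep, identical across lines
  d$value <- ifelse(d$env == "E1", 1, 5) + ifelse(d$rep == 1, 0.1, -0.1)
  vc <- variance_components(d)
  expect_equal(vc$sigma2_G, 0)
})

test_that("single-replicate designs confound error and interaction", {
  d <- make_long(rnorm(6), lines = c("A", "B", "C"), envs = c("E1", "E2"),
                 reps = 1)
  expect_message(vc <- variance_components(d), "confounded")
  expect_equal(vc$sigma2_e, 0)
})

test_that("unbalanced tables are rejected with guidance", {
  d <- make_long(rnorm(12), c("A", "B", "C"), c("E1", "E2"), 2)
  expect_error(variance_components(d[-1, ]), "balanced")
})

test_that("heritability follows the entry-mean formula", {
  vc <- list(sigma2_G = 4, sigma2_GE = 4, sigma2_e = 8, n_env = 4, reps = 2)
  expect_equal(heritability(vc), 2 / 3)
  vc0 <- list(sigma2_G = 3, sigma2_GE = 0, sigma2_e = 0, n_env = 4, reps = 2)
  expect_equal(heritability(vc0), 1)
  expect_error(heritability(list(sigma2_G = 0, sigma2_GE = 0, sigma2_e = 0,
                                 n_env = 2, reps = 1)), "undefined")
  # monotone in E and r
  h <- function(E, r) heritability(list(sigma2_G = 4, sigma2_GE = 4,
                                        sigma2_e = 8, n_env = E, reps = r))
  expect_true(h(4, 2) > h(2, 2))
  expect_true(h(4, 3) > h(4, 2))
})

test_that("entry means are plain means, order-invariant, missing-tolerant", {
  d <- make_long(0, "L1", paste0("E", 1:4), 1)
  d$value <- c(1, 2, 3, 6)
  expect_equal(unname(compute_blues(d)), 3)
  # permuting environment rows changes nothing
  expect_equal(compute_blues(d[base::sample(nrow(d)), ]), compute_blues(d))
  # missing cells averaged over the rest; empty lines dropped with a warning
  d2 <- rbind(d, data.frame(line = "L2", env = paste0("E", 1:4), rep = 1,
                            value = c(NA, 4, 6, NA)))
  suppressMessages(expect_equal(unname(compute_blues(d2)["L2"]), 5))
  d3 <- rbind(d, data.frame(line = "L3", env = paste0("E", 1:4), rep = 1,
                            value = NA_real_))
  suppressMessages(expect_warning(b <- compute_blues(d3), "excluded"))
  expect_false("L3" %in% names(b))
})

test_that("stage correlations are symmetric, unit-diagonal, PSD", {
  set.seed(4)
  b1 <- stats::setNames(rnorm(100), paste0("L", 1:100))
  sc <- stage_correlations(list(s1 = b1, s2 = b1, s3 = -2 * b1 + 5))
  expect_equal(unname(diag(sc$r)), rep(1, 3))
  expect_equal(sc$r[1, 2], 1)
  expect_equal(sc$r[1, 3], -1)
  expect_equal(sc$r, t(sc$r))
  expect_true(all(eigen(sc$r, symmetric = TRUE)$values > -1e-8))
})

test_that("stages sharing half their genetic variance correlate near 0.5", {
  # two stages: shared QTL set contributes half the variance of each
  fams <- c("FAM1", "FAM2")
  arch <- qtl_architecture(
    additive = data.frame(group = rep(paste0("LG0", 1:3), each = 2),
                          pos = rep(c(10, 50), 3)),
    add_effects = matrix(0.5, 6, 2), families = fams,
    stages = c("s1", "s2"),
    # QTL 1-2 act in both stages, 3-4 only in s1, 5-6 only in s2, so the
    # shared QTL carry half of each stage's genetic variance
    add_profiles = rbind(c(1, 1), c(1, 1), c(1, 0), c(1, 0),
                         c(0, 1), c(0, 1)))
  map <- make_map(3, 60, 5)
  fam <- family_spec(fams, c(320, 327))
  pop <- simulate_dh_population(map, fam, arch, seed = 61)
  g1 <- genetic_values(pop, arch, "s1")
  g2 <- genetic_values(pop, arch, "s2")
  expect_lt(abs(stats::cor(g1, g2) - 0.5), 0.1)
})

test_that("parent-family contrast arithmetic and null distribution", {
  expect_equal(parent_family_contrast(c(4, 5, 6), 4, 6)$contrast, 0)
  expect_equal(parent_family_contrast(c(4, 5, 6), 4, 6)$P, 1)
  expect_equal(parent_family_contrast(c(4, 6, 5), 2, 4)$contrast, 2)
  expect_warning(parent_family_contrast(c(3, 3, 3), 1, 2), "zero")
  # under the null (family mean = midparent), P is uniform
  set.seed(8)
  ps <- replicate(200, parent_family_contrast(rnorm(30, mean = 5), 5, 5)$P)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
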