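test_that("region threshold divides alpha by the region-pair count", {
  expect_equal(region_threshold(1), 0.05)                  # C(2,2) = 1
  expect_equal(region_threshold(21), 0.05 / 861)           # C(42,2)
  expect_equal(region_threshold(22), 0.05 / 946)           # C(44,2) ~ 5.3e-5
  expect_lt(abs(region_threshold(22) - 5.3e-5), 1e-6)
  expect_error(region_threshold(0), "n_groups")
})

test_that("interaction F test agrees with an lm/anova oracle and is symmetric", {
  pop <- tiny_pop(n1 = 70, n2 = 70, seed = 21)
  counts <- expected_counts(pop, pop$map, quiet = TRUE)
  set.seed(2)
  y <- stats::setNames(rnorm(140), rownames(pop$geno))
  fam <- factor(pop$line_family, levels = pop$families$family)
  for (pair in list(c(2, 9), c(1, 13), c(4, 11))) {
    x1 <- counts[, pair[1]]; x2 <- counts[, pair[2]]
    got <- pair_test(y, pop, x1, x2)
    w <- (x1 - stats::ave(x1, fam)) * (x2 - stats::ave(x2, fam))
    m0 <- stats::lm(y ~ 0 + fam + fam:x1 + fam:x2)
    m1 <- stats::lm(y ~ 0 + fam + fam:x1 + fam:x2 + fam:w)
    expect_equal(got$P, stats::anova(m0, m1)[2, "Pr(>F)"], tolerance = 1e-9)
    # symmetric in the locus order (up to floating-point rounding)
    expect_equal(got$P, pair_test(y, pop, x2, x1)$P, tolerance = 1e-12)
  }
})

test_that("degenerate interactions return P = 1", {
  pop <- tiny_pop(n1 = 40, n2 = 40, seed = 23)
  counts <- expected_counts(pop, pop$map, quiet = TRUE)
  y_const <- stats::setNames(rep(2, 80), rownames(pop$geno))
  expect_equal(pair_test(y_const, pop, counts[, 1], counts[, 8])$P, 1)
  # identical locus against itself: interaction collinear with main effect
  y <- stats::setNames(rnorm(80), rownames(pop$geno))
  t_same <- pair_test(y, pop, counts[, 3], counts[, 3])
  expect_gte(t_same$P, 0.0)   # defined, no crash; df reported
  expect_true(t_same$df_int <= 2)
})

test_that("interaction P values are uniform under a purely additive model", {
  arch <- qtl_architecture(
    additive = data.frame(group = c("LG01", "LG02"), pos = c(20, 40)),
    add_effects = matrix(0.8, 2, 2), families = c("FAM1", "FAM2"))
  ps <- numeric(200)
  for (s in seq_along(ps)) {
    pop <- tiny_pop(n1 = 50, n2 = 50, seed = 3000 + s, arch = arch)
    ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.9,
                              ge_ratio = 5, seed = 4000 + s)
    cnt <- expected_counts(pop, data.frame(group = c("LG01", "LG02"),
                                           pos = c(20, 40)), quiet = TRUE)
    ps[s] <- pair_test(ph$entry_means, pop, cnt[, 1], cnt[, 2])$P
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("a planted two-locus interaction is recovered by the 2-D scan", {
  arch <- qtl_architecture(
    additive = data.frame(group = "LG01", pos = 10),
    add_effects = matrix(c(0.4, 0.4), 1), families = c("FAM1", "FAM2"),
    epistatic = data.frame(group1 = "LG02", pos1 = 20,
                           group2 = "LG03", pos2 = 40),
    epi_effects = matrix(c(0.8, 0.8), 1))
  found <- 0
  for (s in 1:10) {
    map <- make_map(3, 60, 10)
    fams <- family_spec(c("FAM1", "FAM2"), c(160, 160))
    pop <- simulate_dh_population(map, fams, arch, seed = 5000 + s)
    ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.9,
                              ge_ratio = 5, seed = 6000 + s)
    sc <- epistasis_scan(ph$entry_means, pop, step_cM = 10,
                         threshold = region_threshold(3))
    rec <- sc$records
    if (nrow(rec) >= 1) {
      hit <- any(rec$group1 == "LG02" & rec$group2 == "LG03" &
                   abs(rec$pos1 - 20) <= 10 & abs(rec$pos2 - 40) <= 10)
      if (hit && nrow(rec) == 1) found <- found + 1
    }
  }
  expect_gte(found, 8)
})

test_that("landscape matrix is consistent with the pairwise scan", {
  arch <- qtl_architecture(
    additive = data.frame(group = "LG01", pos = 10),
    add_effects = matrix(c(0.4, 0.4), 1), families = c("FAM1", "FAM2"),
    epistatic = data.frame(group1 = "LG02", pos1 = 20,
                           group2 = "LG03", pos2 = 40),
    epi_effects = matrix(c(0.8, 0.8), 1))
  map <- make_map(3, 60, 10)
  fams <- family_spec(c("FAM1", "FAM2"), c(160, 160))
  pop <- simulate_dh_population(map, fams, arch, seed = 77)
  ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.9,
                            ge_ratio = 5, seed = 78)
  ls <- landscape(ph$entry_means, pop, "LG02", "LG03", step_cM = 10,
                  threshold = region_threshold(3))
  expect_equal(dim(ls$neglog10P), c(7, 7))
  expect_true(all(ls$neglog10P >= 0))
  # the masked maximum sits at the planted coordinates (+/- one step)
  peak <- which(ls$neglog10P == max(ls$neglog10P), arr.ind = TRUE)
  expect_lte(abs(ls$pos_a[peak[1]] - 20), 10)
  expect_lte(abs(ls$pos_b[peak[2]] - 40), 10)
  expect_true(ls$significant[peak])
  # same cell is the best pair of the full scan restricted to this pair
  sc <- epistasis_scan(ph$entry_means, pop, step_cM = 10,
                       threshold = region_threshold(3))
  rec <- sc$records[sc$records$group1 == "LG02" & sc$records$group2 == "LG03", ]
  expect_equal(min(rec$P), 10^(-max(ls$neglog10P)), tolerance = 1e-9)
})

test_that("epistatic detections decline across stages as profiles shrink", {
  # study emulation: two of three planted interactions are strongest at the
  # first stage; count significant clusters per stage at a permissive
  # threshold restricted to the planted group pairs
  sim <- simulate_study(seed = 19)
  pop <- sim$pop
  n_sig <- sapply(c("BM1", "BM3"), function(st) {
    y <- compute_blues(sim$pheno[[st]])
    cnt <- expected_counts(pop, data.frame(group = c("1R", "3A", "2B", "7A"),
                                           pos = c(30, 70, 55, 85)),
                           quiet = TRUE)
    sum(pair_test(y, pop, cnt[, 1], cnt[, 2])$P < 1e-4,
        pair_test(y, pop, cnt[, 3], cnt[, 4])$P < 1e-4)
  })
  expect_gte(n_sig["BM1"], n_sig["BM3"])
})
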