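test_that("position test matches the normal-equations oracle on random data", {
  set.seed(31)
  for (rep in 1:5) {
    pop <- tiny_pop(n1 = 25, n2 = 30, seed = 300 + rep)
    y <- stats::setNames(rnorm(55), rownames(pop$geno))
    xq <- expected_counts(pop, data.frame(group = "LG01", pos = 17),
                          quiet = TRUE)[, 1]
    got <- position_test(y, pop, xq)
    want <- oracle_lod(y, pop$line_family, xq)
    expect_equal(got$lod, want$lod, tolerance = 1e-8)
    expect_equal(got$lr, want$lr, tolerance = 1e-8)
  }
})

test_that("LOD follows (N/2) log10(RSS0/RSS1) and is affine-invariant", {
  pop <- tiny_pop(n1 = 40, n2 = 40, seed = 44)
  set.seed(9)
  y <- stats::setNames(rnorm(80), rownames(pop$geno))
  xq <- pop$geno[, 5]
  t1 <- position_test(y, pop, xq)
  expect_equal(t1$lod, (80 / 2) * log10(t1$rss0 / t1$rss1), tolerance = 1e-12)
  # location/scale changes of Y leave the RSS ratio untouched
  t2 <- position_test(7 - 3 * y, pop, xq)
  expect_equal(t1$lod, t2$lod, tolerance = 1e-9)
})

test_that("a locus orthogonal to the phenotype gives LOD 0", {
  pop <- tiny_pop(n1 = 30, n2 = 30, seed = 51)
  # phenotype constant within family: nothing left for the locus to explain
  y <- stats::setNames(rep(c(1, 5), each = 30), rownames(pop$geno))
  t <- position_test(y, pop, pop$geno[, 3])
  expect_equal(t$lod, 0, tolerance = 1e-9)
})

test_that("non-segregating family blocks are dropped with reduced df", {
  map <- genmap(c("g1", "g1"), c("m1", "m2"), c(0, 40))
  geno <- rbind(c(2, 2), c(2, 0), c(0, 2), c(0, 0),
                c(2, 2), c(2, 2), c(2, 2), c(2, 2))
  lf <- stats::setNames(rep(c("F1", "F2"), each = 4),
                        sprintf("L%02d", 1:8))
  pop <- manual_pop(map, geno, lf)
  y <- stats::setNames(c(1.2, 0.4, -0.3, -1.1, 0.5, 0.2, -0.2, -0.5), names(lf))
  t <- position_test(y, pop, pop$geno[, 1])
  expect_equal(t$df, 1L)                       # family 2 monomorphic
  expect_true(is.na(t$effects["F2"]))
  expect_false(is.na(t$effects["F1"]))
})

test_that("genome scan equals per-position tests under the exclusion rule", {
  arch <- qtl_architecture(
    additive = data.frame(group = "LG01", pos = 25),
    add_effects = matrix(c(0.8, 0.8), 1), families = c("FAM1", "FAM2"))
  pop <- tiny_pop(n1 = 60, n2 = 60, seed = 71, arch = arch)
  ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.8,
                            ge_ratio = 5, seed = 3)
  y <- ph$entry_means
  cof <- select_cofactors(y, pop, max_cofactors = 3)
  grid <- scan_grid(pop$map, 5)
  scan <- genome_scan(y, pop, grid, cof)
  cof_counts <- expected_counts(pop, cof[, c("group", "pos")], quiet = TRUE)
  for (j in base::sample(nrow(grid), 8)) {
    keep <- !(cof$group == grid$group[j] & abs(cof$pos - grid$pos[j]) < 10)
    pt <- position_test(y, pop,
                        expected_counts(pop, grid[j, , drop = FALSE],
                                        quiet = TRUE)[, 1],
                        cof_counts[, keep, drop = FALSE])
    expect_equal(scan$lod[j], pt$lod, tolerance = 1e-9)
  }
  # empty cofactor set reduces to plain interval mapping
  scan_im <- genome_scan(y, pop, grid)
  pt_im <- position_test(y, pop,
                         expected_counts(pop, grid[4, , drop = FALSE],
                                         quiet = TRUE)[, 1])
  expect_equal(scan_im$lod[4], pt_im$lod, tolerance = 1e-9)
})

test_that("cofactor selection is deterministic, bounded, and finds a planted QTL", {
  expect_equal(nrow(select_cofactors(
    stats::setNames(rnorm(120), rownames(tiny_pop(seed = 1)$geno)),
    tiny_pop(seed = 1), max_cofactors = 0)), 0)
  arch <- qtl_architecture(
    additive = data.frame(group = "LG02", pos = 30),
    add_effects = matrix(c(1, 1), 1), families = c("FAM1", "FAM2"))
  hits <- 0
  for (s in 1:20) {
    pop <- tiny_pop(n1 = 100, n2 = 100, seed = 500 + s, arch = arch)
    ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.9,
                              ge_ratio = 5, seed = 600 + s)
    cof <- select_cofactors(ph$entry_means, pop, max_cofactors = 5)
    expect_lte(nrow(cof), 5)
    if (nrow(cof) > 0 && cof$group[1] == "LG02" &&
        abs(cof$pos[1] - 30) <= 10) {
      hits <- hits + 1
    }
    # determinism
    cof2 <- select_cofactors(ph$entry_means, pop, max_cofactors = 5)
    expect_identical(cof, cof2)
  }
  expect_gte(hits, 18)   # nearest marker (+/- one interval) first in >= 90%
})

test_that("cofactor selection stays sparse on pure noise", {
  n_sel <- integer(20)
  for (s in 1:20) {
    pop <- tiny_pop(n1 = 100, n2 = 100, seed = 700 + s)
    y <- stats::setNames(rnorm(200), rownames(pop$geno))
    n_sel[s] <- nrow(select_cofactors(y, pop, max_cofactors = 5))
  }
  expect_gte(mean(n_sel <= 2), 0.9)
})

test_that("QTL declaration handles thresholds, merging, and support intervals", {
  # synthetic LOD profile: nothing above threshold -> empty
  prof <- data.frame(group = "g1", pos = seq(0, 100, 5),
                     lod = rep(1, 21), df = 2)
  prof$eff_F1 <- 0.1
  expect_equal(nrow(declare_qtl(prof, 3)), 0)
  # one smooth peak
  prof$lod <- 5 * exp(-((prof$pos - 50) / 20)^2)
  q <- declare_qtl(prof, 3)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_pos, 50)
  expect_true(q$support_lo < 50 && q$support_hi > 50)
  expect_true(all(prof$lod[prof$pos >= q$support_lo &
                             prof$pos <= q$support_hi] >= q$lod - 1))
  # two peaks separated by a deep valley and > 20 cM -> two QTL
  prof$lod <- 6 * exp(-((prof$pos - 20) / 10)^2) +
    7 * exp(-((prof$pos - 80) / 10)^2)
  expect_equal(nrow(declare_qtl(prof, 3)), 2)
  # close twin peaks merge into the single highest position
  prof$lod <- 6 * exp(-((prof$pos - 45) / 10)^2) +
    6.5 * exp(-((prof$pos - 60) / 10)^2)
  q <- declare_qtl(prof, 3)
  expect_equal(nrow(q), 1)
  expect_equal(q$peak_pos, prof$pos[which.max(prof$lod)])
})

test_that("two well-separated planted QTL are both recovered", {
  arch <- qtl_architecture(
    additive = data.frame(group = c("LG01", "LG01"), pos = c(20, 80)),
    add_effects = matrix(1.1, 2, 2), families = c("FAM1", "FAM2"))
  both <- 0
  for (s in 1:10) {
    pop <- tiny_pop(n1 = 150, n2 = 150, n_groups = 2, length_cM = 100,
                    seed = 800 + s, arch = arch)
    ph <- simulate_phenotypes(pop, arch, "trait", h2_target = 0.9,
                              ge_ratio = 5, seed = 900 + s)
    cof <- select_cofactors(ph$entry_means, pop, max_cofactors = 5)
    scan <- genome_scan(ph$entry_means, pop, scan_grid(pop$map, 5), cof)
    q <- declare_qtl(scan, 4)
    q1 <- q[q$group == "LG01", ]
    if (nrow(q1) == 2 && min(abs(q1$peak_pos - 20)) <= 10 &&
        min(abs(q1$peak_pos - 80)) <= 10) {
      both <- both + 1
    }
  }
  expect_gte(both, 8)
})

test_that("permutation thresholds are quantiles with the expected behaviour", {
  pop <- tiny_pop(n1 = 80, n2 = 80, seed = 99)
  y <- stats::setNames(rnorm(160), rownames(pop$geno))
  grid <- scan_grid(pop$map, 10)
  thr <- permutation_threshold(y, pop, grid, n_perm = 100, alpha = 0.10,
                               seed = 5, max_cofactors = 2)
  # alpha = 1 is the minimum of the max-LOD distribution
  expect_equal(unname(stats::quantile(thr$max_lods, 0, type = 7)),
               min(thr$max_lods))
  # monotone in alpha on the same permutation set
  t05 <- stats::quantile(thr$max_lods, 0.95, type = 7)
  t10 <- stats::quantile(thr$max_lods, 0.90, type = 7)
  expect_gte(t05, t10)
  expect_error(permutation_threshold(y, pop, grid, n_perm = 100, alpha = 0,
                                     seed = 1), "alpha")
  expect_error(permutation_threshold(y, pop, grid, n_perm = 50, alpha = 0.1,
                                     seed = 1), "n_perm")
  # same seed, same threshold
  thr2 <- permutation_threshold(y, pop, grid, n_perm = 100, alpha = 0.10,
                                seed = 5, max_cofactors = 2)
  expect_identical(thr$max_lods, thr2$max_lods)
})

test_that("explained genotypic variance behaves at its edges", {
  arch <- qtl_architecture(
    additive = data.frame(group = "LG01", pos = 30),
    add_effects = matrix(c(1, 0.8), 1), families = c("FAM1", "FAM2"))
  pop <- tiny_pop(n1 = 80, n2 = 80, seed = 111, arch = arch)
  g <- genetic_values(pop, arch, "trait")
  qtl <- data.frame(group = "LG01", peak_pos = 30)
  # noiseless phenotype, h2 = 1: the single QTL explains ~everything
  pg <- proportion_genotypic_variance(qtl, g, pop, h2 = 1)
  expect_gt(pg$pG_combined, 97)
  # adding a zero-effect QTL changes almost nothing
  qtl2 <- rbind(qtl, data.frame(group = "LG02", peak_pos = 45))
  pg2 <- proportion_genotypic_variance(qtl2, g, pop, h2 = 1)
  expect_lt(abs(pg2$pG_combined - pg$pG_combined), 1)
  expect_lt(pg2$pG_single[2], 1)
  # singles sum to at most combined, up to adjusted-R2 numerical slack
  expect_lte(sum(pg2$pG_single), pg2$pG_combined + 2)
  expect_error(proportion_genotypic_variance(qtl, g, pop, h2 = 0), "h2")
  expect_error(proportion_genotypic_variance(qtl[0, ], g, pop, h2 = 1),
               "empty")
})

test_that("overlap classification builds transitive stage clusters", {
  qa <- data.frame(group = c("1A", "2B"), peak_pos = c(10, 50), lod = 5)
  qb <- data.frame(group = c("1A", "3R"), peak_pos = c(20, 70), lod = 5)
  qc <- data.frame(group = "1A", peak_pos = 30, lod = 5)
  ov <- classify_overlap(list(s1 = qa, s2 = qb, s3 = qc))
  # 10-20-30 chain is one all-stage cluster (boundary inclusive, transitive)
  expect_equal(unname(ov$counts["s1+s2+s3"]), 1L)
  expect_equal(unname(ov$counts["s1"]), 1L)
  expect_equal(unname(ov$counts["s2"]), 1L)
  # identical lists are fully shared
  ov2 <- classify_overlap(list(s1 = qa, s2 = qa))
  expect_equal(unname(ov2$counts["s1+s2"]), 2L)
  expect_false("s1" %in% names(ov2$counts))
  # disjoint groups are fully stage-specific
  ov3 <- classify_overlap(list(s1 = qa, s2 = data.frame(group = "7R",
                                                        peak_pos = 10,
                                                        lod = 5)))
  expect_equal(unname(ov3$counts["s1"]), 2L)
  expect_equal(unname(ov3$counts["s2"]), 1L)
})
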