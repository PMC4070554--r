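#' Default study design: four DH families of a triticale biomass trial
#'
#' Four doubled-haploid families of 131, 120, 200 and 196 lines (647 in
#' total), evaluated for one trait at three developmental stages (`BM1`,
#' `BM2`, `BM3`) in four environments (two locations x two years).
#'
#' @return A [family_spec] with families DH06, DH07, EAW74, EAW78.
#' @export
study_families <- function() {
  family_spec(c("DH06", "DH07", "EAW74", "EAW78"),
              c(131L, 120L, 200L, 196L))
}

#' Default 21-group triticale-like map
#'
#' 21 linkage groups (the A, B and R genomes, `1A..7A`, `1B..7B`, `1R..7R`),
#' each 120 cM with markers every 5 cM. Density is configurable because real
#' consensus maps vary; this grid keeps desk-scale scans fast while leaving no
#' interval wider than a typical marker spacing.
#'
#' @param group_length_cM,marker_spacing_cM map geometry.
#' @return A [genmap].
#' @export
study_map <- function(group_length_cM = 120, marker_spacing_cM = 5) {
  groups <- paste0(rep(1:7, 3), rep(c("A", "B", "R"), each = 7))
  make_map(21, group_length_cM, marker_spacing_cM, group_names = groups)
}

#' Default planted QTL architecture of the study emulation
#'
#' Ten additive QTL with family-specific effects plus two epistatic pairs,
#' with stage profiles producing stage-specific, two-stage and all-stage QTL.
#' The major locus on 5R has a large effect confined mostly to family EAW78
#' and a weak-strong-moderate stage profile, so that family's trait
#' distribution is unimodal at BM1, clearly bimodal at BM2 and attenuated at
#' BM3 (the behaviour of a dominant dwarfing locus such as Ddw1). The 5A locus
#' contributes at every stage; the 6A locus only from BM2 onwards, and 6A
#' takes part in the strongest epistatic pair (with 5B), peaking at BM2.
#' Two further epistatic pairs are strongest at BM1, so the number of
#' detectable interactions declines with developmental progression.
#'
#' @return A [qtl_architecture] over stages BM1, BM2, BM3 for the
#'   [study_families] population.
#' @export
study_architecture <- function() {
  fams <- study_families()$family
  stages <- c("BM1", "BM2", "BM3")
  additive <- data.frame(
    group = c("5R", "5A", "6A", "1A", "3B", "2R", "4B", "7R", "2A", "6B"),
    pos   = c(60,   40,   75,   25,   50,   80,   35,   55,   90,   60))
  add_effects <- rbind(
    c(0.35, 0.30, 0.35, 1.20),   # 5R: major, strongest in EAW78
    c(0.32, 0.28, 0.30, 0.26),   # 5A: all families, all stages
    c(0.28, 0.00, 0.32, 0.26),   # 6A: BM2/BM3
    c(0.25, 0.22, 0.00, 0.20),   # 1A: BM1/BM2
    c(0.00, 0.26, 0.24, 0.00),   # 3B: BM1-specific
    c(0.22, 0.00, 0.26, 0.22),   # 2R: BM2/BM3
    c(0.20, 0.24, 0.00, 0.18),   # 4B: all stages
    c(0.00, 0.22, 0.20, 0.20),   # 7R: BM3-specific
    c(0.18, 0.20, 0.22, 0.00),   # 2A: BM1-specific
    c(0.20, 0.18, 0.20, 0.18))   # 6B: BM2/BM3
  add_profiles <- rbind(
    c(0.35, 1.00, 0.75),
    c(1.00, 1.00, 1.00),
    c(0.25, 1.00, 1.00),
    c(1.00, 0.90, 0.30),
    c(1.00, 0.30, 0.20),
    c(0.30, 1.00, 1.00),
    c(1.00, 1.00, 1.00),
    c(0.20, 0.30, 1.00),
    c(1.00, 0.20, 0.20),
    c(0.40, 1.00, 0.90))
  epistatic <- data.frame(group1 = c("6A", "1R", "2B"), pos1 = c(40, 30, 55),
                          group2 = c("5B", "3A", "7A"), pos2 = c(60, 70, 85))
  epi_effects <- rbind(c(0.25, 0.25, 0.25, 0.25),
                       c(0.20, 0.20, 0.20, 0.20),
                       c(0.20, 0.20, 0.20, 0.20))
  epi_profiles <- rbind(c(0.60, 1.00, 0.70),
                        c(1.00, 0.40, 0.50),
                        c(1.00, 0.30, 0.30))
  qtl_architecture(additive, add_effects, families = fams, stages = stages,
                   add_profiles = add_profiles,
                   epistatic = epistatic, epi_effects = epi_effects,
                   epi_profiles = epi_profiles)
}

#' Simulate the full study emulation
#'
#' Generates the default population ([study_map], [study_families],
#' [study_architecture]) and phenotypes for all three stages with the study's
#' variance structure: entry-mean heritabilities rising from 0.81 (BM1) to
#' 0.91 (BM2), genotypic-to-GxE variance ratios from ~3:1 (BM1) to ~7:1
#' (BM2), four environments and two replicates.
#'
#' @param seed RNG seed driving population and phenotypes.
#' @param h2 named per-stage heritability targets.
#' @param ge_ratio named per-stage `s2G/s2GE` ratios.
#' @param n_env,reps_per_env trial dimensions.
#' @param map,families,arch override the default design.
#' @return List with `pop`, `arch`, and `pheno` (list of `pheno_set` per
#'   stage).
#' @export
simulate_study <- function(seed = 1,
                           h2 = c(BM1 = 0.81, BM2 = 0.91, BM3 = 0.86),
                           ge_ratio = c(BM1 = 3, BM2 = 7, BM3 = 5),
                           n_env = 4, reps_per_env = 2,
                           map = study_map(), families = study_families(),
                           arch = study_architecture()) {
  pop <- simulate_dh_population(map, families, arch,
                                seed = child_seed(seed, 1))
  pheno <- lapply(seq_along(arch$stages), function(s) {
    st <- arch$stages[s]
    simulate_phenotypes(pop, arch, st,
                        h2_target = unname(h2[st]),
                        ge_ratio = unname(ge_ratio[st]),
                        n_env = n_env, reps_per_env = reps_per_env,
                        seed = child_seed(seed, 100 + s))
  })
  names(pheno) <- arch$stages
  list(pop = pop, arch = arch, pheno = pheno)
}
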