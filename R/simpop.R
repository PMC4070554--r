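#' Family specification table
#'
#' @param family_id character vector of family names.
#' @param n_lines integer vector of family sizes (`>= 1`).
#' @param parent_a,parent_b parent names per family (distinct within family).
#' @return Data frame with one row per family.
#' @export
family_spec <- function(family_id, n_lines, parent_a = NULL, parent_b = NULL) {
  if (is.null(parent_a)) parent_a <- paste0(family_id, "_P1")
  if (is.null(parent_b)) parent_b <- paste0(family_id, "_P2")
  if (any(n_lines < 1)) stop_param("n_lines must be >= 1")
  if (any(parent_a == parent_b)) stop_param("parents of a family must differ")
  if (anyDuplicated(family_id)) stop_param("family ids must be unique")
  data.frame(family = as.character(family_id),
             n_lines = as.integer(n_lines),
             parent_a = as.character(parent_a),
             parent_b = as.character(parent_b),
             stringsAsFactors = FALSE)
}

#' Assemble a DH population object
#'
#' @param map a [genmap].
#' @param families a [family_spec] table.
#' @param geno line x marker matrix of parent-A allele counts; entries 0, 2 or
#'   `NA` (DH lines are fully homozygous). Row names are line ids, column
#'   names marker ids matching the map.
#' @param line_family named character vector mapping line id to family id.
#' @param qtl_geno optional line x locus matrix of true genotypes at simulated
#'   QTL positions (kept separate from the observed marker matrix).
#' @return A `dh_population` object.
#' @export
dh_population <- function(map, families, geno, line_family, qtl_geno = NULL) {
  validate_genmap(map)
  if (!identical(colnames(geno), map$marker)) {
    geno <- geno[, map$marker, drop = FALSE]
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% c(0, 2))) {
    stop_param("DH genotype codes must be 0, 2 or NA")
  }
  if (!all(rownames(geno) %in% names(line_family))) {
    stop_param("every line needs a family assignment")
  }
  line_family <- line_family[rownames(geno)]
  if (!all(line_family %in% families$family)) {
    stop_param("unknown family in line_family")
  }
  structure(list(map = map, families = families, geno = geno,
                 line_family = line_family, qtl_geno = qtl_geno),
            class = "dh_population")
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf("DH population: %d lines in %d families, %d markers on %d groups\n",
              nrow(x$geno), nrow(x$families), nrow(x$map),
              length(unique(x$map$group))))
  cat("  families:", paste0(x$families$family, " (", x$families$n_lines, ")",
                            collapse = ", "), "\n")
  invisible(x)
}

# Simulate n doubled gametes over ordered positions of one linkage group.
# Returns n x k matrix of parent-A allele counts (0/2). First locus is a fair
# coin; adjacent loci switch parent with Haldane r(d) (no interference).
.sim_group_gametes <- function(n, pos) {
  k <- length(pos)
  alle <- matrix(0L, n, k)
  alle[, 1L] <- stats::rbinom(n, 1L, 0.5)
  if (k > 1L) {
    r <- haldane_r(diff(pos))
    for (j in 2L:k) {
      sw <- stats::rbinom(n, 1L, r[j - 1L])
      alle[, j] <- ifelse(sw == 1L, 1L - alle[, j - 1L], alle[, j - 1L])
    }
  }
  2L * alle
}

#' Simulate one DH family
#'
#' Each line is a single gamete of the F1 between the two family parents,
#' chromosome-doubled: fully homozygous, coded as the count (0 or 2) of
#' parent-A alleles. Crossovers follow the Haldane model (no interference).
#'
#' @param map a [genmap].
#' @param n_lines number of DH lines.
#' @param seed RNG seed (optional).
#' @return Integer matrix `n_lines` x markers with entries 0/2.
#' @export
simulate_dh_family <- function(map, n_lines, seed = NULL) {
  validate_genmap(map)
  with_seed(seed, {
    blocks <- lapply(unique(map$group), function(g) {
      .sim_group_gametes(n_lines, map$pos[map$group == g])
    })
    geno <- do.call(cbind, blocks)
    colnames(geno) <- map$marker
    geno
  })
}

#' Simulate a multi-family DH population
#'
#' Simulates each family on the map; when a QTL architecture is supplied the
#' map is augmented internally with the QTL positions as hidden pseudo-loci so
#' that true QTL genotypes are available for phenotype simulation, while the
#' reported marker matrix contains only the map's markers.
#'
#' @param map a [genmap].
#' @param families a [family_spec] table.
#' @param arch optional [qtl_architecture]; its loci become hidden pseudo-loci.
#' @param seed RNG seed.
#' @return A [dh_population]; `$qtl_geno` holds true QTL genotypes when `arch`
#'   is given (columns in the order of `arch$loci`).
#' @export
simulate_dh_population <- function(map, families, arch = NULL, seed = NULL) {
  validate_genmap(map)
  loci <- if (!is.null(arch)) arch$loci else NULL
  sim_map <- map
  if (!is.null(loci) && nrow(loci)) {
    if (!all(loci$group %in% map$group)) {
      stop_param("QTL groups must exist on the map")
    }
    for (i in seq_len(nrow(loci))) {
      p <- map$pos[map$group == loci$group[i]]
      if (loci$pos[i] < min(p) || loci$pos[i] > max(p)) {
        stop_param("QTL position outside the span of group ", loci$group[i])
      }
    }
    aug <- rbind(data.frame(group = map$group, marker = map$marker,
                            pos = map$pos, stringsAsFactors = FALSE),
                 data.frame(group = loci$group,
                            marker = paste0(".qtl", seq_len(nrow(loci))),
                            pos = loci$pos, stringsAsFactors = FALSE))
    sim_map <- genmap(aug$group, aug$marker, aug$pos)
  }
  with_seed(seed, {
    blocks <- lapply(seq_len(nrow(families)), function(f) {
      simulate_dh_family(sim_map, families$n_lines[f], seed = NULL)
    })
    geno_all <- do.call(rbind, blocks)
    line_ids <- unlist(lapply(seq_len(nrow(families)), function(f) {
      sprintf("%s_%03d", families$family[f], seq_len(families$n_lines[f]))
    }))
    rownames(geno_all) <- line_ids
    line_family <- rep(families$family, families$n_lines)
    names(line_family) <- line_ids
    qtl_geno <- NULL
    if (!is.null(loci) && nrow(loci)) {
      qtl_cols <- paste0(".qtl", seq_len(nrow(loci)))
      qtl_geno <- geno_all[, qtl_cols, drop = FALSE]
      colnames(qtl_geno) <- paste0(loci$group, "@", loci$pos)
    }
    dh_population(map, families, geno_all[, map$marker, drop = FALSE],
                  line_family, qtl_geno = qtl_geno)
  })
}

#' Inject missing genotype calls at random
#'
#' Missing-at-random masking of the observed marker matrix (the hidden QTL
#' genotypes are never masked).
#'
#' @param pop a [dh_population].
#' @param rate fraction of calls to set missing, in `[0, 1)`.
#' @param seed RNG seed.
#' @return The population with `NA`s injected.
#' @export
inject_missing <- function(pop, rate = 0.05, seed = NULL) {
  stopifnot(inherits(pop, "dh_population"))
  if (rate < 0 || rate >= 1) stop_param("rate must be in [0, 1)")
  with_seed(seed, {
    mask <- stats::runif(length(pop$geno)) < rate
    pop$geno[mask] <- NA
    pop
  })
}
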