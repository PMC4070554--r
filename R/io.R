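# Tab-delimited file dialect: one header line, "NA" for missing. One fixed
# dialect keeps parsing deterministic.

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a genetic map file
#'
#' Columns: `group`, `marker`, `pos_cM` (tab-delimited, headered).
#'
#' @param path file path.
#' @return A [genmap].
#' @export
read_map <- function(path) {
  d <- .read_tsv(path)
  need <- c("group", "marker", "pos_cM")
  if (!all(need %in% names(d))) {
    stop_param("map file must have columns ", paste(need, collapse = ", "))
  }
  genmap(d$group, d$marker, d$pos_cM)
}

#' @rdname read_map
#' @param map a [genmap] to write.
#' @export
write_map <- function(map, path) {
  .write_tsv(data.frame(group = map$group, marker = map$marker,
                        pos_cM = map$pos), path)
}

#' Read a family assignment file
#'
#' Columns: `line`, `family`, `parent_a`, `parent_b`.
#'
#' @param path file path.
#' @return List with `families` (a [family_spec]) and `line_family` (named
#'   vector).
#' @export
read_families <- function(path) {
  d <- .read_tsv(path)
  need <- c("line", "family", "parent_a", "parent_b")
  if (!all(need %in% names(d))) {
    stop_param("family file must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(d$line)) stop_param("duplicate line ids in family file")
  fam <- unique(d[, c("family", "parent_a", "parent_b")])
  if (anyDuplicated(fam$family)) {
    stop_param("inconsistent parent assignment within a family")
  }
  n <- table(factor(d$family, levels = fam$family))
  families <- family_spec(fam$family, as.integer(n), fam$parent_a,
                          fam$parent_b)
  line_family <- stats::setNames(d$family, d$line)
  list(families = families, line_family = line_family)
}

#' @rdname read_families
#' @param pop a [dh_population] to write.
#' @export
write_families <- function(pop, path) {
  fm <- pop$families
  i <- match(pop$line_family, fm$family)
  .write_tsv(data.frame(line = names(pop$line_family),
                        family = pop$line_family,
                        parent_a = fm$parent_a[i], parent_b = fm$parent_b[i]),
             path)
}

#' Read a DH genotype matrix file
#'
#' First column `line`; remaining columns one per marker with values 0, 2 or
#' `NA`. Marker columns may appear in any order; they are re-ordered to match
#' the map, and their set must equal the map's markers.
#'
#' @param path file path.
#' @param map the [genmap] the genotypes belong to.
#' @return Line x marker matrix (rows named by line).
#' @export
read_genotypes <- function(path, map) {
  d <- .read_tsv(path)
  if (names(d)[1L] != "line") stop_param("first column must be 'line'")
  mk <- names(d)[-1L]
  if (!setequal(mk, map$marker)) {
    missing_mk <- setdiff(map$marker, mk)
    extra <- setdiff(mk, map$marker)
    stop_param("genotype/map marker mismatch",
               if (length(missing_mk)) paste0("; absent from file: ",
                                              paste(utils::head(missing_mk, 5),
                                                    collapse = ", ")),
               if (length(extra)) paste0("; unknown markers: ",
                                         paste(utils::head(extra, 5),
                                               collapse = ", ")))
  }
  g <- as.matrix(d[, map$marker, drop = FALSE])
  mode(g) <- "numeric"
  bad <- which(!is.na(g) & !(g %in% c(0, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_param("non-DH genotype value ", g[bad[1L, , drop = FALSE]],
               " at line ", d$line[bad[1L, 1L]], ", marker ",
               map$marker[bad[1L, 2L]], " (row ", bad[1L, 1L] + 1L,
               " of the file); DH calls must be 0, 2 or NA")
  }
  rownames(g) <- d$line
  g
}

#' @rdname read_genotypes
#' @param pop a [dh_population] to write.
#' @export
write_genotypes <- function(pop, path) {
  .write_tsv(data.frame(line = rownames(pop$geno), pop$geno,
                        check.names = FALSE), path)
}

#' Read a long phenotype file
#'
#' Columns: `line`, `stage`, `environment`, `rep`, `value`.
#'
#' @param path file path.
#' @return List of long data frames (`line`, `env`, `rep`, `value`), one per
#'   stage.
#' @export
read_phenotypes <- function(path) {
  d <- .read_tsv(path)
  need <- c("line", "stage", "environment", "rep", "value")
  if (!all(need %in% names(d))) {
    stop_param("phenotype file must have columns ",
               paste(need, collapse = ", "))
  }
  lapply(split(d, d$stage), function(s) {
    data.frame(line = s$line, env = s$environment, rep = s$rep,
               value = s$value, stringsAsFactors = FALSE)
  })
}

#' @rdname read_phenotypes
#' @param pheno named list of `pheno_set` objects (one per stage) to write.
#' @export
write_phenotypes <- function(pheno, path) {
  rows <- lapply(pheno, function(p) {
    data.frame(line = p$values$line, stage = p$stage,
               environment = p$values$env, rep = p$values$rep,
               value = p$values$value, stringsAsFactors = FALSE)
  })
  .write_tsv(do.call(rbind, rows), path)
}

#' Assemble a population from map, genotype and family files
#'
#' Cross-validates consistency: marker sets match between map and genotypes,
#' every genotyped line has a family, genotype calls are 0/2/NA.
#'
#' @param map_file,genotype_file,family_file paths.
#' @return A [dh_population].
#' @export
read_population <- function(map_file, genotype_file, family_file) {
  map <- read_map(map_file)
  geno <- read_genotypes(genotype_file, map)
  fam <- read_families(family_file)
  orphan <- setdiff(rownames(geno), names(fam$line_family))
  if (length(orphan)) {
    stop_param("lines without family assignment: ",
               paste(utils::head(orphan, 5), collapse = ", "))
  }
  dh_population(map, fam$families, geno, fam$line_family)
}

#' Write the analysis report files
#'
#' Emits, per stage, the QTL table; a cross-validation summary table shaped
#' like a published CV summary (`QTL_ES`, `pG_ES`, `pG_TS`, relative bias);
#' the Venn-count table of stage overlap; and the locus x stage `pG` matrix
#' describing the temporal dynamics of each detected locus.
#'
#' @param results list with elements `qtl` (named list of QTL tables per
#'   stage), optional `cv` (named list of `cv_result` per stage), optional
#'   `overlap` (from [classify_overlap]), optional `pg_matrix` (locus x stage
#'   data frame), optional `log` (character lines).
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (st in names(results$qtl)) {
    p <- file.path(dir, paste0("qtl_", st, ".tsv"))
    .write_tsv(results$qtl[[st]], p)
    paths <- c(paths, p)
  }
  if (!is.null(results$cv)) {
    cv_tab <- do.call(rbind, lapply(names(results$cv), function(st) {
      cv <- results$cv[[st]]
      data.frame(stage = st, n_runs = cv$n_runs, QTL_ES = cv$qtl_ES_mean,
                 pG_ES = cv$pG_ES_mean, pG_TS = cv$pG_TS_mean,
                 relative_bias = cv$relative_bias)
    }))
    p <- file.path(dir, "cv_summary.tsv")
    .write_tsv(cv_tab, p)
    paths <- c(paths, p)
    for (st in names(results$cv)) {
      p <- file.path(dir, paste0("qtl_frequency_", st, ".tsv"))
      .write_tsv(results$cv[[st]]$frequency, p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(results$overlap)) {
    counts <- results$overlap$counts
    p <- file.path(dir, "venn_counts.tsv")
    .write_tsv(data.frame(stages = names(counts),
                          clusters = as.integer(counts)), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$pg_matrix)) {
    p <- file.path(dir, "pg_by_stage.tsv")
    .write_tsv(results$pg_matrix, p)
    paths <- c(paths, p)
  }
  if (!is.null(results$log)) {
    p <- file.path(dir, "run_log.txt")
    writeLines(results$log, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
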