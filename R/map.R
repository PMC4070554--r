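#' Construct a genetic linkage map
#'
#' A genetic map is a data frame with columns `group` (linkage group
#' identifier), `marker` (globally unique marker name) and `pos` (position in
#' centimorgans, cM). Positions must be non-decreasing within a group and every
#' group needs at least two markers, so that each position on the group lies in
#' a marker interval.
#'
#' @param group character vector of linkage-group identifiers.
#' @param marker character vector of marker names, globally unique.
#' @param pos numeric vector of positions in cM, `>= 0`.
#' @return A `genmap` object (a validated data frame).
#' @export
genmap <- function(group, marker, pos) {
  map <- data.frame(group = as.character(group),
                    marker = as.character(marker),
                    pos = as.numeric(pos),
                    stringsAsFactors = FALSE)
  map <- map[order(match(map$group, unique(map$group)), map$pos), , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("genmap", "data.frame")
  validate_genmap(map)
  map
}

validate_genmap <- function(map) {
  if (!all(c("group", "marker", "pos") %in% names(map))) {
    stop_param("map must have columns group, marker, pos")
  }
  if (anyDuplicated(map$marker)) {
    stop_param("marker names must be globally unique")
  }
  if (any(!is.finite(map$pos)) || any(map$pos < 0)) {
    stop_param("marker positions must be finite and >= 0")
  }
  for (g in unique(map$group)) {
    p <- map$pos[map$group == g]
    if (length(p) < 2L) stop_param("group ", g, " has fewer than 2 markers")
    if (is.unsorted(p)) stop_param("positions not sorted within group ", g)
  }
  invisible(map)
}

#' Build an equally spaced synthetic map
#'
#' Generates `n_groups` linkage groups each carrying markers at
#' `0, spacing, 2*spacing, ..., length` cM. Stands in for a real consensus map
#' when simulating populations; marker density is configurable because real
#' map densities vary widely.
#'
#' @param n_groups number of linkage groups (`>= 1`).
#' @param group_length_cM length of each group in cM.
#' @param marker_spacing_cM distance between adjacent markers in cM
#'   (`0 < spacing <= length`).
#' @param group_names optional character vector of group names; defaults to
#'   `LG01, LG02, ...`.
#' @return A [genmap] object.
#' @examples
#' make_map(1, 100, 10)   # 11 markers at 0,10,...,100
#' @export
make_map <- function(n_groups, group_length_cM, marker_spacing_cM,
                     group_names = NULL) {
  if (!is.numeric(n_groups) || n_groups < 1) {
    stop_param("n_groups must be >= 1")
  }
  if (!is.numeric(group_length_cM) || group_length_cM <= 0 ||
      !is.numeric(marker_spacing_cM) || marker_spacing_cM <= 0) {
    stop_param("group length and marker spacing must be positive")
  }
  if (group_length_cM < marker_spacing_cM) {
    stop_param("group_length_cM must be >= marker_spacing_cM")
  }
  n_groups <- as.integer(n_groups)
  if (is.null(group_names)) {
    group_names <- sprintf("LG%02d", seq_len(n_groups))
  }
  stopifnot(length(group_names) == n_groups)
  pos <- seq(0, group_length_cM, by = marker_spacing_cM)
  if (pos[length(pos)] < group_length_cM) pos <- c(pos, group_length_cM)
  genmap(group = rep(group_names, each = length(pos)),
         marker = paste0(rep(group_names, each = length(pos)), "_M",
                         sprintf("%03d", rep(seq_along(pos), n_groups))),
         pos = rep(pos, n_groups))
}

#' Scan grid over a genetic map
#'
#' Positions at a fixed cM step along every group, always including the marker
#' positions themselves so that observed genotypes are reproduced exactly at
#' marker loci.
#'
#' @param map a [genmap].
#' @param step_cM grid step in cM (`> 0`).
#' @return Data frame with columns `group`, `pos`.
#' @export
scan_grid <- function(map, step_cM = 1) {
  validate_genmap(map)
  if (!is.numeric(step_cM) || step_cM <= 0) stop_param("step_cM must be > 0")
  out <- lapply(unique(map$group), function(g) {
    p <- map$pos[map$group == g]
    grid <- sort(unique(c(seq(min(p), max(p), by = step_cM), p)))
    data.frame(group = g, pos = grid, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.genmap <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers on %d linkage group(s), %.1f cM total\n",
              nrow(x), length(unique(x$group)),
              sum(tapply(x$pos, x$group, function(p) max(p) - min(p)))))
  invisible(x)
}
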