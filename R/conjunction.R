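#' Conjunction classification of two lesion-symptom maps
#'
#' Thresholds each analysis' z map at a common per-voxel criterion `z_star`
#' within the shared inclusion mask and classifies every voxel as
#' non-significant (0), significant for A only (1), for B only (2), or for
#' both (3). Classification is purely voxelwise — no minimum-cluster rule
#' applies here, so structures too small or fragmented to appear in
#' cluster-based reporting can still contribute voxels.
#'
#' @param z_A,z_B z maps (3-D arrays) from two [map_scores()] runs on the
#'   same grid.
#' @param inclusion logical array of tested voxels.
#' @param z_star common z threshold applied to both analyses.
#' @param grid optional `volume_grid` carried through for reporting.
#' @return a `conjunction_result` with fields `category` (integer array),
#'   `counts` (list `A_only`, `B_only`, `both`, `A_total`, `B_total`),
#'   `z_star`, `grid`.
#' @export
classify <- function(z_A, z_B, inclusion, z_star, grid = NULL) {
  if (!all(dim(z_A) == dim(z_B)) || !all(dim(z_A) == dim(inclusion))) {
    stop("z maps and inclusion mask must share one grid")
  }
  a <- inclusion & !is.na(z_A) & z_A >= z_star
  b <- inclusion & !is.na(z_B) & z_B >= z_star
  category <- array(0L, dim(z_A))
  category[a & !b] <- 1L
  category[b & !a] <- 2L
  category[a & b] <- 3L
  counts <- list(A_only = sum(a & !b), B_only = sum(b & !a), both = sum(a & b),
                 A_total = sum(a), B_total = sum(b))
  structure(list(category = category, counts = counts, z_star = z_star,
                 grid = grid),
            class = "conjunction_result")
}

#' @export
print.conjunction_result <- function(x, ...) {
  with(x$counts, cat(sprintf(
    "conjunction_result (z* = %.3f): A-only %d, B-only %d, both %d (A total %d, B total %d)\n",
    x$z_star, A_only, B_only, both, A_total, B_total)))
  invisible(x)
}

#' Selective fractions of a conjunction
#'
#' The percentage of each analysis' significant voxels that are selective
#' (not shared with the other analysis). Raw percentages are retained
#' alongside the integer-rounded values used for reporting. A zero total
#' makes the corresponding fraction undefined (`NA`).
#'
#' @param result a `conjunction_result`, or a list of counts with entries
#'   `A_only`, `B_only`, `both`.
#' @return list with `pct_A_only`, `pct_B_only` (raw) and `pct_A_only_int`,
#'   `pct_B_only_int` (rounded for reporting).
#' @export
selective_fractions <- function(result) {
  cts <- if (inherits(result, "conjunction_result")) result$counts else result
  a_tot <- cts$A_only + cts$both
  b_tot <- cts$B_only + cts$both
  pa <- if (a_tot > 0) 100 * cts$A_only / a_tot else NA_real_
  pb <- if (b_tot > 0) 100 * cts$B_only / b_tot else NA_real_
  list(pct_A_only = pa, pct_B_only = pb,
       pct_A_only_int = if (is.na(pa)) NA_integer_ else as.integer(round(pa)),
       pct_B_only_int = if (is.na(pb)) NA_integer_ else as.integer(round(pb)))
}

#' Per-structure conjunction table
#'
#' Counts A-only, B-only and both-category voxels within each atlas
#' structure. A structure is retained if it reaches `min_report` voxels —
#' by default in at least one of the three categories (`rule = "any"`);
#' `rule = "sum"` instead requires the three counts to total `min_report`.
#'
#' @param result a `conjunction_result`.
#' @param atlas an `atlas_volume` on the same grid.
#' @param min_report minimum voxel count for a row (default 10).
#' @param rule `"any"` (default) or `"sum"`.
#' @return data frame with columns `structure`, `A_only`, `B_only`, `both`,
#'   ordered by decreasing total.
#' @export
conjunction_table <- function(result, atlas, min_report = 10L,
                              rule = c("any", "sum")) {
  rule <- match.arg(rule)
  if (!is.null(result$grid)) stop_if_grid_mismatch(result$grid, atlas$grid, "conjunction and atlas")
  stopifnot(all(dim(result$category) == dim(atlas$labels)))
  sel <- result$category > 0L
  empty <- data.frame(structure = character(0), A_only = integer(0),
                      B_only = integer(0), both = integer(0))
  if (!any(sel)) return(empty)
  labs <- atlas$labels[sel]
  cats <- result$category[sel]
  rows <- lapply(sort(unique(labs)), function(lb) {
    data.frame(
      structure = if (lb == 0L) "unlabeled" else unname(atlas$names[as.character(lb)]),
      A_only = sum(labs == lb & cats == 1L),
      B_only = sum(labs == lb & cats == 2L),
      both = sum(labs == lb & cats == 3L), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- if (rule == "any") {
    pmax(out$A_only, out$B_only, out$both) >= min_report
  } else {
    out$A_only + out$B_only + out$both >= min_report
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out[order(-(out$A_only + out$B_only + out$both)), , drop = FALSE]
}
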