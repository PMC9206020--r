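#' Voxel inclusion (coverage) mask
#'
#' Only voxels damaged in at least a stated fraction of the cohort are
#' tested. The minimum lesioned count is `floor(coverage * n)` — with the
#' conventional 20% rule a 41-subject cohort requires 8 lesioned subjects
#' per voxel. A voxel additionally needs at least `min_intact` undamaged
#' subjects for the two-group comparison to be defined.
#'
#' @param cohort a `lesion_cohort` with n >= 2.
#' @param coverage fraction in (0, 1); default 0.20.
#' @param min_intact minimum intact subjects per testable voxel (default 2).
#' @return list with `mask` (3-D logical array), `min_lesioned` (integer
#'   threshold applied), and `overlay` (the subject-count volume).
#' @export
inclusion_mask <- function(cohort, coverage = 0.20, min_intact = 2L) {
  if (cohort$n < 2L) stop("inclusion mask needs at least 2 subjects")
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  counts <- overlay_map(cohort)
  min_lesioned <- max(1L, as.integer(floor(coverage * cohort$n)))
  mask <- counts >= min_lesioned & (cohort$n - counts) >= min_intact
  list(mask = mask, min_lesioned = min_lesioned, overlay = counts)
}

# Tie-corrected Mann-Whitney normal approximation, vectorized over voxels.
# r: ranks of all N scores; R1: per-voxel sum of lesioned subjects' ranks;
# n1: per-voxel lesioned count. z > 0 when lesioned subjects rank lower
# (score worse); p is the upper normal tail.
mw_z_from_ranks <- function(R1, n1, N, tie_term) {
  n2 <- N - n1
  U <- R1 - n1 * (n1 + 1) / 2
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- ifelse(v > 0, (n1 * n2 / 2 - U) / sqrt(pmax(v, 0)), 0)
  p <- ifelse(v > 0, stats::pnorm(z, lower.tail = FALSE), 0.5)
  list(z = z, p = p, U = U)
}

tie_correction <- function(scores) {
  t <- table(scores)
  sum(t^3 - t)
}

#' Mann-Whitney voxel test
#'
#' Compares the behavioral scores of subjects lesioned at a voxel against
#' those intact there, using the tie-corrected normal approximation of the
#' Mann-Whitney U statistic (no continuity correction). The statistic is
#' signed so that `z > 0` when lesioned subjects score worse (lower), and
#' `p` is the one-sided upper-tail normal probability of `z`. When all
#' observations are identical the comparison carries no signal and
#' `z = 0, p = 0.5` is returned.
#'
#' @param lesioned_scores,intact_scores non-empty numeric vectors.
#' @return list with `z`, `p` (one-sided), and `U` (rank-sum statistic of
#'   the lesioned group).
#' @export
voxel_test <- function(lesioned_scores, intact_scores) {
  if (length(lesioned_scores) == 0L || length(intact_scores) == 0L) {
    stop("both groups must be non-empty")
  }
  all_scores <- c(lesioned_scores, intact_scores)
  r <- rank(all_scores)
  n1 <- length(lesioned_scores)
  N <- length(all_scores)
  res <- mw_z_from_ranks(sum(r[seq_len(n1)]), n1, N, tie_correction(all_scores))
  list(z = unname(res$z), p = unname(res$p), U = unname(res$U))
}

#' Voxelwise lesion-symptom map for one score
#'
#' Applies [voxel_test()] at every included voxel, partitioning subjects by
#' lesion status there. Computation is vectorized through shared ranks (the
#' score ranking does not depend on the voxel), which is algebraically
#' identical to calling `voxel_test` per voxel.
#'
#' @param cohort a `lesion_cohort`.
#' @param score_name score column to map.
#' @param inclusion result of [inclusion_mask()], or a logical array.
#' @return a `vlsm_result` with fields `score_name`, `inclusion`, `z`, `p`
#'   (arrays, `NA` outside the inclusion mask), `sig` (`NULL` until a
#'   selection step runs), `threshold_info`, `min_lesioned`, `grid`, `n`.
#' @export
map_scores <- function(cohort, score_name, inclusion) {
  if (is.list(inclusion)) {
    min_lesioned <- inclusion$min_lesioned
    inc <- inclusion$mask
  } else {
    min_lesioned <- NA_integer_
    inc <- inclusion
  }
  stopifnot(all(dim(inc) == cohort$grid$dims))
  scores <- cohort_score(cohort, score_name)
  N <- cohort$n
  zmap <- array(NA_real_, cohort$grid$dims)
  pmap <- array(NA_real_, cohort$grid$dims)
  vox <- which(inc)
  if (length(vox) == 0L) {
    warning("no voxels pass the inclusion mask; empty result")
  } else {
    lesmat <- vapply(cohort$subjects, function(m) m$data[vox], numeric(length(vox)))
    lesmat <- matrix(lesmat, nrow = length(vox))
    r <- rank(scores)
    R1 <- as.vector(lesmat %*% r)
    n1 <- as.vector(rowSums(lesmat))
    res <- mw_z_from_ranks(R1, n1, N, tie_correction(scores))
    zmap[vox] <- res$z
    pmap[vox] <- res$p
  }
  structure(list(score_name = score_name, inclusion = inc, z = zmap, p = pmap,
                 sig = NULL, threshold_info = NULL,
                 min_lesioned = min_lesioned, grid = cohort$grid, n = N),
            class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf("vlsm_result '%s': %d tested voxels", x$score_name,
              sum(x$inclusion)))
  if (!is.null(x$sig)) {
    cat(sprintf(", %d significant (%s, z* = %.3f)", sum(x$sig),
                x$threshold_info$mode, x$threshold_info$z_star))
  }
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg selection of significant voxels
#'
#' Applies step-up FDR control to the one-sided p values of the included
#' voxels. `threshold_info` records the realized p cutoff (the largest
#' rejected p) and its z equivalent (the smallest rejected z).
#'
#' @param result a `vlsm_result` with the p map filled.
#' @param q target false discovery rate (default 0.05).
#' @return the `vlsm_result` with `sig` and `threshold_info` filled.
#' @export
fdr_select <- function(result, q = 0.05) {
  vox <- which(result$inclusion)
  p <- result$p[vox]
  sig <- array(FALSE, dim(result$inclusion))
  rej <- if (length(p) > 0L) stats::p.adjust(p, method = "BH") <= q else logical(0)
  sig[vox[rej]] <- TRUE
  result$sig <- sig
  result$threshold_info <- list(
    mode = "fdr", q = q,
    p_star = if (any(rej)) max(p[rej]) else NA_real_,
    z_star = if (any(rej)) min(result$z[vox][rej]) else NA_real_)
  result
}

#' Lenient fixed-z selection of significant voxels
#'
#' Marks included voxels with `z >= z_star` significant. Used when an
#' analysis lacks the power to survive FDR correction: the threshold is
#' then borrowed from a better-powered reference analysis via
#' [derive_lenient_threshold()], or fixed (z 2.09 corresponds to one-sided
#' p 0.018).
#'
#' @param result a `vlsm_result` with the z map filled.
#' @param z_star z threshold.
#' @return the `vlsm_result` with `sig` and `threshold_info` filled.
#' @export
lenient_select <- function(result, z_star) {
  sig <- array(FALSE, dim(result$inclusion))
  vox <- which(result$inclusion)
  sig[vox] <- result$z[vox] >= z_star
  result$sig <- sig
  result$threshold_info <- list(
    mode = "lenient", q = NA_real_, p_star = stats::pnorm(z_star, lower.tail = FALSE),
    z_star = z_star)
  result
}

#' Derive a lenient z threshold from a reference FDR result
#'
#' Returns the minimal z among the reference analysis' FDR-surviving
#' voxels, the value a lower-powered companion analysis is then thresholded
#' at.
#'
#' @param reference a `vlsm_result` whose `sig` was filled by [fdr_select()]
#'   with at least one significant voxel.
#' @return the minimum significant z (numeric scalar).
#' @export
derive_lenient_threshold <- function(reference) {
  if (is.null(reference$sig) || !any(reference$sig)) {
    stop("reference analysis has no significant voxels to derive a threshold from")
  }
  min(reference$z[reference$sig])
}
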