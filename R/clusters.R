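adjacency_offsets <- function(adjacency = 26L) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  keep <- switch(as.character(adjacency),
                 "6" = rowSums(abs(g)) == 1L,
                 "18" = rowSums(abs(g)) <= 2L,
                 "26" = rep(TRUE, nrow(g)),
                 stop("adjacency must be 6, 18 or 26"))
  g[keep, , drop = FALSE]
}

#' Label connected components of a 3-D binary volume
#'
#' Flood-fill labeling under 6-, 18- or 26-neighborhood adjacency.
#'
#' @param mask 3-D logical/0-1 array.
#' @param adjacency 6, 18 or 26 (default 26, the common volumetric choice).
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, adjacency = 26L) {
  dims <- dim(mask)
  offs <- adjacency_offsets(adjacency)
  lab <- array(0L, dims)
  fg <- which(mask > 0)
  nlab <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    lab[start] <- nlab
    queue <- start
    while (length(queue) > 0L) {
      ijk <- arrayInd(queue, dims)
      nb <- matrix(0L, nrow = nrow(ijk) * nrow(offs), ncol = 3L)
      for (a in 1:3) {
        nb[, a] <- rep(ijk[, a], each = nrow(offs)) + rep(offs[, a], nrow(ijk))
      }
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L))
      lin <- lin[mask[lin] > 0 & lab[lin] == 0L]
      lab[lin] <- nlab
      queue <- lin
    }
  }
  lab
}

#' Pick the reporting voxel of a cluster
#'
#' Among the voxels attaining the cluster's maximum z, picks by
#' lexicographic priority on world coordinates: most superior (greatest z),
#' then most posterior (least y), then most left (least x). The cluster
#' centroid is deliberately not used — it need not attain the maximum nor
#' even be significant.
#'
#' @param voxels n x 3 matrix of 1-based voxel indices.
#' @param z numeric vector of z values at those voxels.
#' @param grid a `volume_grid`.
#' @return list with `index` (1-based ijk), `mm` (world coordinates), and
#'   `max_z`.
#' @export
report_voxel <- function(voxels, z, grid) {
  voxels <- rbind(voxels)
  if (nrow(voxels) == 0L) stop("empty cluster")
  top <- which(z == max(z))
  mm <- rbind(voxel_to_world(grid, voxels[top, , drop = FALSE]))
  pick <- top[order(-mm[, 3], mm[, 2], mm[, 1])[1]]
  list(index = voxels[pick, ], mm = drop(voxel_to_world(grid, voxels[pick, ])),
       max_z = max(z))
}

#' Extract reportable clusters from a significance map
#'
#' Connected components of the significant voxels are formed under the
#' configured adjacency; components smaller than `min_size` are dropped
#' (the conventional 10-voxel reporting rule). Each surviving cluster
#' carries its maximum z and the reporting voxel chosen by [report_voxel()].
#'
#' @param result a `vlsm_result` with `sig` filled.
#' @param min_size minimum cluster size in voxels (default 10).
#' @param adjacency 6, 18 or 26 (default 26).
#' @return list of `cluster` objects, ordered by decreasing max z; each has
#'   `voxels` (n x 3 index matrix), `size`, `max_z`, `report_voxel`,
#'   `report_mm`.
#' @export
extract_clusters <- function(result, min_size = 10L, adjacency = 26L) {
  if (is.null(result$sig)) stop("run fdr_select() or lenient_select() first")
  lab <- label_components(result$sig, adjacency)
  ids <- setdiff(unique(as.vector(lab)), 0L)
  clusters <- list()
  for (id in ids) {
    vox <- which(lab == id, arr.ind = TRUE)
    if (nrow(vox) < min_size) next
    zv <- result$z[lab == id]
    rep_v <- report_voxel(vox, zv, result$grid)
    clusters[[length(clusters) + 1L]] <- structure(
      list(voxels = vox, size = nrow(vox), max_z = rep_v$max_z,
           report_voxel = rep_v$index, report_mm = rep_v$mm),
      class = "cluster")
  }
  clusters[order(-vapply(clusters, function(cl) cl$max_z, numeric(1)))]
}

#' Cluster summary table
#' @param clusters list of `cluster` objects from [extract_clusters()].
#' @return data frame with cluster id, size, max z, and reporting mm
#'   coordinates.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(cluster_id = integer(0), size = integer(0),
                      max_z = numeric(0), x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0)))
  }
  data.frame(
    cluster_id = seq_along(clusters),
    size = vapply(clusters, function(cl) cl$size, integer(1)),
    max_z = vapply(clusters, function(cl) cl$max_z, numeric(1)),
    x_mm = vapply(clusters, function(cl) cl$report_mm[1], numeric(1)),
    y_mm = vapply(clusters, function(cl) cl$report_mm[2], numeric(1)),
    z_mm = vapply(clusters, function(cl) cl$report_mm[3], numeric(1)))
}

#' Tabulate reported clusters against an atlas
#'
#' For each structure intersecting the reported clusters: the number of
#' significant in-cluster voxels falling in the structure, the percentage
#' of the structure's area that represents, the structure-wise maximum z
#' and its reporting voxel (same superior/posterior/left priority).
#' Significant voxels on unlabeled atlas voxels are tallied under
#' `"unlabeled"`.
#'
#' @param result a `vlsm_result` with `sig` filled.
#' @param clusters list of `cluster` objects from [extract_clusters()].
#' @param atlas an `atlas_volume` on the cohort grid.
#' @return data frame with columns `structure`, `max_z`, `x_mm`, `y_mm`,
#'   `z_mm`, `n_voxels`, `percent_area`, ordered by decreasing voxel count.
#' @export
tabulate_structures <- function(result, clusters, atlas) {
  stop_if_grid_mismatch(result$grid, atlas$grid, "result and atlas")
  empty <- data.frame(structure = character(0), max_z = numeric(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      n_voxels = integer(0), percent_area = numeric(0))
  if (length(clusters) == 0L) return(empty)
  vox <- do.call(rbind, lapply(clusters, function(cl) cl$voxels))
  lin <- vox[, 1] + result$grid$dims[1] * (vox[, 2] - 1L) +
    prod(result$grid$dims[1:2]) * (vox[, 3] - 1L)
  labs <- atlas$labels[lin]
  rows <- lapply(sort(unique(labs)), function(lb) {
    sel <- labs == lb
    rv <- report_voxel(vox[sel, , drop = FALSE], result$z[lin[sel]], result$grid)
    struct_size <- sum(atlas$labels == lb)
    data.frame(
      structure = if (lb == 0L) "unlabeled" else unname(atlas$names[as.character(lb)]),
      max_z = rv$max_z, x_mm = rv$mm[1], y_mm = rv$mm[2], z_mm = rv$mm[3],
      n_voxels = sum(sel),
      percent_area = if (struct_size > 0L) 100 * sum(sel) / struct_size else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n_voxels), , drop = FALSE]
}
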