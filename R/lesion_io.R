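#' Construct a lesion mask
#'
#' A `lesion_mask` holds one subject's binary lesion volume on the cohort
#' grid. Values must be 0/1; use [read_mask()] to binarize arbitrary input.
#'
#' @param data 3-D array of 0/1 values.
#' @param grid the `volume_grid` the mask lives on.
#' @param subject_id subject identifier string.
#' @return A `lesion_mask` with fields `subject_id`, `grid`, `data`.
#' @export
lesion_mask <- function(data, grid, subject_id = "subject") {
  stopifnot(inherits(grid, "volume_grid"))
  data <- as.array(data)
  if (!all(dim(data) == grid$dims)) stop("mask dimensions do not match grid")
  if (!all(is.finite(data))) stop("mask contains non-finite values")
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(subject_id = as.character(subject_id), grid = grid,
                 data = data),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("lesion_mask '%s': %d lesioned voxels (%.2f cc) on %s grid\n",
              x$subject_id, sum(x$data), lesion_volume_cc(x),
              paste(x$grid$dims, collapse = "x")))
  invisible(x)
}

#' Lesion volume in cubic centimeters
#' @param mask a `lesion_mask`.
#' @return lesion volume in cc.
#' @export
lesion_volume_cc <- function(mask) {
  sum(mask$data) * prod(mask$grid$voxel_size) / 1000
}

#' Read a lesion mask from a NIfTI file
#'
#' Values are binarized at 0.5 (any value > 0.5 becomes lesion), which
#' handles interpolated masks symmetrically. The grid is taken from the
#' NIfTI header and optionally checked against an expected cohort grid.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param expected_grid optional `volume_grid`; an error is raised on
#'   mismatch.
#' @param subject_id identifier; defaults to the file stem.
#' @return a `lesion_mask`.
#' @export
read_mask <- function(path, expected_grid = NULL, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1]
  if (!all(is.finite(arr))) stop(sprintf("non-finite values in mask '%s'", path))
  grid <- grid_from_nifti(img)
  if (!is.null(expected_grid)) stop_if_grid_mismatch(grid, expected_grid, "mask and cohort")
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  lesion_mask((arr > 0.5) * 1L, grid, subject_id)
}

#' Mirror a mask about the left-right mid-plane
#'
#' Reflects voxel index i to (X - 1 - i) (zero-based) along the first
#' (left-right) axis. The operation is exact for even and odd axis lengths,
#' preserves lesion volume, and is an involution: applying it twice returns
#' the original mask. Used to place right-hemisphere lesions onto a single
#' left-hemisphere template before cohort-level mapping.
#'
#' @param mask a `lesion_mask` whose first axis is left-right.
#' @return the mirrored `lesion_mask`.
#' @export
flip_to_left <- function(mask) {
  x <- mask$grid$dims[1]
  mask$data <- mask$data[x:1, , , drop = FALSE]
  mask
}

#' Does the lesion sit mostly in the right (positive-x) half-space?
#'
#' Decides per-subject flipping in the pipeline: masks whose lesion center
#' of mass has positive world x are mirrored onto the left hemisphere.
#'
#' @param mask a `lesion_mask`.
#' @return `TRUE` if the lesion center of mass has world x > 0; `FALSE` for
#'   left-sided or empty masks.
#' @export
needs_flip <- function(mask) {
  idx <- which(mask$data > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(FALSE)
  mean(voxel_to_world(mask$grid, idx)[, 1]) > 0
}

#' Construct an atlas volume
#'
#' @param labels 3-D integer array of structure labels (0 = unlabeled).
#' @param grid the `volume_grid`.
#' @param names named character vector mapping label id (as name) to
#'   structure name, or a data frame with columns `label` and `name`.
#' @return an `atlas_volume`.
#' @export
atlas_volume <- function(labels, grid, names) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- as.array(labels)
  if (!all(dim(labels) == grid$dims)) stop("atlas dimensions do not match grid")
  storage.mode(labels) <- "integer"
  if (is.data.frame(names)) {
    names <- stats::setNames(as.character(names$name), as.character(names$label))
  }
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(as.character(present), names(names))
  if (length(missing) > 0L) {
    stop(sprintf("atlas labels without names: %s", paste(missing, collapse = ", ")))
  }
  structure(list(grid = grid, labels = labels, names = names),
            class = "atlas_volume")
}

#' Read an atlas parcellation from NIfTI plus a names table
#'
#' @param path label volume (NIfTI, integer labels, 0 = unlabeled).
#' @param names_path TSV with columns `label` and `name`.
#' @return an `atlas_volume`.
#' @export
read_atlas <- function(path, names_path) {
  img <- RNifti::readNifti(path)
  labels <- round(as.array(img))
  tab <- utils::read.delim(names_path, stringsAsFactors = FALSE)
  atlas_volume(labels, grid_from_nifti(img), tab)
}

#' Assemble a cohort of lesion masks and behavioral scores
#'
#' Checks that subject ids are unique, that masks and scores cover exactly
#' the same subjects, that all masks share one grid, and that any FMA-UL
#' column stays within its 0-66 scale.
#'
#' @param masks list of `lesion_mask` objects.
#' @param scores long-format data frame with columns `subject_id`, `score`,
#'   `value` (one row per subject per score).
#' @return a `lesion_cohort` with fields `subjects` (named list of masks),
#'   `scores`, `grid`, `n`.
#' @export
lesion_cohort <- function(masks, scores) {
  stopifnot(length(masks) >= 1L, is.data.frame(scores),
            all(c("subject_id", "score", "value") %in% names(scores)))
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids among masks")
  names(masks) <- ids
  grid <- masks[[1]]$grid
  for (m in masks) stop_if_grid_mismatch(m$grid, grid, "cohort masks")
  scored <- unique(scores$subject_id)
  if (!setequal(scored, ids)) {
    stop("scored subjects and masked subjects differ: every scored subject needs a mask and vice versa")
  }
  fma <- scores$value[scores$score == "FMA_UL"]
  if (length(fma) > 0L && (any(fma < 0) || any(fma > 66))) {
    stop("FMA_UL scores must lie in [0, 66]")
  }
  structure(list(subjects = masks, scores = scores, grid = grid,
                 n = length(masks)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("lesion_cohort: %d subjects, scores: %s\n", x$n,
              paste(unique(x$scores$score), collapse = ", ")))
  invisible(x)
}

#' Extract one score as a vector aligned with cohort subjects
#' @param cohort a `lesion_cohort`.
#' @param score_name name of the score column to extract.
#' @return named numeric vector, one value per subject in cohort order.
#' @export
cohort_score <- function(cohort, score_name) {
  sc <- cohort$scores[cohort$scores$score == score_name, ]
  if (nrow(sc) == 0L) stop(sprintf("score '%s' not present in cohort", score_name))
  v <- stats::setNames(sc$value, sc$subject_id)[names(cohort$subjects)]
  if (any(is.na(v))) stop(sprintf("score '%s' missing for some subjects", score_name))
  v
}

#' Read a long-format score table
#' @param path TSV with columns `subject_id`, `score`, `value`.
#' @return data frame.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("subject_id", "score", "value") %in% names(tab)))
  tab$subject_id <- as.character(tab$subject_id)
  tab$value <- as.numeric(tab$value)
  tab
}

#' Lesion overlay map of a cohort
#'
#' @param cohort a `lesion_cohort`.
#' @return 3-D integer array; each voxel counts the subjects lesioned there.
#' @export
overlay_map <- function(cohort) {
  acc <- array(0L, cohort$grid$dims)
  for (m in cohort$subjects) acc <- acc + m$data
  acc
}

#' Per-structure lesion damage table
#'
#' For every atlas structure reports how many of its voxels are lesioned and
#' the percentage damaged. Lesioned voxels on unlabeled atlas voxels appear
#' in an `unlabeled` row so the table partitions the total lesion volume.
#' A structure absent from the label volume gets `NA` percent (undefined),
#' not 0.
#'
#' @param mask a `lesion_mask`.
#' @param atlas an `atlas_volume` on the same grid.
#' @return data frame with columns `label`, `structure`, `lesioned_voxels`,
#'   `structure_voxels`, `percent`.
#' @export
percent_damage <- function(mask, atlas) {
  stop_if_grid_mismatch(mask$grid, atlas$grid, "mask and atlas")
  lab_ids <- sort(as.integer(names(atlas$names)))
  les <- mask$data > 0L
  out <- data.frame(
    label = c(lab_ids, 0L),
    structure = c(unname(atlas$names[as.character(lab_ids)]), "unlabeled"),
    lesioned_voxels = NA_integer_, structure_voxels = NA_integer_,
    percent = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    in_struct <- atlas$labels == out$label[r]
    out$structure_voxels[r] <- sum(in_struct)
    out$lesioned_voxels[r] <- sum(in_struct & les)
    out$percent[r] <- if (out$structure_voxels[r] > 0L) {
      100 * out$lesioned_voxels[r] / out$structure_voxels[r]
    } else NA_real_
  }
  out
}
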