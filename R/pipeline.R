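#' Build a pipeline run configuration
#'
#' Every parameter has a recorded default; the effective configuration is
#' serialized into the output directory by [run_all()] so any run can be
#' reproduced from its artifacts.
#'
#' @param out_dir output directory.
#' @param seed master seed (drives the synthetic cohort when used).
#' @param n_subjects synthetic cohort size.
#' @param score_A,score_B the two score names to map (A is the reference
#'   analysis for the derived lenient threshold).
#' @param coverage inclusion coverage fraction.
#' @param q FDR level for the reference analysis.
#' @param min_cluster minimum reported cluster size.
#' @param adjacency cluster adjacency (6, 18 or 26).
#' @param lenient_mode `"derived"` (threshold = minimal FDR-surviving z of
#'   analysis A) or `"fixed"` (use `lenient_z`).
#' @param lenient_z fixed lenient z threshold (default 2.09, one-sided
#'   p 0.018).
#' @param flip mirror right-sided masks onto the left hemisphere before
#'   mapping.
#' @param masks_dir,scores_path optional real-data inputs (NIfTI mask
#'   directory and long-format score TSV); when `NULL` a synthetic cohort
#'   is generated.
#' @param synthetic optional `synthetic_spec` overriding the default.
#' @param write_volumes write NIfTI outputs (default TRUE).
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("lesionmap_run_"), seed = 1L,
                       n_subjects = 41L, score_A = "FMA_UL",
                       score_B = "TSRT", coverage = 0.20, q = 0.05,
                       min_cluster = 10L, adjacency = 26L,
                       lenient_mode = c("derived", "fixed"),
                       lenient_z = 2.09, flip = TRUE, masks_dir = NULL,
                       scores_path = NULL, synthetic = NULL,
                       write_volumes = TRUE) {
  lenient_mode <- match.arg(lenient_mode)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = as.integer(n_subjects), score_A = score_A,
                 score_B = score_B, coverage = coverage, q = q,
                 min_cluster = as.integer(min_cluster),
                 adjacency = as.integer(adjacency),
                 lenient_mode = lenient_mode, lenient_z = lenient_z,
                 flip = flip, masks_dir = masks_dir,
                 scores_path = scores_path, synthetic = synthetic,
                 write_volumes = write_volumes),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full lesion-symptom mapping pipeline
#'
#' Orchestrates cohort assembly (synthetic or from files), optional
#' hemisphere flipping, the lesion overlay map, VLSM of both scores, FDR
#' selection of the reference score, lenient-threshold derivation,
#' cluster extraction and atlas tabulation for both analyses, and the
#' conjunction classification. Writes volumes (NIfTI), tables (TSV), a
#' machine-readable `manifest.json`, a plain-text `run.log`, and the
#' effective `config.yaml` into `config$out_dir`.
#'
#' @param config a `run_config`.
#' @param atlas optional `atlas_volume`; defaults to [toy_atlas()] on the
#'   cohort grid.
#' @return (invisibly) a list with the cohort, both `vlsm_result`s, the
#'   clusters, tables, `conjunction_result`, truth (when synthetic) and the
#'   manifest.
#' @export
run_all <- function(config = run_config(), atlas = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  }
  cat(sprintf("lesionmap run, seed %d\n", config$seed), file = log_path)

  assembled <- stage("cohort", {
    if (!is.null(config$masks_dir)) {
      files <- list.files(config$masks_dir, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
      masks <- lapply(files, read_mask)
      list(cohort = lesion_cohort(masks, read_scores(config$scores_path)),
           truth = NULL)
    } else {
      spec <- config$synthetic
      if (is.null(spec)) {
        spec <- synthetic_spec(n_subjects = config$n_subjects,
                               seed = config$seed)
      }
      gen <- generate_cohort(spec)
      list(cohort = gen$cohort, truth = gen$truth)
    }
  })
  cohort <- assembled$cohort
  truth <- assembled$truth
  logf("cohort: n = %d", cohort$n)

  if (config$flip) {
    cohort$subjects <- lapply(cohort$subjects, function(m) {
      if (needs_flip(m)) flip_to_left(m) else m
    })
  }
  if (is.null(atlas)) atlas <- toy_atlas(cohort$grid)
  stage("atlas", stop_if_grid_mismatch(atlas$grid, cohort$grid, "atlas and cohort"))

  inc <- stage("inclusion", inclusion_mask(cohort, config$coverage))
  logf("inclusion: min_lesioned = %d, %d voxels tested", inc$min_lesioned,
       sum(inc$mask))

  res_A <- stage("vlsm_A", map_scores(cohort, config$score_A, inc))
  res_B <- stage("vlsm_B", map_scores(cohort, config$score_B, inc))

  res_A <- stage("fdr_A", fdr_select(res_A, config$q))
  logf("FDR(%s): %d significant voxels at q = %g", config$score_A,
       sum(res_A$sig), config$q)

  z_star <- stage("lenient_threshold", {
    if (config$lenient_mode == "derived") {
      if (any(res_A$sig)) derive_lenient_threshold(res_A) else {
        logf("reference FDR selection empty; lenient threshold set to +Inf")
        Inf
      }
    } else config$lenient_z
  })
  logf("lenient z* = %g (%s)", z_star, config$lenient_mode)

  res_A_len <- lenient_select(res_A, z_star)
  res_B_len <- lenient_select(res_B, z_star)
  logf("lenient(%s): %d voxels; lenient(%s): %d voxels", config$score_A,
       sum(res_A_len$sig), config$score_B, sum(res_B_len$sig))

  cl_A <- stage("clusters_A", extract_clusters(res_A, config$min_cluster,
                                               config$adjacency))
  cl_B <- stage("clusters_B", extract_clusters(res_B_len, config$min_cluster,
                                               config$adjacency))
  tab_A <- stage("structures_A", tabulate_structures(res_A, cl_A, atlas))
  tab_B <- stage("structures_B", tabulate_structures(res_B_len, cl_B, atlas))

  conj <- stage("conjunction", classify(res_A$z, res_B$z, inc$mask, z_star,
                                        grid = cohort$grid))
  fr <- selective_fractions(conj)
  conj_tab <- stage("conjunction_table", conjunction_table(conj, atlas))
  logf("conjunction: A-only %d, B-only %d, both %d", conj$counts$A_only,
       conj$counts$B_only, conj$counts$both)

  manifest <- list(
    seed = config$seed, n = cohort$n, min_lesioned = inc$min_lesioned,
    n_included = sum(inc$mask), q = config$q, z_star = z_star,
    lenient_mode = config$lenient_mode,
    n_sig_fdr_A = sum(res_A$sig), n_sig_lenient_A = sum(res_A_len$sig),
    n_sig_lenient_B = sum(res_B_len$sig),
    n_clusters_A = length(cl_A), n_clusters_B = length(cl_B),
    conjunction = conj$counts,
    selective_pct_A = fr$pct_A_only, selective_pct_B = fr$pct_B_only)

  ov <- overlay_map(cohort)
  if (config$write_volumes) {
    grid <- cohort$grid
    write_volume(ov, grid, file.path(config$out_dir, "overlay.nii.gz"))
    na0 <- function(x) { x[is.na(x)] <- 0; x }
    write_volume(na0(res_A$z), grid, file.path(config$out_dir, "z_A.nii.gz"))
    write_volume(na0(res_B$z), grid, file.path(config$out_dir, "z_B.nii.gz"))
    write_volume(res_A$sig * 1L, grid, file.path(config$out_dir, "sig_fdr_A.nii.gz"))
    write_volume(res_B_len$sig * 1L, grid, file.path(config$out_dir, "sig_lenient_B.nii.gz"))
    write_volume(conj$category, grid, file.path(config$out_dir, "conjunction.nii.gz"))
  }
  wt <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(cluster_table(cl_A), "clusters_A.tsv")
  wt(cluster_table(cl_B), "clusters_B.tsv")
  wt(tab_A, "structures_A.tsv")
  wt(tab_B, "structures_B.tsv")
  wt(conj_tab, "conjunction_table.tsv")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- config
  cfg$synthetic <- NULL  # not YAML-serializable; the seed reproduces it
  yaml::write_yaml(unclass(cfg), file.path(config$out_dir, "config.yaml"))

  invisible(list(cohort = cohort, inclusion = inc, overlay = ov,
                 result_A = res_A, result_B = res_B_len,
                 result_A_lenient = res_A_len,
                 clusters_A = cl_A, clusters_B = cl_B,
                 structures_A = tab_A, structures_B = tab_B,
                 conjunction = conj, conjunction_table = conj_tab,
                 z_star = z_star, truth = truth, manifest = manifest))
}
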