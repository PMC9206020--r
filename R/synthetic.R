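#' Specification of a synthetic stroke cohort
#'
#' Bundles every parameter of the simulated study: grid geometry, the
#' single-hemisphere territory in which lesions grow (emulating
#' middle-cerebral-artery strokes after flipping onto the left
#' hemisphere), the lognormal lesion-volume distribution, two planted
#' critical regions (region B smaller than and partially overlapping
#' region A, so a conjunction of the two maps has shared and selective
#' voxels by construction), the lesion-to-score model for an FMA-like
#' paresis score and a TSRT-like spasticity angle, and the stretch-trial
#' simulator. All randomness flows from `seed`.
#'
#' Lesion-volume parameters are solved from the target cohort moments
#' (mean 31.7 cc, SD 44.7 cc, range clipped to 0.4-182.3 cc). Score
#' models: `score = baseline - effect * |lesion overlap with region| +
#' noise`, clipped to \[0, 66\] for the FMA-like score.
#'
#' @param n_subjects cohort size (default 41).
#' @param seed integer master seed.
#' @param grid a `volume_grid`; default 40 x 48 x 40 voxels at 4 mm.
#' @param territory,region_A,region_B index boxes, each a list of 1-based
#'   inclusive ranges `list(i =, j =, k =)`; regions must lie inside the
#'   territory and B must overlap A without being contained in it.
#' @param lesion_cc_meanlog,lesion_cc_sdlog lognormal parameters of lesion
#'   volume in cc.
#' @param lesion_cc_range clipping range in cc.
#' @param seed_sd per-axis SD (in voxels) of the Gaussian placing lesion
#'   seed voxels around the territory core, concentrating coverage the way
#'   real single-territory strokes do.
#' @param score_A,score_B lists with `name`, `baseline`, `effect`
#'   (score units per overlapping voxel), `noise_sd`, and for A `clip`.
#' @param stretch list of stretch-trial parameters: velocity bands (deg/s),
#'   `n_trials`, `fs`, `start_angle`, `tsrt_slope`, `angle_noise_sd`,
#'   `emg_noise_sd`, `burst_amp`, `gonio_noise_sd`.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(
    n_subjects = 41L, seed = 1L,
    grid = volume_grid(c(40L, 48L, 40L), c(4, 4, 4)),
    territory = list(i = c(3L, 18L), j = c(12L, 40L), k = c(10L, 32L)),
    region_A = list(i = c(8L, 14L), j = c(21L, 30L), k = c(17L, 24L)),
    region_B = list(i = c(9L, 13L), j = c(26L, 33L), k = c(18L, 24L)),
    lesion_cc_meanlog = 2.909, lesion_cc_sdlog = 1.046,
    lesion_cc_range = c(0.4, 182.3),
    seed_sd = c(3, 5, 4),
    score_A = list(name = "FMA_UL", baseline = 66, effect = 0.45,
                   noise_sd = 6, clip = c(0, 66)),
    score_B = list(name = "TSRT", baseline = 135, effect = 0.52,
                   noise_sd = 10, clip = NULL),
    stretch = list(bands = list(slow = c(30, 70), moderate = c(90, 140),
                                fast = c(160, 200)),
                   n_trials = 20L, fs = 1000, start_angle = 40,
                   tsrt_slope = -0.3, angle_noise_sd = 3,
                   emg_noise_sd = 1, burst_amp = 20, gonio_noise_sd = 0)) {
  for (box in list(territory, region_A, region_B)) {
    stopifnot(all(vapply(box, length, integer(1)) == 2L))
  }
  d <- grid$dims
  if (territory$i[1] < 2L || territory$i[2] > d[1] - 1L ||
      territory$j[1] < 2L || territory$j[2] > d[2] - 1L ||
      territory$k[1] < 2L || territory$k[2] > d[3] - 1L) {
    stop("territory must sit strictly inside the grid")
  }
  spec <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
               grid = grid, territory = territory, region_A = region_A,
               region_B = region_B, lesion_cc_meanlog = lesion_cc_meanlog,
               lesion_cc_sdlog = lesion_cc_sdlog,
               lesion_cc_range = lesion_cc_range, seed_sd = seed_sd,
               score_A = score_A, score_B = score_B, stretch = stretch)
  ra <- box_array(grid, region_A)
  rb <- box_array(grid, region_B)
  if (!any(ra & rb) || all(which(rb) %in% which(ra))) {
    stop("region_B must overlap region_A without being contained in it")
  }
  if (!all(which(ra) %in% which(box_array(grid, territory))) ||
      !all(which(rb) %in% which(box_array(grid, territory)))) {
    stop("planted regions must lie inside the territory")
  }
  structure(spec, class = "synthetic_spec")
}

#' Logical array for an index box
#' @param grid a `volume_grid`.
#' @param box list of inclusive 1-based ranges `i`, `j`, `k`.
#' @return 3-D logical array.
#' @export
box_array <- function(grid, box) {
  arr <- array(FALSE, grid$dims)
  arr[box$i[1]:box$i[2], box$j[1]:box$j[2], box$k[1]:box$k[2]] <- TRUE
  arr
}

# Randomized frontier-growth of one connected lesion, restricted to the
# territory. Linear-index arithmetic is safe because the territory is
# strictly interior to the grid.
grow_lesion <- function(seed_lin, target_voxels, terr, dims) {
  nx <- dims[1]
  nxy <- dims[1] * dims[2]
  offs <- c(-1L, 1L, -nx, nx, -nxy, nxy)
  in_mask <- logical(prod(dims))
  in_front <- logical(prod(dims))
  in_mask[seed_lin] <- TRUE
  n <- 1L
  frontier <- seed_lin + offs
  frontier <- frontier[terr[frontier]]
  in_front[frontier] <- TRUE
  while (n < target_voxels && length(frontier) > 0L) {
    j <- sample.int(length(frontier), 1L)
    v <- frontier[j]
    frontier[j] <- frontier[length(frontier)]
    frontier <- frontier[-length(frontier)]
    in_front[v] <- FALSE
    in_mask[v] <- TRUE
    n <- n + 1L
    nb <- v + offs
    nb <- nb[terr[nb] & !in_mask[nb] & !in_front[nb]]
    if (length(nb) > 0L) {
      in_front[nb] <- TRUE
      frontier <- c(frontier, nb)
    }
  }
  in_mask
}

#' Generate the cohort's lesion masks
#'
#' Each subject receives one connected lesion: a seed voxel drawn from a
#' Gaussian around the territory core, grown by randomized frontier
#' expansion to a volume drawn from the clipped lognormal. All lesions lie
#' within the single-hemisphere territory (the post-flip configuration).
#'
#' @param spec a `synthetic_spec`.
#' @return list of `lesion_mask` objects.
#' @export
generate_lesions <- function(spec) {
  set.seed(spec$seed)
  d <- spec$grid$dims
  terr_arr <- box_array(spec$grid, spec$territory)
  terr <- as.vector(terr_arr)
  vox_cc <- prod(spec$grid$voxel_size) / 1000
  cc <- pmin(pmax(stats::rlnorm(spec$n_subjects, spec$lesion_cc_meanlog,
                                spec$lesion_cc_sdlog),
                  spec$lesion_cc_range[1]), spec$lesion_cc_range[2])
  target <- pmax(1L, as.integer(round(cc / vox_cc)))
  target <- pmin(target, sum(terr))
  core <- vapply(spec$territory, mean, numeric(1))
  lapply(seq_len(spec$n_subjects), function(s) {
    ijk <- round(stats::rnorm(3, mean = core, sd = spec$seed_sd))
    ijk <- pmin(pmax(ijk, vapply(spec$territory, `[`, integer(1), 1L)),
                vapply(spec$territory, `[`, integer(1), 2L))
    seed_lin <- ijk[1] + d[1] * (ijk[2] - 1) + d[1] * d[2] * (ijk[3] - 1)
    data <- array(as.integer(grow_lesion(as.integer(seed_lin), target[s],
                                         terr, d)), d)
    lesion_mask(data, spec$grid, sprintf("S%02d", s))
  })
}

#' Generate behavioral scores from lesion-region overlap
#'
#' Implements the lesion-to-deficit model the mapping is designed to
#' detect: each score is its baseline minus an effect proportional to the
#' lesion's overlap with the planted critical region, plus Gaussian noise,
#' with the FMA-like score clipped to its scale. Setting both effects to 0
#' yields a null cohort for type-I-error calibration.
#'
#' @param masks list of `lesion_mask` objects on the spec grid.
#' @param spec a `synthetic_spec`.
#' @return long-format score data frame with attribute `truth` holding the
#'   per-subject region overlaps.
#' @export
generate_scores <- function(masks, spec) {
  set.seed(spec$seed + 1L)
  ra <- box_array(spec$grid, spec$region_A)
  rb <- box_array(spec$grid, spec$region_B)
  ov_a <- vapply(masks, function(m) sum(m$data[ra]), numeric(1))
  ov_b <- vapply(masks, function(m) sum(m$data[rb]), numeric(1))
  n <- length(masks)
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  a <- spec$score_A$baseline - spec$score_A$effect * ov_a +
    stats::rnorm(n, 0, spec$score_A$noise_sd)
  if (!is.null(spec$score_A$clip)) {
    a <- pmin(pmax(a, spec$score_A$clip[1]), spec$score_A$clip[2])
  }
  b <- spec$score_B$baseline - spec$score_B$effect * ov_b +
    stats::rnorm(n, 0, spec$score_B$noise_sd)
  if (!is.null(spec$score_B$clip)) {
    b <- pmin(pmax(b, spec$score_B$clip[1]), spec$score_B$clip[2])
  }
  scores <- rbind(
    data.frame(subject_id = ids, score = spec$score_A$name, value = a,
               stringsAsFactors = FALSE),
    data.frame(subject_id = ids, score = spec$score_B$name, value = b,
               stringsAsFactors = FALSE))
  attr(scores, "truth") <- data.frame(subject_id = ids, overlap_A = ov_a,
                                      overlap_B = ov_b,
                                      stringsAsFactors = FALSE)
  scores
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' @param spec a `synthetic_spec`.
#' @return list with `cohort` (a `lesion_cohort`) and `truth` (planted
#'   region arrays, per-subject overlaps, spec parameters).
#' @export
generate_cohort <- function(spec = synthetic_spec()) {
  masks <- generate_lesions(spec)
  scores <- generate_scores(masks, spec)
  cohort <- lesion_cohort(masks, scores)
  list(cohort = cohort,
       truth = list(region_A = box_array(spec$grid, spec$region_A),
                    region_B = box_array(spec$grid, spec$region_B),
                    overlaps = attr(scores, "truth"), spec = spec))
}

#' Simulate one subject's stretch-trial series
#'
#' Each trial is a constant-velocity ramp from the starting angle toward
#' full extension, preceded by a rest phase. The reflex EMG burst begins
#' when the ramp crosses the planted dynamic threshold
#' `tsrt_true + tsrt_slope * velocity`, perturbed per trial by Gaussian
#' angle noise; trials whose threshold is never reached carry no burst and
#' exercise the exclusion path. Baseline EMG is Gaussian noise.
#'
#' @param tsrt_true planted TSRT angle in degrees.
#' @param spec a `synthetic_spec` (its `stretch` element is used).
#' @param seed integer seed for this subject's series.
#' @return list of `stretch_trial` objects (one per stretch, velocities
#'   equally distributed between the slow/moderate/fast bands in
#'   randomized order).
#' @export
generate_stretch_cohort <- function(tsrt_true, spec = synthetic_spec(),
                                    seed = spec$seed) {
  st <- spec$stretch
  set.seed(seed)
  bands <- rep(names(st$bands), length.out = st$n_trials)
  bands <- sample(bands)
  lapply(seq_len(st$n_trials), function(i) {
    band <- st$bands[[bands[i]]]
    v <- stats::runif(1, band[1], band[2])
    fs <- st$fs
    n_rest <- as.integer(round(0.6 * fs))
    ramp_len <- as.integer(ceiling((180 - st$start_angle) / v * fs))
    n_hold <- as.integer(round(0.25 * fs))
    angle <- c(rep(st$start_angle, n_rest),
               st$start_angle + v / fs * seq_len(ramp_len),
               rep(180, n_hold))
    angle <- pmin(angle, 180)
    if (st$gonio_noise_sd > 0) {
      angle <- pmin(pmax(angle + stats::rnorm(length(angle), 0, st$gonio_noise_sd), 0), 180)
    }
    emg <- stats::rnorm(length(angle), 0, st$emg_noise_sd)
    theta <- tsrt_true + st$tsrt_slope * v + stats::rnorm(1, 0, st$angle_noise_sd)
    cross <- which(angle >= theta & seq_along(angle) > n_rest)
    if (length(cross) > 0L) {
      burst_from <- cross[1]
      burst_to <- n_rest + ramp_len + n_hold
      emg[burst_from:burst_to] <- emg[burst_from:burst_to] + st$burst_amp
    }
    stretch_trial(angle, emg, fs, trial_id = sprintf("T%02d", i),
                  nominal_speed = bands[i])
  })
}

#' Deterministic toy atlas parcellation
#'
#' Partitions a left-hemisphere box into 16 rectangular parcels named
#' `parcel_01` ... `parcel_16`; everything else is unlabeled. A stand-in
#' label volume for tabulation logic, which is atlas-agnostic; it is
#' synthetic and carries no anatomical meaning.
#'
#' @param grid a `volume_grid`.
#' @return an `atlas_volume` with 16 structures.
#' @export
toy_atlas <- function(grid) {
  d <- grid$dims
  box <- list(i = c(2L, max(3L, d[1] %/% 2 - 1L)),
              j = c(max(2L, d[2] %/% 5), min(d[2] - 1L, d[2] - d[2] %/% 8)),
              k = c(max(2L, d[3] %/% 5), min(d[3] - 1L, d[3] - d[3] %/% 6)))
  cuts <- function(rng, parts) {
    br <- round(seq(rng[1], rng[2] + 1L, length.out = parts + 1L))
    list(lo = br[-(parts + 1L)], hi = br[-1] - 1L)
  }
  ci <- cuts(box$i, 2L)
  cj <- cuts(box$j, 4L)
  ck <- cuts(box$k, 2L)
  labels <- array(0L, d)
  lab <- 0L
  for (a in 1:2) for (b in 1:4) for (cc in 1:2) {
    lab <- lab + 1L
    labels[ci$lo[a]:ci$hi[a], cj$lo[b]:cj$hi[b], ck$lo[cc]:ck$hi[cc]] <- lab
  }
  nm <- stats::setNames(sprintf("parcel_%02d", 1:16), as.character(1:16))
  atlas_volume(labels, grid, nm)
}
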