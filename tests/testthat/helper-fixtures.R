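# Shared fixtures and independent oracles.

tiny_grid <- function(dims = c(10L, 8L, 6L), vs = c(2, 2, 2)) {
  volume_grid(dims, vs)
}

# Mask with given 1-based voxel indices lesioned.
mask_at <- function(grid, ijk, id = "s1") {
  arr <- array(0L, grid$dims)
  ijk <- rbind(ijk)
  arr[ijk] <- 1L
  lesion_mask(arr, grid, id)
}

# A small cohort from per-subject voxel-index lists plus one score vector.
tiny_cohort <- function(grid, lesion_lists, scores, score_name = "FMA_UL") {
  masks <- lapply(seq_along(lesion_lists), function(i) {
    mask_at(grid, lesion_lists[[i]], sprintf("s%02d", i))
  })
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  lesion_cohort(masks, data.frame(subject_id = ids, score = score_name,
                                  value = scores))
}

# Exhaustive-permutation oracle for the rank-sum test: one-sided p that the
# lesioned group's rank sum is as small or smaller, over all assignments.
perm_rank_oracle <- function(lesioned, intact) {
  all_scores <- c(lesioned, intact)
  n1 <- length(lesioned)
  r <- rank(all_scores)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(all_scores), n1)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  list(p = mean(stats <= obs),
       p_mid = mean(stats < obs) + 0.5 * mean(stats == obs),
       rank_sum = obs, U = obs - n1 * (n1 + 1) / 2)
}

# Brute-force Benjamini-Hochberg step-up rule.
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k) > 0L) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

dice_coef <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

# Bernoulli-lesion cohort: spatially independent lesion patterns, scores
# independent of lesions. For type-I-error checks.
bernoulli_cohort <- function(n = 41L, dims = c(10L, 10L, 5L), p_lesion = 0.3,
                             seed = 1L) {
  set.seed(seed)
  grid <- volume_grid(dims, c(2, 2, 2))
  masks <- lapply(seq_len(n), function(i) {
    lesion_mask(array(stats::rbinom(prod(dims), 1L, p_lesion), dims), grid,
                sprintf("s%02d", i))
  })
  ids <- vapply(masks, function(m) m$subject_id, character(1))
  lesion_cohort(masks, data.frame(subject_id = ids, score = "FMA_UL",
                                  value = round(stats::runif(n, 10, 60))))
}

# Simulated dynamic thresholds on a planted line, velocities split equally
# over the three nominal bands.
simulate_thresholds <- function(tsrt_true = 107.4, slope = -0.3,
                                noise_sd = 3, n = 20L) {
  bands <- list(c(30, 70), c(90, 140), c(160, 200))
  v <- unlist(lapply(seq_len(n), function(i) {
    b <- bands[[(i - 1L) %% 3L + 1L]]
    stats::runif(1, b[1], b[2])
  }))
  data.frame(angle_deg = tsrt_true + slope * v + stats::rnorm(n, 0, noise_sd),
             velocity_dps = v)
}
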