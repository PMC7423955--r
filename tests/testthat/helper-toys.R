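# shared toy builders for the suite

kT300 <- fepcycle::kBT(300)

harmonic_spec <- function(k0 = 1, k1 = 2, ...) {
  toy_potential("harmonic", spring_constant_initial = k0,
                spring_constant_final = k1, ...)
}

# small seeded transformation used where statistical precision is not
# the point
quick_transformation <- function(seed, k0 = 1, k1 = 2, n_windows = 4,
                                 n_steps = 4000) {
  generate_transformation(harmonic_spec(k0, k1), n_windows, n_steps,
                          seed = seed)
}

# independent brute-force root of Bennett's implicit equation by grid
# refinement (no reuse of the package's solver)
bar_grid_oracle <- function(fw, rv, temperature) {
  kT <- fepcycle::kBT(temperature)
  obj <- function(C) {
    sum(1 / (1 + exp((fw - C) / kT))) - sum(1 / (1 + exp((rv + C) / kT)))
  }
  lo <- min(-rv, fw) - 30
  hi <- max(-rv, fw) + 30
  for (pass in 1:60) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, obj, numeric(1))
    i <- which(vals >= 0)[1]
    if (is.na(i) || i == 1) i <- 2
    lo <- grid[i - 1]
    hi <- grid[i]
    if (hi - lo < 1e-10) break
  }
  C <- (lo + hi) / 2
  C - kT * log(length(rv) / length(fw))
}

# brute-force O(N*M) neighbour count with strict inequality
count_within_oracle <- function(ref, probe, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(probe))) {
    dmin <- Inf
    for (j in seq_len(nrow(ref))) {
      dmin <- min(dmin, sqrt(sum((probe[i, ] - ref[j, ])^2)))
    }
    if (dmin < cutoff) n <- n + 1L
  }
  n
}

# independent greedy leader clustering oracle over a precomputed
# distance matrix
reverse_cluster_oracle <- function(dist_mat, scores, cutoff) {
  ord <- order(-ifelse(is.na(scores), -Inf, scores), seq_along(scores))
  reps <- integer(0)
  assign <- integer(length(scores))
  for (i in ord) {
    d <- dist_mat[i, reps]
    if (length(reps) == 0 || all(d > cutoff)) {
      reps <- c(reps, i)
      assign[i] <- i
    } else {
      assign[i] <- reps[which.min(d)]
    }
  }
  list(representatives = reps, assignment = assign)
}

random_pose_set <- function(n_poses, n_atoms, spread = 2, seed) {
  set.seed(seed)
  base <- matrix(rnorm(n_atoms * 3), ncol = 3)
  lapply(seq_len(n_poses), function(i) {
    pose(paste0("p", i), base + matrix(rnorm(n_atoms * 3, sd = spread),
                                       ncol = 3),
         score = runif(1))
  })
}
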