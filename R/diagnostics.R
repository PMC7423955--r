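#' Forward/reverse work-distribution overlap
#'
#' Convergence diagnostic for a lambda window: histograms of the forward
#' work and the negated reverse work on a shared grid spanning the
#' pooled samples. Well-converged windows show strongly overlapping,
#' unimodal distributions; floppy or charged degrees of freedom that
#' sample non-overlapping phase space produce separated or bimodal
#' histograms. The overlap coefficient
#' \eqn{\sum_i \min(p_F, p_R) \, \Delta w} lies in \[0, 1\].
#'
#' @param forward_w forward work samples, kcal/mol
#' @param reverse_w reverse work samples, kcal/mol (negated internally)
#' @param n_bins number of histogram bins (>= 2), default 50
#' @return object of class `overlap_report`: list with `bin_edges`,
#'   `density_forward`, `density_reverse_negated` (each integrating to 1
#'   on the grid) and `overlap_coefficient`
#' @examples
#' w <- rnorm(1000)
#' work_overlap(w, -w)$overlap_coefficient # 1: identical distributions
#' @export
work_overlap <- function(forward_w, reverse_w, n_bins = 50) {
  if (length(forward_w) == 0 || length(reverse_w) == 0) {
    stop("both sample sets must be non-empty")
  }
  if (n_bins < 2) stop("n_bins must be >= 2")
  f <- forward_w
  r <- -reverse_w
  pooled <- c(f, r)
  lo <- min(pooled)
  hi <- max(pooled)
  if (lo == hi) {
    # all mass in one point for both distributions: complete overlap
    edges <- seq(lo - 0.5, hi + 0.5, length.out = n_bins + 1)
    width <- diff(edges)[1]
    df <- dr <- numeric(n_bins)
    idx <- findInterval(lo, edges, rightmost.closed = TRUE)
    df[idx] <- dr[idx] <- 1 / width
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1)
    width <- diff(edges)[1]
    bin_of <- function(x) pmin(pmax(findInterval(x, edges,
                                                 rightmost.closed = TRUE),
                                    1L), n_bins)
    df <- tabulate(bin_of(f), n_bins) / (length(f) * width)
    dr <- tabulate(bin_of(r), n_bins) / (length(r) * width)
  }
  structure(list(bin_edges = edges,
                 density_forward = df,
                 density_reverse_negated = dr,
                 overlap_coefficient = sum(pmin(df, dr)) * width),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("work overlap coefficient %.4f over %d bins\n",
              x$overlap_coefficient, length(x$density_forward)))
  invisible(x)
}

#' Hysteresis between independent forward and reverse transformations
#'
#' Free energy is a state function: a transformation computed A -> B and
#' the independently computed B -> A must sum to zero up to statistical
#' error. The discrepancy `forward_total$value + reverse_total$value` is
#' reported with its root-sum-square standard error and flagged when it
#' exceeds twice that error.
#'
#' @param forward_total accumulated [fe_estimate()] for the forward
#'   transformation
#' @param reverse_total accumulated [fe_estimate()] for the opposite
#'   direction, computed from its own simulations
#' @return list with `discrepancy` (kcal/mol), `stderr`, and logical
#'   `flagged`
#' @export
hysteresis <- function(forward_total, reverse_total) {
  stopifnot(inherits(forward_total, "fe_estimate"),
            inherits(reverse_total, "fe_estimate"))
  d <- forward_total$value + reverse_total$value
  se <- sqrt(forward_total$stderr^2 + reverse_total$stderr^2)
  list(discrepancy = d, stderr = se, flagged = abs(d) > 2 * se)
}

#' Wrap angles into the principal interval (-180, 180]
#'
#' @param angles angles in degrees
#' @return equivalent angles in (-180, 180]
#' @export
wrap_angle <- function(angles) {
  w <- angles %% 360
  ifelse(w > 180, w - 360, w)
}

#' Circular mean of dihedral angle samples
#'
#' Mean direction of angular data (e.g. a side-chain chi1 dihedral over
#' a trajectory) via the resultant of unit vectors: atan2 of the mean
#' sine and cosine. The resultant length in \[0, 1\] measures
#' concentration; for nearly uniform data (length below 1e-9) the mean
#' direction is undefined and an error is raised.
#'
#' @param angles angles in degrees (wrapped internally)
#' @return list with `mean` (degrees in (-180, 180\]) and
#'   `resultant_length`
#' @examples
#' circular_mean(c(10, 350)) # mean 0, tight cluster across the wrap
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0) stop("empty angle sample")
  rad <- wrap_angle(angles) * pi / 180
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  R <- sqrt(s^2 + c_^2)
  if (R < 1e-9) {
    stop("resultant length < 1e-9: circular mean undefined for ",
         "(near-)uniform angles")
  }
  list(mean = wrap_angle(atan2(s, c_) * 180 / pi), resultant_length = R)
}

#' Polar histogram counts for angle samples
#'
#' Bins wrapped angles into equal-width sectors for polar-coordinate
#' histograms of dihedral distributions.
#'
#' @param angles angles in degrees
#' @param n_bins number of sectors, default 36 (10 degree bins)
#' @return data frame with `bin_low`, `bin_high` (degrees, covering
#'   (-180, 180\]) and `count`
#' @export
angle_histogram <- function(angles, n_bins = 36) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  w <- wrap_angle(angles)
  edges <- seq(-180, 180, length.out = n_bins + 1)
  idx <- pmin(pmax(ceiling((w + 180) / (360 / n_bins)), 1L), n_bins)
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             count = tabulate(idx, n_bins))
}

#' Count probe points within a cutoff of a reference set
#'
#' Number of probe points whose minimum distance to any reference point
#' is strictly less than the cutoff — the primitive behind hydration
#' counts (waters within 3 A of a residue) and overlap pruning (waters
#' within 2 A of a ligand).
#'
#' @param reference_points numeric matrix, one point per row (non-empty)
#' @param probe_points numeric matrix, one point per row, same dimension
#' @param cutoff distance cutoff, Angstrom (> 0); strict `<` comparison
#' @return integer count
#' @examples
#' count_within(rbind(c(0, 0, 0)), rbind(c(1, 0, 0), c(4, 0, 0)), 3) # 1
#' @export
count_within <- function(reference_points, probe_points, cutoff) {
  reference_points <- as.matrix(reference_points)
  probe_points <- as.matrix(probe_points)
  if (nrow(reference_points) == 0) stop("empty reference set")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (nrow(probe_points) == 0) return(0L)
  if (ncol(reference_points) != ncol(probe_points)) {
    stop("reference and probe points must share a dimension")
  }
  # squared-distance matrix probes x references
  pp <- rowSums(probe_points^2)
  rr <- rowSums(reference_points^2)
  d2 <- outer(pp, rr, "+") - 2 * probe_points %*% t(reference_points)
  mind2 <- apply(d2, 1, min)
  sum(mind2 < cutoff^2)
}

#' Per-frame neighbour counts with mean and standard deviation
#'
#' Applies [count_within()] to each frame of a trajectory and aggregates
#' as mean and standard deviation, the form in which hydration numbers
#' are reported with error bars.
#'
#' @param reference_frames list of reference-point matrices, one per
#'   frame
#' @param probe_frames list of probe-point matrices, one per frame (same
#'   length)
#' @param cutoff distance cutoff, Angstrom
#' @return list with `counts` (integer per frame), `mean` and `sd`
#' @export
count_within_frames <- function(reference_frames, probe_frames, cutoff) {
  if (length(reference_frames) != length(probe_frames)) {
    stop("frame lists must have equal length")
  }
  counts <- mapply(count_within, reference_frames, probe_frames,
                   MoreArgs = list(cutoff = cutoff))
  list(counts = as.integer(counts), mean = mean(counts),
       sd = if (length(counts) > 1) stats::sd(counts) else 0)
}
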