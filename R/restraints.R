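#' Flat-bottom distance restraint definition
#'
#' One-sided harmonic wall used to tame hypermobile charged side chains
#' during alchemical legs: the restraint contributes nothing while the
#' restrained pair distance stays at or below the upper wall, and rises
#' harmonically beyond it. Wall positions are chosen so the restraint
#' energy is exactly zero on the physical end-state structures.
#'
#' @param pair_label identifier for the restrained atom pair
#' @param upper_wall wall position, Angstrom (> 0)
#' @param force_constant wall force constant k, kcal/mol/A^2 (>= 0);
#'   the protocol default is 10
#' @return object of class `flat_bottom_restraint`
#' @export
flat_bottom_restraint <- function(pair_label, upper_wall,
                                  force_constant = 10) {
  if (!is.finite(upper_wall) || upper_wall <= 0) {
    stop("upper_wall must be > 0")
  }
  if (!is.finite(force_constant) || force_constant < 0) {
    stop("force_constant must be >= 0")
  }
  structure(list(pair_label = as.character(pair_label),
                 upper_wall = upper_wall, force_constant = force_constant),
            class = "flat_bottom_restraint")
}

#' @export
print.flat_bottom_restraint <- function(x, ...) {
  cat(sprintf("flat-bottom restraint %s: wall %.3f A, k = %g kcal/mol/A^2\n",
              x$pair_label, x$upper_wall, x$force_constant))
  invisible(x)
}

#' Flat-bottom restraint energy
#'
#' \deqn{E(d) = 0 \quad (d \le wall), \qquad
#'       E(d) = \frac{k}{2}(d - wall)^2 \quad (d > wall)}
#' Continuous and once-differentiable at the wall; zero below it.
#'
#' @param distance pair distance(s), Angstrom (>= 0); vectorised
#' @param restraint a [flat_bottom_restraint()]
#' @return energy in kcal/mol
#' @examples
#' r <- flat_bottom_restraint("NH1-OD1", upper_wall = 4.7)
#' restraint_energy(c(4.0, 4.7, 5.7), r) # 0, 0, 5
#' @export
restraint_energy <- function(distance, restraint) {
  stopifnot(inherits(restraint, "flat_bottom_restraint"))
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("distance must be finite and >= 0")
  }
  excess <- pmax(distance - restraint$upper_wall, 0)
  0.5 * restraint$force_constant * excess^2
}

#' Propose upper walls from equilibrium distance series
#'
#' Places each wall at the maximum distance observed in the pair's
#' unrestrained equilibrium series plus a safety margin, guaranteeing
#' the restraint energy is exactly zero on every calibration frame
#' while still confining excursions beyond the native range.
#'
#' @param distance_samples named list of non-empty numeric distance
#'   series (Angstrom), one per restrained pair
#' @param margin extra clearance added to the observed maximum,
#'   Angstrom (>= 0), default 0.5
#' @param force_constant wall force constant for the proposed
#'   restraints, kcal/mol/A^2
#' @return named list of [flat_bottom_restraint()] objects
#' @examples
#' propose_upper_walls(list(`R208-D119` = c(4.0, 4.2, 3.9)))
#' @export
propose_upper_walls <- function(distance_samples, margin = 0.5,
                                force_constant = 10) {
  if (length(distance_samples) == 0) stop("no distance series supplied")
  if (margin < 0) stop("margin must be >= 0")
  labels <- names(distance_samples)
  if (is.null(labels)) labels <- paste0("pair", seq_along(distance_samples))
  out <- lapply(seq_along(distance_samples), function(i) {
    s <- distance_samples[[i]]
    if (length(s) == 0) stop("empty distance series for pair ", labels[i])
    if (any(!is.finite(s)) || any(s < 0)) {
      stop("invalid distances for pair ", labels[i])
    }
    flat_bottom_restraint(labels[i], max(s) + margin, force_constant)
  })
  names(out) <- labels
  out
}
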