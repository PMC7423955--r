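#' Result of one alchemical leg of the thermodynamic cycle
#'
#' The relative binding free energy of a protein mutation is assembled
#' from two alchemical legs: mutating the residue in the ligand-free
#' (apo) protein and in the ligand-bound (holo) protein. The binding
#' free energy change is the difference of the holo and apo mutation
#' free energies.
#'
#' @param leg `"apo"` or `"holo"`
#' @param mutation mutation name, e.g. `"D112E"`
#' @param estimate accumulated [fe_estimate()] for the leg
#' @param system_label label keying this leg into correction tables
#'   (e.g. `"apo"`, `"gbi1"`, `"gbi2"`); defaults to `leg`
#' @return object of class `leg_result`
#' @export
leg_result <- function(leg = c("apo", "holo"), mutation, estimate,
                       system_label = NULL) {
  leg <- match.arg(leg)
  stopifnot(inherits(estimate, "fe_estimate"))
  if (is.null(system_label)) system_label <- leg
  structure(list(leg = leg, mutation = as.character(mutation),
                 estimate = estimate,
                 system_label = as.character(system_label)),
            class = "leg_result")
}

#' @export
print.leg_result <- function(x, ...) {
  cat(sprintf("%s leg of %s (%s): dG = %.4f +- %.4f kcal/mol\n",
              x$leg, x$mutation, x$system_label, x$estimate$value,
              x$estimate$stderr))
  invisible(x)
}

#' Relative binding free energy from apo and holo legs
#'
#' \deqn{\Delta\Delta G = \Delta G_{holo} - \Delta G_{apo}} with the
#' root-sum-square of the two legs' standard errors.
#'
#' @param apo apo-leg [leg_result()]
#' @param holo holo-leg [leg_result()] for the same mutation
#' @return list with `mutation`, `value`, `stderr` (kcal/mol)
#' @examples
#' a <- leg_result("apo", "D112E", fe_estimate(1, 0.3, "bar"))
#' h <- leg_result("holo", "D112E", fe_estimate(2, 0.4, "bar"))
#' ddg(a, h) # 1.0 +- 0.5
#' @export
ddg <- function(apo, holo) {
  stopifnot(inherits(apo, "leg_result"), inherits(holo, "leg_result"))
  if (apo$leg != "apo" || holo$leg != "holo") {
    stop("ddg expects one apo leg and one holo leg, in that order")
  }
  if (apo$mutation != holo$mutation) {
    stop(sprintf("mismatched mutations: apo '%s' vs holo '%s'",
                 apo$mutation, holo$mutation))
  }
  list(mutation = apo$mutation,
       value = holo$estimate$value - apo$estimate$value,
       stderr = sqrt(apo$estimate$stderr^2 + holo$estimate$stderr^2))
}

#' Orient a ddG into the canonical wild-type-to-mutant direction
#'
#' Transformations run in the reversed direction (mutant prepared
#' first, e.g. S211R instead of R211S) estimate the negative of the
#' canonical quantity; comparison on a common scale uses
#' -1 x the reversed value, with the standard error unchanged.
#' Orienting twice with `direction = "reversed"` returns the original
#' value.
#'
#' @param ddg_value ddG value, kcal/mol (or a list with `value` and
#'   `stderr` as returned by [ddg()])
#' @param direction `"forward"` (unchanged) or `"reversed"` (negated)
#' @return same shape as the input with the value oriented
#' @export
orient <- function(ddg_value, direction = c("forward", "reversed")) {
  direction <- match.arg(direction)
  flip <- if (direction == "reversed") -1 else 1
  if (is.list(ddg_value)) {
    ddg_value$value <- flip * ddg_value$value
    ddg_value
  } else {
    flip * ddg_value
  }
}

#' Apply additive per-leg corrections (e.g. finite-size charge
#' corrections)
#'
#' Charge-changing mutations in periodic electrostatics acquire an
#' artefactual contribution from the uniform neutralizing background;
#' analytical corrections are additive constants per leg, keyed by the
#' leg's system label. Each leg value is shifted by its correction
#' (standard errors unchanged); a leg with no entry gets 0 with a
#' warning. Because the correction is nearly identical for apo and holo
#' legs, the induced change in each ddG
#' (`holo_correction - apo_correction`) is typically negligible even
#' when the individual corrections are not.
#'
#' @param legs list of [leg_result()] objects
#' @param corrections named numeric vector of corrections, kcal/mol,
#'   keyed by system label
#' @return list with `legs` (corrected) and `applied` (data frame of
#'   label and correction used)
#' @export
apply_corrections <- function(legs, corrections) {
  stopifnot(all(vapply(legs, inherits, logical(1), "leg_result")))
  if (any(!is.finite(corrections))) stop("non-finite correction value")
  used <- numeric(length(legs))
  out <- lapply(seq_along(legs), function(i) {
    leg <- legs[[i]]
    corr <- unname(corrections[leg$system_label])
    if (is.na(corr)) {
      warning(sprintf("no correction for system '%s'; using 0",
                      leg$system_label))
      corr <- 0
    }
    used[i] <<- corr
    leg$estimate$value <- leg$estimate$value + corr
    leg
  })
  list(legs = out,
       applied = data.frame(
         system_label = vapply(legs, `[[`, character(1), "system_label"),
         mutation = vapply(legs, `[[`, character(1), "mutation"),
         leg = vapply(legs, `[[`, character(1), "leg"),
         correction = as.numeric(used)))
}

#' Shift in a ddG induced by per-leg corrections
#'
#' @param apo_correction,holo_correction additive leg corrections,
#'   kcal/mol
#' @return the change in ddG, `holo_correction - apo_correction`
#' @examples
#' ddg_correction_shift(-3.1042, -3.1030) # +0.0012
#' @export
ddg_correction_shift <- function(apo_correction, holo_correction) {
  holo_correction - apo_correction
}

#' Free energy equivalent of a fold change in an equilibrium constant
#'
#' \deqn{\Delta G = k_B T \ln(fold)}; at 300 K a 10-fold change in the
#' binding constant corresponds to about 1.4 kcal/mol, the width of the
#' agreement band used when comparing computed and experimental ddG.
#'
#' @param temperature temperature, Kelvin (> 0)
#' @param fold fold change (> 0)
#' @return kcal/mol
#' @examples
#' fold_change_threshold(300, 10) # 1.3726...
#' @export
fold_change_threshold <- function(temperature, fold) {
  if (fold <= 0) stop("fold must be > 0")
  kBT(temperature) * log(fold)
}

#' Compare computed ddG values against an experimental table
#'
#' Per-mutation deviations and the mean absolute error (MAE) of
#' computed relative binding free energies against experimental
#' reference values, with a band flag marking mutations whose deviation
#' stays within the free energy equivalent of a given fold change in
#' the binding constant (default: 10-fold at 300 K, ~1.4 kcal/mol).
#' The MAE is computed at full precision and also reported rounded to
#' 0.1 kcal/mol, the precision at which such tables are typically
#' printed.
#'
#' @param computed data frame with columns `mutation` and `ddg`
#'   (kcal/mol), optionally `stderr`
#' @param table experimental records: data frame with columns
#'   `mutation`, `ddg_expt_kcal_mol`, `err_expt_kcal_mol` (see
#'   [read_experiment_table()])
#' @param exclude character vector of mutation names to drop from the
#'   MAE (still listed per-mutation), or NULL
#' @param temperature band temperature, Kelvin
#' @param fold fold change defining the agreement band
#' @return list with `per_mutation` (data frame: mutation, computed,
#'   experimental, deviation, included, within_band), `mae`,
#'   `mae_rounded`, `band_kcal_mol`, `n_included`
#' @export
compare_to_experiment <- function(computed, table, exclude = NULL,
                                  temperature = 300, fold = 10) {
  req <- c("mutation", "ddg")
  if (!all(req %in% names(computed))) {
    stop("computed must have columns 'mutation' and 'ddg'")
  }
  missing_mut <- setdiff(computed$mutation, table$mutation)
  if (length(missing_mut) > 0) {
    stop("mutations absent from the experimental table: ",
         paste(missing_mut, collapse = ", "))
  }
  m <- match(computed$mutation, table$mutation)
  dev <- computed$ddg - table$ddg_expt_kcal_mol[m]
  band <- fold_change_threshold(temperature, fold)
  included <- !(computed$mutation %in% exclude)
  if (!any(included)) stop("no mutations left after exclusion")
  per <- data.frame(mutation = computed$mutation,
                    ddg_computed = computed$ddg,
                    ddg_expt = table$ddg_expt_kcal_mol[m],
                    err_expt = table$err_expt_kcal_mol[m],
                    deviation = dev,
                    included = included,
                    within_band = abs(dev) <= band)
  mae <- mean(abs(dev[included]))
  list(per_mutation = per, mae = mae, mae_rounded = round(mae, 1),
       band_kcal_mol = band, n_included = sum(included))
}
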