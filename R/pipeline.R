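#' Read a run manifest
#'
#' A YAML (or JSON) description of a full cycle analysis:
#'
#' ```yaml
#' temperature: 300
#' seed: 42
#' estimator: {method: bar, decorrelate: true, tolerance: 1.0e-8}
#' experiment_table: path/to/table.csv   # optional
#' corrections: path/to/corrections.csv  # optional
#' exclude_from_mae: [R211S]             # optional
#' mutations:
#'   - name: D112E
#'     direction: forward
#'     apo:  {type: toy_harmonic, k_initial: 1, k_final: 2,
#'            n_windows: 4, n_steps: 5000}
#'     holo: {type: fepout, forward: fwd.fepout, reverse: rev.fepout,
#'            system_label: gbi2}
#' ```
#'
#' Leg sources may be `toy_harmonic` (simulated with
#' [generate_transformation()]), `fepout` or `csv` (paired
#' forward/reverse files). Neither the temperature nor the seed has a
#' default: both must be stated and both are echoed in the report.
#'
#' @param path manifest path (`.yaml`/`.yml` or `.json`)
#' @return manifest list
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  manifest <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  .validate_manifest(manifest)
  manifest
}

.validate_manifest <- function(manifest) {
  if (is.null(manifest$temperature)) {
    stop("manifest must state a temperature (no silent default)")
  }
  if (manifest$temperature <= 0) stop("manifest temperature must be > 0")
  if (is.null(manifest$seed)) {
    stop("manifest must state a seed (no silent default)")
  }
  if (is.null(manifest$mutations) || length(manifest$mutations) == 0) {
    stop("manifest lists no mutations")
  }
  for (m in manifest$mutations) {
    if (is.null(m$name)) stop("a mutation entry has no name")
    for (leg in c("apo", "holo")) {
      if (is.null(m[[leg]])) {
        stop(sprintf("mutation %s: missing %s leg", m$name, leg))
      }
      src <- m[[leg]]
      if (is.null(src$type) ||
          !src$type %in% c("toy_harmonic", "fepout", "csv")) {
        stop(sprintf("mutation %s, %s leg: unknown source type", m$name, leg))
      }
      if (src$type %in% c("fepout", "csv")) {
        for (p in c(src$forward, src$reverse)) {
          if (is.null(p) || !file.exists(p)) {
            stop(sprintf("mutation %s, %s leg: missing file '%s'",
                         m$name, leg, if (is.null(p)) "<unset>" else p))
          }
        }
      }
    }
  }
  invisible(manifest)
}

# build the window list for one leg source
.leg_windows <- function(src, temperature, seed, leg_index) {
  if (src$type == "toy_harmonic") {
    spec <- toy_potential(
      "harmonic",
      spring_constant_initial = src$k_initial,
      spring_constant_final = src$k_final,
      center_initial = if (is.null(src$center_initial)) 0 else
        src$center_initial,
      center_final = if (is.null(src$center_final)) 0 else src$center_final,
      temperature = temperature)
    n_windows <- if (is.null(src$n_windows)) 10L else as.integer(src$n_windows)
    n_steps <- if (is.null(src$n_steps)) 10000L else as.integer(src$n_steps)
    generate_transformation(spec, n_windows, n_steps,
                            seed = .window_seed(seed, 1000L * leg_index, 0L))
  } else if (src$type == "fepout") {
    pair_directions(parse_fepout(src$forward), parse_fepout(src$reverse),
                    temperature = temperature)
  } else {
    pair_directions(read_window_csv(src$forward, temperature),
                    read_window_csv(src$reverse, temperature),
                    temperature = temperature)
  }
}

#' Run the full thermodynamic-cycle pipeline from a manifest
#'
#' For every mutation: obtain apo and holo per-window samples (simulate
#' or parse), subsample each direction to effectively independent
#' observations, estimate each window (BAR by default), accumulate
#' across windows with root-sum-square errors, apply any per-leg
#' additive corrections, assemble ddG = dG_holo - dG_apo, orient
#' reversed-direction mutations into the canonical wild-type-to-mutant
#' convention, and (when an experimental table is given) compare with
#' per-mutation deviations and the MAE. Identical manifest and seed
#' give an identical report.
#'
#' @param manifest manifest list (see [read_manifest()]) or a path
#' @param out_dir optional directory; when given, writes
#'   `cycle_report.csv`, `per_window.csv` and `run_info.json`
#' @param verbose print one progress line per pipeline stage?
#' @return list with `settings` (echoed seed, temperature, estimator),
#'   `legs` (per-leg accumulated estimates, data frame), `cycle` (per
#'   mutation: ddg, stderr, corrections applied), `comparison` (from
#'   [compare_to_experiment()], or NULL), `per_window` (data frame)
#' @export
run_pipeline <- function(manifest, out_dir = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  .validate_manifest(manifest)
  Tk <- manifest$temperature
  seed <- as.integer(manifest$seed)
  est <- manifest$estimator
  method <- if (is.null(est$method)) "bar" else est$method
  decorr <- if (is.null(est$decorrelate)) TRUE else isTRUE(est$decorrelate)
  tol <- if (is.null(est$tolerance)) 1e-8 else est$tolerance
  corrections <- if (!is.null(manifest$corrections)) {
    read_corrections(manifest$corrections)
  } else NULL

  say <- function(...) if (verbose) message(sprintf(...))
  legs_rows <- list()
  cycle_rows <- list()
  perwin_rows <- list()
  leg_index <- 0L

  for (m in manifest$mutations) {
    direction <- if (is.null(m$direction)) "forward" else m$direction
    leg_ests <- list()
    for (leg in c("apo", "holo")) {
      leg_index <- leg_index + 1L
      src <- m[[leg]]
      windows <- .leg_windows(src, Tk, seed, leg_index)
      res <- estimate_transformation(windows, method = method,
                                     decorrelate = decorr, tolerance = tol)
      label <- if (is.null(src$system_label)) leg else src$system_label
      say("%s %s leg (%s): %d windows, dG = %.4f +- %.4f kcal/mol",
          m$name, leg, label, length(windows), res$total$value,
          res$total$stderr)
      leg_ests[[leg]] <- leg_result(leg, m$name, res$total,
                                    system_label = label)
      pw <- res$per_window
      pw$mutation <- m$name
      pw$leg <- leg
      perwin_rows[[length(perwin_rows) + 1L]] <- pw
    }
    correction_shift <- 0
    if (!is.null(corrections)) {
      corrected <- suppressWarnings(
        apply_corrections(leg_ests, corrections))
      applied <- corrected$applied$correction
      correction_shift <- ddg_correction_shift(applied[1], applied[2])
      leg_ests <- stats::setNames(corrected$legs, c("apo", "holo"))
    }
    dd <- ddg(leg_ests$apo, leg_ests$holo)
    oriented <- orient(dd, direction)
    cycle_rows[[length(cycle_rows) + 1L]] <- data.frame(
      mutation = m$name, direction = direction,
      dg_apo = leg_ests$apo$estimate$value,
      dg_holo = leg_ests$holo$estimate$value,
      ddg = oriented$value, stderr = oriented$stderr,
      correction_shift = correction_shift)
    for (leg in c("apo", "holo")) {
      e <- leg_ests[[leg]]$estimate
      legs_rows[[length(legs_rows) + 1L]] <- data.frame(
        mutation = m$name, leg = leg,
        system_label = leg_ests[[leg]]$system_label,
        dG = e$value, stderr = e$stderr,
        n_eff_forward = e$n_effective_forward,
        n_eff_reverse = e$n_effective_reverse)
    }
  }

  legs_df <- do.call(rbind, legs_rows)
  cycle_df <- do.call(rbind, cycle_rows)
  perwin_df <- do.call(rbind, perwin_rows)

  comparison <- NULL
  if (!is.null(manifest$experiment_table)) {
    tab <- read_experiment_table(manifest$experiment_table)
    comparison <- compare_to_experiment(
      data.frame(mutation = cycle_df$mutation, ddg = cycle_df$ddg),
      tab, exclude = unlist(manifest$exclude_from_mae),
      temperature = Tk)
    say("MAE over %d mutations: %.4f kcal/mol", comparison$n_included,
        comparison$mae)
  }

  settings <- list(seed = seed, temperature = Tk, method = method,
                   decorrelate = decorr, tolerance = tol,
                   package_version = as.character(
                     utils::packageVersion("fepcycle")))
  report <- list(settings = settings, legs = legs_df, cycle = cycle_df,
                 comparison = comparison, per_window = perwin_df)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    # fixed-format numeric output so identical runs are byte-identical
    fmt <- function(df) {
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
      df
    }
    utils::write.csv(fmt(cycle_df), file.path(out_dir, "cycle_report.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(fmt(perwin_df), file.path(out_dir, "per_window.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(settings, file.path(out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}
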