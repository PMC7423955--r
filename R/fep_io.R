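#' @name fepout-format
#' @title The fepout text dialect
#' @description
#' Per-window energy differences are serialized in a NAMD-style text
#' dialect, one file per sampling direction:
#'
#' * window header: `#NEW FEP WINDOW: LAMBDA SET TO <from> LAMBDA2 <to>`
#'   where `<from>` is the sampled lambda and `<to>` the perturbed-to
#'   lambda (so a reverse-direction file has `<from> > <to>`);
#' * data line: `FepEnergy: <step> <dE> <T>` with the step index
#'   (strictly increasing within a window), the energy difference
#'   U(to) - U(from) in kcal/mol, and the temperature in K;
#' * all other lines are ignored.
#'
#' Numeric fields are written with 6 decimals; that is the round-trip
#' precision contract. Blank lines and trailing whitespace are
#' insignificant.
#' @keywords internal
NULL

.fepout_header_re <-
  "^#NEW FEP WINDOW: LAMBDA SET TO ([0-9.eE+-]+) LAMBDA2 ([0-9.eE+-]+)\\s*$"

#' Parse a fepout-dialect file
#'
#' See `?"fepout-format"` for the dialect. Returns one record set per
#' window in file order; an empty window raises a warning, a data line
#' before any header or a malformed numeric field is an error naming
#' the line.
#'
#' @param path path to the fepout-dialect text file
#' @return list of `fepout_window` objects: lists with `lambda_from`,
#'   `lambda_to`, `steps`, `dU`, `temperature`
#' @export
parse_fepout <- function(path) {
  lines <- readLines(path)
  windows <- list()
  cur <- NULL
  flush <- function(cur, windows) {
    if (is.null(cur)) return(windows)
    if (length(cur$dU) == 0) {
      warning(sprintf("empty window [%g -> %g] in %s", cur$lambda_from,
                      cur$lambda_to, path))
    }
    cur$steps <- as.integer(cur$steps)
    windows[[length(windows) + 1L]] <- structure(cur,
                                                 class = "fepout_window")
    windows
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    hm <- regmatches(line, regexec(.fepout_header_re, line))[[1]]
    if (length(hm) == 3) {
      windows <- flush(cur, windows)
      lam <- as.numeric(hm[2:3])
      if (any(is.na(lam))) {
        stop(sprintf("%s:%d: malformed lambda in window header", path, ln))
      }
      cur <- list(lambda_from = lam[1], lambda_to = lam[2],
                  steps = integer(0), dU = numeric(0),
                  temperature = NA_real_)
      next
    }
    if (grepl("^FepEnergy:", line)) {
      if (is.null(cur)) {
        stop(sprintf("%s:%d: data line before any window header", path, ln))
      }
      tok <- strsplit(trimws(sub("^FepEnergy:", "", line)), "\\s+")[[1]]
      if (length(tok) < 3) {
        stop(sprintf("%s:%d: expected 'FepEnergy: <step> <dE> <T>'",
                     path, ln))
      }
      vals <- suppressWarnings(as.numeric(tok[1:3]))
      if (any(is.na(vals))) {
        stop(sprintf("%s:%d: malformed numeric field", path, ln))
      }
      if (length(cur$steps) > 0 && vals[1] <= cur$steps[length(cur$steps)]) {
        stop(sprintf("%s:%d: step indices must be strictly increasing",
                     path, ln))
      }
      cur$steps <- c(cur$steps, vals[1])
      cur$dU <- c(cur$dU, vals[2])
      cur$temperature <- vals[3]
    }
    # anything else: ignored
  }
  windows <- flush(cur, windows)
  if (length(windows) == 0) stop("no FEP windows found in ", path)
  windows
}

#' Write per-window energy differences in the fepout dialect
#'
#' @param windows list of [window_samples()] objects in lambda order
#' @param path output path
#' @param direction which direction's samples to serialize:
#'   `"forward"` (sampled at lambda_low) or `"reverse"` (sampled at
#'   lambda_high)
#' @return `path`, invisibly
#' @export
write_fepout <- function(windows, path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(all(vapply(windows, inherits, logical(1), "window_samples")))
  con <- file(path, "w")
  on.exit(close(con))
  for (w in windows) {
    if (direction == "forward") {
      from <- w$lambda_low; to <- w$lambda_high; dU <- w$forward_dU
    } else {
      from <- w$lambda_high; to <- w$lambda_low; dU <- w$reverse_dU
    }
    writeLines(sprintf("#NEW FEP WINDOW: LAMBDA SET TO %.6f LAMBDA2 %.6f",
                       from, to), con)
    if (length(dU) > 0) {
      writeLines(sprintf("FepEnergy: %d %.6f %.6f", seq_along(dU), dU,
                         w$temperature), con)
    }
  }
  invisible(path)
}

#' Read per-window energy differences from headerless CSV
#'
#' Plain-format alternative to the fepout dialect: headerless rows
#' `lambda_from,lambda_to,step,dU`, grouped into windows by consecutive
#' runs of identical lambda pairs. The sampled lambda comes first, so
#' reverse-direction files have `lambda_from > lambda_to`.
#'
#' @param path CSV path
#' @param temperature temperature to attach, Kelvin (the plain format
#'   does not carry one)
#' @return list of `fepout_window` objects as from [parse_fepout()]
#' @export
read_window_csv <- function(path, temperature = 300) {
  df <- utils::read.csv(path, header = FALSE,
                        col.names = c("lambda_from", "lambda_to", "step",
                                      "dU"))
  if (nrow(df) == 0) stop("empty window CSV: ", path)
  if (any(!is.finite(as.matrix(df)))) {
    stop("non-numeric field in window CSV: ", path)
  }
  key <- paste(df$lambda_from, df$lambda_to)
  grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  lapply(split(df, grp), function(d) {
    structure(list(lambda_from = d$lambda_from[1],
                   lambda_to = d$lambda_to[1],
                   steps = as.integer(d$step), dU = d$dU,
                   temperature = temperature),
              class = "fepout_window")
  })
}

#' Write per-window energy differences as headerless CSV
#'
#' @inheritParams write_fepout
#' @export
write_window_csv <- function(windows, path,
                             direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  rows <- lapply(windows, function(w) {
    if (direction == "forward") {
      data.frame(a = w$lambda_low, b = w$lambda_high,
                 step = seq_along(w$forward_dU),
                 dU = sprintf("%.6f", w$forward_dU))
    } else {
      data.frame(a = w$lambda_high, b = w$lambda_low,
                 step = seq_along(w$reverse_dU),
                 dU = sprintf("%.6f", w$reverse_dU))
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pair parsed forward and reverse windows into window_samples
#'
#' Matches each forward window (sampled at lambda_low, perturbing up)
#' with the reverse window sampled at its lambda_high and perturbing
#' back down.
#'
#' @param forward_windows,reverse_windows lists of `fepout_window`
#'   objects from [parse_fepout()] or [read_window_csv()]
#' @param temperature temperature override, Kelvin; defaults to the
#'   temperature carried by the forward windows
#' @return list of [window_samples()] in lambda order
#' @export
pair_directions <- function(forward_windows, reverse_windows,
                            temperature = NULL) {
  fkey <- vapply(forward_windows, function(w)
    sprintf("%.6f|%.6f", w$lambda_from, w$lambda_to), character(1))
  rkey <- vapply(reverse_windows, function(w)
    sprintf("%.6f|%.6f", w$lambda_to, w$lambda_from), character(1))
  out <- lapply(seq_along(forward_windows), function(i) {
    j <- match(fkey[i], rkey)
    if (is.na(j)) {
      stop("no reverse window matching forward window [",
           forward_windows[[i]]$lambda_from, ", ",
           forward_windows[[i]]$lambda_to, "]")
    }
    fw <- forward_windows[[i]]
    rv <- reverse_windows[[j]]
    Tk <- temperature
    if (is.null(Tk)) Tk <- fw$temperature
    if (is.na(Tk)) Tk <- 300
    window_samples(fw$lambda_from, fw$lambda_to, fw$dU, rv$dU, Tk)
  })
  ord <- order(vapply(out, `[[`, numeric(1), "lambda_low"))
  out[ord]
}

#' Read an experimental mutation table
#'
#' CSV with required columns `mutation`, `ddg_expt_kcal_mol`,
#' `err_expt_kcal_mol`, `direction` (`forward` or `reversed`). The
#' packaged fixture `hv1_2gbi_table1.csv` carries the six experimental
#' relative binding free energies of the 2GBI/Hv1 mutation series.
#'
#' @param path CSV path; defaults to the packaged Hv1/2GBI table
#' @return validated data frame of mutation records
#' @examples
#' tab <- read_experiment_table()
#' tab[tab$mutation == "D112E", "ddg_expt_kcal_mol"] # 1.01
#' @export
read_experiment_table <- function(path = system.file(
  "extdata", "hv1_2gbi_table1.csv", package = "fepcycle")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("mutation", "ddg_expt_kcal_mol", "err_expt_kcal_mol", "direction")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("experiment table missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("ddg_expt_kcal_mol", "err_expt_kcal_mol")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("non-numeric value in column ", col)
    }
  }
  if (any(df$err_expt_kcal_mol < 0)) stop("negative experimental stderr")
  dup <- df$mutation[duplicated(df$mutation)]
  if (length(dup) > 0) {
    stop("duplicate mutation name(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(df$direction), c("forward", "reversed"))
  if (length(bad) > 0) {
    stop("invalid direction value(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Read a per-leg correction table
#'
#' CSV with columns `system_label` and `correction_kcal_mol`; returns a
#' named numeric vector for [apply_corrections()]. The packaged fixture
#' `r211s_charge_corrections.csv` holds the analytical finite-size
#' corrections for the charge-changing R211S transformation.
#'
#' @param path CSV path; defaults to the packaged R211S corrections
#' @return named numeric vector of corrections, kcal/mol
#' @export
read_corrections <- function(path = system.file(
  "extdata", "r211s_charge_corrections.csv", package = "fepcycle")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("system_label", "correction_kcal_mol")
  if (!all(req %in% names(df))) {
    stop("correction table must have columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(df$correction_kcal_mol))) {
    stop("non-finite correction value")
  }
  stats::setNames(df$correction_kcal_mol, df$system_label)
}
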