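# Scenario suites reproducing the computational experiments: monoculture
# dose panels, merged and stress cocultures, and the fibroblast
# renormalization counterfactual.

#' Run a monoculture dose panel
#'
#' Simulates one scenario per dose (Gln scenarios set \code{A0}, NH4+
#' scenarios set \code{W0}) and summarizes concentrations and live-cell
#' counts at the observation times.
#'
#' @param cell_type \code{"CAF"} or \code{"CC"}.
#' @param params [mono_params()]; defaults to the published set.
#' @param gln_doses,nh4_doses treatment doses, mM (defaults: the nonzero
#'   published panel).
#' @param X0 seeded cells.
#' @param obs_times observation grid, hours.
#' @param ... passed to [simulate_scenario()].
#' @return List with \code{trajectories} (named list of \code{gln_traj}) and
#'   \code{summary} (data frame: scenario, time, Gln, NH4+, cells).
#' @export
run_monoculture_suite <- function(cell_type = c("CAF", "CC"), params = NULL,
                                  gln_doses = c(1, 2, 4),
                                  nh4_doses = c(5, 10, 25),
                                  X0 = 8e4, obs_times = c(0, 24, 48, 72),
                                  ...) {
  cell_type <- match.arg(cell_type)
  if (is.null(params))
    params <- published_params(tolower(cell_type))
  variant <- if (cell_type == "CAF") "caf_mono" else "cc_mono"
  mk <- function(A0, W0, id)
    scenario(variant, A0 = A0, W0 = W0, X0 = X0,
             horizon = max(obs_times), obs_times = obs_times, id = id)
  scns <- c(lapply(gln_doses, function(d) mk(d, 0, sprintf("gln_%g", d))),
            lapply(nh4_doses, function(d) mk(0, d, sprintf("nh4_%g", d))))
  names(scns) <- vapply(scns, `[[`, "", "id")
  trs <- lapply(scns, simulate_scenario, params = params, ...)
  summ <- do.call(rbind, lapply(trs, function(tr)
    data.frame(scenario_id = tr$scenario$id, time_h = tr$times,
               Gln_mM = tr$states[, "A"], NH4_mM = tr$states[, "W"],
               cells = tr$states[, "X"], stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(trajectories = trs, summary = summ)
}

#' Run the coculture treatment panel
#'
#' Simulates the coculture at NH4+ doses and one Gln dose under the chosen
#' variant and tracks the population composition
#' \eqn{\%CC = Y/(X+Y)} of live cells at the observation times.  The merged
#' variant uses the two adjusted coculture growth rates; the stress variant
#' uses the reverted monoculture growth rates plus the stress constants
#' (both available via [published_params()]).
#'
#' @param params [co_params()]; defaults to the published set for the
#'   variant.
#' @param variant \code{"coculture_merged"}, \code{"coculture_stress"} or
#'   \code{"coculture_normalized"}.
#' @param nh4_doses,gln_dose treatment panel, mM.
#' @param X0,Y0 seeded cells per type (1:1 of 8e4 total by default).
#' @param obs_times observation grid, hours.
#' @param ... passed to [simulate_scenario()].
#' @return List with \code{trajectories} and \code{composition} (data frame:
#'   scenario, time, live counts, total, pct_cc).
#' @export
run_coculture_suite <- function(params = NULL,
                                variant = c("coculture_merged",
                                            "coculture_stress",
                                            "coculture_normalized"),
                                nh4_doses = c(5, 10, 25), gln_dose = 4,
                                X0 = 4e4, Y0 = 4e4,
                                obs_times = c(0, 24, 48, 72), ...) {
  variant <- match.arg(variant)
  if (is.null(params))
    params <- published_params(
      if (variant == "coculture_stress") "coculture_stress"
      else "coculture_merged")
  mk <- function(A0, W0, id)
    scenario(variant, A0 = A0, W0 = W0, X0 = X0, Y0 = Y0,
             horizon = max(obs_times), obs_times = obs_times, id = id)
  scns <- c(lapply(nh4_doses, function(d) mk(0, d, sprintf("nh4_%g", d))),
            if (length(gln_dose))
              lapply(gln_dose, function(d) mk(d, 0, sprintf("gln_%g", d))))
  names(scns) <- vapply(scns, `[[`, "", "id")
  trs <- lapply(scns, simulate_scenario, params = params, ...)
  comp <- do.call(rbind, lapply(trs, function(tr) {
    X <- tr$states[, "X"]; Y <- tr$states[, "Y"]
    data.frame(scenario_id = tr$scenario$id, time_h = tr$times,
               cells_CAF = X, cells_CC = Y, cells_total = X + Y,
               pct_cc = 100 * Y / (X + Y), stringsAsFactors = FALSE)
  }))
  rownames(comp) <- NULL
  list(trajectories = trs, composition = comp)
}

#' Compare the merged coculture with renormalized fibroblasts
#'
#' The renormalization counterfactual models a therapy returning CAFs to
#' normal fibroblast behavior: they no longer convert NH4+ back to Gln
#' (CAF \code{k2 = 0}).  Both models are simulated at one NH4+ dose and the
#' total live-cell counts compared over time.
#'
#' @param params merged-variant [co_params()]; defaults to the published set.
#' @param dose NH4+ dose, mM.
#' @param X0,Y0 seeded cells per type.
#' @param obs_times observation grid, hours.
#' @param ... passed to [simulate_scenario()].
#' @return List with \code{merged} and \code{normalized} trajectories and
#'   \code{delta}: per-time totals and their difference
#'   (merged - normalized).
#' @export
run_renormalization_comparison <- function(params = NULL, dose = 5,
                                           X0 = 4e4, Y0 = 4e4,
                                           obs_times = c(0, 24, 48, 72),
                                           ...) {
  if (is.null(params)) params <- published_params("coculture_merged")
  mk <- function(variant)
    scenario(variant, A0 = 0, W0 = dose, X0 = X0, Y0 = Y0,
             horizon = max(obs_times), obs_times = obs_times,
             id = sprintf("%s_nh4_%g", variant, dose))
  tr_m <- simulate_scenario(mk("coculture_merged"), params, ...)
  tr_n <- simulate_scenario(mk("coculture_normalized"), params, ...)
  tot_m <- tr_m$states[, "X"] + tr_m$states[, "Y"]
  tot_n <- tr_n$states[, "X"] + tr_n$states[, "Y"]
  delta <- data.frame(time_h = tr_m$times,
                      total_merged = tot_m, total_normalized = tot_n,
                      delta = tot_m - tot_n,
                      Gln_merged = tr_m$states[, "A"],
                      Gln_normalized = tr_n$states[, "A"],
                      stringsAsFactors = FALSE)
  list(merged = tr_m, normalized = tr_n, delta = delta)
}

#' Write suite results as a plain-text report
#'
#' Writes every tabular component of a suite result (any list whose elements
#' are data frames, trajectories, or nested lists of those) as tab-separated
#' files with stable column order, plus a \code{run_info.txt} logging the
#' seed, solver settings and package version.  Output is byte-identical
#' across reruns with the same inputs and seed.
#'
#' @param results named list of results.
#' @param dir output directory (created if needed).
#' @param seed seed to log (optional).
#' @param solver_settings named list logged verbatim.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, dir, seed = NULL,
                         solver_settings = list(rtol = 1e-8, atol = 1e-10,
                                                solver = "dp45")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(x, name) {
    if (inherits(x, "gln_traj")) x <- as.data.frame(x)
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(name, ".tsv"))
      write.table(format(x, digits = 15, trim = TRUE, scientific = NA),
                  f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, f)
    } else if (is.list(x)) {
      for (nm in names(x)) emit(x[[nm]], paste(name, nm, sep = "_"))
    }
  }
  for (nm in names(results)) emit(results[[nm]], nm)
  info <- file.path(dir, "run_info.txt")
  lines <- c(sprintf("package: glnamm %s",
                     as.character(utils::packageVersion("glnamm"))),
             sprintf("seed: %s", if (is.null(seed)) "none" else format(seed)),
             sprintf("solver: %s", paste(names(solver_settings),
                                         unlist(solver_settings),
                                         sep = "=", collapse = " ")))
  writeLines(lines, info)
  files <- c(files, info)
  invisible(files)
}
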