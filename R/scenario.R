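# Culture scenarios: composition, initial conditions, treatment, horizon.

#' Define a culture scenario
#'
#' A scenario fixes the model variant, the initial metabolic environment and
#' seeding, the time horizon and the observation grid.  Defaults follow the
#' experimental design: the alternative energy pool starts at 20 mM in all
#' scenarios, cultures run for 72 h and are observed every 24 h, and time is
#' in hours throughout (values in days are not converted).
#'
#' @param variant one of \code{"caf_mono"}, \code{"cc_mono"},
#'   \code{"coculture_merged"}, \code{"coculture_stress"},
#'   \code{"coculture_normalized"}.
#' @param A0 initial Gln concentration, mM.
#' @param W0 initial NH4+ concentration, mM.
#' @param R0 initial alternative-energy concentration, mM.
#' @param X0 seeded cells (CAFs in coculture; the single cell type in
#'   monoculture).
#' @param Y0 seeded cancer cells (coculture only).
#' @param horizon simulation horizon, hours.
#' @param obs_times observation times in hours; must start at 0, be sorted,
#'   and lie within \code{[0, horizon]}.
#' @param id scenario identifier used in datasets and reports.
#' @return An object of class \code{"scenario"}.
#' @examples
#' scenario("caf_mono", A0 = 4, X0 = 8e4)
#' @export
scenario <- function(variant, A0 = 0, W0 = 0, R0 = 20, X0 = 8e4, Y0 = 0,
                     horizon = 72, obs_times = c(0, 24, 48, 72), id = NULL) {
  variant <- match.arg(variant, .VARIANTS)
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(nm, " must be a nonnegative scalar", call. = FALSE)
    x
  }
  A0 <- num1(A0, "A0"); W0 <- num1(W0, "W0"); R0 <- num1(R0, "R0")
  X0 <- num1(X0, "X0"); Y0 <- num1(Y0, "Y0")
  horizon <- num1(horizon, "horizon")
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (is.unsorted(obs_times, strictly = TRUE))
    stop("obs_times must be strictly increasing", call. = FALSE)
  if (obs_times[1] != 0)
    stop("obs_times must start at 0", call. = FALSE)
  if (max(obs_times) > horizon)
    stop("obs_times must lie within [0, horizon]", call. = FALSE)
  co <- grepl("^coculture", variant)
  if (co && Y0 <= 0)
    stop("coculture scenarios need Y0 > 0", call. = FALSE)
  if (!co && Y0 != 0)
    stop("monoculture scenarios must have Y0 = 0", call. = FALSE)
  if (is.null(id)) {
    treat <- if (A0 > 0 && W0 > 0) sprintf("gln%g_nh4%g", A0, W0)
             else if (W0 > 0) sprintf("nh4%g", W0)
             else sprintf("gln%g", A0)
    id <- paste(variant, treat, sep = "_")
  }
  structure(list(variant = variant, A0 = A0, W0 = W0, R0 = R0, X0 = X0,
                 Y0 = Y0, horizon = horizon, obs_times = as.numeric(obs_times),
                 id = as.character(id)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$id, x$variant))
  cat(sprintf("  Gln %g mM, NH4+ %g mM, R %g mM; X0 = %g",
              x$A0, x$W0, x$R0, x$X0))
  if (x$Y0 > 0) cat(sprintf(", Y0 = %g", x$Y0))
  cat(sprintf("; %g h, observed at %s h\n",
              x$horizon, paste(x$obs_times, collapse = "/")))
  invisible(x)
}

# states tracked by a variant (L only in the stress variant)
scenario_states <- function(variant) {
  switch(variant,
         caf_mono = ,
         cc_mono = c("A", "W", "R", "X"),
         coculture_stress = c("A", "W", "R", "X", "Y", "L"),
         c("A", "W", "R", "X", "Y"))
}

scenario_y0 <- function(scn) {
  y0 <- c(A = scn$A0, W = scn$W0, R = scn$R0, X = scn$X0)
  if (grepl("^coculture", scn$variant)) {
    y0 <- c(y0, Y = scn$Y0)
    if (scn$variant == "coculture_stress") y0 <- c(y0, L = 0)
  }
  y0
}

# check scenario variant against the parameter object class
check_variant_params <- function(scn, params) {
  co <- grepl("^coculture", scn$variant)
  if (co && !inherits(params, "co_params"))
    stop(sprintf("scenario '%s' needs co_params", scn$id), call. = FALSE)
  if (!co && !inherits(params, "mono_params"))
    stop(sprintf("scenario '%s' needs mono_params", scn$id), call. = FALSE)
  if (scn$variant == "coculture_stress" && params$g <= 0)
    stop(sprintf("scenario '%s': stress variant needs g > 0", scn$id),
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write scenario configuration files
#'
#' Scenarios are serialized as YAML with the field names of [scenario()].
#' Several scenarios are stored as a named list keyed by scenario id.
#'
#' @param scenarios a \code{scenario} or list of scenarios.
#' @param path file path.
#' @return \code{read_scenarios()} returns a named list of scenarios.
#' @export
write_scenarios <- function(scenarios, path) {
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  lst <- lapply(scenarios, function(s) unclass(s))
  names(lst) <- vapply(scenarios, `[[`, "", "id")
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- lapply(lst, function(s) {
    if (!is.null(s$horizon_days) || !is.null(s$obs_times_days))
      stop("scenario times must be given in hours, not days", call. = FALSE)
    scenario(variant = s$variant, A0 = s$A0, W0 = s$W0, R0 = s$R0,
             X0 = s$X0, Y0 = s$Y0, horizon = s$horizon,
             obs_times = unlist(s$obs_times), id = s$id)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
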