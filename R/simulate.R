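# ODE integration of a scenario.

#' Simulate a culture scenario
#'
#' Integrates the scenario's model variant from its initial state and returns
#' the trajectory at the requested times.  The default engine is an adaptive
#' Dormand-Prince 5(4) Runge-Kutta (compiled); \code{solver = "lsoda"}
#' selects \code{deSolve::lsoda} as a stiff fallback.  Components are clipped
#' to 0 only within solver tolerance; an excursion below \code{-neg_tol} is an
#' integration error, not clipped.
#'
#' @param scn a [scenario()].
#' @param params a [mono_params()] or [co_params()] object matching the
#'   scenario's variant ([published_params()] supplies the fitted sets).
#' @param times output times in hours.  Defaults to the scenario's
#'   \code{obs_times}; use \code{dense = TRUE} for a fine plotting grid.
#' @param rtol,atol relative and absolute solver tolerances.
#' @param solver \code{"dp45"} (default) or \code{"lsoda"}.
#' @param dense if \code{TRUE}, output on a 361-point uniform grid over the
#'   horizon instead of \code{obs_times}.
#' @param r_reset optional \code{list(time =, value =)}: reset the
#'   alternative-energy pool R to \code{value} at \code{time} (medium
#'   replenishment thought experiment).
#' @param neg_tol largest tolerated negative excursion before erroring.
#' @return An object of class \code{"gln_traj"}: list with \code{times},
#'   \code{states} (matrix, one row per time), \code{scenario}.
#' @examples
#' tr <- simulate_scenario(scenario("caf_mono", A0 = 4), published_params("caf"))
#' tr$states
#' @export
simulate_scenario <- function(scn, params, times = NULL,
                              rtol = 1e-8, atol = 1e-10,
                              solver = c("dp45", "lsoda"),
                              dense = FALSE, r_reset = NULL,
                              neg_tol = 1e-6) {
  solver <- match.arg(solver)
  stopifnot(inherits(scn, "scenario"))
  check_variant_params(scn, params)
  if (is.null(times))
    times <- if (dense) seq(0, scn$horizon, length.out = 361L) else scn$obs_times
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop("output times must be strictly increasing from 0", call. = FALSE)

  y0 <- scenario_y0(scn)
  if (!is.null(r_reset)) {
    if (!is.list(r_reset) || is.null(r_reset$time) || is.null(r_reset$value))
      stop("r_reset must be list(time =, value =)", call. = FALSE)
    states <- integrate_with_reset(scn, params, y0, times, rtol, atol, solver,
                                   r_reset)
  } else {
    states <- integrate_leg(scn, params, y0, times, rtol, atol, solver)
  }

  low <- min(states)
  if (low < -neg_tol)
    stop(sprintf("scenario '%s': state fell below -neg_tol (min %.3g)",
                 scn$id, low), call. = FALSE)
  states[states < 0] <- 0
  colnames(states) <- scenario_states(scn$variant)
  structure(list(times = times, states = states, scenario = scn,
                 dense = dense, solver = solver),
            class = "gln_traj")
}

# integration over one leg (no events)
integrate_leg <- function(scn, params, y0, times, rtol, atol, solver) {
  variant <- scn$variant
  if (grepl("^coculture", variant)) {
    p <- params
    if (variant == "coculture_normalized") p$caf[["k2"]] <- 0
    if (variant != "coculture_stress") { p$g <- 0; p$m <- 0 }
    pars <- c(p$caf, p$cc, p$g, p$m)
    # merged/normalized variants carry no L state; pad for the 6-state core
    has_L <- variant == "coculture_stress"
    y <- if (has_L) y0 else c(y0, L = 0)
    model <- 2L
  } else {
    pars <- unclass(params)
    y <- y0
    has_L <- TRUE  # nothing to strip
    model <- 1L
  }
  states <- if (solver == "dp45") {
    run_dp45(y, times, pars, model, rtol, atol, scn$id)
  } else {
    run_lsoda(y, times, pars, model, rtol, atol, scn$id)
  }
  if (!has_L) states <- states[, -ncol(states), drop = FALSE]
  states
}

run_dp45 <- function(y, times, pars, model, rtol, atol, id) {
  if (length(times) == 1L) return(matrix(y, nrow = 1L))
  res <- tryCatch(
    .dp45_integrate(as.numeric(y), as.numeric(times), as.numeric(pars),
                    model, rtol, atol),
    error = function(e) stop(sprintf("scenario '%s': %s", id, conditionMessage(e)),
                             call. = FALSE))
  res
}

run_lsoda <- function(y, times, pars, model, rtol, atol, id) {
  if (length(times) == 1L) return(matrix(y, nrow = 1L))
  deriv <- if (model == 1L) {
    function(t, y, p) {
      names(y) <- c("A", "W", "R", "X")
      list(unname(mono_rhs(pmax(y, 0), p)))
    }
  } else {
    function(t, y, p) {
      names(y) <- c("A", "W", "R", "X", "Y", "L")
      list(unname(co_rhs_raw(pmax(y, 0), p)))
    }
  }
  p <- if (model == 1L) structure(pars, class = "mono_params") else pars
  res <- tryCatch(
    deSolve::lsoda(as.numeric(y), as.numeric(times), deriv, p,
                   rtol = rtol, atol = atol),
    error = function(e) stop(sprintf("scenario '%s': %s", id, conditionMessage(e)),
                             call. = FALSE))
  if (attr(res, "istate")[1] < 0)
    stop(sprintf("scenario '%s': lsoda failed", id), call. = FALSE)
  unname(res[, -1, drop = FALSE])
}

# 6-state coculture RHS on a bare parameter vector (caf12, cc12, g, m);
# used only by the lsoda fallback.
co_rhs_raw <- function(y, pars) {
  pf <- pars[1:12]; pc <- pars[13:24]; g <- pars[25]; m <- pars[26]
  names(pf) <- names(pc) <- .PARAM_NAMES
  A <- y[["A"]]; W <- y[["W"]]; R <- y[["R"]]
  X <- y[["X"]]; Y <- y[["Y"]]; L <- y[["L"]]
  glnloss_f <- pf[["k1"]] * A * X
  glnloss_c <- pc[["k1"]] * A * Y
  recycle_f <- pf[["k2"]] * W * R * X
  recycle_c <- pc[["k2"]] * W * R * Y
  kill <- m * L^2
  c(A = -glnloss_f + pf[["c2"]] * recycle_f - glnloss_c + pc[["c2"]] * recycle_c,
    W = pf[["c1"]] * glnloss_f - recycle_f + pc[["c1"]] * glnloss_c -
      recycle_c + pf[["h"]] * X + pc[["h"]] * Y,
    R = -recycle_f - recycle_c - pf[["k3"]] * R * X - pc[["k3"]] * R * Y,
    X = (.monod(pf[["r1"]], pf[["K1"]], A) + .monod(pf[["r2"]], pf[["K2"]], R) -
           pf[["d1"]] * W - pf[["d2"]] - kill) * X,
    Y = (.monod(pc[["r1"]], pc[["K1"]], A) + .monod(pc[["r2"]], pc[["K2"]], R) -
           pc[["d1"]] * W - pc[["d2"]] - kill) * Y,
    L = g * X * Y)
}

integrate_with_reset <- function(scn, params, y0, times, rtol, atol, solver,
                                 r_reset) {
  tr <- r_reset$time
  if (tr <= 0 || tr >= max(times))
    stop("r_reset$time must lie strictly inside the output span", call. = FALSE)
  t1 <- unique(c(times[times <= tr], tr))
  leg1 <- integrate_leg(scn, params, y0, t1, rtol, atol, solver)
  y_mid <- leg1[nrow(leg1), ]
  names(y_mid) <- scenario_states(scn$variant)
  y_mid[["R"]] <- r_reset$value
  t2 <- c(tr, times[times > tr])
  leg2 <- integrate_leg(scn, params, y_mid, t2 - 0, rtol, atol, solver)
  # reindex leg2 onto times > tr (its first row is the reset instant)
  keep1 <- leg1[match(times[times <= tr], t1), , drop = FALSE]
  keep2 <- leg2[-1, , drop = FALSE]
  rbind(keep1, keep2)
}

#' @export
print.gln_traj <- function(x, ...) {
  cat(sprintf("Trajectory of scenario '%s' (%s), %d time points\n",
              x$scenario$id, x$scenario$variant, length(x$times)))
  print(cbind(time_h = x$times, x$states), ...)
  invisible(x)
}

#' Tidy a trajectory
#'
#' @param x a \code{gln_traj}.
#' @param row.names,optional unused, for generic consistency.
#' @param ... unused.
#' @return Long-format data frame with columns \code{scenario_id},
#'   \code{time_h}, \code{variable}, \code{value}.
#' @export
as.data.frame.gln_traj <- function(x, row.names = NULL, optional = FALSE, ...) {
  vars <- colnames(x$states)
  data.frame(scenario_id = x$scenario$id,
             time_h = rep(x$times, times = length(vars)),
             variable = rep(vars, each = length(x$times)),
             value = as.vector(x$states),
             stringsAsFactors = FALSE)
}

#' Write trajectories as tidy delimited text
#'
#' @param trajectories a \code{gln_traj} or list of them.
#' @param path output file (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  if (inherits(trajectories, "gln_traj")) trajectories <- list(trajectories)
  tidy <- do.call(rbind, lapply(trajectories, as.data.frame))
  write.table(tidy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.gln_traj <- function(x, which = colnames(x$states), ...) {
  st <- x$states[, which, drop = FALSE]
  matplot(x$times, st, type = "l", lty = 1, xlab = "time (h)", ylab = "value",
          main = x$scenario$id, ...)
  legend("topright", legend = colnames(st), lty = 1,
         col = seq_len(ncol(st)), bty = "n")
  invisible(x)
}
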