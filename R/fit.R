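# Nelder-Mead least-squares fitting of the exchange models.

#' Control settings for [glnfit()]
#'
#' @param maxit maximum Nelder-Mead iterations per optimizer run.
#' @param reltol relative convergence tolerance of the simplex.
#' @param restarts deterministic restarts of the simplex from the best vertex
#'   (Nelder-Mead can stall in 10+ dimensions; each restart rebuilds the
#'   simplex around the incumbent).
#' @param penalty finite objective value substituted when simulation fails.
#' @param rtol,atol,solver ODE solver settings ([simulate_scenario()]).
#' @return A list of class \code{"glnfit_control"}.
#' @export
glnfit_control <- function(maxit = 2000, reltol = 1e-10, restarts = 2,
                           penalty = 1e12, rtol = 1e-8, atol = 1e-10,
                           solver = "dp45") {
  structure(list(maxit = maxit, reltol = reltol, restarts = restarts,
                 penalty = penalty, rtol = rtol, atol = atol,
                 solver = solver),
            class = "glnfit_control")
}

default_free <- function(theta, cell_type) {
  if (cell_type == "coculture") return(c("caf.r1", "cc.r1"))
  free <- names(theta)[theta > 0]
  if (theta[["r2"]] == 0) free <- setdiff(free, "K2")
  free
}

#' Fit exchange-model parameters to time-course data
#'
#' Minimizes the least-squares objective [gln_objective()] over the free
#' parameters by Nelder-Mead on the log scale (positivity is enforced by the
#' transform), jointly over all scenarios in the dataset.  The fit is
#' deterministic given \code{(data, init, free, weights, control)}.
#'
#' @param data a [gln_data()] dataset.
#' @param init initial parameters: a [mono_params()]/[co_params()] object or
#'   a named theta vector.  Defaults to the published set for the dataset's
#'   cell type.  Free parameters must be strictly positive at \code{init}.
#' @param free names of the parameters to estimate; the rest stay pinned at
#'   \code{init}.  Defaults: all positive monoculture parameters (minus the
#'   inert \code{K2} when \code{r2 = 0}); for cocultures the two growth rates
#'   \code{caf.r1}, \code{cc.r1} (the published refit strategy).
#' @param weights stream weight scales, see [stream_weights()].
#' @param control a [glnfit_control()] list.
#' @param use_measured_t0 use measured t = 0 concentrations as initial
#'   conditions instead of nominal dosed values.
#' @return An object of class \code{"glnfit"} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{fitted}, \code{residuals},
#'   \code{predict}, \code{simulate} and \code{plot}.
#' @examples
#' \donttest{
#' d <- generate_data(design_spec("CAF", noise = 0), published_params("caf"))
#' f <- glnfit(d, init = published_params("caf"), free = c("r1", "d1"))
#' coef(f)[c("r1", "d1")]
#' }
#' @seealso [bootstrap_ci()], [estimate_sigmas()]
#' @export
glnfit <- function(data, init = NULL, free = NULL,
                   weights = stream_weights(), control = glnfit_control(),
                   use_measured_t0 = FALSE) {
  stopifnot(inherits(data, "gln_data"))
  if (!inherits(control, "glnfit_control"))
    control <- do.call(glnfit_control, control)
  ct <- dataset_cell_type(data)
  if (is.null(init))
    init <- switch(ct, CAF = published_params("caf"),
                   CC = published_params("cc"),
                   published_params("coculture_merged"))
  theta0 <- if (is.numeric(init) && !inherits(init, "mono_params"))
    init else params_to_theta(init)
  if (is.null(free)) free <- default_free(theta0, ct)
  bad <- setdiff(free, names(theta0))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(free) && any(theta0[free] <= 0))
    stop("free parameters must be strictly positive at init: ",
         paste(free[theta0[free] <= 0], collapse = ", "), call. = FALSE)

  ctx <- obj_context(data, weights, control$rtol, control$atol,
                     control$solver, use_measured_t0)
  theta <- theta0
  fn <- function(lx) {
    theta[free] <- exp(lx)
    ctx_objective(ctx, theta, control$penalty)
  }

  if (length(free) == 0L) {
    # evaluate-only: all parameters pinned at init
    f0 <- ctx_objective(ctx, theta, control$penalty)
    return(structure(list(coefficients = theta, objective = f0,
                          value_at_init = f0, init = theta0, free = free,
                          n_evals = 1L, converged = TRUE,
                          data = data, weights = weights, control = control,
                          use_measured_t0 = use_measured_t0,
                          cell_type = ct, ctx = ctx),
                     class = "glnfit"))
  }

  f0 <- fn(log(theta0[free]))
  best_par <- log(theta0[free])
  best_val <- f0
  n_evals <- 1L
  converged <- FALSE
  for (run in seq_len(control$restarts + 1L)) {
    if (length(free) == 1L) {
      op <- optim(best_par, fn, method = "Brent",
                  lower = best_par - 12, upper = best_par + 12,
                  control = list(maxit = control$maxit))
      op$convergence <- 0L
      op$counts <- c(`function` = control$maxit, gradient = NA)
    } else {
      op <- optim(best_par, fn, method = "Nelder-Mead",
                  control = list(maxit = control$maxit,
                                 reltol = control$reltol))
    }
    n_evals <- n_evals + unname(op$counts[1])
    improved <- op$value < best_val - max(1e-12, abs(best_val) * 1e-8)
    if (op$value <= best_val) {
      best_val <- op$value
      best_par <- op$par
    }
    converged <- op$convergence == 0L
    if (!improved && run > 1L) break
  }
  theta[free] <- exp(best_par)

  structure(list(coefficients = theta, objective = best_val,
                 value_at_init = f0, init = theta0, free = free,
                 n_evals = n_evals, converged = converged,
                 data = data, weights = weights, control = control,
                 use_measured_t0 = use_measured_t0,
                 cell_type = ct, ctx = ctx),
            class = "glnfit")
}

#' @export
coef.glnfit <- function(object, ...) object$coefficients

#' @export
print.glnfit <- function(x, digits = 4, ...) {
  cat(sprintf("Exchange-model fit (%s): %d observations, %d scenarios\n",
              x$cell_type, x$ctx$n_obs, length(x$ctx$scenarios)))
  cat(sprintf("objective %.6g (at init %.6g), %d evaluations, %s\n",
              x$objective, x$value_at_init, x$n_evals,
              if (x$converged) "converged" else "NOT converged"))
  est <- x$coefficients
  mark <- ifelse(names(est) %in% x$free, "", " (pinned)")
  cat("parameters:\n")
  for (i in seq_along(est))
    cat(sprintf("  %-8s %.*g%s\n", names(est)[i], digits, est[i], mark[i]))
  invisible(x)
}

#' @export
fitted.glnfit <- function(object, ...) {
  r <- ctx_residuals(object$ctx, object$coefficients)
  data.frame(scenario_id = r$scenario_id, time_h = r$time_h,
             stream = r$stream, value = r$fitted_w * r$weight,
             stringsAsFactors = FALSE)
}

#' Residuals of an exchange-model fit
#'
#' @param object a [glnfit()] object.
#' @param type \code{"weighted"} (model minus data on the objective's
#'   weighted scale; the scale on which error variances are estimated) or
#'   \code{"raw"} (original units per stream).
#' @param ... unused.
#' @return Numeric vector with attributes lost; use
#'   \code{residual_table()} for the annotated version.
#' @export
residuals.glnfit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- ctx_residuals(object$ctx, object$coefficients)
  if (type == "weighted") r$resid_w else r$resid_w * r$weight
}

#' Annotated residual table of a fit
#'
#' @param object a [glnfit()] object.
#' @return Data frame with scenario, time, stream, error group, weighted
#'   fitted/observed values and weighted residual.
#' @export
residual_table <- function(object) {
  stopifnot(inherits(object, "glnfit"))
  ctx_residuals(object$ctx, object$coefficients)
}

#' Predict trajectories at the fitted parameters
#'
#' @param object a [glnfit()] object.
#' @param scenarios scenarios to simulate; defaults to the fitted dataset's.
#' @param dense output on a fine grid (for curves) instead of obs_times.
#' @param ... passed to [simulate_scenario()].
#' @return Named list of \code{gln_traj}.
#' @export
predict.glnfit <- function(object, scenarios = NULL, dense = FALSE, ...) {
  if (is.null(scenarios)) scenarios <- dataset_scenarios(object$data)
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  params <- theta_to_params(object$coefficients)
  out <- lapply(scenarios, simulate_scenario, params = params, dense = dense,
                rtol = object$control$rtol, atol = object$control$atol,
                solver = object$control$solver, ...)
  names(out) <- vapply(scenarios, `[[`, "", "id")
  out
}

#' @export
summary.glnfit <- function(object, ...) {
  r <- ctx_residuals(object$ctx, object$coefficients)
  per_stream <- vapply(split(r$resid_w, r$stream),
                       function(z) sum(z^2), 0)
  sig2 <- tryCatch(estimate_sigmas(object), error = function(e) NULL)
  structure(list(fit = object, rss_per_stream = per_stream,
                 sigma2 = sig2),
            class = "summary.glnfit")
}

#' @export
print.summary.glnfit <- function(x, ...) {
  print(x$fit)
  cat("weighted RSS per stream:\n")
  print(round(x$rss_per_stream, 6))
  if (!is.null(x$sigma2)) {
    cat("estimated error variances (weighted scale):\n")
    print(signif(x$sigma2, 4))
  }
  invisible(x)
}

#' Plot observed data against fitted curves
#'
#' One panel per scenario; points are the observations, lines the model at
#' the fitted parameters, both on the weighted scale so concentrations and
#' counts share an axis.
#'
#' @param x a [glnfit()] object.
#' @param ... passed to [matplot()].
#' @export
plot.glnfit <- function(x, ...) {
  scns <- dataset_scenarios(x$data)
  n <- length(scns)
  mf <- c(ceiling(n / 4), min(n, 4))
  op <- par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(par(op))
  trs <- predict(x, dense = TRUE)
  w <- x$weights
  for (id in names(scns)) {
    tr <- trs[[id]]
    obs <- x$data[x$data$scenario_id == id, ]
    streams <- unique(obs$stream)
    curves <- sapply(streams, function(st)
      stream_from_states(tr$states, st, tr$scenario$variant) / w[[st]])
    matplot(tr$times, curves, type = "l", lty = 1, xlab = "time (h)",
            ylab = "weighted value", main = id, ...)
    for (j in seq_along(streams)) {
      o <- obs[obs$stream == streams[j], ]
      points(o$time_h, o$value / w[[streams[j]]], col = j, pch = 19)
    }
    legend("topright", legend = streams, col = seq_along(streams),
           lty = 1, pch = 19, bty = "n", cex = 0.7)
  }
  invisible(x)
}
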