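# Least-squares objective: F(theta) = sum_k |u(t_k; theta) - w(t_k)|^2 over
# all data points of all scenarios of one cell type, with each stream first
# divided by its weight scale.
#
# The optimizer calls the objective ~1e3 times per fit and the bootstrap runs
# hundreds of refits, so the inner loop works on a precomputed context and
# calls the compiled integrator directly, bypassing the (validating)
# simulate_scenario() wrapper.  Both paths share the same integrator, so
# their trajectories are bit-identical.

#' Stream weight scales for the objective
#'
#' The raw sum of squared residuals mixes cell counts (order 1e4-1e5) with
#' concentrations (order 0.1-25 mM) and would be dominated entirely by the
#' counts.  The default scales express counts in units of 1e4 cells and leave
#' concentrations in mM, making the stream magnitudes comparable;
#' \code{mode = "unweighted"} reproduces the literal unweighted sum.
#'
#' @param mode \code{"scaled"} (default) or \code{"unweighted"}.
#' @return Named numeric vector of divisors, one per stream.
#' @export
stream_weights <- function(mode = c("scaled", "unweighted")) {
  mode <- match.arg(mode)
  if (mode == "unweighted")
    return(setNames(rep(1, length(.STREAMS)), .STREAMS))
  c(Gln_mM = 1, NH4_mM = 1,
    cells_CAF = 1e4, cells_CC = 1e4, cells_total = 1e4)
}

# column of the integrator output (A W R X [Y L]) holding a stream;
# 0 encodes X + Y (cells_total in coculture)
stream_col <- function(stream, variant) {
  co <- grepl("^coculture", variant)
  switch(stream,
         Gln_mM = 1L, NH4_mM = 2L,
         cells_CAF = 4L,
         cells_CC = if (co) 5L else 4L,
         cells_total = if (co) 0L else 4L,
         stop("unknown stream ", stream, call. = FALSE))
}

# index of theta entries feeding the integrator parameter vector, plus the
# per-variant fix-ups (caf k2 zeroed for the normalized variant, g/m zeroed
# for the merged ones)
theta_pars_map <- function(theta_names, variant) {
  if (!grepl("^coculture", variant)) {
    stopifnot(identical(theta_names, .PARAM_NAMES))
    return(list(idx = 1:12, zero = integer(), model = 1L))
  }
  idx <- match(c(paste0("caf.", .PARAM_NAMES), paste0("cc.", .PARAM_NAMES),
                 "g", "m"), theta_names)
  stopifnot(!anyNA(idx))
  zero <- integer()
  if (variant == "coculture_normalized") zero <- 3L           # caf k2
  if (variant != "coculture_stress") zero <- c(zero, 25L, 26L)  # g, m
  list(idx = idx, zero = zero, model = 2L)
}

# Precomputed evaluation context.  Per scenario: initial state, integrator
# model code and parameter map, output times, and per-record stream blocks
# (output column, time indices, weights, weighted observations).
obj_context <- function(data, weights = stream_weights(),
                        rtol = 1e-8, atol = 1e-10, solver = "dp45",
                        use_measured_t0 = FALSE) {
  stopifnot(inherits(data, "gln_data"))
  miss <- setdiff(unique(data$stream), names(weights))
  if (length(miss))
    stop("no weight scale for stream(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ct <- dataset_cell_type(data)
  theta_names <- if (ct == "coculture")
    c(paste0("caf.", .PARAM_NAMES), paste0("cc.", .PARAM_NAMES), "g", "m")
  else .PARAM_NAMES
  scns <- dataset_scenarios(data)
  used <- intersect(names(scns), unique(data$scenario_id))
  per_scn <- lapply(used, function(id) {
    scn <- scns[[id]]
    rec <- data[data$scenario_id == id, , drop = FALSE]
    times <- sort(unique(c(0, rec$time_h)))
    if (use_measured_t0) {
      a0 <- rec$value[rec$time_h == 0 & rec$stream == "Gln_mM"]
      w0 <- rec$value[rec$time_h == 0 & rec$stream == "NH4_mM"]
      if (length(a0)) scn$A0 <- a0[1]
      if (length(w0)) scn$W0 <- w0[1]
    }
    y0 <- scenario_y0(scn)
    map <- theta_pars_map(theta_names, scn$variant)
    if (map$model == 2L && scn$variant != "coculture_stress")
      y0 <- c(y0, L = 0)
    blocks <- lapply(split(seq_len(nrow(rec)), rec$stream), function(ii) {
      st <- rec$stream[ii[1]]
      list(stream = st,
           col = stream_col(st, scn$variant),
           t_idx = match(rec$time_h[ii], times),
           time_h = rec$time_h[ii],
           w = unname(weights[[st]]),
           obs = rec$value[ii],
           group = stream_group(st, ct))
    })
    list(scn = scn, times = times, y0 = unname(y0), map = map,
         blocks = blocks)
  })
  list(scenarios = per_scn, cell_type = ct, weights = weights,
       theta_names = theta_names,
       rtol = rtol, atol = atol, solver = solver, n_obs = nrow(data))
}

# integrate one context scenario under theta; NULL on failure
ctx_states <- function(ctx, sc, theta) {
  pars <- unname(theta)[sc$map$idx]
  if (length(sc$map$zero)) pars[sc$map$zero] <- 0
  if (anyNA(pars) || any(pars < 0)) return(NULL)
  if (ctx$solver == "dp45") {
    tryCatch(.dp45_integrate(sc$y0, sc$times, pars, sc$map$model,
                             ctx$rtol, ctx$atol),
             error = function(e) NULL)
  } else {
    tryCatch(run_lsoda(sc$y0, sc$times, pars, sc$map$model,
                       ctx$rtol, ctx$atol, sc$scn$id),
             error = function(e) NULL)
  }
}

block_fitted_w <- function(states, b) {
  vals <- if (b$col == 0L) states[, 4L] + states[, 5L] else states[, b$col]
  vals[b$t_idx] / b$w
}

ctx_objective <- function(ctx, theta, penalty = 1e12) {
  if (!identical(names(theta), ctx$theta_names)) {
    theta <- theta[ctx$theta_names]
    if (anyNA(theta)) return(penalty)
  }
  ss <- 0
  for (sc in ctx$scenarios) {
    states <- ctx_states(ctx, sc, theta)
    if (is.null(states)) return(penalty)
    for (b in sc$blocks) {
      r <- block_fitted_w(states, b) - b$obs / b$w
      ss <- ss + sum(r * r)
    }
  }
  if (!is.finite(ss)) return(penalty)
  ss
}

# annotated residual table (slow path; same integrator as the fast path)
ctx_residuals <- function(ctx, theta) {
  if (!identical(names(theta), ctx$theta_names))
    theta <- theta[ctx$theta_names]
  if (anyNA(theta)) return(NULL)
  out <- list()
  for (sc in ctx$scenarios) {
    states <- ctx_states(ctx, sc, theta)
    if (is.null(states)) return(NULL)
    for (b in sc$blocks) {
      fw <- block_fitted_w(states, b)
      out[[length(out) + 1L]] <-
        data.frame(scenario_id = sc$scn$id, time_h = b$time_h,
                   stream = b$stream, group = b$group, weight = b$w,
                   fitted_w = fw, obs_w = b$obs / b$w,
                   resid_w = fw - b$obs / b$w, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Least-squares objective of a parameter vector
#'
#' Computes \eqn{F(\theta) = \sum_k |u(t_k;\theta) - w(t_k)|^2} over all data
#' points of all scenarios in the dataset, where \eqn{u} is the model
#' solution at the observation times and \eqn{w} the observations, each
#' stream first divided by its weight scale.  A simulation failure under
#' \code{theta} returns the finite \code{penalty} value so a Nelder-Mead
#' search can step past it.
#'
#' @param theta named parameter vector (see [params_to_theta()]).
#' @param data a [gln_data()] dataset.
#' @param weights stream weight scales, see [stream_weights()].
#' @param rtol,atol,solver solver settings, as in [simulate_scenario()].
#' @param penalty finite value returned when simulation fails.
#' @param use_measured_t0 use measured t = 0 concentrations as initial
#'   conditions instead of the nominal dosed values.
#' @return Nonnegative scalar.
#' @examples
#' d <- generate_data(design_spec("CAF", noise = 0), published_params("caf"))
#' gln_objective(params_to_theta(published_params("caf")), d)  # ~0
#' @export
gln_objective <- function(theta, data, weights = stream_weights(),
                          rtol = 1e-8, atol = 1e-10, solver = "dp45",
                          penalty = 1e12, use_measured_t0 = FALSE) {
  ctx <- obj_context(data, weights, rtol, atol, solver, use_measured_t0)
  ctx_objective(ctx, theta, penalty)
}
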