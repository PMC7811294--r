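# Parametric bootstrap: error-variance estimation, replicate generation,
# percentile confidence intervals, and CI-width sensitivity ranking.

#' Estimate measurement-error variances from fit residuals
#'
#' Pools the weighted residuals \eqn{w - u(\cdot;\hat\psi)} within each error
#' group and returns the unbiased sample variance per group.  The default
#' grouping is per cell type, matching the assumed error model
#' \eqn{\epsilon = (\epsilon_{CAF}, \epsilon_{CC})} with independent
#' \eqn{N(0, \sigma^2)} components (coculture concentration streams form a
#' third, shared group); \code{grouping = "stream"} estimates one variance
#' per stream instead.
#'
#' @param object a [glnfit()] object.
#' @param grouping \code{"cell_type"} (default) or \code{"stream"}.
#' @return Named numeric vector of variances on the weighted scale.
#' @export
estimate_sigmas <- function(object, grouping = c("cell_type", "stream")) {
  stopifnot(inherits(object, "glnfit"))
  grouping <- match.arg(grouping)
  r <- ctx_residuals(object$ctx, object$coefficients)
  if (is.null(r)) stop("fit is not simulatable", call. = FALSE)
  g <- if (grouping == "cell_type") r$group else r$stream
  sizes <- table(g)
  if (any(sizes < 2))
    stop("error group(s) with fewer than 2 residuals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  vapply(split(r$resid_w, g), var, 0)
}

#' Simulate parametric replicate datasets from a fit
#'
#' Each replicate is the model at the fitted parameters plus independent
#' Gaussian noise with the group variances of [estimate_sigmas()], truncated
#' at 0 — the data model of the parametric bootstrap.
#'
#' @param object a [glnfit()] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (reproducible given the seed).
#' @param grouping error grouping passed to [estimate_sigmas()].
#' @param sigma2 optional variance vector overriding the estimate.
#' @param ... unused.
#' @return List of \code{nsim} [gln_data()] datasets.
#' @export
simulate.glnfit <- function(object, nsim = 1, seed = NULL,
                            grouping = c("cell_type", "stream"),
                            sigma2 = NULL, ...) {
  grouping <- match.arg(grouping)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (is.null(sigma2)) sigma2 <- estimate_sigmas(object, grouping)
  r <- ctx_residuals(object$ctx, object$coefficients)
  g <- if (grouping == "cell_type") r$group else r$stream
  sd_w <- sqrt(sigma2[g])
  mu_raw <- r$fitted_w * r$weight
  sd_raw <- sd_w * r$weight
  scns <- dataset_scenarios(object$data)
  ct <- dataset_cell_type(object$data)
  lapply(seq_len(nsim), function(i) {
    val <- pmax(mu_raw + rnorm(length(mu_raw), 0, sd_raw), 0)
    gln_data(data.frame(scenario_id = r$scenario_id, time_h = r$time_h,
                        stream = r$stream, value = val,
                        stringsAsFactors = FALSE),
             scns, ct)
  })
}

#' Parametric-bootstrap confidence intervals
#'
#' Simulates \code{n_replicates} datasets at the fitted parameters
#' (model + Gaussian noise per error group, truncated at 0), refits each
#' replicate starting from the point estimate with the same free-parameter
#' mask, and returns percentile confidence intervals.  Fully reproducible
#' given \code{seed}.  Aborts if more than \code{max_fail} of the replicate
#' refits fail.
#'
#' @param object a converged [glnfit()].
#' @param n_replicates bootstrap replicates (published analysis used 300).
#' @param level confidence level.
#' @param seed integer seed.
#' @param grouping error grouping, see [estimate_sigmas()].
#' @param control optional [glnfit_control()] for the replicate refits;
#'   defaults to the original fit's control with a single optimizer run.
#' @param max_fail largest tolerated fraction of failed refits.
#' @param method \code{"percentile"} (default) or \code{"normal"}
#'   (normal approximation using the replicate SD).
#' @return An object of class \code{"glnboot"}: replicate estimates,
#'   \code{ci_low}/\code{ci_high} per parameter, noise-variance estimates,
#'   seed.
#' @seealso [sensitivity_table()]
#' @export
bootstrap_ci <- function(object, n_replicates = 300, level = 0.95,
                         seed = 1, grouping = c("cell_type", "stream"),
                         control = NULL, max_fail = 0.1,
                         method = c("percentile", "normal")) {
  stopifnot(inherits(object, "glnfit"))
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  if (!object$converged)
    warning("bootstrapping a fit that did not report convergence")
  if (is.null(control)) {
    control <- object$control
    control$restarts <- 0
  }
  sigma2 <- estimate_sigmas(object, grouping)
  sims <- simulate(object, nsim = n_replicates, seed = seed,
                   grouping = grouping, sigma2 = sigma2)
  point <- object$coefficients
  reps <- matrix(NA_real_, n_replicates, length(point),
                 dimnames = list(NULL, names(point)))
  failed <- 0L
  for (i in seq_len(n_replicates)) {
    fi <- tryCatch(
      glnfit(sims[[i]], init = point, free = object$free,
             weights = object$weights, control = control,
             use_measured_t0 = object$use_measured_t0),
      error = function(e) NULL)
    if (is.null(fi) || fi$objective >= control$penalty) {
      failed <- failed + 1L
    } else {
      reps[i, ] <- fi$coefficients
    }
  }
  if (failed > max_fail * n_replicates)
    stop(sprintf("bootstrap aborted: %d/%d replicate refits failed",
                 failed, n_replicates), call. = FALSE)
  ok <- !is.na(reps[, 1])
  alpha <- (1 - level) / 2
  ci_low <- point
  ci_high <- point
  for (p in object$free) {
    x <- reps[ok, p]
    if (method == "percentile") {
      q <- quantile(x, c(alpha, 1 - alpha), names = FALSE, type = 7)
    } else {
      q <- point[[p]] + stats::qnorm(c(alpha, 1 - alpha)) * stats::sd(x)
    }
    ci_low[p] <- q[1]
    ci_high[p] <- q[2]
  }
  structure(list(replicates = reps[ok, , drop = FALSE], point = point,
                 ci_low = ci_low, ci_high = ci_high, level = level,
                 n_replicates = n_replicates, n_failed = failed,
                 sigma_estimates = sigma2, grouping = grouping,
                 seed = seed, free = object$free, method = method),
            class = "glnboot")
}

#' @export
print.glnboot <- function(x, digits = 4, ...) {
  cat(sprintf("Parametric bootstrap: %d replicates (%d failed), %.0f%% %s CIs, seed %s\n",
              x$n_replicates, x$n_failed, 100 * x$level, x$method,
              format(x$seed)))
  tab <- data.frame(estimate = signif(x$point[x$free], digits),
                    ci_low = signif(x$ci_low[x$free], digits),
                    ci_high = signif(x$ci_high[x$free], digits))
  print(tab)
  cat("noise variances (weighted scale):",
      paste(sprintf("%s=%.4g", names(x$sigma_estimates), x$sigma_estimates),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sensitivity ranking by normalized confidence-interval width
#'
#' Normalizes each parameter's interval by its point estimate and ranks
#' parameters by relative width, narrowest first: a narrow interval means the
#' objective deteriorates quickly when the parameter moves off its optimum,
#' i.e. a highly sensitive (well-identified) parameter.
#'
#' @param x a [bootstrap_ci()] result, or a data frame with columns
#'   \code{parameter}, \code{estimate}, \code{ci_low}, \code{ci_high} (e.g.
#'   a published parameter table, see
#'   \code{published_params(set, ci = TRUE)}).
#' @param ... unused.
#' @return Data frame (\code{parameter}, \code{low_rel}, \code{high_rel},
#'   \code{rel_width}, \code{flagged}) sorted by ascending relative width;
#'   parameters with a zero point estimate are flagged, not divided, and sort
#'   last.
#' @examples
#' sensitivity_table(published_params("caf", ci = TRUE))
#' @export
sensitivity_table <- function(x, ...) UseMethod("sensitivity_table")

#' @export
sensitivity_table.glnboot <- function(x, ...) {
  df <- data.frame(parameter = x$free,
                   estimate = unname(x$point[x$free]),
                   ci_low = unname(x$ci_low[x$free]),
                   ci_high = unname(x$ci_high[x$free]),
                   stringsAsFactors = FALSE)
  sensitivity_table(df)
}

#' @export
sensitivity_table.data.frame <- function(x, ...) {
  need <- c("parameter", "ci_low", "ci_high")
  if (!all(need %in% names(x)))
    stop("need columns parameter, estimate (or value), ci_low, ci_high",
         call. = FALSE)
  est <- if ("estimate" %in% names(x)) x$estimate else x$value
  if (is.null(est)) stop("need an estimate or value column", call. = FALSE)
  zero <- est == 0
  low_rel <- ifelse(zero, NA_real_, x$ci_low / est)
  high_rel <- ifelse(zero, NA_real_, x$ci_high / est)
  out <- data.frame(parameter = x$parameter,
                    low_rel = low_rel, high_rel = high_rel,
                    rel_width = high_rel - low_rel,
                    flagged = zero, stringsAsFactors = FALSE)
  out <- out[order(out$flagged, out$rel_width), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
plot.glnboot <- function(x, ...) {
  tab <- sensitivity_table(x)
  tab <- tab[!tab$flagged, ]
  n <- nrow(tab)
  plot(NA, xlim = range(c(tab$low_rel, tab$high_rel, 1)), ylim = c(0.5, n + 0.5),
       yaxt = "n", xlab = "value relative to estimate", ylab = "",
       main = sprintf("%.0f%% bootstrap CIs (normalized)", 100 * x$level), ...)
  axis(2, at = seq_len(n), labels = tab$parameter, las = 1)
  segments(tab$low_rel, seq_len(n), tab$high_rel, seq_len(n))
  points(rep(1, n), seq_len(n), pch = 19)
  invisible(x)
}
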