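# Synthetic experiment generator: reproduces the dosing design and the
# additive-Gaussian measurement model the inference machinery assumes.

#' Describe a synthetic experiment design
#'
#' Defaults mirror the culture protocol: monocultures seeded at 8e4 cells and
#' dosed with Gln at 0/1/2/4 mM or NH4Cl at 0/5/10/25 mM; cocultures seeded
#' 1:1 at the same total; the alternative energy pool at 20 mM; observations
#' every 24 h for 72 h, each the average of three independently noised
#' replicates.
#'
#' Noise is measurement error only (no process noise): each replicate
#' observation is the model value plus independent Gaussian noise.  \code{noise}
#' is the per-replicate standard deviation on the weighted scale of
#' [stream_weights()] (concentrations in mM, counts in units of 1e4 cells), so
#' one sigma per error group spans streams of different physical units.  It
#' may be a scalar or a named vector over groups (\code{CAF}, \code{CC}, and
#' \code{shared} for coculture concentrations).
#'
#' @param cell_type \code{"CAF"}, \code{"CC"} or \code{"coculture"}.
#' @param gln_doses Gln doses, mM (one scenario each; \code{A0 = dose}).
#' @param nh4_doses NH4Cl doses, mM (one scenario each; \code{W0 = dose}).
#' @param obs_times observation times, hours.
#' @param X0_total total seeded cells.
#' @param coculture_ratio CAF fraction of the seeded coculture.
#' @param R0 initial alternative-energy concentration, mM.
#' @param noise per-replicate measurement SD on the weighted scale (see
#'   Details); 0 gives noiseless data.
#' @param n_replicates_averaged replicates averaged per reported observation.
#' @param variant coculture model variant (ignored for monocultures).
#' @return An object of class \code{"design_spec"}.
#' @seealso [generate_data()]
#' @export
design_spec <- function(cell_type = c("CAF", "CC", "coculture"),
                        gln_doses = c(0, 1, 2, 4),
                        nh4_doses = c(0, 5, 10, 25),
                        obs_times = c(0, 24, 48, 72),
                        X0_total = 8e4,
                        coculture_ratio = 0.5,
                        R0 = 20,
                        noise = 0.3,
                        n_replicates_averaged = 3,
                        variant = c("coculture_merged", "coculture_stress",
                                    "coculture_normalized")) {
  cell_type <- match.arg(cell_type)
  variant <- match.arg(variant)
  if (any(gln_doses < 0) || any(nh4_doses < 0))
    stop("doses must be nonnegative", call. = FALSE)
  if (coculture_ratio <= 0 || coculture_ratio >= 1)
    stop("coculture_ratio must be in (0, 1)", call. = FALSE)
  if (any(noise < 0)) stop("noise SD must be nonnegative", call. = FALSE)
  if (n_replicates_averaged < 1)
    stop("n_replicates_averaged must be >= 1", call. = FALSE)
  structure(list(cell_type = cell_type, gln_doses = gln_doses,
                 nh4_doses = nh4_doses, obs_times = obs_times,
                 X0_total = X0_total, coculture_ratio = coculture_ratio,
                 R0 = R0, noise = noise,
                 n_replicates_averaged = as.integer(n_replicates_averaged),
                 variant = if (cell_type == "coculture") variant else NA_character_),
            class = "design_spec")
}

design_scenarios <- function(design) {
  ct <- design$cell_type
  variant <- switch(ct, CAF = "caf_mono", CC = "cc_mono", design$variant)
  co <- ct == "coculture"
  X0 <- if (co) design$X0_total * design$coculture_ratio else design$X0_total
  Y0 <- if (co) design$X0_total - X0 else 0
  mk <- function(A0, W0, tag) {
    scenario(variant, A0 = A0, W0 = W0, R0 = design$R0, X0 = X0, Y0 = Y0,
             horizon = max(design$obs_times), obs_times = design$obs_times,
             id = tag)
  }
  scns <- c(lapply(design$gln_doses, function(d) mk(d, 0, sprintf("gln_%g", d))),
            lapply(design$nh4_doses, function(d) mk(0, d, sprintf("nh4_%g", d))))
  names(scns) <- vapply(scns, `[[`, "", "id")
  scns
}

design_streams <- function(cell_type) {
  switch(cell_type,
         CAF = c("Gln_mM", "NH4_mM", "cells_CAF"),
         CC = c("Gln_mM", "NH4_mM", "cells_CC"),
         coculture = c("Gln_mM", "NH4_mM", "cells_CAF", "cells_CC"))
}

# error group of a stream under the per-cell-type grouping
stream_group <- function(stream, cell_type) {
  if (cell_type == "CAF") return(rep("CAF", length(stream)))
  if (cell_type == "CC") return(rep("CC", length(stream)))
  ifelse(stream == "cells_CAF", "CAF",
         ifelse(stream == "cells_CC", "CC", "shared"))
}

noise_sd_of_group <- function(noise, group) {
  if (is.null(names(noise))) return(rep(unname(noise)[1], length(group)))
  miss <- setdiff(unique(group), names(noise))
  if (length(miss))
    stop("noise has no SD for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  unname(noise[group])
}

# model value of a stream from a trajectory state matrix
stream_from_states <- function(states, stream, variant) {
  co <- grepl("^coculture", variant)
  switch(stream,
         Gln_mM = states[, "A"],
         NH4_mM = states[, "W"],
         cells_CAF = states[, "X"],
         cells_CC = if (co) states[, "Y"] else states[, "X"],
         cells_total = if (co) states[, "X"] + states[, "Y"] else states[, "X"],
         stop("unknown stream ", stream, call. = FALSE))
}

#' Generate a synthetic dataset
#'
#' Simulates every dosing scenario of the design at the given true
#' parameters, samples the observation times, and reports the average of
#' \code{n_replicates_averaged} independently Gaussian-noised copies of each
#' observation (mimicking triplicate averaging).  Averages are truncated at 0
#' and cell counts rounded to whole cells.  The true parameter vector is
#' attached as attribute \code{"truth"} for recovery scoring.
#'
#' @param design a [design_spec()].
#' @param truth true parameters ([mono_params()] or [co_params()] matching
#'   the design's cell type).
#' @param seed integer seed; the result is bit-reproducible given the seed.
#' @param rtol,atol solver tolerances passed to [simulate_scenario()].
#' @return A [gln_data()] with attributes \code{truth}, \code{design},
#'   \code{seed}.
#' @examples
#' d <- generate_data(design_spec("CAF", noise = 0.1), published_params("caf"),
#'                    seed = 1)
#' head(d)
#' @export
generate_data <- function(design, truth, seed = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  scns <- design_scenarios(design)
  streams <- design_streams(design$cell_type)
  w <- stream_weights()
  nrep <- design$n_replicates_averaged
  recs <- lapply(scns, function(scn) {
    check_variant_params(scn, truth)
    tr <- simulate_scenario(scn, truth, rtol = rtol, atol = atol)
    do.call(rbind, lapply(streams, function(st) {
      mu <- stream_from_states(tr$states, st, scn$variant)
      grp <- stream_group(st, design$cell_type)[1]
      sd_raw <- noise_sd_of_group(design$noise, grp) * w[[st]]
      if (sd_raw > 0) {
        obs <- pmax(vapply(mu, function(m) mean(rnorm(nrep, m, sd_raw)), 0), 0)
        # counts are whole cells; concentrations are not rounded.  sigma = 0
        # must return the model output exactly, so no rounding then.
        if (st %in% c("cells_CAF", "cells_CC", "cells_total"))
          obs <- round(obs)
      } else obs <- mu
      data.frame(scenario_id = scn$id, time_h = tr$times, stream = st,
                 value = obs, stringsAsFactors = FALSE)
    }))
  })
  records <- do.call(rbind, c(recs, make.row.names = FALSE))
  out <- gln_data(records, scns, design$cell_type)
  attr(out, "truth") <- params_to_theta(truth)
  attr(out, "design") <- design
  attr(out, "seed") <- seed
  out
}
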