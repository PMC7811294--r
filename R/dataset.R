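# Observed time-course datasets: tidy records plus the scenario definitions
# needed to simulate them.

.STREAMS <- c("Gln_mM", "NH4_mM", "cells_CAF", "cells_CC", "cells_total")

#' Assemble a time-course dataset
#'
#' A dataset holds tidy observation records — one row per
#' (scenario, time, stream) — together with the [scenario()] definitions
#' needed to simulate each scenario.  Streams are \code{Gln_mM},
#' \code{NH4_mM}, \code{cells_CAF}, \code{cells_CC}, \code{cells_total}.
#'
#' @param records data frame with columns \code{scenario_id}, \code{time_h},
#'   \code{stream}, \code{value}; values nonnegative, each
#'   (scenario, time, stream) unique.
#' @param scenarios named list of [scenario()] objects covering every
#'   \code{scenario_id} in \code{records}.
#' @param cell_type \code{"CAF"}, \code{"CC"} or \code{"coculture"}; which
#'   cell type's experiment this is (fits pool all scenarios of one cell
#'   type).
#' @return A data frame of class \code{"gln_data"} carrying the scenarios and
#'   cell type as attributes.
#' @export
gln_data <- function(records, scenarios, cell_type = c("CAF", "CC",
                                                       "coculture")) {
  cell_type <- match.arg(cell_type)
  need <- c("scenario_id", "time_h", "stream", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  records <- records[need]
  if (!all(records$stream %in% .STREAMS))
    stop("unknown stream(s): ",
         paste(setdiff(unique(records$stream), .STREAMS), collapse = ", "),
         call. = FALSE)
  if (any(records$value < 0) || anyNA(records$value))
    stop("observed values must be nonnegative and non-missing", call. = FALSE)
  key <- paste(records$scenario_id, records$time_h, records$stream)
  if (anyDuplicated(key))
    stop("duplicate (scenario, time, stream) records", call. = FALSE)
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  names(scenarios) <- vapply(scenarios, `[[`, "", "id")
  missing_scn <- setdiff(unique(records$scenario_id), names(scenarios))
  if (length(missing_scn))
    stop("no scenario definition for: ", paste(missing_scn, collapse = ", "),
         call. = FALSE)
  for (s in scenarios) {
    tt <- records$time_h[records$scenario_id == s$id]
    if (length(tt) && !all(tt %in% s$obs_times))
      stop(sprintf("scenario '%s': record times outside obs_times", s$id),
           call. = FALSE)
  }
  structure(records, scenarios = scenarios, cell_type = cell_type,
            class = c("gln_data", "data.frame"))
}

dataset_scenarios <- function(data) attr(data, "scenarios")
dataset_cell_type <- function(data) attr(data, "cell_type")

#' Read and write datasets as tidy delimited text
#'
#' The records go to a tab-separated file with columns \code{scenario_id},
#' \code{time_h}, \code{stream}, \code{value}; the scenario definitions go to
#' a YAML sidecar (default \code{<path>.scenarios.yaml}).
#'
#' @param data a [gln_data()] object.
#' @param path records file path.
#' @param scenarios_path scenario sidecar path.
#' @param cell_type required by \code{read_dataset} (not stored in the TSV).
#' @return \code{read_dataset()} returns a \code{gln_data};
#'   \code{write_dataset()} returns \code{path} invisibly.
#' @export
write_dataset <- function(data, path,
                          scenarios_path = paste0(path, ".scenarios.yaml")) {
  stopifnot(inherits(data, "gln_data"))
  write.table(as.data.frame(unclass(data)[c("scenario_id", "time_h",
                                            "stream", "value")]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_scenarios(dataset_scenarios(data), scenarios_path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, cell_type,
                         scenarios_path = paste0(path, ".scenarios.yaml")) {
  records <- read.delim(path, stringsAsFactors = FALSE)
  scenarios <- read_scenarios(scenarios_path)
  gln_data(records, scenarios, cell_type)
}

#' @export
print.gln_data <- function(x, ...) {
  cat(sprintf("Time-course dataset (%s): %d records, %d scenarios\n",
              dataset_cell_type(x), nrow(x),
              length(dataset_scenarios(x))))
  NextMethod()
}
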