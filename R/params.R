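# Parameter containers for the monoculture and coculture models.
#
# Internal parameter order is fixed and shared with the compiled integrator:
# k1 c1 k2 c2 h k3 r1 K1 r2 K2 d1 d2.

.PARAM_NAMES <- c("k1", "c1", "k2", "c2", "h", "k3",
                  "r1", "K1", "r2", "K2", "d1", "d2")

#' Kinetic parameters of a monoculture model
#'
#' Constructs the 12-parameter set of the single-cell-type Gln/NH4+ exchange
#' model.  Units assume concentrations in mM, cell numbers in cells and time
#' in hours, so published table values can be used verbatim.
#'
#' @param k1 conversion rate of Gln to NH4+, 1/(cell h).
#' @param c1 dimensionless NH4+ yield per Gln converted.
#' @param k2 conversion rate of NH4+ back to Gln, 1/(cell mM h); the reverse
#'   reaction also consumes the alternative energy pool.
#' @param c2 dimensionless Gln yield per NH4+ converted.
#' @param h basal NH4+ production rate, mM/(cell h).
#' @param k3 consumption rate of the alternative energy pool, 1/(cell h).
#' @param r1 maximal growth rate on Gln, 1/h (Monod kinetics).
#' @param K1 half-saturation Gln concentration, mM.
#' @param r2 maximal growth rate on the alternative energy pool, 1/h.  Cancer
#'   cells cannot grow on this pool, so their set has \code{r2 = 0}.
#' @param K2 half-saturation concentration of the alternative pool, mM.
#'   Inert when \code{r2 = 0}.
#' @param d1 NH4+-induced death rate, 1/(mM h).
#' @param d2 background death rate, 1/h.
#'
#' @return A named numeric vector of class \code{"mono_params"}.
#' @examples
#' p <- published_params("caf")
#' p["r1"]
#' @seealso [published_params()], [co_params()], [mono_rhs()]
#' @export
mono_params <- function(k1, c1, k2, c2, h, k3, r1, K1, r2 = 0, K2 = 1,
                        d1, d2) {
  p <- c(k1 = k1, c1 = c1, k2 = k2, c2 = c2, h = h, k3 = k3,
         r1 = r1, K1 = K1, r2 = r2, K2 = K2, d1 = d1, d2 = d2)
  validate_mono_params(p)
  structure(p, class = "mono_params")
}

validate_mono_params <- function(p) {
  if (!is.numeric(p) || length(p) != 12L || !identical(names(p), .PARAM_NAMES))
    stop("monoculture parameters must be the 12 named rates ",
         paste(.PARAM_NAMES, collapse = ", "), call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop("monoculture parameters must be finite", call. = FALSE)
  if (any(p < 0))
    stop("monoculture parameters must be nonnegative; negative: ",
         paste(names(p)[p < 0], collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Parameters of a coculture model
#'
#' Bundles a CAF and a CC monoculture parameter set sharing one metabolic
#' environment, plus the stress-factor constants used by the stress variant:
#' the stress factor L is produced at rate \code{g*X*Y} and kills both cell
#' types at per-capita rate \code{m*L^2}.  The merged coculture model is the
#' special case \code{g = m = 0}.
#'
#' @param caf,cc \code{mono_params} for the fibroblasts and the cancer cells.
#' @param g stress production rate, 1/(h cell^2).
#' @param m stress kill coefficient, 1/h.
#' @return An object of class \code{"co_params"}.
#' @seealso [published_params()], [co_rhs()]
#' @export
co_params <- function(caf, cc, g = 0, m = 0) {
  validate_mono_params(caf)
  validate_mono_params(cc)
  if (!is.numeric(g) || length(g) != 1L || !is.finite(g) || g < 0)
    stop("g must be a nonnegative scalar", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0)
    stop("m must be a nonnegative scalar", call. = FALSE)
  structure(list(caf = unclass(caf), cc = unclass(cc),
                 g = unname(g), m = unname(m)),
            class = "co_params")
}

#' Published parameter sets
#'
#' Returns the fitted parameter values shipped with the package as plain-text
#' fixtures (see \code{system.file("extdata", package = "glnamm")}):
#' \describe{
#'   \item{\code{"caf"}}{CAF monoculture fit (12 parameters).}
#'   \item{\code{"cc"}}{cancer-cell monoculture fit (\code{r2 = 0}; \code{K2}
#'     inert and set to 1).}
#'   \item{\code{"coculture_merged"}}{both monoculture sets with the two
#'     adjusted coculture growth rates (\code{caf.r1 = 5e-3},
#'     \code{cc.r1 = 6e-2}) and no stress factor.}
#'   \item{\code{"coculture_stress"}}{monoculture growth rates reverted to
#'     their original values, plus the stress constants \code{g}, \code{m}.}
#' }
#'
#' @param set which parameter set to load.
#' @param ci if \code{TRUE}, return the full fixture table (estimate and 95\%
#'   confidence bounds) as a data frame instead of a parameter object.  Only
#'   available for the monoculture sets.
#' @return A \code{mono_params}, a \code{co_params}, or a data frame.
#' @examples
#' published_params("caf")["r1"]
#' head(published_params("cc", ci = TRUE))
#' @export
published_params <- function(set = c("caf", "cc", "coculture_merged",
                                     "coculture_stress"),
                             ci = FALSE) {
  set <- match.arg(set)
  read_fixture <- function(f) {
    path <- system.file("extdata", f, package = "glnamm", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
  }
  mono_from_table <- function(tab) {
    p <- setNames(tab$value, tab$parameter)
    if (!"r2" %in% names(p)) p[["r2"]] <- 0
    if (!"K2" %in% names(p)) p[["K2"]] <- 1
    do.call(mono_params, as.list(p[.PARAM_NAMES]))
  }
  if (set %in% c("caf", "cc")) {
    tab <- read_fixture(paste0("params_", set, ".tsv"))
    if (ci) return(tab)
    return(mono_from_table(tab))
  }
  if (ci) stop("CI tables are shipped for the monoculture sets only",
               call. = FALSE)
  caf <- published_params("caf")
  cc <- published_params("cc")
  if (set == "coculture_merged") {
    adj <- read_fixture("params_coculture.tsv")
    caf["r1"] <- adj$value[adj$parameter == "caf.r1"]
    cc["r1"] <- adj$value[adj$parameter == "cc.r1"]
    return(co_params(caf, cc, g = 0, m = 0))
  }
  st <- read_fixture("params_stress.tsv")
  co_params(caf, cc,
            g = st$value[st$parameter == "g"],
            m = st$value[st$parameter == "m"])
}

# --- flat parameter vectors ("theta") used by the optimizer ----------------

#' Flatten a parameter object to a named vector
#'
#' Monoculture parameters flatten to their 12 named rates; coculture
#' parameters flatten to 26 entries with \code{caf.}/\code{cc.} prefixes plus
#' \code{g} and \code{m}.  [theta_to_params()] is the inverse.
#'
#' @param params a \code{mono_params} or \code{co_params} object.
#' @return A named numeric vector.
#' @export
params_to_theta <- function(params) {
  if (inherits(params, "mono_params")) return(unclass(params))
  if (inherits(params, "co_params")) {
    th <- c(setNames(params$caf, paste0("caf.", .PARAM_NAMES)),
            setNames(params$cc, paste0("cc.", .PARAM_NAMES)),
            g = params$g, m = params$m)
    return(th)
  }
  stop("params must be mono_params or co_params", call. = FALSE)
}

#' @rdname params_to_theta
#' @param theta a named numeric vector as produced by [params_to_theta()].
#' @export
theta_to_params <- function(theta) {
  if (length(theta) == 12L && identical(names(theta), .PARAM_NAMES))
    return(structure(theta, class = "mono_params"))
  if (length(theta) == 26L) {
    caf <- setNames(unname(theta[paste0("caf.", .PARAM_NAMES)]), .PARAM_NAMES)
    cc <- setNames(unname(theta[paste0("cc.", .PARAM_NAMES)]), .PARAM_NAMES)
    return(co_params(structure(caf, class = "mono_params"),
                     structure(cc, class = "mono_params"),
                     g = theta[["g"]], m = theta[["m"]]))
  }
  stop("theta must have 12 (monoculture) or 26 (coculture) named entries",
       call. = FALSE)
}

#' Read and write parameter configuration files
#'
#' Parameter sets are serialized as flat key/value YAML with the table names
#' (\code{k1 ... d2}, with \code{caf.}/\code{cc.} prefixes and \code{g},
#' \code{m} for cocultures).
#'
#' @param params a \code{mono_params} or \code{co_params} object.
#' @param path file path.
#' @return \code{read_params()} returns a parameter object;
#'   \code{write_params()} returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  th <- params_to_theta(params)
  yaml::write_yaml(as.list(th), path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  theta_to_params(unlist(x))
}

#' @export
print.mono_params <- function(x, ...) {
  cat("Monoculture kinetic parameters (mM, cells, hours):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.co_params <- function(x, ...) {
  cat("Coculture kinetic parameters (mM, cells, hours):\n")
  cat("CAF:\n"); print(x$caf, ...)
  cat("CC:\n"); print(x$cc, ...)
  cat(sprintf("stress: g = %g 1/(h cell^2), m = %g 1/h\n", x$g, x$m))
  invisible(x)
}
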