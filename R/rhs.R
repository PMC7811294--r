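# Model right-hand sides (pure R).  These mirror the compiled versions used
# by the simulator and exist as the reference formulation: validation,
# documentation, tests and the deSolve fallback all go through them.

.VARIANTS <- c("caf_mono", "cc_mono", "coculture_merged",
               "coculture_stress", "coculture_normalized")

.monod <- function(r, K, s) {
  if (r == 0) return(0)
  den <- K + s
  if (den <= 0) return(0)
  r * s / den
}

#' Monoculture model time derivatives
#'
#' Right-hand side of the single-cell-type Gln/NH4+ exchange model.  With
#' state \eqn{(A, W, R, X)} (Gln mM, NH4+ mM, alternative energy mM, live
#' cells) the derivatives per hour are
#' \deqn{dA/dt = -k_1 A X + c_2 k_2 W R X}
#' \deqn{dW/dt = c_1 k_1 A X - k_2 W R X + h X}
#' \deqn{dR/dt = -k_2 W R X - k_3 R X}
#' \deqn{dX/dt = (r_1 A/(K_1+A) + r_2 R/(K_2+R) - d_1 W - d_2) X.}
#' Every term carries a factor \eqn{X}, so the derivative vanishes when no
#' cells are present, and each component's derivative is nonnegative on its
#' zero boundary, which keeps trajectories nonnegative.
#'
#' @param state named numeric vector with components \code{A}, \code{W},
#'   \code{R}, \code{X}, all nonnegative.
#' @param params a [mono_params()] object (or named vector in that order).
#' @return Named numeric vector of derivatives (per hour).
#' @examples
#' mono_rhs(c(A = 0, W = 0, R = 20, X = 8e4), published_params("caf"))
#' @export
mono_rhs <- function(state, params) {
  p <- unclass(params)
  if (is.null(names(p))) names(p) <- .PARAM_NAMES[seq_along(p)]
  validate_mono_params(p[.PARAM_NAMES])
  s <- check_state(state, c("A", "W", "R", "X"))
  p <- as.list(unclass(params))
  glnloss <- p$k1 * s[["A"]] * s[["X"]]
  recycle <- p$k2 * s[["W"]] * s[["R"]] * s[["X"]]
  c(A = -glnloss + p$c2 * recycle,
    W = p$c1 * glnloss - recycle + p$h * s[["X"]],
    R = -recycle - p$k3 * s[["R"]] * s[["X"]],
    X = (.monod(p$r1, p$K1, s[["A"]]) + .monod(p$r2, p$K2, s[["R"]]) -
           p$d1 * s[["W"]] - p$d2) * s[["X"]])
}

check_state <- function(state, want) {
  if (is.null(names(state)) || !all(want %in% names(state)))
    stop("state must have named components ", paste(want, collapse = ", "),
         call. = FALSE)
  s <- state[want]
  if (anyNA(s) || any(!is.finite(s)))
    stop("state components must be finite", call. = FALSE)
  if (any(s < 0))
    stop("state components must be nonnegative; negative: ",
         paste(want[s < 0], collapse = ", "), call. = FALSE)
  s
}

#' Coculture model time derivatives
#'
#' Right-hand side of the merged coculture model: both cell types share one
#' metabolic environment \eqn{(A, W, R)} and each contributes its own
#' monoculture conversion, production and consumption terms, weighted by its
#' own live-cell count (\eqn{X} CAFs, \eqn{Y} cancer cells).  The stress
#' variant adds a dimensionless crowding factor \eqn{L} with
#' \eqn{dL/dt = g X Y}, \eqn{L(0) = 0}, and an extra per-capita loss
#' \eqn{-m L^2} in both growth equations.  The normalized-fibroblast variant
#' evaluates the CAF \eqn{k_2} terms as zero (fibroblasts no longer recycle
#' NH4+ to Gln).
#'
#' @param state named numeric vector with components \code{A}, \code{W},
#'   \code{R}, \code{X}, \code{Y} and, for the stress variant, \code{L}.
#' @param params a [co_params()] object.
#' @param variant one of \code{"coculture_merged"}, \code{"coculture_stress"},
#'   \code{"coculture_normalized"}.
#' @return Named numeric vector of derivatives (per hour); includes \code{L}
#'   for the stress variant.
#' @examples
#' p <- published_params("coculture_merged")
#' co_rhs(c(A = 4, W = 0, R = 20, X = 4e4, Y = 4e4), p)
#' @export
co_rhs <- function(state, params,
                   variant = c("coculture_merged", "coculture_stress",
                               "coculture_normalized")) {
  variant <- match.arg(variant)
  if (!inherits(params, "co_params"))
    stop("params must be a co_params object", call. = FALSE)
  stress <- variant == "coculture_stress"
  if (stress && (params$g <= 0 || params$m < 0))
    stop("stress variant needs g > 0 and m >= 0 in params", call. = FALSE)
  comps <- c("A", "W", "R", "X", "Y", if (stress) "L")
  s <- check_state(state, comps)
  pf <- as.list(params$caf)
  pc <- as.list(params$cc)
  if (variant == "coculture_normalized") pf$k2 <- 0
  A <- s[["A"]]; W <- s[["W"]]; R <- s[["R"]]
  X <- s[["X"]]; Y <- s[["Y"]]
  L <- if (stress) s[["L"]] else 0
  glnloss_f <- pf$k1 * A * X
  glnloss_c <- pc$k1 * A * Y
  recycle_f <- pf$k2 * W * R * X
  recycle_c <- pc$k2 * W * R * Y
  kill <- params$m * L^2
  d <- c(A = -glnloss_f + pf$c2 * recycle_f - glnloss_c + pc$c2 * recycle_c,
         W = pf$c1 * glnloss_f - recycle_f + pc$c1 * glnloss_c - recycle_c +
           pf$h * X + pc$h * Y,
         R = -recycle_f - recycle_c - pf$k3 * R * X - pc$k3 * R * Y,
         X = (.monod(pf$r1, pf$K1, A) + .monod(pf$r2, pf$K2, R) -
                pf$d1 * W - pf$d2 - kill) * X,
         Y = (.monod(pc$r1, pc$K1, A) + .monod(pc$r2, pc$K2, R) -
                pc$d1 * W - pc$d2 - kill) * Y)
  if (stress) d <- c(d, L = params$g * X * Y)
  d
}
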