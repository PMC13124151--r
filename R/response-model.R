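#' Sigmoid affinity-fitness response parameters
#'
#' The intrinsic birth (division) rate of a germinal-center B cell is modeled
#' as a four-parameter sigmoid of its log10-relative binding affinity `x`:
#' \deqn{\lambda(x) = \frac{y_c}{1 + e^{-x_c (x - x_h)}} + y_h}
#' where `xscale` (\eqn{x_c}) sets the steepness of the transition, `xshift`
#' (\eqn{x_h}) its midpoint on the affinity axis, `yscale` (\eqn{y_c}) the
#' height of the sigmoid (births per day), and `yshift` (\eqn{y_h}) the lower
#' asymptote — the residual fitness of very-low-affinity cells.
#'
#' @param xscale Steepness of the sigmoid transition (per affinity unit).
#' @param xshift Midpoint affinity of the transition (affinity units).
#' @param yscale Scale (upper minus lower asymptote) of the birth rate, > 0.
#' @param yshift Lower asymptote of the birth rate, >= 0.
#' @return An object of class `sigmoid_params`.
#' @examples
#' p <- sigmoid_params(1.6, 2.0, 18.2, 0.4)
#' sigmoid_response(p, 0)
#' @export
sigmoid_params <- function(xscale, xshift, yscale, yshift) {
  vals <- c(xscale = xscale, xshift = xshift, yscale = yscale, yshift = yshift)
  if (!all(is.finite(vals))) stop("sigmoid parameters must be finite")
  if (yscale <= 0) stop("yscale must be > 0")
  if (yshift < 0) stop("yshift must be >= 0")
  structure(as.list(vals), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_params> xscale=%.4g xshift=%.4g yscale=%.4g yshift=%.4g (naive rate %.4g)\n",
    x$xscale, x$xshift, x$yscale, x$yshift, naive_birth_rate(x)
  ))
  invisible(x)
}

#' @export
as.data.frame.sigmoid_params <- function(x, ...) {
  data.frame(xscale = x$xscale, xshift = x$xshift, yscale = x$yscale, yshift = x$yshift)
}

#' Evaluate the sigmoid affinity-fitness response
#'
#' Returns the intrinsic birth rate \eqn{\lambda(x)} for affinity `x`.
#' Evaluation is overflow-safe: extreme affinities return the corresponding
#' asymptote (`yshift` at \eqn{-\infty}, `yshift + yscale` at \eqn{+\infty}).
#'
#' @param params A [sigmoid_params()] object.
#' @param x Numeric vector of affinities (log10 relative to naive).
#' @return Numeric vector of birth rates (per day).
#' @export
sigmoid_response <- function(params, x) {
  stopifnot(inherits(params, "sigmoid_params"))
  z <- -params$xscale * (x - params$xshift)
  # exp() overflows above ~709; clamping the argument yields the exact
  # asymptote in double precision without warnings
  z <- pmin(pmax(z, -745), 745)
  params$yscale / (1 + exp(z)) + params$yshift
}

#' Naive (zero-affinity) birth rate
#'
#' The birth rate of the unmutated naive cell, neglecting the lower asymptote
#' `yshift`: \eqn{\lambda_0 = y_c / (1 + e^{x_c x_h})}. This is the quantity
#' constrained during training-set parameter sampling; it satisfies
#' `naive_birth_rate(p) + p$yshift == sigmoid_response(p, 0)` exactly.
#'
#' @param params A [sigmoid_params()] object.
#' @return The naive birth rate (per day).
#' @export
naive_birth_rate <- function(params) {
  stopifnot(inherits(params, "sigmoid_params"))
  z <- pmin(pmax(params$xscale * params$xshift, -745), 745)
  params$yscale / (1 + exp(z))
}

#' Affinity from dissociation constants
#'
#' Binding affinity is expressed on a log10 scale relative to the naive
#' antibody's dissociation constant: \eqn{x = -\log_{10}(K_D / K_D^N)}.
#' Stronger binding (lower \eqn{K_D}) gives larger `x`; the naive sequence has
#' affinity 0. The default naive \eqn{K_D^N} is 40 nM.
#'
#' @param k_d Dissociation constant(s), molar. Must be positive.
#' @param k_d_naive Naive dissociation constant, molar. Default `4e-8`.
#' @return Affinity value(s), dimensionless.
#' @seealso [relative_kd()] for the inverse map.
#' @export
affinity_from_kd <- function(k_d, k_d_naive = 4e-8) {
  if (any(k_d <= 0) || any(k_d_naive <= 0)) {
    stop("dissociation constants must be positive")
  }
  -log10(k_d / k_d_naive)
}

#' Relative dissociation constant from affinity
#'
#' Inverse of [affinity_from_kd()]: the ratio \eqn{K_D / K_D^N = 10^{-x}}.
#' An affinity of +2 corresponds to a \eqn{K_D} 0.01 times the naive value.
#'
#' @param x Affinity value(s).
#' @return Ratio of \eqn{K_D} to the naive \eqn{K_D}.
#' @export
relative_kd <- function(x) 10^(-x)

#' Parameter bounds for sampling and network clipping
#'
#' Closed intervals for each sigmoid parameter, the admissible interval for
#' the naive birth rate \eqn{\lambda_0}, and the (wider) clip intervals
#' applied to network outputs during training and prediction.
#'
#' @param xscale,xshift,yscale,yshift Length-2 numeric intervals for sampling.
#' @param lambda0 Length-2 interval for the naive birth rate.
#' @param clip Named list of length-2 intervals used by [clip_params()].
#' @return An object of class `param_bounds`.
#' @export
param_bounds <- function(xscale = c(0.01, 2), xshift = c(-0.5, 3),
                         yscale = c(0.5, 35), yshift = c(0, 0.6),
                         lambda0 = c(0.1, 15),
                         clip = list(xscale = c(0.001, 3.5), xshift = c(-1.5, 5),
                                     yscale = c(0.1, 65), yshift = c(0, 10))) {
  b <- list(xscale = xscale, xshift = xshift, yscale = yscale,
            yshift = yshift, lambda0 = lambda0, clip = clip)
  chk <- function(iv, nm) {
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] > iv[2]) {
      stop("invalid interval for ", nm)
    }
  }
  for (nm in c("xscale", "xshift", "yscale", "yshift", "lambda0")) chk(b[[nm]], nm)
  for (nm in names(b$clip)) chk(b$clip[[nm]], paste0("clip$", nm))
  structure(b, class = "param_bounds")
}

#' Training-set parameter bounds
#'
#' The default sampling box used to generate the training sample: xscale in
#' \[0.01, 2\], xshift in \[-0.5, 3\], yscale in \[0.5, 35\], yshift in
#' \[0, 0.6\], naive birth rate in \[0.1, 15\].
#'
#' @return A [param_bounds()] object.
#' @export
training_bounds <- function() param_bounds()

#' Central data-mimic sigmoid parameters
#'
#' The fixed parameter set used for data-mimic evaluation samples:
#' xscale 1.6, xshift 2.0, yscale 18.2, yshift 0.4.
#'
#' @return A [sigmoid_params()] object.
#' @export
central_mimic_params <- function() sigmoid_params(1.6, 2.0, 18.2, 0.4)

#' Sample sigmoid parameters subject to the naive-rate constraint
#'
#' Draws parameter sets uniformly within their boxes while guaranteeing that
#' the naive birth rate \eqn{\lambda_0} lies inside `bounds$lambda0`.
#' Parameters are drawn in the fixed order xscale, xshift, yscale, with the
#' admissible interval for each truncated by the constraint implied by the
#' previously drawn values:
#' \itemize{
#'   \item xshift is restricted to
#'     \eqn{(\log(y_c^l/\lambda_0^u - 1)/x_c,\ \log(y_c^u/\lambda_0^l - 1)/x_c)};
#'     a non-positive log argument makes that one-sided constraint vacuous
#'     (algebraically \eqn{\lambda_0 < y_c}, so the lower constraint cannot
#'     bind whenever \eqn{y_c^l < \lambda_0^u}).
#'   \item yscale is restricted to
#'     \eqn{(\lambda_0^l (1+e^{x_c x_h}),\ \lambda_0^u (1+e^{x_c x_h}))}.
#' }
#' yshift is drawn independently within its own box. Intervals are truncated
#' before drawing (no rejection loop), so draw counts per seed are
#' reproducible.
#'
#' @param n Number of draws.
#' @param bounds A [param_bounds()] object; default [training_bounds()].
#' @return A tibble with columns `xscale`, `xshift`, `yscale`, `yshift` and
#'   `lambda0` (the implied naive birth rate), one row per draw.
#' @export
sample_sigmoid_params <- function(n = 1, bounds = training_bounds()) {
  stopifnot(inherits(bounds, "param_bounds"), n >= 1)
  l0l <- bounds$lambda0[1]; l0u <- bounds$lambda0[2]
  ycl <- bounds$yscale[1]; ycu <- bounds$yscale[2]

  xc <- stats::runif(n, bounds$xscale[1], bounds$xscale[2])

  # Constraint interval for xshift given xscale; log of a non-positive
  # argument => that side is vacuous
  xh_lo_c <- if (ycl / l0u - 1 > 0) log(ycl / l0u - 1) / xc else rep(-Inf, n)
  xh_hi_c <- if (ycu / l0l - 1 > 0) log(ycu / l0l - 1) / xc else rep(Inf, n)
  xh_lo <- pmax(bounds$xshift[1], xh_lo_c)
  xh_hi <- pmin(bounds$xshift[2], xh_hi_c)
  if (any(xh_lo >= xh_hi)) {
    stop("empty feasible interval for xshift after applying the naive-rate constraint")
  }
  xh <- stats::runif(n, xh_lo, xh_hi)

  denom <- 1 + exp(pmin(xc * xh, 709))
  yc_lo <- pmax(bounds$yscale[1], l0l * denom)
  yc_hi <- pmin(bounds$yscale[2], l0u * denom)
  # an xshift draw at its constraint boundary collapses the yscale interval
  # to a point; treat tiny floating-point inversions as that degenerate case
  deg <- yc_lo >= yc_hi
  if (any(yc_lo - yc_hi > 1e-6 * pmax(1, abs(yc_hi)))) {
    stop("empty feasible interval for yscale after applying the naive-rate constraint")
  }
  yc_lo[deg] <- yc_hi[deg]
  yc <- stats::runif(n, yc_lo, yc_hi)
  yh <- stats::runif(n, bounds$yshift[1], bounds$yshift[2])

  tibble::tibble(xscale = xc, xshift = xh, yscale = yc, yshift = yh,
                 lambda0 = yc / denom)
}

#' Clip sigmoid parameters to the network clip box
#'
#' Clamps each parameter to its clip interval (wider than the sampling box).
#' The same clamp is applied to network outputs during training and
#' prediction. Idempotent.
#'
#' @param params A [sigmoid_params()] object.
#' @param bounds A [param_bounds()] object carrying the `clip` intervals.
#' @return A clipped [sigmoid_params()] object.
#' @export
clip_params <- function(params, bounds = training_bounds()) {
  stopifnot(inherits(params, "sigmoid_params"), inherits(bounds, "param_bounds"))
  cl <- bounds$clip
  clamp <- function(v, iv) min(max(v, iv[1]), iv[2])
  sigmoid_params(clamp(params$xscale, cl$xscale), clamp(params$xshift, cl$xshift),
                 clamp(params$yscale, cl$yscale), clamp(params$yshift, cl$yshift))
}

#' Write/read parameter bounds as a YAML config
#'
#' Serializes the sampling box, naive-rate interval and clip intervals.
#'
#' @param bounds A [param_bounds()] object.
#' @param path File path.
#' @return `read_param_bounds()` returns a [param_bounds()] object.
#' @export
write_param_bounds <- function(bounds, path) {
  stopifnot(inherits(bounds, "param_bounds"))
  yaml::write_yaml(unclass(bounds), path)
  invisible(path)
}

#' @rdname write_param_bounds
#' @export
read_param_bounds <- function(path) {
  b <- yaml::read_yaml(path)
  param_bounds(xscale = as.numeric(b$xscale), xshift = as.numeric(b$xshift),
               yscale = as.numeric(b$yscale), yshift = as.numeric(b$yshift),
               lambda0 = as.numeric(b$lambda0),
               clip = lapply(b$clip, as.numeric))
}
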