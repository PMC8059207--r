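# FRAP (fluorescence recovery after photobleaching) trace normalization
# and single-exponential recovery fitting.

#' Construct a normalized FRAP curve
#'
#' @param times Seconds from the bleach event; `t = 0` is the first
#'   post-bleach frame. Strictly increasing.
#' @param intensities Normalized fluorescence (pre-bleach mean = 1,
#'   first post-bleach value = 0).
#' @param frame_interval Acquisition interval in seconds.
#' @param n_prebleach Number of pre-bleach frames the normalization was
#'   based on.
#' @return An object of class `frap_curve`.
#' @seealso [normalize_frap()], [fit_frap()]
#' @export
frap_curve <- function(times, intensities, frame_interval = NA_real_,
                       n_prebleach = NA_integer_) {
  if (length(times) != length(intensities)) {
    stop("`times` and `intensities` must have equal length")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing")
  }
  if (!all(is.finite(intensities))) stop("`intensities` must be finite")
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         frame_interval = frame_interval, n_prebleach = n_prebleach),
    class = "frap_curve")
}

#' Normalize a raw FRAP trace
#'
#' Applies the affine map that sends the pre-bleach mean intensity to 1
#' and the first post-bleach intensity to 0, matching the recovery model
#' `FRAP(t) = a (1 - exp(-k t))` which starts at 0 and plateaus at the
#' mobile fraction `a`. Time zero is assigned to the first post-bleach
#' frame.
#'
#' @param raw_trace Numeric vector of raw intensities (arbitrary units),
#'   pre-bleach frames first.
#' @param n_prebleach Number of leading pre-bleach frames (>= 1).
#' @param frame_interval Seconds between frames (default 0.8 s, the
#'   standard acquisition cadence of 300 frames over 5 minutes).
#' @param times Optional explicit frame times (seconds, full trace);
#'   overrides `frame_interval`.
#' @return A [frap_curve()] covering the post-bleach frames.
#' @export
normalize_frap <- function(raw_trace, n_prebleach, frame_interval = 0.8,
                           times = NULL) {
  n <- length(raw_trace)
  if (n_prebleach < 1) stop("`n_prebleach` must be >= 1")
  if (n - n_prebleach < 10) {
    stop("need at least 10 post-bleach points (got ", n - n_prebleach, ")")
  }
  pre <- mean(raw_trace[seq_len(n_prebleach)])
  post <- raw_trace[(n_prebleach + 1):n]
  span <- pre - post[1]
  if (!is.finite(span) || span == 0) {
    stop("degenerate trace: pre-bleach mean equals first post-bleach value ",
         "(zero dynamic range)")
  }
  if (is.null(times)) {
    t_post <- (seq_along(post) - 1) * frame_interval
  } else {
    if (length(times) != n) stop("`times` must match the full trace length")
    t_post <- times[(n_prebleach + 1):n] - times[n_prebleach + 1]
  }
  frap_curve(t_post, (post - post[1]) / span,
             frame_interval = frame_interval, n_prebleach = n_prebleach)
}

#' Fit the single-exponential FRAP recovery model
#'
#' Bounded nonlinear least squares fit of
#' \deqn{FRAP(t) = a\,(1 - e^{-k t})}
#' to a normalized recovery curve, where `a` is the apparent mobile
#' fraction and `k` the apparent exchange rate. The recovery half-time
#' is \eqn{t_{1/2} = -\ln(0.5)/k}. Any immobile material (including
#' molecules pinned to the glass surface) folds into `1 - a`; no
#' separate immobile term is fitted.
#'
#' @param curve A [frap_curve()] (or any list with `times` and
#'   `intensities`), with at least 10 points and `t >= 0`.
#' @param lower,upper Parameter bounds `c(a, k)`; defaults `a` in
#'   `[0, 1.2]`, `k` in `[1e-5, 10]` 1/s.
#' @return An object of class `frap_fit`: list with `mobile_fraction_a`,
#'   `rate_k` (1/s), `t_half` (s, exactly `-log(0.5)/rate_k`), `se`
#'   (standard errors), `covariance`, `residual_sd`, `at_bounds`
#'   (logical flag), `fitted`, `curve`.
#' @examples
#' cv <- gen_frap(preset = "psi_short", seed = 1, noise_sd = 0)
#' fit_frap(cv)
#' @export
fit_frap <- function(curve, lower = c(0, 1e-5), upper = c(1.2, 10)) {
  t <- curve$times
  y <- curve$intensities
  if (length(t) < 10) stop("need at least 10 points to fit")
  if (any(t < 0)) stop("times must be non-negative (t = 0 at bleach)")

  a0 <- min(max(mean(y[t >= stats::quantile(t, 0.9)]), 0.01), upper[1])
  i_half <- which(y >= a0 / 2)
  k0 <- if (length(i_half) && t[i_half[1]] > 0) log(2) / t[i_half[1]] else 0.05
  k0 <- min(max(k0, lower[2] * 10), upper[2] / 10)

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-k * t)),
                      start = list(a = a0, k = k0),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("FRAP fit did not converge: ", conditionMessage(e))
  )
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  at_bounds <- any(abs(est - lower) < 1e-10) || any(abs(est - upper) < 1e-10)
  if (at_bounds) warning("FRAP fit parameter at bounds; estimates may be unreliable")
  structure(
    list(mobile_fraction_a = unname(est["a"]),
         rate_k = unname(est["k"]),
         t_half = -log(0.5) / unname(est["k"]),
         se = sqrt(diag(vc)),
         covariance = vc,
         residual_sd = stats::sd(stats::resid(fit)),
         at_bounds = at_bounds,
         fitted = stats::fitted(fit),
         curve = curve),
    class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> mobile fraction a = %.3f | k = %.4g 1/s | t1/2 = %.1f s | residual sd = %.3g%s\n",
    x$mobile_fraction_a, x$rate_k, x$t_half, x$residual_sd,
    if (x$at_bounds) " [at bounds]" else ""))
  invisible(x)
}

#' Mean-intensity trace of a region of interest across an image stack
#'
#' Extracts the per-frame mean intensity inside a mask (for example a
#' bleach ROI, or one condensate from [segment_condensates()]) from a
#' 3-D image stack, producing a raw trace for [normalize_frap()].
#'
#' @param stack `x * y * frame` numeric array (e.g. a TIFF stack read
#'   with `EBImage::readImage`).
#' @param roi Logical/0-1 matrix matching the frame size.
#' @return Numeric vector of per-frame mean ROI intensities.
#' @export
roi_trace <- function(stack, roi) {
  stopifnot(length(dim(stack)) == 3)
  roi <- roi > 0
  if (!any(roi)) stop("empty ROI")
  apply(stack, 3, function(fr) mean(fr[roi]))
}
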