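# Stability of surface-anchored condensates under buffer flow:
# registration, background-subtracted intensity traces, exponential
# decay fitting, and intensity-based molecule counting.

# Corrective integer-pixel roll (dx, dy) that aligns `frame` onto
# `ref`, found as the argmax of the FFT cross-correlation: if the
# frame content moved by +s relative to ref, this returns -s.
.xcorr_shift <- function(ref, frame) {
  F1 <- stats::fft(ref)
  F2 <- stats::fft(frame)
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  d <- ij - 1L
  n <- dim(ref)
  ifelse(d > n / 2, d - n, d)          # wrap to signed shifts
}

.roll_matrix <- function(m, dx, dy) {
  n <- dim(m)
  ix <- ((seq_len(n[1]) - 1 - dx) %% n[1]) + 1
  iy <- ((seq_len(n[2]) - 1 - dy) %% n[2]) + 1
  m[ix, iy, drop = FALSE]
}

.as_two_channel <- function(stack) {
  if (is.list(stack) && !is.null(stack$channels)) stack <- stack$channels
  if (is.array(stack) && length(dim(stack)) == 4) {
    stack <- lapply(seq_len(dim(stack)[4]), function(c) stack[, , , c])
  }
  if (!is.list(stack) || length(stack) != 2 ||
      !all(vapply(stack, function(a) length(dim(a)) == 3, logical(1)))) {
    stop("`stack` must hold two channels of x-y-frame arrays")
  }
  if (dim(stack[[1]])[3] < 2) stop("need at least 2 frames")
  stack
}

.ring_mask <- function(mask, inner = 2, outer = 5) {
  di <- EBImage::dilate(EBImage::Image(mask * 1),
                        EBImage::makeBrush(2 * inner + 1, shape = "disc"))
  do <- EBImage::dilate(EBImage::Image(mask * 1),
                        EBImage::makeBrush(2 * outer + 1, shape = "disc"))
  EBImage::imageData(do) > 0 & !(EBImage::imageData(di) > 0)
}

#' Extract background-subtracted intensity traces from a two-channel stack
#'
#' Registers all frames to the first frame (integer-pixel shifts from
#' cross-correlation on channel 1, applied to both channels), segments
#' condensates on the first frame of each channel, keeps only
#' condensates visible in both color channels, and records for every
#' condensate and frame the maximum pixel intensity inside the
#' condensate mask minus the mean background intensity in a surrounding
#' ring.
#'
#' @param stack Two-channel time series: a list of two `x * y * frame`
#'   arrays (or a list with element `channels`, or a 4-D array with
#'   channel as the 4th dimension).
#' @param frame_interval Seconds between frames.
#' @param ring_inner,ring_outer Ring radii in pixels: the ring is the
#'   mask dilated by `ring_outer` minus the mask dilated by
#'   `ring_inner`.
#' @param register Apply integer-pixel registration before measuring.
#' @param min_area,threshold,sigma Segmentation parameters, see
#'   [segment_condensates()].
#' @return data.frame of class `intensity_traces`: `condensate_id`,
#'   `channel` (1 or 2), `frame`, `time`, `intensity` (max pixel minus
#'   ring background), `background`. Empty (zero-row) if no condensate
#'   is present in both channels of frame 1. The attribute `objects`
#'   holds the frame-1 segmentation (label, area, centroid) of the
#'   retained condensates, keyed by `condensate_id`.
#' @export
extract_traces <- function(stack, frame_interval = 1, ring_inner = 2,
                           ring_outer = 5, register = TRUE, min_area = 4,
                           threshold = "otsu", sigma = 1) {
  chans <- .as_two_channel(stack)
  n_frames <- dim(chans[[1]])[3]

  if (register) {
    ref <- chans[[1]][, , 1]
    for (f in 2:n_frames) {
      d <- .xcorr_shift(ref, chans[[1]][, , f])
      if (any(d != 0)) {
        for (c in 1:2) chans[[c]][, , f] <- .roll_matrix(chans[[c]][, , f], d[1], d[2])
      }
    }
  }

  seg1 <- segment_condensates(chans[[1]][, , 1], min_area = min_area,
                              threshold = threshold, sigma = sigma)
  seg2 <- segment_condensates(chans[[2]][, , 1], min_area = min_area,
                              threshold = threshold, sigma = sigma)
  empty <- data.frame(condensate_id = integer(), channel = integer(),
                      frame = integer(), time = numeric(),
                      intensity = numeric(), background = numeric())
  class(empty) <- c("intensity_traces", "data.frame")
  if (seg1$n == 0 || seg2$n == 0) return(empty)

  # dual-channel presence: keep channel-1 objects overlapping any channel-2 object
  keep <- which(vapply(seq_len(seg1$n), function(l) {
    any(seg2$labels[seg1$labels == l] > 0)
  }, logical(1)))
  if (length(keep) == 0) return(empty)

  out <- vector("list", length(keep) * 2L)
  i <- 0L
  for (id in keep) {
    mask <- seg1$labels == id
    ring <- .ring_mask(mask, ring_inner, ring_outer) & seg1$labels == 0
    for (c in 1:2) {
      mx <- apply(chans[[c]], 3, function(fr) max(fr[mask]))
      bg <- apply(chans[[c]], 3, function(fr) mean(fr[ring]))
      i <- i + 1L
      out[[i]] <- data.frame(condensate_id = id, channel = c,
                             frame = seq_len(n_frames),
                             time = (seq_len(n_frames) - 1) * frame_interval,
                             intensity = mx - bg, background = bg)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("intensity_traces", "data.frame")
  attr(res, "objects") <- seg1$objects[seg1$objects$label %in% keep, ]
  res
}

#' Fit an exponential decay to an intensity trace
#'
#' Bounded least-squares fit of a single- or double-exponential decay,
#' \deqn{I(t) = A_1 e^{-k_1 t} (+\,A_2 e^{-k_2 t}) (+\,c),}
#' with non-negative amplitudes and positive rates. For the double
#' model the components are returned fast-first (`rates[1] > rates[2]`).
#' The offset `c` is excluded by default (full decay to zero).
#'
#' @param times,intensities Trace vectors (>= 10 points), or pass a
#'   one-condensate/one-channel subset of [extract_traces()] output as
#'   `times` and leave `intensities` missing.
#' @param model `"single"` or `"double"`.
#' @param offset Fit an additive plateau term.
#' @return Object of class `decay_fit`: `model`, `amplitudes`, `rates`
#'   (1/s), `offset`, `residual_sd`, `aicc`, `n`, `fitted`.
#' @export
fit_decay <- function(times, intensities, model = c("single", "double"),
                      offset = FALSE) {
  model <- match.arg(model)
  if (missing(intensities) && is.data.frame(times)) {
    intensities <- times$intensity
    times <- times$time
  }
  t <- as.numeric(times); y <- as.numeric(intensities)
  if (length(t) < 10) stop("need at least 10 points to fit a decay")

  # zero dynamic range: nothing decays; report the constant directly
  if (diff(range(y)) <= 1e-12 * max(1, abs(mean(y)))) {
    n_amp <- if (model == "single") 1 else 2
    level <- if (offset) mean(y) else 0
    return(structure(
      list(model = model, amplitudes = rep(0, n_amp),
           rates = rep(NA_real_, n_amp), offset = level,
           residual_sd = sqrt(mean((y - level)^2)),
           aicc = NA_real_, n = length(y),
           fitted = rep(level, length(y))),
      class = "decay_fit"))
  }

  y0 <- max(y[1], max(y) * 0.1, .Machine$double.eps)
  # crude rate guess from the time the trace halves
  i_half <- which(y <= y0 / 2)
  k0 <- if (length(i_half) && t[i_half[1]] > 0) log(2) / t[i_half[1]] else
    1 / max(t[length(t)], 1)
  dat <- data.frame(t = t, y = y)
  ctl <- minpack.lm::nls.lm.control(maxiter = 500)

  fit <- tryCatch({
    if (model == "single" && !offset) {
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t), data = dat,
                        start = list(A1 = y0, k1 = k0),
                        lower = c(0, 1e-8), upper = c(Inf, Inf), control = ctl)
    } else if (model == "single") {
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t) + c0, data = dat,
                        start = list(A1 = max(y0 - min(y), 1e-6), k1 = k0,
                                     c0 = min(y)),
                        lower = c(0, 1e-8, -Inf), upper = c(Inf, Inf, Inf),
                        control = ctl)
    } else if (model == "double" && !offset) {
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t), data = dat,
                        start = list(A1 = y0 / 2, k1 = k0 * 5,
                                     A2 = y0 / 2, k2 = k0 / 5),
                        lower = c(0, 1e-8, 0, 1e-8), upper = c(Inf, Inf, Inf, Inf),
                        control = ctl)
    } else {
      minpack.lm::nlsLM(y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t) + c0, data = dat,
                        start = list(A1 = y0 / 2, k1 = k0 * 5,
                                     A2 = y0 / 2, k2 = k0 / 5, c0 = min(y)),
                        lower = c(0, 1e-8, 0, 1e-8, -Inf),
                        upper = c(Inf, Inf, Inf, Inf, Inf), control = ctl)
    }
  }, error = function(e) stop("decay fit did not converge: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  if (model == "single") {
    amps <- unname(cf["A1"]); rates <- unname(cf["k1"])
  } else {
    amps <- unname(cf[c("A1", "A2")]); rates <- unname(cf[c("k1", "k2")])
    ord <- order(-rates)                         # fast component first
    amps <- amps[ord]; rates <- rates[ord]
  }
  rss <- sum(stats::resid(fit)^2)
  n <- length(y)
  p <- length(cf) + 1                            # + residual variance
  aicc <- n * log(rss / n) + 2 * p +
    if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
  structure(
    list(model = model, amplitudes = amps, rates = rates,
         offset = if (offset) unname(cf["c0"]) else 0,
         residual_sd = sqrt(rss / max(n - length(cf), 1)),
         aicc = aicc, n = n, fitted = stats::fitted(fit)),
    class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s | amplitudes: %s | rates (1/s): %s | offset %.3g | AICc %.1f\n",
              x$model, paste(signif(x$amplitudes, 4), collapse = ", "),
              paste(signif(x$rates, 4), collapse = ", "), x$offset, x$aicc))
  invisible(x)
}

#' Compare single- vs double-exponential decay models
#'
#' Fits both models and prefers the one with the lower corrected Akaike
#' information criterion (AICc).
#'
#' @inheritParams fit_decay
#' @return List with `single`, `double` (both [fit_decay()] results),
#'   `preferred` (`"single"` or `"double"`), and `delta_aicc`
#'   (`AICc_single - AICc_double`; positive favors the double model).
#' @export
compare_decay_models <- function(times, intensities, offset = FALSE) {
  s <- fit_decay(times, intensities, model = "single", offset = offset)
  d <- fit_decay(times, intensities, model = "double", offset = offset)
  list(single = s, double = d,
       preferred = if (d$aicc < s$aicc) "double" else "single",
       delta_aicc = s$aicc - d$aicc)
}

#' Estimate the number of DNA molecules in a condensate
#'
#' Divides the condensate's background-subtracted intensity by the
#' intensity of a single dye and by the fraction of labeled DNA
#' molecules:
#' \deqn{n = I_{cond} / I_{dye} / f_{labeled}.}
#'
#' @param condensate_intensity Background-subtracted condensate
#'   intensity (vectorized, arbitrary units).
#' @param single_dye_intensity Intensity of one dye molecule (same
#'   units, > 0); typically [estimate_single_dye()] on a calibration
#'   measurement.
#' @param labeled_fraction Fraction of DNA molecules carrying the dye,
#'   in `(0, 1]`.
#' @param condensate_id Optional ids carried into the result.
#' @return data.frame of class `molecule_count`: `condensate_id`,
#'   `n_molecules` (continuous estimate), `n_rounded`,
#'   `single_dye_intensity`, `labeled_fraction`.
#' @examples
#' count_molecules(10, 1, 0.5)  # 20 molecules
#' @export
count_molecules <- function(condensate_intensity, single_dye_intensity,
                            labeled_fraction,
                            condensate_id = seq_along(condensate_intensity)) {
  if (!is.numeric(single_dye_intensity) || any(single_dye_intensity <= 0)) {
    stop("`single_dye_intensity` must be positive")
  }
  if (any(labeled_fraction <= 0 | labeled_fraction > 1)) {
    stop("`labeled_fraction` must lie in (0, 1]")
  }
  n <- condensate_intensity / single_dye_intensity / labeled_fraction
  structure(
    data.frame(condensate_id = condensate_id, n_molecules = n,
               n_rounded = round(n),
               single_dye_intensity = single_dye_intensity,
               labeled_fraction = labeled_fraction),
    class = c("molecule_count", "data.frame"))
}

#' Single-dye intensity from a calibration measurement
#'
#' Median background-subtracted intensity of isolated surface-anchored
#' single-dye spots.
#'
#' @param intensities Numeric vector of single-spot intensities.
#' @return Scalar intensity estimate.
#' @export
estimate_single_dye <- function(intensities) {
  stats::median(intensities)
}

#' Normalize decay traces for aggregation across condensates
#'
#' Divides each condensate's trace by the mean of its first
#' `n_baseline` frames, then returns the per-frame mean and standard
#' error across condensates.
#'
#' @param traces [extract_traces()] output (single channel).
#' @param n_baseline Frames defining the per-condensate baseline.
#' @return data.frame: `frame`, `time`, `mean_intensity`, `sem`, `n`.
#' @export
aggregate_decay <- function(traces, n_baseline = 3) {
  stopifnot(all(c("condensate_id", "frame", "time", "intensity") %in% names(traces)))
  sp <- split(traces, traces$condensate_id)
  norm <- lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    base <- mean(d$intensity[seq_len(min(n_baseline, nrow(d)))])
    d$rel <- d$intensity / base
    d
  })
  all <- do.call(rbind, norm)
  agg <- split(all, all$frame)
  data.frame(
    frame = as.integer(names(agg)),
    time = vapply(agg, function(d) d$time[1], numeric(1)),
    mean_intensity = vapply(agg, function(d) mean(d$rel), numeric(1)),
    sem = vapply(agg, function(d) stats::sd(d$rel) / sqrt(nrow(d)), numeric(1)),
    n = vapply(agg, nrow, integer(1)),
    row.names = NULL)
}
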