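# Synthetic-data generators with embedded ground truth. Every analysis
# stage in the package has at least one recovery test driven purely by
# this module; all generators are deterministic under a fixed seed.

# Run `code` under `seed` without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' FRAP generator presets
#'
#' Named parameter bundles for [gen_frap()] covering the characteristic
#' recovery regimes of short-DNA condensates: `psi_short` (PEG/Mg
#' condensation; mobile fraction 0.66, time constant 99 s), `h1_short`
#' (linker-histone condensation; 0.58, 60 s), `chromatin_short`
#' (reconstituted chromatin; 0.40, 69 s), and `h1_low_conc`
#' (near-critical H1 condensates; 0.25, 60 s).
#'
#' @format Named list of `list(a, k)` with `a` the mobile fraction and
#'   `k` the exchange rate in 1/s.
#' @export
frap_presets <- list(
  psi_short       = list(a = 0.66, k = 1 / 99),
  h1_short        = list(a = 0.58, k = 1 / 60),
  chromatin_short = list(a = 0.40, k = 1 / 69),
  h1_low_conc     = list(a = 0.25, k = 1 / 60)
)

#' Simulate a normalized FRAP recovery curve
#'
#' Draws `FRAP(t) = a (1 - exp(-k t)) + N(0, noise_sd)` at the standard
#' acquisition cadence (300 frames, 0.8 s interval). With `raw = TRUE`
#' an un-normalized trace with pre-bleach frames, gain and offset is
#' returned instead, suitable for exercising [normalize_frap()].
#'
#' @param preset Name from [frap_presets], or `NULL` to use `a`, `k`.
#' @param a,k Mobile fraction and exchange rate (1/s); override the
#'   preset when given.
#' @param seed Integer seed (same seed, same curve).
#' @param noise_sd Gaussian noise standard deviation in normalized
#'   units.
#' @param n_frames,frame_interval Post-bleach frames and interval (s).
#' @param raw Return a raw trace (list with `raw_trace`,
#'   `n_prebleach`) instead of a normalized [frap_curve()].
#' @param n_prebleach,gain,intensity_offset Raw-trace parameters: number of
#'   pre-bleach frames and the affine camera transform
#'   `raw = intensity_offset + gain * signal`.
#' @return A [frap_curve()] (or raw-trace list) with attribute `truth`
#'   holding the generating parameters.
#' @export
gen_frap <- function(preset = "psi_short", a = NULL, k = NULL, seed = NULL,
                     noise_sd = 0.02, n_frames = 300, frame_interval = 0.8,
                     raw = FALSE, n_prebleach = 5, gain = 1,
                     intensity_offset = 0) {
  if (!is.null(preset)) {
    if (!preset %in% names(frap_presets)) {
      stop("unknown preset '", preset, "'; see ?frap_presets")
    }
    p <- frap_presets[[preset]]
    if (is.null(a)) a <- p$a
    if (is.null(k)) k <- p$k
  }
  stopifnot(is.numeric(a), is.numeric(k), k > 0)
  times <- (seq_len(n_frames) - 1) * frame_interval
  clean <- a * (1 - exp(-k * times))
  y <- .with_seed(seed, clean + stats::rnorm(n_frames, sd = noise_sd))
  truth <- list(a = a, k = k, noise_sd = noise_sd, preset = preset)
  if (raw) {
    raw_trace <- intensity_offset + gain * c(rep(1, n_prebleach), y)
    return(structure(list(raw_trace = raw_trace, n_prebleach = n_prebleach,
                          frame_interval = frame_interval),
                     truth = truth, class = "frap_raw"))
  }
  structure(frap_curve(times, y, frame_interval = frame_interval,
                       n_prebleach = n_prebleach),
            truth = truth)
}

# --- shape rendering ------------------------------------------------------

.place_centers <- function(n, dims, spacing, seed_offset = 0) {
  nx <- floor(dims[1] / spacing); ny <- floor(dims[2] / spacing)
  if (n > nx * ny) {
    stop("cannot place ", n, " non-overlapping objects of spacing ", spacing,
         " in a ", dims[1], "x", dims[2], " image (packing limit ", nx * ny, ")")
  }
  cells <- sample(nx * ny, n)
  cx <- ((cells - 1) %% nx) * spacing + spacing / 2
  cy <- ((cells - 1) %/% nx) * spacing + spacing / 2
  cbind(x = round(cx + stats::runif(n, -spacing * 0.05, spacing * 0.05)),
        y = round(cy + stats::runif(n, -spacing * 0.05, spacing * 0.05)))
}

.render_ellipse <- function(img, x0, y0, a_axis, b_axis, angle, value) {
  nx <- nrow(img); ny <- ncol(img)
  r <- ceiling(max(a_axis, b_axis)) + 1
  xs <- max(1, x0 - r):min(nx, x0 + r)
  ys <- max(1, y0 - r):min(ny, y0 + r)
  dx <- outer(xs - x0, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - y0)
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a_axis)^2 + (v / b_axis)^2 <= 1
  img[xs, ys][inside] <- value
  img
}

# Eden-growth aggregate: repeatedly occupy a random boundary neighbor,
# with selection probability ~ (1 + distance from the seed)^roughness.
# roughness 0 gives compact quasi-round aggregates; larger values favor
# tip growth and increasingly irregular, elongated shapes.
.grow_blob <- function(img, x0, y0, n_pixels, roughness, value) {
  nx <- nrow(img); ny <- ncol(img)
  occ <- matrix(FALSE, nx, ny)
  occ[x0, y0] <- TRUE
  frontier <- matrix(c(x0 + c(1, -1, 0, 0), y0 + c(0, 0, 1, -1)), ncol = 2)
  for (i in seq_len(n_pixels - 1)) {
    keep <- frontier[, 1] >= 1 & frontier[, 1] <= nx &
      frontier[, 2] >= 1 & frontier[, 2] <= ny
    frontier <- frontier[keep, , drop = FALSE]
    frontier <- frontier[!occ[frontier], , drop = FALSE]
    if (nrow(frontier) == 0) break
    d <- sqrt((frontier[, 1] - x0)^2 + (frontier[, 2] - y0)^2)
    pick <- sample.int(nrow(frontier), 1, prob = (1 + d)^roughness)
    px <- frontier[pick, 1]; py <- frontier[pick, 2]
    occ[px, py] <- TRUE
    frontier <- rbind(frontier[-pick, , drop = FALSE],
                      cbind(px + c(1, -1, 0, 0), py + c(0, 0, 1, -1)))
  }
  img[occ] <- value
  img
}

#' Simulate a condensate snapshot image with known shapes
#'
#' Renders non-overlapping objects of three kinds on a dark background:
#' discs (round, liquid-like mimic; programmed aspect ratio 0),
#' ellipses with a chosen semi-axis ratio (programmed aspect ratio
#' `(a-b)/(a+b)`), and irregular aggregates grown by seeded Eden-growth
#' on the pixel lattice (roughness-controlled; programmed aspect ratio
#' unknown, measured downstream).
#'
#' @param n_discs,n_ellipses,n_blobs Object counts.
#' @param disc_radius Disc radius in pixels (recycled).
#' @param ellipse_axes Length-2 vector `c(a, b)` of ellipse semi-axes in
#'   pixels.
#' @param ellipse_angle Ellipse orientation (radians).
#' @param blob_area Pixels per aggregate.
#' @param roughness Eden-growth tip bias; 0 = compact, larger = more
#'   irregular.
#' @param dims Image size `c(nx, ny)`.
#' @param intensity,background Foreground/background levels.
#' @param noise_sd Gaussian pixel noise.
#' @param seed Integer seed.
#' @return List of class `shape_image`: `image` (matrix) and `truth`
#'   (data.frame: `id`, `type`, `x`, `y`, `size`, `target_aspect_ratio`).
#' @export
gen_shapes <- function(n_discs = 5, n_ellipses = 0, n_blobs = 0,
                       disc_radius = 30, ellipse_axes = c(40, 20),
                       ellipse_angle = 0, blob_area = 1200, roughness = 6,
                       dims = c(512, 512), intensity = 0.9,
                       background = 0.05, noise_sd = 0, seed = NULL) {
  n <- n_discs + n_ellipses + n_blobs
  if (n == 0) {
    return(structure(list(image = matrix(background, dims[1], dims[2]),
                          truth = data.frame()), class = "shape_image"))
  }
  .with_seed(seed, {
    ext <- max(disc_radius, ellipse_axes, ceiling(sqrt(blob_area)) * 1.6)
    spacing <- 2 * ext + 8
    centers <- .place_centers(n, dims, spacing)
    img <- matrix(background, dims[1], dims[2])
    type <- rep(c("disc", "ellipse", "blob"),
                c(n_discs, n_ellipses, n_blobs))
    radii <- rep_len(disc_radius, max(n_discs, 1))
    size <- numeric(n); target <- numeric(n)
    for (i in seq_len(n)) {
      if (type[i] == "disc") {
        r <- radii[i]
        img <- .render_ellipse(img, centers[i, 1], centers[i, 2], r, r, 0,
                               intensity)
        size[i] <- r; target[i] <- 0
      } else if (type[i] == "ellipse") {
        img <- .render_ellipse(img, centers[i, 1], centers[i, 2],
                               ellipse_axes[1], ellipse_axes[2],
                               ellipse_angle, intensity)
        size[i] <- ellipse_axes[1]
        target[i] <- (max(ellipse_axes) - min(ellipse_axes)) /
          (max(ellipse_axes) + min(ellipse_axes))
      } else {
        img <- .grow_blob(img, centers[i, 1], centers[i, 2], blob_area,
                          roughness, intensity)
        size[i] <- blob_area; target[i] <- NA_real_
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                          nrow(img), ncol(img))
    }
    structure(list(image = img,
                   truth = data.frame(id = seq_len(n), type = type,
                                      x = centers[, 1], y = centers[, 2],
                                      size = size,
                                      target_aspect_ratio = target)),
              class = "shape_image")
  })
}

#' Simulate a double-exponential intensity decay trace
#'
#' Mean condensate signal of a two-population disassembly process,
#' \deqn{I(t) = A_{fast} e^{-k_{fast} t} + A_{slow} e^{-k_{slow} t} +
#'   N(0, \sigma),}
#' the aggregate of a smaller quickly-disassembling and a larger
#' gradually-disassembling condensate population.
#'
#' @param amplitude_fast,amplitude_slow Component amplitudes.
#' @param k_fast,k_slow Decay rates (1/s), `k_fast > k_slow`.
#' @param n_frames,frame_interval Trace length and cadence (s).
#' @param noise_sd Gaussian noise (absolute units).
#' @param seed Integer seed.
#' @return data.frame `time`, `intensity` with attribute `truth`.
#' @export
gen_decay_trace <- function(amplitude_fast = 0.3, amplitude_slow = 0.7,
                            k_fast = 0.02, k_slow = 0.0015,
                            n_frames = 200, frame_interval = 2,
                            noise_sd = 0.02, seed = NULL) {
  stopifnot(k_fast > k_slow)
  t <- (seq_len(n_frames) - 1) * frame_interval
  clean <- amplitude_fast * exp(-k_fast * t) + amplitude_slow * exp(-k_slow * t)
  y <- .with_seed(seed, clean + stats::rnorm(n_frames, sd = noise_sd))
  structure(data.frame(time = t, intensity = y),
            truth = list(amplitudes = c(amplitude_fast, amplitude_slow),
                         rates = c(k_fast, k_slow), noise_sd = noise_sd))
}

#' Simulate a two-channel TIRF stack of decaying condensates
#'
#' Places Gaussian-profile spots (integer-pixel centers) on a constant
#' background in two color channels. Each spot holds a programmed
#' number of DNA molecules; its center-pixel amplitude in a channel is
#' `n_molecules * labeled_fraction[channel] * dye_intensity`, decaying
#' over time with a per-spot rate drawn from a fast (minority) or slow
#' (majority) population. Optional linear integer-pixel stage drift and
#' Poisson shot plus Gaussian read noise emulate acquisition.
#'
#' @param n_spots Number of condensates.
#' @param molecules Molecule counts per condensate (recycled), or a
#'   range `c(lo, hi)` with `sample_molecules = TRUE` to draw uniformly.
#' @param sample_molecules Draw counts uniformly from
#'   `molecules[1]:molecules[2]`.
#' @param labeled_fraction Length-2 labeled fractions per channel.
#' @param dye_intensity Intensity of one dye (counts).
#' @param fraction_fast,k_fast,k_slow Two-population decay parameters;
#'   set both rates to 0 for constant traces.
#' @param n_frames,frame_interval Frames and cadence (s).
#' @param dims Image size.
#' @param psf_sigma Spot Gaussian width (px).
#' @param background Constant background level (counts).
#' @param drift_total Integer total drift `c(dx, dy)` in px applied
#'   linearly across the stack.
#' @param shot_noise Apply Poisson noise to each pixel.
#' @param read_noise_sd Gaussian read noise (counts).
#' @param seed Integer seed.
#' @return List of class `flow_stack`: `channels` (list of two
#'   `x*y*frame` arrays), `frame_interval`, and `truth` (data.frame:
#'   `id`, `x`, `y`, `n_molecules`, `population`, `rate`,
#'   `amp_ch1`, `amp_ch2`).
#' @export
gen_flow_stack <- function(n_spots = 8, molecules = c(2, 4),
                           sample_molecules = TRUE,
                           labeled_fraction = c(0.5, 0.5),
                           dye_intensity = 200, fraction_fast = 0.3,
                           k_fast = 0.02, k_slow = 0.001,
                           n_frames = 60, frame_interval = 2,
                           dims = c(96, 96), psf_sigma = 1.5,
                           background = 20, drift_total = c(0, 0),
                           shot_noise = TRUE, read_noise_sd = 0,
                           seed = NULL) {
  .with_seed(seed, {
    centers <- .place_centers(n_spots, dims, spacing = 16)
    nmol <- if (sample_molecules && length(molecules) == 2) {
      sample(molecules[1]:molecules[2], n_spots, replace = TRUE)
    } else rep_len(molecules, n_spots)
    pop <- ifelse(stats::runif(n_spots) < fraction_fast, "fast", "slow")
    rate <- ifelse(pop == "fast", k_fast, k_slow)
    amp <- outer(nmol, labeled_fraction) * dye_intensity  # n_spots x 2

    t <- (seq_len(n_frames) - 1) * frame_interval
    shift <- cbind(round(seq(0, drift_total[1], length.out = n_frames)),
                   round(seq(0, drift_total[2], length.out = n_frames)))
    # spot template on a local window
    w <- ceiling(4 * psf_sigma)
    gx <- -w:w
    tmpl <- exp(-outer(gx^2, gx^2, "+") / (2 * psf_sigma^2))

    chans <- lapply(1:2, function(ch) {
      arr <- array(background, c(dims[1], dims[2], n_frames))
      for (f in seq_len(n_frames)) {
        fr <- matrix(0, dims[1], dims[2])
        for (s in seq_len(n_spots)) {
          x0 <- centers[s, 1] + shift[f, 1]
          y0 <- centers[s, 2] + shift[f, 2]
          xs <- (x0 + gx); ys <- (y0 + gx)
          okx <- xs >= 1 & xs <= dims[1]; oky <- ys >= 1 & ys <= dims[2]
          fr[xs[okx], ys[oky]] <- fr[xs[okx], ys[oky]] +
            amp[s, ch] * exp(-rate[s] * t[f]) * tmpl[okx, oky]
        }
        arr[, , f] <- arr[, , f] + fr
      }
      if (shot_noise) {
        arr[] <- stats::rpois(length(arr), lambda = pmax(arr, 0))
      }
      if (read_noise_sd > 0) {
        arr[] <- arr + stats::rnorm(length(arr), sd = read_noise_sd)
      }
      arr
    })
    structure(
      list(channels = chans, frame_interval = frame_interval,
           truth = data.frame(id = seq_len(n_spots), x = centers[, 1],
                              y = centers[, 2], n_molecules = nmol,
                              population = pop, rate = rate,
                              amp_ch1 = amp[, 1], amp_ch2 = amp[, 2])),
      class = "flow_stack")
  })
}

#' Simulate a length-concentration condition grid
#'
#' Emulates an experimental condensation phase diagram: a grid of DNA
#' lengths (12 bp to 48.5 kb) by DNA concentrations (10 ng/mL to 100
#' ug/mL). Condensates appear only above a per-length critical
#' concentration that falls steeply with length. Among detected cells,
#' the mean mobile fraction drops with length (sigmoidal, midpoint
#' `mf_midpoint_bp`) before the mean aspect ratio rises (midpoint
#' `ar_midpoint_bp` > `mf_midpoint_bp`), producing in order the
#' liquid-like (I: mobile + round), intermediate (II: static + round)
#' and solid-like (III: static + irregular) regimes; both features also
#' shift mildly with depth into the two-phase region. True class
#' labels derived from the noiseless feature values are recorded.
#'
#' @param lengths_bp DNA lengths (bp).
#' @param concentrations Mass concentrations (g/mL).
#' @param mf_midpoint_bp,ar_midpoint_bp Sigmoid midpoints (bp) of the
#'   mobile-fraction drop and aspect-ratio rise.
#' @param steepness Sigmoid Hill exponent on length.
#' @param noise_mf,noise_ar Gaussian noise on the two features.
#' @param seed Integer seed.
#' @return data.frame of class `condition_grid`: `dna_length_bp`,
#'   `dna_concentration`, `detected_true`, `mean_mobile_fraction`,
#'   `mean_aspect_ratio` (NA when absent), `region_true`.
#' @export
gen_condition_grid <- function(lengths_bp = c(12, 200, 1000, 2500, 10000,
                                              17000, 48500),
                               concentrations = 10^seq(-8, -4, length.out = 9),
                               mf_midpoint_bp = 1600, ar_midpoint_bp = 5000,
                               steepness = 6, noise_mf = 0.04,
                               noise_ar = 0.03, seed = NULL) {
  grid <- expand.grid(dna_length_bp = lengths_bp,
                      dna_concentration = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  L <- grid$dna_length_bp
  conc <- grid$dna_concentration
  c_crit <- 10^(-3.9 - 1.45 * log10(L))
  detected <- conc >= c_crit
  depth <- pmax(log10(conc / c_crit), 0)        # decades into two-phase region

  mf0 <- 0.15 + 0.55 / (1 + (L / mf_midpoint_bp)^steepness) - 0.02 * depth
  ar0 <- 0.08 + 0.42 / (1 + (ar_midpoint_bp / L)^steepness) + 0.015 * depth
  mf0 <- pmin(pmax(mf0, 0), 1); ar0 <- pmin(pmax(ar0, 0), 1)
  region <- ifelse(mf0 >= 0.45, "I", ifelse(ar0 < 0.3, "II", "III"))

  .with_seed(seed, {
    mf <- pmin(pmax(mf0 + stats::rnorm(nrow(grid), sd = noise_mf), 0), 1)
    ar <- pmin(pmax(ar0 + stats::rnorm(nrow(grid), sd = noise_ar), 0), 1)
    grid$detected_true <- detected
    grid$mean_mobile_fraction <- ifelse(detected, mf, NA_real_)
    grid$mean_aspect_ratio <- ifelse(detected, ar, NA_real_)
    grid$region_true <- ifelse(detected, region, "no condensates")
    class(grid) <- c("condition_grid", "data.frame")
    grid
  })
}

#' Match extracted condensates to generator truth entries
#'
#' Maps each condensate id in an [extract_traces()] result to the
#' nearest spot of a [gen_flow_stack()] truth table by centroid
#' distance.
#'
#' @param traces [extract_traces()] output (carrying its `objects`
#'   attribute).
#' @param truth Truth data.frame with columns `id`, `x`, `y`.
#' @return data.frame with `condensate_id` and matched `truth_id`.
#' @export
match_condensates <- function(traces, truth) {
  obj <- attr(traces, "objects")
  if (is.null(obj)) stop("`traces` carries no segmentation objects")
  idx <- vapply(seq_len(nrow(obj)), function(i) {
    which.min((truth$x - obj$centroid_x[i])^2 +
                (truth$y - obj$centroid_y[i])^2)
  }, integer(1))
  data.frame(condensate_id = obj$label, truth_id = truth$id[idx])
}
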