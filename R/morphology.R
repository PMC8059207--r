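# Condensate morphology: segmentation, the radial aspect-ratio
# statistic, and complete-linkage clustering of conditions into
# liquid-like / intermediate / solid-like classes.

.as_ebimage <- function(image) {
  if (inherits(image, "Image")) image else EBImage::Image(image)
}

#' Segment condensates in a fluorescence image
#'
#' Gaussian-smooths the image, thresholds it (Otsu by default), labels
#' connected components, and discards objects below `min_area` pixels.
#' With `watershed = TRUE`, touching objects are split by a
#' distance-map watershed.
#'
#' @param image 2-D numeric matrix (grayscale) or `EBImage::Image`.
#' @param min_area Minimum object area in pixels.
#' @param threshold `"otsu"` for automatic thresholding on the smoothed
#'   image, or a numeric threshold on the same intensity scale.
#' @param sigma Standard deviation (pixels) of the Gaussian smoothing
#'   applied before thresholding; `0` disables smoothing.
#' @param watershed Split touching objects using
#'   `EBImage::watershed(EBImage::distmap(mask))`.
#' @return A list of class `condensate_segmentation`: `labels` (integer
#'   matrix, 0 = background), `n` (number of objects), and `objects`, a
#'   data.frame with `label`, `area`, `centroid_x`, `centroid_y`
#'   (pixel coordinates). A blank image yields `n = 0` and an empty
#'   data.frame (not an error).
#' @export
segment_condensates <- function(image, min_area = 20, threshold = "otsu",
                                sigma = 1, watershed = FALSE) {
  img <- .as_ebimage(image)
  if (length(dim(img)) != 2) stop("`image` must be a single 2-D grayscale frame")
  rng <- range(as.numeric(img))
  # otsu() requires intensities in [0, 1]
  scaled <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  sm <- if (sigma > 0) EBImage::gblur(scaled, sigma = sigma) else scaled
  thr <- if (identical(threshold, "otsu")) {
    if (rng[2] == rng[1]) Inf else EBImage::otsu(sm)
  } else {
    if (rng[2] > rng[1]) (threshold - rng[1]) / (rng[2] - rng[1]) else Inf
  }
  mask <- sm > thr
  labels <- if (watershed) {
    EBImage::watershed(EBImage::distmap(mask))
  } else {
    EBImage::bwlabel(mask)
  }
  labels <- EBImage::imageData(labels)
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0])
    drop <- which(areas < min_area)
    if (length(drop)) labels[labels %in% drop] <- 0L
    # relabel 1..n
    keep <- sort(unique(labels[labels > 0]))
    labels[] <- match(labels, keep, nomatch = 0L)
  }
  n <- max(labels)
  objects <- if (n > 0) {
    idx <- which(labels > 0, arr.ind = TRUE)
    lab <- labels[labels > 0]
    data.frame(
      label = seq_len(n),
      area = as.integer(tabulate(lab, nbins = n)),
      centroid_x = as.numeric(tapply(idx[, 1], lab, mean)),
      centroid_y = as.numeric(tapply(idx[, 2], lab, mean))
    )
  } else {
    data.frame(label = integer(), area = integer(),
               centroid_x = numeric(), centroid_y = numeric())
  }
  structure(list(labels = labels, n = n, objects = objects),
            class = "condensate_segmentation")
}

#' Radial aspect ratio of a segmented condensate
#'
#' Computes the shape statistic
#' \deqn{AR = \frac{R_{max} - R_{min}}{R_{max} + R_{min}}}
#' where \eqn{R_{max}} and \eqn{R_{min}} are the maximum and minimum
#' distance from the object's centroid to its boundary contour. The
#' statistic vanishes for a circle and approaches 1 for an elongated
#' rod. The centroid is intensity-weighted when `image` is supplied,
#' otherwise the binary mask centroid. An alternative convention using
#' half the min/max Feret diameters is available via
#' `convention = "feret"`.
#'
#' @param mask Logical/0-1 matrix for a single object, or the `labels`
#'   matrix of a [segment_condensates()] result together with `label`.
#' @param label Object label to extract when `mask` is a label matrix.
#' @param image Optional intensity image for centroid weighting.
#' @param convention `"centroid"` (radial distances from the centroid,
#'   default) or `"feret"` (half min/max caliper diameters).
#' @return An object of class `condensate_shape`: list with `area`,
#'   `centroid`, `r_max`, `r_min`, `aspect_ratio`, `degenerate` (TRUE
#'   for single-pixel masks, which get aspect ratio 0).
#' @export
aspect_ratio <- function(mask, label = NULL, image = NULL,
                         convention = c("centroid", "feret")) {
  convention <- match.arg(convention)
  m <- if (inherits(mask, "Image")) EBImage::imageData(mask) else mask
  if (!is.null(label)) m <- m == label
  m <- m > 0
  area <- sum(m)
  if (area == 0) stop("empty mask")
  if (area == 1) {
    ij <- which(m, arr.ind = TRUE)
    return(structure(list(area = 1L, centroid = as.numeric(ij),
                          r_max = 0, r_min = 0, aspect_ratio = 0,
                          degenerate = TRUE),
                     class = "condensate_shape"))
  }
  idx <- which(m, arr.ind = TRUE)
  w <- if (is.null(image)) rep(1, nrow(idx)) else {
    imat <- if (inherits(image, "Image")) EBImage::imageData(image) else image
    pmax(imat[idx], 0)
  }
  if (sum(w) <= 0) w <- rep(1, nrow(idx))
  cx <- sum(idx[, 1] * w) / sum(w)
  cy <- sum(idx[, 2] * w) / sum(w)

  contour <- EBImage::ocontour(EBImage::Image(m * 1))[[1]]
  # ocontour coordinates are 0-based (x, y); shift to pixel centers
  bx <- contour[, 1] + 1
  by <- contour[, 2] + 1
  if (convention == "centroid") {
    r <- sqrt((bx - cx)^2 + (by - cy)^2)
    r_max <- max(r); r_min <- min(r)
  } else {
    # min/max Feret radii: half of extreme caliper widths over directions
    th <- seq(0, pi, length.out = 180)
    proj <- outer(bx, cos(th)) + outer(by, sin(th))
    widths <- apply(proj, 2, function(p) diff(range(p)))
    r_max <- max(widths) / 2; r_min <- min(widths) / 2
  }
  structure(
    list(area = as.integer(area), centroid = c(cx, cy),
         r_max = r_max, r_min = r_min,
         aspect_ratio = if (r_max + r_min > 0) (r_max - r_min) / (r_max + r_min) else 0,
         degenerate = FALSE),
    class = "condensate_shape")
}

#' @export
print.condensate_shape <- function(x, ...) {
  cat(sprintf("<condensate_shape> area = %d px | r_max = %.2f | r_min = %.2f | AR = %.3f%s\n",
              x$area, x$r_max, x$r_min, x$aspect_ratio,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Segment an image and measure every condensate
#'
#' Convenience wrapper combining [segment_condensates()] and
#' [aspect_ratio()].
#'
#' @inheritParams segment_condensates
#' @param ... Passed to [segment_condensates()].
#' @return data.frame with one row per condensate: `label`, `area`,
#'   `centroid_x`, `centroid_y`, `r_max`, `r_min`, `aspect_ratio`.
#' @export
condensate_shapes <- function(image, ...) {
  seg <- segment_condensates(image, ...)
  if (seg$n == 0) {
    return(cbind(seg$objects,
                 data.frame(r_max = numeric(), r_min = numeric(),
                            aspect_ratio = numeric())))
  }
  shp <- lapply(seq_len(seg$n), function(l) {
    aspect_ratio(seg$labels, label = l, image = image)
  })
  cbind(seg$objects,
        data.frame(r_max = vapply(shp, `[[`, numeric(1), "r_max"),
                   r_min = vapply(shp, `[[`, numeric(1), "r_min"),
                   aspect_ratio = vapply(shp, `[[`, numeric(1), "aspect_ratio")))
}

#' Cluster conditions into fluidity classes
#'
#' Clusters (DNA length, concentration) conditions on their mean aspect
#' ratio and mean mobile fraction into `k` groups using Euclidean
#' distances and complete-linkage hierarchical clustering, then maps the
#' unlabeled clusters to condensate classes ordered by decreasing mean
#' mobile fraction: region I (liquid-like, dynamic round), region II
#' (intermediate), region III (solid-like, static irregular). Ties in
#' mean mobile fraction are broken by increasing mean aspect ratio.
#'
#' Features are rescaled before clustering; `scaling = "minmax"`
#' (default) maps each feature to `[0, 1]`, `"zscore"` standardizes.
#' Rows with a missing feature (conditions without detectable
#' condensates) are excluded from clustering and labeled
#' `"no condensates"`.
#'
#' @param records data.frame with columns `mean_aspect_ratio` and
#'   `mean_mobile_fraction` (one row per condition).
#' @param k Number of clusters.
#' @param scaling `"minmax"` or `"zscore"`.
#' @return `records` with columns `cluster` (integer cluster id) and
#'   `region` (`"I"`, `"II"`, `"III"`, ... or `"no condensates"`).
#' @export
classify_conditions <- function(records, k = 3,
                                scaling = c("minmax", "zscore")) {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(records),
            all(c("mean_aspect_ratio", "mean_mobile_fraction") %in% names(records)))
  feats <- records[, c("mean_aspect_ratio", "mean_mobile_fraction")]
  ok <- stats::complete.cases(feats)
  if (sum(ok) < k) {
    stop("need at least k = ", k, " conditions with both features; got ", sum(ok))
  }
  x <- as.matrix(feats[ok, ])
  x <- apply(x, 2, function(col) {
    if (scaling == "minmax") {
      rg <- range(col)
      if (rg[2] > rg[1]) (col - rg[1]) / (rg[2] - rg[1]) else col * 0
    } else {
      s <- stats::sd(col)
      if (s > 0) (col - mean(col)) / s else col * 0
    }
  })
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "complete")
  cl <- stats::cutree(hc, k = k)

  mf <- tapply(records$mean_mobile_fraction[ok], cl, mean)
  ar <- tapply(records$mean_aspect_ratio[ok], cl, mean)
  ord <- order(-mf, ar)                      # I = most mobile
  region_of <- stats::setNames(as.roman(seq_len(k)), names(mf)[ord])

  records$cluster <- NA_integer_
  records$cluster[ok] <- match(as.character(cl), names(mf)[ord])
  records$region <- "no condensates"
  records$region[ok] <- as.character(region_of[as.character(cl)])
  records
}

#' Annotate a length-concentration phase diagram
#'
#' Builds the tidy per-condition table behind an experimental phase
#' diagram: one row per (DNA length, concentration) cell with a
#' condensate-detection flag, the fluidity-class cluster from
#' [classify_conditions()], and the mean aspect ratio and mobile
#' fraction. Cells without condensates are flagged absent (the "gray
#' diamonds" of such diagrams) and carry no class.
#'
#' @param records data.frame with columns `dna_length_bp`,
#'   `dna_concentration`, `mean_aspect_ratio`, `mean_mobile_fraction`
#'   (features `NA` where nothing was detected).
#' @param k Number of fluidity classes.
#' @return data.frame with the input columns plus `detected`, `cluster`,
#'   `region`. An empty input yields an empty table.
#' @export
annotate_phase_diagram <- function(records, k = 3) {
  if (nrow(records) == 0) {
    records$detected <- logical(0)
    records$cluster <- integer(0)
    records$region <- character(0)
    return(records)
  }
  records$detected <- stats::complete.cases(
    records[, c("mean_aspect_ratio", "mean_mobile_fraction")])
  out <- classify_conditions(records, k = k)
  out[order(out$dna_length_bp, out$dna_concentration), ]
}

#' Plot an annotated phase diagram
#'
#' Length-concentration grid with one glyph per condition: circles for
#' region I (liquid-like), triangles for region II, squares for region
#' III, diamonds where no condensates were detected; fill encodes the
#' mean mobile fraction. Requires ggplot2.
#'
#' @param annotated Output of [annotate_phase_diagram()].
#' @return A ggplot object.
#' @export
plot_phase_diagram <- function(annotated) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_phase_diagram requires the ggplot2 package")
  }
  shp <- c(I = 21, II = 24, III = 22, `no condensates` = 23)
  ggplot2::ggplot(annotated,
                  ggplot2::aes(x = factor(dna_length_bp),
                               y = factor(dna_concentration))) +
    ggplot2::geom_point(ggplot2::aes(shape = region,
                                     fill = mean_mobile_fraction),
                        size = 4) +
    ggplot2::scale_shape_manual(values = shp) +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(x = "DNA length (bp)", y = "DNA concentration (g/mL)",
                  fill = "mobile fraction", shape = "class")
}
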