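#' Segmentation parameters
#'
#' Tunables for cell-body detection and process-network extraction on a
#' 2D projection. Defaults are calibrated for 0.19 um/px GFP-like material:
#' a light Gaussian smooth, a robust background-referenced global
#' threshold, a 2 um opening to isolate somata from the thin process
#' meshwork, and a 1 um attribution gap bridging the cut that separates
#' process skeletons from the soma mask.
#'
#' @param smoothing_sigma_um Gaussian smoothing sigma before thresholding.
#' @param body_opening_radius_um Radius of the morphological opening used
#'   to suppress processes when detecting somata.
#' @param global_threshold_method `"background"` (robust median/MAD
#'   background reference, the default) or `"otsu"` (Otsu split on
#'   log-intensities).
#' @param min_body_area_um2 Smallest connected component kept as a soma at
#'   detection time (the population filter applies the stricter 10 um^2
#'   rule later).
#' @param attribution_max_gap_um Maximum distance between a skeleton
#'   component and a soma contour for the component to be rooted there.
#' @param body_detach_um Width of the guard band carved around each
#'   detected soma before thinning, so each primary process becomes its own
#'   skeleton stem.
#' @param spur_min_length_um Skeleton spurs shorter than this are treated
#'   as thinning artefacts and pruned.
#' @param junction_merge_um Junction nodes closer than this along the
#'   skeleton are merged into one branch point.
#' @param min_component_px Foreground specks smaller than this many pixels
#'   are dropped before thinning.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma_um = 0.12,
                                body_opening_radius_um = 2,
                                global_threshold_method = "background",
                                min_body_area_um2 = 5,
                                attribution_max_gap_um = 1,
                                body_detach_um = 0.6,
                                spur_min_length_um = 0.9,
                                junction_merge_um = 1.2,
                                min_component_px = 6L) {
  vals <- list(smoothing_sigma_um = smoothing_sigma_um,
               body_opening_radius_um = body_opening_radius_um,
               global_threshold_method = global_threshold_method,
               min_body_area_um2 = min_body_area_um2,
               attribution_max_gap_um = attribution_max_gap_um,
               body_detach_um = body_detach_um,
               spur_min_length_um = spur_min_length_um,
               junction_merge_um = junction_merge_um,
               min_component_px = as.integer(min_component_px))
  num <- vals[vapply(vals, is.numeric, TRUE)]
  if (any(unlist(num) < 0)) abort("segmentation lengths must be >= 0.")
  structure(vals, class = "segmentation_params")
}

# Euclidean binary erosion / dilation by radius r (pixels) via an exact
# distance transform; much faster than brush convolution at these radii.
erode_r <- function(mask, r) {
  if (r <= 0) return(mask)
  cpp_edt_sq(!mask) > r * r
}

dilate_r <- function(mask, r) {
  if (r <= 0) return(mask)
  if (!any(mask)) return(mask)
  cpp_edt_sq(mask) <= r * r
}

# Otsu split computed on log-intensities: fluorescence contrast is
# multiplicative, so the log keeps the background/signal split dominant
# over the process/soma split in the between-class variance. Callers place
# the working threshold a fixed way up from the background class mean (see
# detect_cell_bodies), which keeps thin blurred strokes intact.
otsu_threshold <- function(img, levels = 256L) {
  v <- log(pmax(img, 1e-4))
  rng <- range(v)
  if (diff(rng) < 1e-12) return(Inf)
  h <- as.numeric(
    tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)),
             levels))
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w <- cumsum(h)
  m <- cumsum(h * mids)
  n <- w[levels]; mt <- m[levels]
  w0 <- w[-levels]; m0 <- m[-levels]
  valid <- w0 > 0 & w0 < n
  bcv <- rep(-Inf, levels - 1L)
  bcv[valid] <- (mt * w0[valid] - m0[valid] * n)^2 /
    (w0[valid] * (n - w0[valid]))
  exp(mids[which.max(bcv)])
}

#' Detect cell bodies on a calibrated 2D projection
#'
#' The projection is Gaussian-smoothed and thresholded globally (see
#' `global_threshold_method` in [segmentation_params()]); a morphological
#' opening of the foreground with `body_opening_radius_um` suppresses the
#' thin ramifications, the surviving blobs are labelled as somata and
#' refined to their half-maximum contour. Per body the centroid, area,
#' mean fluorescence (on the raw projection) and a digitisation-robust
#' perimeter/roundness are measured.
#'
#' @param projection Numeric matrix on the `[0, 1]` grey scale.
#' @param params A [segmentation_params()].
#' @param pixel_size_um Calibration.
#' @return Object of class `body_detection`: list with `bodies` (tibble:
#'   `body_id`, `centroid_x_um`, `centroid_y_um`, `body_area_um2`,
#'   `mean_intensity`, `perimeter_um`, `roundness`), `label_mask`,
#'   `foreground`, `threshold`, `pixel_size_um`.
#' @export
detect_cell_bodies <- function(projection, params = segmentation_params(),
                               pixel_size_um = 0.19) {
  s <- pixel_size_um
  sigma_px <- params$smoothing_sigma_um / s
  smooth <- if (sigma_px > 0) {
    cpp_gauss_blur(projection, sigma_px)
  } else projection

  if (diff(range(smooth)) < 1e-12) {
    # blank field: no objects, not an error
    return(structure(list(bodies = empty_bodies_table(),
                          label_mask = matrix(0L, nrow(projection),
                                              ncol(projection)),
                          foreground = matrix(FALSE, nrow(projection),
                                              ncol(projection)),
                          threshold = Inf, pixel_size_um = s),
                     class = "body_detection"))
  }
  # threshold estimated on a pixel subsample: statistically equivalent on
  # megapixel mosaics at a fraction of the cost
  sub <- if (length(smooth) > 1e6) {
    smooth[seq(1, length(smooth), by = length(smooth) %/% 1e6 + 1L)]
  } else smooth
  if (identical(params$global_threshold_method, "otsu")) {
    t0 <- otsu_threshold(sub)
    bg_mean <- mean(sub[sub <= t0])
    sig_mean <- mean(sub[sub > t0])
    thr <- bg_mean + 0.25 * (sig_mean - bg_mean)
  } else {
    # background-referenced threshold: cells cover only a few percent of a
    # mosaic, so the median and MAD estimate the background level and
    # noise; the cut sits a noise-safe margin above background, but at
    # least a quarter of the way to the bright-signal reference so the
    # blur skirt of thin strokes stays out
    bg_mean <- median(sub)
    sigma_bg <- stats::mad(sub)
    signal_ref <- stats::quantile(sub, 0.999, names = FALSE)
    thr <- bg_mean + max(6 * sigma_bg, 0.25 * (signal_ref - bg_mean))
  }
  fg <- smooth > thr

  r_open <- params$body_opening_radius_um / s
  seedm <- erode_r(fg, r_open)
  body_mask <- dilate_r(seedm, r_open) & fg

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(body_mask * 1)))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0) {
    return(structure(list(bodies = empty_bodies_table(), label_mask = lab,
                          foreground = fg, threshold = thr,
                          pixel_size_um = s),
                     class = "body_detection"))
  }

  # refine each soma to its half-maximum contour: the generous working
  # threshold overstates soma size by the blur skirt, the half-max cut
  # recovers the true boundary of the (flat-topped) soma profile
  body_idx <- which(lab > 0L)
  if (length(body_idx) > 0) {
    peak <- rep(-Inf, n)
    lb0 <- lab[body_idx]
    pk <- tapply(smooth[body_idx], lb0, max)
    peak[as.integer(names(pk))] <- pk
    cut <- (bg_mean + peak) / 2
    drop_px <- smooth[body_idx] < cut[lb0]
    lab[body_idx[drop_px]] <- 0L
  }

  min_px <- params$min_body_area_um2 / s^2
  areas_px <- tabulate(lab, n)
  keep <- which(areas_px >= min_px)
  relabel <- integer(n)
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  n <- length(keep)
  if (n == 0) {
    return(structure(list(bodies = empty_bodies_table(), label_mask = lab,
                          foreground = fg, threshold = thr,
                          pixel_size_um = s),
                     class = "body_detection"))
  }

  idx <- which(lab > 0)
  lb <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area_px <- tabulate(lb, n)
  cx <- tapply((cols - 0.5) * s, lb, mean)
  cy <- tapply((rows - 0.5) * s, lb, mean)
  mi <- tapply(projection[idx], lb, mean)

  shape <- body_shape_metrics(lab, n, s)

  bodies <- tibble(
    body_id = seq_len(n),
    centroid_x_um = as.numeric(cx),
    centroid_y_um = as.numeric(cy),
    body_area_um2 = area_px * s^2,
    mean_intensity = as.numeric(mi),
    perimeter_um = shape$perimeter_um,
    roundness = shape$roundness)

  structure(list(bodies = bodies, label_mask = lab, foreground = fg,
                 threshold = thr, pixel_size_um = s),
            class = "body_detection")
}

empty_bodies_table <- function() {
  tibble(body_id = integer(), centroid_x_um = numeric(),
         centroid_y_um = numeric(), body_area_um2 = numeric(),
         mean_intensity = numeric(), perimeter_um = numeric(),
         roundness = numeric())
}

# Perimeter and roundness per labelled object from its ordered boundary
# chain (see chain_metrics() in morpho.R).
body_shape_metrics <- function(lab, n, pixel_size_um) {
  oc <- EBImage::ocontour(EBImage::Image(lab))
  per <- numeric(n); rnd <- numeric(n)
  for (i in seq_len(n)) {
    m <- chain_metrics(oc[[i]])
    per[i] <- m$perimeter * pixel_size_um
    rnd[i] <- m$roundness
  }
  list(perimeter_um = per, roundness = rnd)
}

#' Extract the one-pixel process skeleton and its graph
#'
#' The thresholded foreground minus a guard band around each detected soma
#' is thinned (Zhang-Suen) to a one-pixel skeleton, which is converted to a
#' geometric graph: nodes at junctions and endpoints, polyline edges with
#' physical lengths. Spurs below `spur_min_length_um` are pruned, junction
#' clusters closer than `junction_merge_um` merged, and residual degree-2
#' nodes dissolved.
#'
#' @param projection Numeric matrix (same one given to
#'   [detect_cell_bodies()]).
#' @param bodies A [detect_cell_bodies()] result.
#' @param params A [segmentation_params()].
#' @return Object of class `skeleton_graph`: list with `nodes` (tibble:
#'   `node_id`, `x_um`, `y_um`, `degree`, `kind`), `edges` (tibble:
#'   `edge_id`, `node_a`, `node_b`, `length_um`, `pts` polyline
#'   list-column in pixel coordinates), `proc_labels` (labelled foreground
#'   component mask), `skeleton` (logical matrix) and `pixel_size_um`.
#' @export
extract_process_skeleton <- function(projection, bodies,
                                     params = segmentation_params()) {
  stopifnot(inherits(bodies, "body_detection"))
  s <- bodies$pixel_size_um
  fg <- bodies$foreground
  detach_px <- params$body_detach_um / s
  proc <- fg & !dilate_r(bodies$label_mask > 0, detach_px)

  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(proc * 1)))
  storage.mode(lab) <- "integer"
  if (max(lab) > 0) {
    sizes <- tabulate(lab, max(lab))
    drop <- which(sizes < params$min_component_px)
    if (length(drop) > 0) proc[lab %in% drop] <- FALSE
    lab[!proc] <- 0L
  }

  skel <- cpp_thin(proc)
  g <- build_skeleton_graph(skel, s, params)
  g$proc_labels <- lab
  g
}
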