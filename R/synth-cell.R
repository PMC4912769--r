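#' Generate one synthetic microglial cell with known ground truth
#'
#' Grows a ramified process tree from the given archetype and (optionally)
#' renders it into a raster patch. Processes are smoothed random-walk
#' polylines with bounded turning; each primary ramification is confined to
#' its own angular sector around the soma so arbors never self-cross, and a
#' clearance check regenerates the rare tree whose branches come closer than
#' one stroke width. The returned truth record stores every downstream
#' criterion computed analytically from the tree, pre-rasterisation:
#' segment counts by branch order, complexity index
#' (`segments / primaries`), covered environment area (convex hull over the
#' process extremities), body area (`pi r^2`) and cytoplasm area (body plus
#' the stroke area of the order-1 segments).
#'
#' @param archetype A [cell_archetype()].
#' @param seed Optional integer seed; the same archetype and seed always
#'   yield the identical truth record and raster.
#' @param centroid_um Soma centre in micrometres (length-2 numeric).
#' @param detail `"counts"` grows only the branching structure (fast, no
#'   geometry, covered environment area is `NA`), `"tree"` adds polylines
#'   and endpoints, `"raster"` additionally renders the patch.
#' @param pixel_size_um Pixel calibration used when rendering.
#' @param max_extent_um Maximum allowed radial extent of the arbor; trees
#'   exceeding it are regrown so tissue-level spacing guarantees hold.
#' @param max_tries Regrowth attempts before giving up.
#' @return List with elements `truth` (one-row tibble; list-columns
#'   `endpoints_um` -- a two-column matrix -- and `segments` -- a tibble of
#'   per-segment order/length/polyline) and `patch` (for
#'   `detail = "raster"`: list `img`, `row0`, `col0` placing the patch into
#'   a larger raster), else `NULL`.
#' @examples
#' am <- generate_cell(archetype_presets()$amoeboid, seed = 1)
#' am$truth$true_CI   # amoeboid: exactly 1, no branch nodes
#' @export
generate_cell <- function(archetype, seed = NULL,
                          centroid_um = c(0, 0),
                          detail = c("raster", "tree", "counts"),
                          pixel_size_um = 0.19,
                          max_extent_um = 34,
                          max_tries = 400L) {
  if (!inherits(archetype, "cell_archetype")) {
    abort("`archetype` must be a cell_archetype object.")
  }
  detail <- match.arg(detail)
  with_seed(seed, {
    tree <- NULL
    for (try in seq_len(max_tries)) {
      cand <- grow_tree(archetype, centroid_um,
                        geometry = detail != "counts",
                        max_extent = max_extent_um)
      if (detail == "counts" ||
          tree_is_clean(cand, archetype, centroid_um, max_extent_um)) {
        tree <- cand
        break
      }
    }
    if (is.null(tree)) {
      abort("could not grow a self-avoiding arbor; relax archetype parameters")
    }
    truth <- tree_truth(tree, archetype, centroid_um)
    patch <- NULL
    if (detail == "raster") {
      patch <- render_cell_patch(tree, archetype, centroid_um, pixel_size_um)
    }
    list(truth = truth, patch = patch)
  })
}

# -- tree growth ------------------------------------------------------------

# Segments are grown breadth-first. Geometry (when requested) is a polyline
# per segment in absolute micrometres; headings are clamped both to the
# primary's angular sector and to +/-0.6 rad of the segment's initial
# heading (bounded turning). Growth respects the extent cap natively:
# segments truncate where they reach it and branching stops when the
# remaining radial room could not hold a detectable child segment.
grow_tree <- function(arch, centroid, geometry = TRUE, max_extent = 26) {
  step <- 0.7
  turn_sd <- 0.10
  decay <- 0.8
  sector_half <- min(pi / arch$n_primary * 0.85, 1.0)
  cap <- max_extent - 0.8

  segs <- list()
  queue <- list()
  next_id <- 1L

  base_jitter <- runif(arch$n_primary, -0.25, 0.25) * 2 * pi / arch$n_primary
  for (k in seq_len(arch$n_primary)) {
    theta <- 2 * pi * (k - 1) / arch$n_primary + base_jitter[k]
    queue[[length(queue) + 1L]] <-
      list(parent = 0L, order = 1L, heading = theta, base = theta,
           origin = centroid +
             (arch$body_radius_um - 0.25 * arch$process_thickness_um) *
             c(cos(theta), sin(theta)))
  }

  while (length(queue) > 0) {
    job <- queue[[1L]]; queue[[1L]] <- NULL
    mu <- arch$mean_segment_length_um * decay^(job$order - 1L)
    sdv <- arch$segment_length_sd_um * decay^(job$order - 1L)
    # floor of 3 um: shorter segments are not resolvable against the
    # stroke width at the default calibration
    len <- clamp(rnorm(1, mu, sdv), max(3.5, mu - 2 * sdv), mu + 2 * sdv)

    if (geometry) {
      nstep <- max(2L, as.integer(round(len / step)))
      dh <- rnorm(nstep, 0, turn_sd)
      h <- numeric(nstep)
      prev <- job$heading
      for (t in seq_len(nstep)) {
        ht <- clamp(prev + dh[t], job$base - sector_half, job$base + sector_half)
        ht <- clamp(ht, job$heading - 0.6, job$heading + 0.6)
        h[t] <- ht
        prev <- ht
      }
      pts <- rbind(job$origin,
                   cbind(job$origin[1] + cumsum(step * cos(h)),
                         job$origin[2] + cumsum(step * sin(h))))
      rad <- sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2)
      over <- which(rad >= cap)
      if (length(over) > 0) {
        cut <- max(3L, over[1] - 1L)   # keep at least two steps
        pts <- pts[seq_len(cut), , drop = FALSE]
        nstep <- cut - 1L
      }
      end <- pts[nrow(pts), ]
      end_heading <- h[nstep]
      seg_len <- step * nstep
    } else {
      pts <- NULL
      end <- NULL
      end_heading <- job$heading
      seg_len <- len
    }

    id <- next_id; next_id <- next_id + 1L
    p <- arch$branch_prob_per_order
    pb <- if (job$order <= length(p)) p[job$order] else 0
    branch <- job$order < arch$max_order && runif(1) < pb
    if (branch && geometry &&
        cap - sqrt(sum((end - centroid)^2)) < 3.5) {
      branch <- FALSE    # no room for a detectable child near the cap
    }

    segs[[id]] <- list(seg_id = id, parent_id = job$parent, order = job$order,
                       length_um = seg_len, pts = pts, end = end,
                       terminal = !branch)
    if (branch) {
      spread <- 0.62 + runif(1, 0, 0.2)
      for (s in c(-1, 1)) {
        queue[[length(queue) + 1L]] <-
          list(parent = id, order = job$order + 1L,
               heading = end_heading + s * spread, base = job$base,
               origin = end)
      }
    }
  }
  segs
}

# Reject trees whose geometry would confuse the segmentation oracle:
# excursions beyond `max_extent`, non-adjacent branches closer than one
# stroke clearance, or process points re-entering the soma.
tree_is_clean <- function(segs, arch, centroid, max_extent) {
  pts <- do.call(rbind, lapply(segs, function(s) s$pts))
  rel <- sweep(pts, 2, centroid)
  rad <- sqrt(rowSums(rel^2))
  if (max(rad) > max_extent) return(FALSE)

  # keep the arbor clear of the soma surroundings: anything re-entering
  # the attribution gap around the soma would read as a phantom extra
  # primary downstream. Only the proximal stretch of each primary stem is
  # exempt.
  r_in <- arch$body_radius_um + 2.3
  owner <- rep.int(seq_along(segs), vapply(segs, function(s) nrow(s$pts), 1L))
  stem_exempt <- unlist(lapply(segs, function(s) {
    k <- nrow(s$pts)
    if (s$order == 1L) c(rep(TRUE, min(6L, k)), rep(FALSE, max(0L, k - 6L)))
    else rep(FALSE, k)
  }))
  if (any(rad < r_in & !stem_exempt)) return(FALSE)

  if (length(segs) > 1L) {
    clear <- max(1.2, arch$process_thickness_um + 0.6)
    parent <- vapply(segs, function(s) s$parent_id, 1L)
    d2 <- as.matrix(stats::dist(pts))^2
    near <- d2 < clear^2
    diag(near) <- FALSE
    if (any(near)) {
      ij <- which(near, arr.ind = TRUE)
      ij <- ij[owner[ij[, 1]] < owner[ij[, 2]], , drop = FALSE]
      for (r in seq_len(nrow(ij))) {
        a <- owner[ij[r, 1]]; b <- owner[ij[r, 2]]
        if (a == b) next
        shared <- shared_node(segs, parent, a, b)
        if (is.null(shared)) return(FALSE)
        if (sum((pts[ij[r, 1], ] - shared)^2) > 2.5^2 ||
            sum((pts[ij[r, 2], ] - shared)^2) > 2.5^2) return(FALSE)
      }
    }
  }
  TRUE
}

# Shared node of two segments, if adjacent: parent/child junction or the
# common parent's end for siblings; NULL otherwise.
shared_node <- function(segs, parent, a, b) {
  if (parent[b] == a) return(segs[[a]]$end)
  if (parent[a] == b) return(segs[[b]]$end)
  if (parent[a] != 0L && parent[a] == parent[b]) return(segs[[parent[a]]]$end)
  NULL
}

# -- truth assembly ---------------------------------------------------------

tree_truth <- function(segs, arch, centroid) {
  order_raw <- vapply(segs, function(s) s$order, 1L)
  n_primary <- sum(order_raw == 1L)
  n_secondary <- sum(order_raw == 2L)
  n_tertiary <- sum(order_raw >= 3L)
  n_segments <- length(segs)
  lengths <- vapply(segs, function(s) s$length_um, 1)

  has_geom <- !is.null(segs[[1L]]$pts)
  endpoints <- if (has_geom) {
    ep <- do.call(rbind, lapply(segs[vapply(segs, function(s) s$terminal,
                                            TRUE)],
                                function(s) s$end))
    `colnames<-`(ep, c("x", "y"))
  } else {
    matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y")))
  }
  cea <- if (has_geom) convex_hull_area(endpoints) else NA_real_

  body_area <- pi * arch$body_radius_um^2
  cyto_area <- body_area +
    sum(lengths[order_raw == 1L]) * arch$process_thickness_um

  seg_tbl <- tibble(
    seg_id = vapply(segs, function(s) s$seg_id, 1L),
    parent_id = vapply(segs, function(s) s$parent_id, 1L),
    order = order_raw,
    length_um = lengths,
    terminal = vapply(segs, function(s) s$terminal, TRUE),
    pts = lapply(segs, function(s) s$pts)
  )

  tibble(
    archetype = arch$name,
    centroid_x_um = centroid[1], centroid_y_um = centroid[2],
    true_body_area_um2 = body_area,
    true_cytoplasm_area_um2 = cyto_area,
    true_n_primary = n_primary, true_n_secondary = n_secondary,
    true_n_tertiary = n_tertiary, true_n_segments = n_segments,
    true_total_length_um = sum(lengths),
    true_CI = n_segments / n_primary,
    true_CEA_um2 = cea,
    endpoints_um = list(endpoints),
    segments = list(seg_tbl)
  )
}

# -- rendering --------------------------------------------------------------

# Render soma and processes into a minimal patch; `row0`/`col0` give the
# 1-based position of patch[1,1] in the enclosing raster. Pixel (i, j) is
# centred at x = (j - 0.5) px, y = (i - 0.5) px.
render_cell_patch <- function(segs, arch, centroid, pixel_size_um) {
  s <- pixel_size_um
  pts <- do.call(rbind, lapply(segs, function(sg) sg$pts))
  half <- 0.5 * arch$process_thickness_um
  xr <- range(c(pts[, 1], centroid[1] + c(-1, 1) * arch$body_radius_um))
  yr <- range(c(pts[, 2], centroid[2] + c(-1, 1) * arch$body_radius_um))
  margin <- half + 3 * s
  col0 <- floor((xr[1] - margin) / s) + 1L
  row0 <- floor((yr[1] - margin) / s) + 1L
  ncol_p <- ceiling((xr[2] + margin) / s) - col0 + 1L
  nrow_p <- ceiling((yr[2] + margin) / s) - row0 + 1L

  to_px <- function(xy) {
    cbind(xy[, 2] / s + 0.5 - (row0 - 1L),   # row from y
          xy[, 1] / s + 0.5 - (col0 - 1L))   # col from x
  }
  img <- matrix(0, nrow_p, ncol_p)
  img <- cpp_stamp_polyline(img, to_px(matrix(centroid, ncol = 2)),
                            arch$body_radius_um / s, arch$intensity_body)
  for (sg in segs) {
    img <- cpp_stamp_polyline(img, to_px(sg$pts), half / s,
                              arch$intensity_process)
  }
  list(img = img, row0 = row0, col0 = col0)
}
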