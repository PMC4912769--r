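#' Complexity index: segments per primary ramification
#'
#' The complexity index (CI) of a cell is its number of segments (a segment
#' being the stretch of process between two nodes: soma root, junction or
#' endpoint) divided by its number of primary ramifications — the mean
#' branching complexity carried by each primary process. An unbranched cell
#' has CI = 1; amoeboid cells are defined by exactly that value.
#'
#' @param n_segments,n_primary Counts (vectorised).
#' @return Numeric vector of ratios.
#' @examples
#' complexity_index(3, 1)       # one primary that bifurcates once
#' complexity_index(c(2, 5), c(2, 3))
#' @export
complexity_index <- function(n_segments, n_primary) {
  if (any(n_primary == 0)) {
    abort(paste("complexity index undefined for cells without primary",
                "ramifications; exclude process-free cells first."))
  }
  if (any(n_segments < n_primary)) {
    abort("`n_segments` cannot be smaller than `n_primary`.")
  }
  n_segments / n_primary
}

#' Covered environment area: territory spanned by the process extremities
#'
#' The covered environment area (CEA) is the planar area of the polygon
#' over the extremities of a cell's processes, implemented as the convex
#' hull — the unique polygon that needs no vertex ordering convention.
#' Fewer than three non-collinear extremities give area 0.
#'
#' @param endpoints Two-column matrix (or data frame) of extremity
#'   coordinates in micrometres; may be empty.
#' @return Area in square micrometres.
#' @examples
#' covered_environment_area(rbind(c(0, 0), c(10, 0), c(0, 10)))  # 50
#' @export
covered_environment_area <- function(endpoints) {
  if (is.null(endpoints) || length(endpoints) == 0) return(0)
  xy <- as.matrix(endpoints)
  if (ncol(xy) != 2) abort("`endpoints` must have two columns.")
  convex_hull_area(xy)
}

#' Roundness of a soma mask
#'
#' The normalised area-to-perimeter ratio `4 * pi * A / P^2`, equal to 1
#' for a disc. Area and perimeter are both measured on the ordered
#' boundary chain of the mask after a 3-point moving-average smoothing
#' (which removes the staircase excess of raw chain lengths), keeping the
#' estimate close to the analytic value for digitised shapes: discs score
#' near 1, squares near `pi / 4`, elongated noise well below the 0.7
#' population filter.
#'
#' @param mask Logical (or 0/1) matrix containing a single object.
#' @return Roundness in `(0, 1]`.
#' @export
roundness <- function(mask) {
  m <- (as.matrix(mask) > 0) * 1
  if (!any(m > 0)) abort("empty mask.")
  oc <- EBImage::ocontour(EBImage::Image(m))[[1]]
  chain_metrics(oc)$roundness
}

# Perimeter and shoelace area of a closed 8-connected boundary chain,
# measured on the chain smoothed with a 3-point circular moving average:
# the smoothing removes the staircase excess that makes raw chain lengths
# overestimate curved boundaries, while barely rounding true corners.
# Roundness = 4*pi*A/P^2, clamped to 1.
chain_metrics <- function(oc) {
  n <- nrow(oc)
  if (is.null(n) || n < 4) {
    return(list(perimeter = max(n, 1), area = max(n, 1) / 4, roundness = 1))
  }
  prev <- c(n, 1:(n - 1))
  nxt <- c(2:n, 1)
  sm <- (oc[prev, , drop = FALSE] + oc + oc[nxt, , drop = FALSE]) / 3
  d <- sm[nxt, , drop = FALSE] - sm
  per <- sum(sqrt(rowSums(d^2)))
  area <- shoelace_area(sm)
  r <- if (per > 0 && area > 0) 4 * pi * area / per^2 else 1
  list(perimeter = per, area = area, roundness = clamp(r, 1e-6, 1))
}

#' Areal density of retained cells
#'
#' @param n_cells Cell count (or a records tibble, whose rows are counted).
#' @param scanned_area_mm2 Scanned tissue area in square millimetres.
#' @param scope Label for the summarised scope (a region name or
#'   `"brain"`).
#' @return One-row tibble: `scope`, `n_cells`, `scanned_area_mm2`,
#'   `density_cells_per_mm2`.
#' @export
areal_density <- function(n_cells, scanned_area_mm2, scope = "brain") {
  if (is.data.frame(n_cells)) n_cells <- nrow(n_cells)
  stopifnot_scalar_number(scanned_area_mm2, "scanned_area_mm2",
                          positive = TRUE)
  tibble(scope = scope, n_cells = as.integer(n_cells),
         scanned_area_mm2 = scanned_area_mm2,
         density_cells_per_mm2 = n_cells / scanned_area_mm2)
}

#' Measure every morphological criterion for the cells of one projection
#'
#' Assembles the per-cell feature table from a body detection and an
#' attributed process forest: body and cytoplasm areas, roundness,
#' background-subtracted mean fluorescence over the whole cell (soma plus
#' attributed process foreground), ramification counts by branch order,
#' total ramification length, complexity index and covered environment
#' area. Cells whose segmentation yields no primary process are reported as
#' amoeboid with CI = 1.
#'
#' @param projection The raw projection the detections came from.
#' @param bodies A [detect_cell_bodies()] result.
#' @param forest An [assign_processes_to_cells()] result.
#' @param subvolume_index Axial sub-volume tag stored with each record.
#' @return Tibble, one row per detected body, with list-column
#'   `endpoints_um` carrying the extremities used for the CEA.
#' @export
measure_cells <- function(projection, bodies, forest, subvolume_index = 0L) {
  stopifnot(inherits(bodies, "body_detection"),
            inherits(forest, "process_forest"))
  s <- bodies$pixel_size_um
  btab <- bodies$bodies
  n <- nrow(btab)
  if (n == 0) return(empty_records_table())

  lab_body <- bodies$label_mask
  body_idx <- which(lab_body > 0L)
  body_int <- rowsum(projection[body_idx], lab_body[body_idx])
  body_px <- tabulate(lab_body[body_idx], n)

  proc_lab <- forest$graph$proc_labels
  proc_idx <- which(proc_lab > 0L)
  if (length(proc_idx) > 0) {
    n_lab <- max(proc_lab)
    proc_px_by_lab <- tabulate(proc_lab[proc_idx], n_lab)
    proc_int_by_lab <- as.numeric(
      rowsum(projection[proc_idx],
             factor(proc_lab[proc_idx], levels = seq_len(n_lab))))
  } else {
    proc_px_by_lab <- numeric(0)
    proc_int_by_lab <- numeric(0)
  }
  bg <- if (is.finite(bodies$threshold)) bodies$threshold else 0
  nodes <- forest$graph$nodes

  rec <- vector("list", n)
  for (b in seq_len(n)) {
    tr <- forest$trees[[as.character(b)]]
    if (!is.null(tr)) tr <- order_branches(tr)

    if (is.null(tr) || nrow(tr$edges) == 0L) {
      counts <- list(n_primary = 0L, n_secondary = 0L, n_tertiary = 0L,
                     n_segments = 0L)
      total_len <- 0
      cea <- 0
      endpoints <- matrix(numeric(0), ncol = 2,
                          dimnames = list(NULL, c("x", "y")))
      proc_area_px <- 0
      proc_int <- 0
      cyto_extra_px <- 0
    } else {
      counts <- tr$counts
      total_len <- sum(tr$edges$length_um)

      cell_labels <- unique(vapply(tr$edges$pts, function(p) {
        proc_lab[p[2, 1], p[2, 2]]
      }, 1L))
      cell_labels <- cell_labels[cell_labels > 0L]
      proc_area_px <- sum(proc_px_by_lab[cell_labels])
      proc_int <- sum(proc_int_by_lab[cell_labels])

      cell_nodes <- unique(c(tr$edges$node_a, tr$edges$node_b))
      tips <- setdiff(cell_nodes[nodes$kind[cell_nodes] == "endpoint"],
                      tr$root_nodes)
      endpoints <- cbind(x = nodes$x_um[tips], y = nodes$y_um[tips])
      cea <- covered_environment_area(endpoints)

      cyto_extra_px <- primary_coverage_px(tr, proc_lab, proc_area_px, s)
    }

    n_prim <- counts$n_primary
    ci <- if (n_prim == 0L) 1 else counts$n_segments / n_prim
    tot_px <- body_px[b] + proc_area_px
    mean_int <- (body_int[b] + proc_int) / tot_px - bg

    rec[[b]] <- tibble(
      cell_id = sprintf("cell_%04d", b),
      animal_id = NA_character_, condition = NA_character_,
      region = NA_character_,
      subvolume_index = as.integer(subvolume_index),
      centroid_x_um = btab$centroid_x_um[b],
      centroid_y_um = btab$centroid_y_um[b],
      body_area_um2 = btab$body_area_um2[b],
      cytoplasm_area_um2 = btab$body_area_um2[b] + cyto_extra_px * s^2,
      roundness = btab$roundness[b],
      mean_intensity = max(mean_int, 0),
      n_primary = counts$n_primary, n_secondary = counts$n_secondary,
      n_tertiary = counts$n_tertiary, n_segments = counts$n_segments,
      n_ramifications = counts$n_segments,
      total_ramification_length_um = total_len,
      CI = ci, CEA_um2 = cea,
      is_amoeboid = ci == 1,
      endpoints_um = list(endpoints))
  }
  dplyr::bind_rows(rec)
}

# Foreground pixels covered by the order-1 segments of a tree: the order-1
# polylines are stamped with the cell's estimated stroke radius and
# intersected with the cell's foreground components.
primary_coverage_px <- function(tr, proc_lab, proc_area_px, pixel_size_um) {
  prim <- tr$edges[tr$edges$branch_order == 1L, ]
  if (nrow(prim) == 0L) return(0)
  len_px <- sum(tr$edges$length_um) / pixel_size_um
  thick_px <- if (len_px > 0) proc_area_px / len_px else 2
  pts_all <- do.call(rbind, prim$pts)
  r0 <- max(1L, min(pts_all[, 1]) - 6L); r1 <- min(nrow(proc_lab), max(pts_all[, 1]) + 6L)
  c0 <- max(1L, min(pts_all[, 2]) - 6L); c1 <- min(ncol(proc_lab), max(pts_all[, 2]) + 6L)
  stamp <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
  for (k in seq_len(nrow(prim))) {
    p <- prim$pts[[k]]
    loc <- cbind(p[, 1] - r0 + 1L, p[, 2] - c0 + 1L)
    stamp <- cpp_stamp_polyline(stamp, loc, thick_px / 2 + 0.5, 1)
  }
  sum(stamp > 0 & proc_lab[r0:r1, c0:c1] > 0L)
}

empty_records_table <- function() {
  tibble(cell_id = character(), animal_id = character(),
         condition = character(), region = character(),
         subvolume_index = integer(),
         centroid_x_um = numeric(), centroid_y_um = numeric(),
         body_area_um2 = numeric(), cytoplasm_area_um2 = numeric(),
         roundness = numeric(), mean_intensity = numeric(),
         n_primary = integer(), n_secondary = integer(),
         n_tertiary = integer(), n_segments = integer(),
         n_ramifications = integer(),
         total_ramification_length_um = numeric(),
         CI = numeric(), CEA_um2 = numeric(), is_amoeboid = logical(),
         endpoints_um = list())
}

#' Quantify one 2D projection end to end
#'
#' Convenience wrapper: body detection, skeleton extraction, process
#' attribution and per-cell measurement in one call.
#'
#' @inheritParams detect_cell_bodies
#' @inheritParams measure_cells
#' @return Tibble of cell records (see [measure_cells()]).
#' @export
quantify_projection <- function(projection, params = segmentation_params(),
                                pixel_size_um = 0.19,
                                subvolume_index = 0L) {
  bodies <- detect_cell_bodies(projection, params, pixel_size_um)
  graph <- extract_process_skeleton(projection, bodies, params)
  forest <- assign_processes_to_cells(graph, bodies, params)
  measure_cells(projection, bodies, forest, subvolume_index)
}

#' Quantify a full image stack across its axial sub-volumes
#'
#' Splits the stack into sub-volumes, maximum-intensity projects each, and
#' quantifies every projection, tagging records with their sub-volume
#' index so duplicates can be eliminated downstream.
#'
#' @param stack An [image_stack()].
#' @param params A [segmentation_params()].
#' @param n_subvolumes Number of axial blocks.
#' @return Tibble of cell records across all sub-volumes.
#' @export
quantify_stack <- function(stack, params = segmentation_params(),
                           n_subvolumes = 3L) {
  ps <- split_and_project(stack, n_subvolumes)
  recs <- lapply(seq_along(ps$projections), function(k) {
    r <- quantify_projection(ps$projections[[k]], params,
                             ps$pixel_size_um, subvolume_index = k - 1L)
    if (nrow(r) > 0) {
      r$cell_id <- sprintf("sv%d_%s", k - 1L, r$cell_id)
    }
    r
  })
  dplyr::bind_rows(recs)
}
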