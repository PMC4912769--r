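#' Population filter configuration
#'
#' Thresholds for the elimination of outliers and redundant cells: somata
#' outside the 10-500 um^2 size window or with roundness below 0.7 are
#' treated as tissue-noise artefacts; the bounds themselves are kept
#' (strict inequalities). Duplicates of one cell detected on two adjacent
#' axial sub-volumes are matched by centroid proximity.
#'
#' @param min_body_area_um2,max_body_area_um2 Soma size window.
#' @param min_roundness Roundness cutoff.
#' @param edge_margin_um Width of the border band used by
#'   [remove_edge_cells()]; 0 means touching the border is enough.
#' @param dedup_max_centroid_dist_um Match radius for sub-volume
#'   duplicates (about one soma radius).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_body_area_um2 = 10,
                          max_body_area_um2 = 500,
                          min_roundness = 0.7,
                          edge_margin_um = 0,
                          dedup_max_centroid_dist_um = 5) {
  if (min_body_area_um2 >= max_body_area_um2) {
    abort("`min_body_area_um2` must be < `max_body_area_um2`.")
  }
  if (edge_margin_um < 0 || dedup_max_centroid_dist_um < 0) {
    abort("margins and match radii must be >= 0.")
  }
  structure(list(min_body_area_um2 = min_body_area_um2,
                 max_body_area_um2 = max_body_area_um2,
                 min_roundness = min_roundness,
                 edge_margin_um = edge_margin_um,
                 dedup_max_centroid_dist_um = dedup_max_centroid_dist_um),
            class = "filter_config")
}

#' Filter size and roundness outliers from a feature table
#'
#' @param records Cell records carrying `body_area_um2` and `roundness`.
#' @param config A [filter_config()].
#' @return List with `kept` and `rejected` tibbles; `rejected` carries a
#'   `reject_reason` column (`"too_small"`, `"too_large"`,
#'   `"low_roundness"`).
#' @export
filter_outliers <- function(records, config = filter_config()) {
  reason <- dplyr::case_when(
    records$body_area_um2 < config$min_body_area_um2 ~ "too_small",
    records$body_area_um2 > config$max_body_area_um2 ~ "too_large",
    records$roundness < config$min_roundness ~ "low_roundness",
    TRUE ~ NA_character_)
  rejected <- records[!is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reject_reason <- reason[!is.na(reason)]
  else rejected$reject_reason <- character(0)
  list(kept = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Remove cells whose territory touches the mosaic border
#'
#' A cell is removed when its process-extremity hull or its soma disc
#' intersects the band of width `edge_margin_um` along the mosaic border —
#' such cells may be truncated by the field of view.
#'
#' @param records Cell records with centroids and an `endpoints_um`
#'   list-column.
#' @param mosaic_width_um,mosaic_height_um Physical mosaic size.
#' @param config A [filter_config()].
#' @return The kept records.
#' @export
remove_edge_cells <- function(records, mosaic_width_um, mosaic_height_um,
                              config = filter_config()) {
  if (nrow(records) == 0) return(records)
  m <- config$edge_margin_um
  body_r <- sqrt(records$body_area_um2 / pi)
  eps <- if ("endpoints_um" %in% names(records)) records$endpoints_um
         else replicate(nrow(records), NULL, simplify = FALSE)
  clipped <- vapply(seq_len(nrow(records)), function(i) {
    ep <- eps[[i]]
    xs <- c(records$centroid_x_um[i] + c(-1, 1) * body_r[i],
            if (!is.null(ep) && nrow(ep) > 0) ep[, 1])
    ys <- c(records$centroid_y_um[i] + c(-1, 1) * body_r[i],
            if (!is.null(ep) && nrow(ep) > 0) ep[, 2])
    min(xs) <= m || min(ys) <= m ||
      max(xs) >= mosaic_width_um - m || max(ys) >= mosaic_height_um - m
  }, TRUE)
  records[!clipped, , drop = FALSE]
}

#' Merge duplicate detections of one cell across adjacent sub-volumes
#'
#' A cell whose soma spans the boundary between two axial sub-volumes is
#' detected on both projections. Pairs of records on adjacent sub-volumes
#' (indices differing by 1) with centroids within the match radius are
#' merged, keeping the member with the larger soma (ties: the lower
#' sub-volume index). Records on non-adjacent sub-volumes are never
#' merged.
#'
#' @param records Cell records with `subvolume_index` and centroids.
#' @param config A [filter_config()].
#' @return Deduplicated records.
#' @export
deduplicate_across_subvolumes <- function(records,
                                          config = filter_config()) {
  n <- nrow(records)
  if (n < 2) return(records)
  r_max <- config$dedup_max_centroid_dist_um
  x <- records$centroid_x_um; y <- records$centroid_y_um
  sv <- records$subvolume_index
  area <- records$body_area_um2

  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (abs(sv[i] - sv[j]) != 1L) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d <= r_max) pairs[[length(pairs) + 1L]] <- c(i, j, d)
    }
  }
  if (length(pairs) == 0) return(records)
  pm <- do.call(rbind, pairs)
  pm <- pm[order(pm[, 3]), , drop = FALSE]

  drop <- logical(n)
  for (k in seq_len(nrow(pm))) {
    i <- pm[k, 1]; j <- pm[k, 2]
    if (drop[i] || drop[j]) next
    loser <- if (area[i] > area[j]) j
             else if (area[j] > area[i]) i
             else if (sv[i] <= sv[j]) j else i
    drop[loser] <- TRUE
  }
  records[!drop, , drop = FALSE]
}

#' Apply the full population filter
#'
#' Size/roundness outlier removal, mosaic-edge removal and adjacent
#' sub-volume deduplication, in that order, with a per-stage count log.
#'
#' @inheritParams filter_outliers
#' @inheritParams remove_edge_cells
#' @return List with `kept`, `rejected` (outliers with reasons) and `log`
#'   (tibble of per-stage input/output counts).
#' @export
apply_population_filter <- function(records, mosaic_width_um,
                                    mosaic_height_um,
                                    config = filter_config()) {
  f <- filter_outliers(records, config)
  e <- remove_edge_cells(f$kept, mosaic_width_um, mosaic_height_um, config)
  d <- deduplicate_across_subvolumes(e, config)
  log <- tibble(
    stage = c("input", "outlier_filter", "edge_removal", "deduplication"),
    n_cells = c(nrow(records), nrow(f$kept), nrow(e), nrow(d)))
  list(kept = d, rejected = f$rejected, log = log)
}
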