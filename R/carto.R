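#' In-situ 2D cartography of phenotyped cells
#'
#' Builds the single-cell resolution map of a mosaic: one glyph per cell at
#' its physical position, coloured either by a joint (CI, CEA) gradient —
#' the rank of the summed z-scores, running from yellow (low complexity,
#' small territory) to red (high complexity, large territory) — or by
#' cluster / sub-population label. The mapping is deterministic: a fixed
#' colour table and no randomness, so identical inputs give identical
#' output.
#'
#' @param records Cell records; for `mode = "cluster"` a `.cluster` or
#'   cluster label column (see [augment.microglia_kmeans()]), for
#'   `mode = "subpopulation"` a `subpopulation` column.
#' @param mode `"gradient"`, `"cluster"` or `"subpopulation"`.
#' @param background Optional background raster (matrix, `[0, 1]` grey)
#'   drawn under the glyphs.
#' @param pixel_size_um Calibration of `background`.
#' @return Object of class `cartography`: list with `plot` (ggplot),
#'   `annotations` (tibble: cell, position, plotted value, hex colour).
#' @export
render_cartography <- function(records,
                               mode = c("gradient", "cluster",
                                        "subpopulation"),
                               background = NULL,
                               pixel_size_um = 0.19) {
  mode <- match.arg(mode)
  n <- nrow(records)

  if (n == 0) {
    ann <- tibble(cell_id = character(), x_um = numeric(), y_um = numeric(),
                  CI = numeric(), CEA_um2 = numeric(), value = numeric(),
                  class = character(), colour = character())
  } else {
    if (!is.null(background)) {
      w <- ncol(background) * pixel_size_um
      h <- nrow(background) * pixel_size_um
      out <- records$centroid_x_um < 0 | records$centroid_x_um > w |
        records$centroid_y_um < 0 | records$centroid_y_um > h
      if (any(out)) {
        warn(sprintf("%d cell(s) fall outside the background; clipped.",
                     sum(out)))
        records <- records[!out, , drop = FALSE]
        n <- nrow(records)
      }
    }
    if (mode == "gradient") {
      z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
      comp <- z(records$CI) + z(records$CEA_um2)
      val <- (rank(comp, ties.method = "average") - 1)
      val <- if (n > 1) val / (n - 1) else rep(0.5, n)
      pal <- grDevices::colorRamp(c("#FFEB3B", "#FF9800", "#D32F2F"))
      col <- grDevices::rgb(pal(val), maxColorValue = 255)
      cls <- NA_character_
    } else {
      cls <- as.character(
        if (mode == "cluster") {
          records$.cluster %||% records$cluster
        } else records$subpopulation)
      lut <- c(SP1 = "#FFEB3B", SP2 = "#FFA726", SP3 = "#F4511E",
               SP4 = "#B71C1C", amoeboid = "#7E57C2",
               `1` = "#FFEB3B", `2` = "#FFA726", `3` = "#F4511E",
               `4` = "#B71C1C")
      col <- unname(lut[cls])
      col[is.na(col)] <- "#9E9E9E"
      val <- NA_real_
    }
    ann <- tibble(cell_id = records$cell_id,
                  x_um = records$centroid_x_um,
                  y_um = records$centroid_y_um,
                  CI = records$CI, CEA_um2 = records$CEA_um2,
                  value = val, class = cls, colour = col)
  }

  p <- ggplot2::ggplot(ann, ggplot2::aes(x = .data$x_um, y = .data$y_um))
  if (!is.null(background)) {
    p <- p + ggplot2::annotation_raster(
      grDevices::as.raster(clamp(background, 0, 1)),
      xmin = 0, xmax = ncol(background) * pixel_size_um,
      ymin = 0, ymax = nrow(background) * pixel_size_um)
  }
  p <- p +
    ggplot2::geom_point(colour = ann$colour, size = 1.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()

  structure(list(plot = p, annotations = ann, mode = mode),
            class = "cartography")
}

#' @export
print.cartography <- function(x, ...) {
  cat(sprintf("<cartography> %s mode, %d cells\n", x$mode,
              nrow(x$annotations)))
  invisible(x)
}

#' Write cartography outputs: PNG overlay plus annotation CSV
#'
#' @param carto A [render_cartography()] result.
#' @param png_path,csv_path Output paths (either may be `NULL` to skip).
#' @param width_px,height_px PNG size.
#' @return Invisibly, the annotation tibble.
#' @export
write_cartography <- function(carto, png_path = NULL, csv_path = NULL,
                              width_px = 1200, height_px = 1200) {
  stopifnot(inherits(carto, "cartography"))
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = width_px, height = height_px)
    print(carto$plot)
    grDevices::dev.off()
  }
  if (!is.null(csv_path)) {
    readr::write_csv(carto$annotations, csv_path)
  }
  invisible(carto$annotations)
}
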