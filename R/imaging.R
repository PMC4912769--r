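#' Calibrated image stack
#'
#' A light container for a multi-plane grayscale acquisition: a list of
#' equally sized numeric matrices plus the physical calibration. Values are
#' expected on the `[0, 1]` grey scale used by TIFF float/16-bit IO.
#'
#' @param planes List of numeric matrices (or a single matrix).
#' @param pixel_size_um In-plane calibration, micrometres per pixel.
#' @param z_step_um Axial distance between consecutive planes.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(planes, pixel_size_um, z_step_um = 2) {
  if (is.matrix(planes)) planes <- list(planes)
  if (length(planes) < 1) abort("a stack needs at least one plane.")
  dims <- unique(lapply(planes, dim))
  if (length(dims) != 1) abort("all planes must share dimensions.")
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar_number(z_step_um, "z_step_um", positive = TRUE)
  structure(list(planes = planes, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<image_stack> %d plane(s) of %d x %d px, %.3g um/px, %.3g um z-step\n",
              length(x$planes), d[1], d[2], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Read / write an image stack as multi-page grayscale TIFF
#'
#' Calibration is not stored in the TIFF; supply it on read (or via a
#' sidecar YAML written by [write_stack()]).
#'
#' @param path TIFF file path.
#' @param pixel_size_um,z_step_um Calibration for the returned stack; when
#'   `NULL`, [read_stack()] looks for `<path>.yml`.
#' @param stack An [image_stack()].
#' @param sidecar Write `<path>.yml` holding the calibration.
#' @return [read_stack()]: an `image_stack`; [write_stack()]: `path`,
#'   invisibly.
#' @export
read_stack <- function(path, pixel_size_um = NULL, z_step_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  })
  side <- paste0(path, ".yml")
  if ((is.null(pixel_size_um) || is.null(z_step_um)) && file.exists(side)) {
    meta <- yaml::read_yaml(side)
    pixel_size_um <- pixel_size_um %||% meta$pixel_size_um
    z_step_um <- z_step_um %||% meta$z_step_um
  }
  if (is.null(pixel_size_um)) {
    abort("pixel_size_um not given and no sidecar YAML found.")
  }
  image_stack(pages, pixel_size_um = pixel_size_um,
              z_step_um = z_step_um %||% 2)
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(lapply(stack$planes, function(p) clamp(p, 0, 1)), path,
                  bits.per.sample = 16L)
  if (sidecar) {
    yaml::write_yaml(list(pixel_size_um = stack$pixel_size_um,
                          z_step_um = stack$z_step_um,
                          n_planes = length(stack$planes)),
                     paste0(path, ".yml"))
  }
  invisible(path)
}

#' Contiguous plane partition into axial sub-volumes
#'
#' Planes are split into `n_subvolumes` contiguous blocks with sizes as
#' equal as possible, earlier blocks larger: 16 planes over 3 sub-volumes
#' gives blocks of 6, 5 and 5 planes (10 um each at a 2 um z-step).
#'
#' @param n_planes Number of planes.
#' @param n_subvolumes Number of blocks.
#' @return Integer vector of length `n_planes`: the 1-based sub-volume
#'   index of each plane.
#' @export
subvolume_partition <- function(n_planes, n_subvolumes = 3L) {
  if (n_planes < n_subvolumes) {
    abort("fewer planes than sub-volumes.")
  }
  base <- n_planes %/% n_subvolumes
  extra <- n_planes %% n_subvolumes
  sizes <- base + as.integer(seq_len(n_subvolumes) <= extra)
  rep.int(seq_len(n_subvolumes), sizes)
}

#' Split a stack into sub-volumes and maximum-intensity project each
#'
#' @param stack An [image_stack()].
#' @param n_subvolumes Number of axial blocks (default 3, matching three
#'   10-um sub-volumes of a 30-um acquisition).
#' @return Object of class `projection_set`: list with `projections` (list
#'   of matrices), `plane_ranges` (tibble with 1-based `first`/`last`
#'   plane of each block) and `pixel_size_um`.
#' @examples
#' st <- image_stack(replicate(4, matrix(0.1, 8, 8), simplify = FALSE), 0.19)
#' ps <- split_and_project(st, 2)
#' ps$plane_ranges
#' @export
split_and_project <- function(stack, n_subvolumes = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  part <- subvolume_partition(length(stack$planes), n_subvolumes)
  projections <- lapply(seq_len(n_subvolumes), function(k) {
    Reduce(pmax, stack$planes[part == k])
  })
  ranges <- tibble(
    subvolume = seq_len(n_subvolumes) - 1L,
    first = vapply(seq_len(n_subvolumes), function(k) min(which(part == k)), 1L),
    last = vapply(seq_len(n_subvolumes), function(k) max(which(part == k)), 1L))
  structure(list(projections = projections, plane_ranges = ranges,
                 pixel_size_um = stack$pixel_size_um),
            class = "projection_set")
}

#' Assemble a grid of registered tiles into one mosaic
#'
#' Tiles are assumed pre-registered with zero overlap; no blending is done.
#'
#' @param tiles List of equally sized matrices in row-major order.
#' @param grid_rows,grid_cols Grid shape; `grid_rows * grid_cols` must
#'   equal `length(tiles)`.
#' @param pixel_size_um Calibration attached to the coordinate map.
#' @return List with `mosaic` (matrix), `layout` (tibble: tile, grid row and
#'   column, pixel offsets) and `pixel_size_um`.
#' @export
assemble_mosaic <- function(tiles, grid_rows, grid_cols,
                            pixel_size_um = 0.19) {
  if (length(tiles) != grid_rows * grid_cols) {
    abort("grid shape does not match the number of tiles.")
  }
  dims <- unique(lapply(tiles, dim))
  if (length(dims) != 1) abort("ragged tile grid: tiles differ in size.")
  th <- dims[[1]][1]; tw <- dims[[1]][2]
  mosaic <- matrix(0, grid_rows * th, grid_cols * tw)
  layout <- vector("list", length(tiles))
  k <- 0L
  for (r in seq_len(grid_rows)) {
    for (c in seq_len(grid_cols)) {
      k <- k + 1L
      rows <- (r - 1L) * th + seq_len(th)
      cols <- (c - 1L) * tw + seq_len(tw)
      mosaic[rows, cols] <- tiles[[k]]
      layout[[k]] <- tibble(tile = k, grid_row = r, grid_col = c,
                            offset_row = (r - 1L) * th,
                            offset_col = (c - 1L) * tw)
    }
  }
  list(mosaic = mosaic, layout = dplyr::bind_rows(layout),
       pixel_size_um = pixel_size_um)
}

#' Convert mosaic pixel indices to physical coordinates
#'
#' Pixel `(row, col)` (1-based) is centred at
#' `x = (col - 0.5) * pixel_size_um`, `y = (row - 0.5) * pixel_size_um`.
#'
#' @param row,col Pixel indices (vectors).
#' @param pixel_size_um Calibration.
#' @return Tibble with `x_um`, `y_um`.
#' @export
pixel_to_um <- function(row, col, pixel_size_um) {
  tibble(x_um = (col - 0.5) * pixel_size_um,
         y_um = (row - 0.5) * pixel_size_um)
}

#' @rdname pixel_to_um
#' @param x_um,y_um Physical coordinates.
#' @return For [um_to_pixel()]: tibble with 1-based `row`, `col`.
#' @export
um_to_pixel <- function(x_um, y_um, pixel_size_um) {
  tibble(row = ceiling(y_um / pixel_size_um),
         col = ceiling(x_um / pixel_size_um))
}
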