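# Shared fixtures: small rendered tiles and a brute-force convex hull
# oracle kept deliberately independent of the package implementation.

# Render one generated cell into a square tile with flat background.
render_cell_tile <- function(cell, dim_px = 530L, background = 0.08) {
  img <- matrix(0, dim_px, dim_px)
  p <- cell$patch
  rows <- p$row0:(p$row0 + nrow(p$img) - 1L)
  cols <- p$col0:(p$col0 + ncol(p$img) - 1L)
  keep_r <- rows >= 1 & rows <= dim_px
  keep_c <- cols >= 1 & cols <= dim_px
  img[rows[keep_r], cols[keep_c]] <- p$img[keep_r, keep_c, drop = FALSE]
  img + background
}

# O(n^3) convex hull area: an edge (i, j) lies on the hull iff every other
# point sits on one side; hull vertices are chained and the polygon area
# taken by the shoelace formula. Independent of grDevices::chull.
brute_force_hull_area <- function(xy) {
  xy <- unique(round(xy, 12))
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- xy[j, ] - xy[i, ]
      cross <- (xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1]
      if (all(cross <= 1e-12)) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  if (length(edges) < 3) return(0)
  em <- do.call(rbind, edges)
  # chain the edges into a cycle
  start <- em[1, 1]
  verts <- c(start, em[1, 2])
  while (tail(verts, 1) != start && length(verts) <= n + 1) {
    nxt <- em[em[, 1] == tail(verts, 1), 2]
    verts <- c(verts, nxt[1])
  }
  verts <- verts[-length(verts)]
  poly <- xy[verts, , drop = FALSE]
  m <- nrow(poly)
  jdx <- c(m, seq_len(m - 1))
  abs(sum(poly[jdx, 1] * poly[, 2] - poly[, 1] * poly[jdx, 2])) / 2
}

# Draw a filled disc mask (pixel centre inside radius).
disc_mask <- function(dim_px, centre, radius) {
  rc <- expand.grid(r = seq_len(dim_px), c = seq_len(dim_px))
  m <- matrix(FALSE, dim_px, dim_px)
  m[as.matrix(rc[, c("r", "c")])] <-
    (rc$r - centre[1])^2 + (rc$c - centre[2])^2 <= radius^2
  m
}
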