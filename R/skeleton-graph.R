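# Skeleton-graph construction: from a one-pixel skeleton raster to a
# geometric graph with junction/endpoint nodes and polyline edges.

OFFS <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),       # orthogonal first
              c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))

build_skeleton_graph <- function(skel, pixel_size_um, params) {
  nr <- nrow(skel); nc <- ncol(skel)
  nb <- cpp_neighbour_count(skel)
  skel[nb == 0L] <- FALSE

  node_mask <- skel & nb != 2L
  node_idx <- which(node_mask)
  if (length(node_idx) == 0L) {
    return(empty_skeleton_graph(skel, pixel_size_um))
  }
  node_r <- (node_idx - 1L) %% nr + 1L
  node_c <- (node_idx - 1L) %/% nr + 1L

  # cluster node pixels by 8-adjacency
  key <- function(r, c) (c - 1L) * nr + r
  id_of <- integer(nr * nc)
  id_of[node_idx] <- seq_along(node_idx)
  adj <- list()
  for (o in seq_len(nrow(OFFS))) {
    rr <- node_r + OFFS[o, 1]; cc <- node_c + OFFS[o, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    j <- id_of[key(rr[ok], cc[ok])]
    i <- seq_along(node_idx)[ok]
    hit <- j > 0L
    if (any(hit)) adj[[length(adj) + 1L]] <- cbind(i[hit], j[hit])
  }
  gg <- igraph::graph_from_edgelist(
    if (length(adj)) unique(do.call(rbind, adj)) else
      matrix(integer(0), ncol = 2), directed = FALSE)
  gg <- igraph::add_vertices(gg,
                             max(0L, length(node_idx) - igraph::vcount(gg)))
  memb <- as.integer(igraph::components(gg)$membership)

  n_clust <- max(memb)
  cluster_px <- split(data.frame(r = node_r, c = node_c), memb)
  names(cluster_px) <- NULL
  cid_mat <- matrix(0L, nr, nc)
  cid_mat[node_idx] <- memb

  traced <- cpp_trace_edges(skel, cid_mat, n_clust)
  if (nrow(traced$synthetic) > 0) {
    for (k in seq_len(nrow(traced$synthetic))) {
      cluster_px[[traced$synthetic[k, 1]]] <-
        data.frame(r = traced$synthetic[k, 2], c = traced$synthetic[k, 3])
    }
  }
  e_pts <- traced$pts
  e_len <- vapply(e_pts, function(p) {
    steps <- diff(p)
    sum(sqrt(rowSums(steps^2))) * pixel_size_um
  }, numeric(1))

  simplify_graph(traced$a, traced$b, e_len, e_pts, cluster_px, skel,
                 pixel_size_um, params)
}

empty_skeleton_graph <- function(skel, pixel_size_um) {
  structure(list(
    nodes = tibble(node_id = integer(), x_um = numeric(), y_um = numeric(),
                   degree = integer(), kind = character()),
    edges = tibble(edge_id = integer(), node_a = integer(),
                   node_b = integer(), length_um = numeric(), pts = list()),
    skeleton = skel, pixel_size_um = pixel_size_um),
    class = "skeleton_graph")
}

# Contract short junction-junction edges, prune short spurs, dissolve
# degree-2 nodes, and emit the tidy node/edge tables.
simplify_graph <- function(e_a, e_b, e_len, e_pts, cluster_px, skel,
                           pixel_size_um, params) {
  n_clust <- length(cluster_px)
  parent <- seq_len(n_clust)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  alive <- rep(TRUE, length(e_a))

  degree_of <- function() {
    ends <- c(vapply(e_a[alive], find, 1L), vapply(e_b[alive], find, 1L))
    tabulate(ends, n_clust)
  }

  # Iterate the cleanup moves to a fixpoint: each move can expose work for
  # the others (a contraction can create a self-loop, a pruned spur can
  # leave a degree-2 node whose dissolution reunites a split stroke).
  for (sweep in 1:12) {
    changed <- FALSE

    # contract very short edges incident to a junction: junction pairs
    # closer than the merge radius are one branch point split by thinning,
    # and sub-radius stubs hanging off a junction are digitisation debris
    if (any(alive)) {
      deg <- degree_of()
      for (e in which(alive)) {
        a <- find(e_a[e]); b <- find(e_b[e])
        if (a != b && e_len[e] < params$junction_merge_um &&
            (deg[a] >= 3L || deg[b] >= 3L)) {
          parent[b] <- a
          alive[e] <- FALSE
          changed <- TRUE
        }
      }
    }

    # drop tiny self-loops at junctions (thinning can leave a 2-3 px ring
    # where sibling strokes overlap); isolated rings are real short
    # processes and are kept
    if (any(alive)) {
      deg <- degree_of()
      for (e in which(alive)) {
        a <- find(e_a[e]); b <- find(e_b[e])
        if (a == b && e_len[e] < 2 && deg[a] > 2L) {
          alive[e] <- FALSE
          changed <- TRUE
        }
      }
    }

    # prune short spurs: a short edge hanging off a junction with a free
    # end. Isolated edges (both ends free) are real short processes,
    # never spurs, so they are kept whatever their length.
    if (any(alive)) {
      deg <- degree_of()
      da <- deg[vapply(e_a, find, 1L)]; db <- deg[vapply(e_b, find, 1L)]
      spur <- alive & e_len < params$spur_min_length_um &
        ((da == 1L & db >= 3L) | (db == 1L & da >= 3L))
      spur[vapply(e_a, find, 1L) == vapply(e_b, find, 1L)] <- FALSE
      if (any(spur)) {
        alive[spur] <- FALSE
        changed <- TRUE
      }
    }

    # dissolve degree-2 clusters left over by pruning/merging
    repeat {
      deg <- degree_of()
      ra <- vapply(e_a, find, 1L); rb <- vapply(e_b, find, 1L)
      mid <- which(deg == 2L)
      done <- TRUE
      for (m in mid) {
        es <- which(alive & (ra == m | rb == m))
        if (length(es) != 2L) next      # a loop at m, leave it
        e1 <- es[1]; e2 <- es[2]
        p1 <- e_pts[[e1]]; if (ra[e1] == m) { p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE] }
        p2 <- e_pts[[e2]]; if (rb[e2] == m) { p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE] }
        gap <- sqrt(sum((p2[1, ] - p1[nrow(p1), ])^2)) * pixel_size_um
        e_pts[[e1]] <- rbind(p1, p2)
        e_len[e1] <- e_len[e1] + e_len[e2] + gap
        e_a[e1] <- if (ra[e1] == m) rb[e1] else ra[e1]
        e_b[e1] <- if (ra[e2] == m) rb[e2] else ra[e2]
        alive[e2] <- FALSE
        done <- FALSE
        changed <- TRUE
        break
      }
      if (done) break
    }

    if (!changed) break
  }

  keep <- which(alive)
  ra <- vapply(e_a[keep], find, 1L)
  rb <- vapply(e_b[keep], find, 1L)
  roots <- sort(unique(c(ra, rb)))
  remap <- integer(n_clust)
  remap[roots] <- seq_along(roots)

  # node positions: centroid over all member pixels of the merged cluster
  members <- split(seq_len(n_clust), vapply(seq_len(n_clust), find, 1L))
  node_xy <- t(vapply(roots, function(rt) {
    px <- do.call(rbind, cluster_px[members[[as.character(rt)]]])
    c(mean((px$c - 0.5)) * pixel_size_um, mean((px$r - 0.5)) * pixel_size_um,
      mean(px$r), mean(px$c))
  }, numeric(4)))

  deg <- tabulate(c(remap[ra], remap[rb]), length(roots))
  nodes <- tibble(
    node_id = seq_along(roots),
    x_um = node_xy[, 1], y_um = node_xy[, 2],
    row = node_xy[, 3], col = node_xy[, 4],
    degree = deg,
    kind = dplyr::case_when(deg == 1L ~ "endpoint",
                            deg >= 3L ~ "junction",
                            TRUE ~ "link"))
  edges <- tibble(
    edge_id = seq_along(keep),
    node_a = remap[ra], node_b = remap[rb],
    length_um = e_len[keep],
    pts = e_pts[keep])

  structure(list(nodes = nodes, edges = edges, skeleton = skel,
                 pixel_size_um = pixel_size_um),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes (%d junctions), %d edges, %.3g um/px\n",
              nrow(x$nodes), sum(x$nodes$kind == "junction"),
              nrow(x$edges), x$pixel_size_um))
  invisible(x)
}

#' Attribute skeleton components to detected cell bodies
#'
#' Every connected skeleton component whose closest node lies within the
#' attribution gap of a soma contour (over and above the guard band carved
#' around somata before thinning) is rooted at that soma. Components
#' reachable from no soma are returned as unattributed; a component
#' touching several somata is split along the skeleton, each edge going to
#' the soma with the shorter along-skeleton path.
#'
#' @param graph A [extract_process_skeleton()] result.
#' @param bodies The matching [detect_cell_bodies()] result.
#' @param params A [segmentation_params()].
#' @return Object of class `process_forest`: list with `trees` (one entry
#'   per owning body: `body_id`, `root_nodes`, `edges` tibble) and
#'   `unattributed_edges`.
#' @export
assign_processes_to_cells <- function(graph, bodies,
                                      params = segmentation_params()) {
  stopifnot(inherits(graph, "skeleton_graph"),
            inherits(bodies, "body_detection"))
  s <- graph$pixel_size_um
  lab <- bodies$label_mask
  nr <- nrow(lab); nc <- ncol(lab)
  gap_px <- (params$attribution_max_gap_um + params$body_detach_um) / s + 2

  nodes <- graph$nodes
  edges <- graph$edges
  if (nrow(edges) == 0L) {
    return(structure(list(trees = list(),
                          unattributed_edges = edges,
                          graph = graph),
                     class = "process_forest"))
  }

  # nearest body label within the gap, per node
  w <- as.integer(ceiling(gap_px))
  node_body <- integer(nrow(nodes))
  node_body_d <- rep(Inf, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    r0 <- max(1L, as.integer(round(nodes$row[i])) - w)
    r1 <- min(nr, as.integer(round(nodes$row[i])) + w)
    c0 <- max(1L, as.integer(round(nodes$col[i])) - w)
    c1 <- min(nc, as.integer(round(nodes$col[i])) + w)
    sub <- lab[r0:r1, c0:c1, drop = FALSE]
    nz <- which(sub > 0L)
    if (length(nz) == 0L) next
    rr <- (nz - 1L) %% nrow(sub) + r0
    cc <- (nz - 1L) %/% nrow(sub) + c0
    d2 <- (rr - nodes$row[i])^2 + (cc - nodes$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= gap_px^2) {
      node_body[i] <- sub[nz[j]]
      node_body_d[i] <- sqrt(d2[j])
    }
  }

  ig <- igraph::graph_from_data_frame(
    data.frame(from = edges$node_a, to = edges$node_b,
               weight = pmax(edges$length_um, 1e-9)),
    directed = FALSE,
    vertices = data.frame(name = nodes$node_id))
  comp <- igraph::components(ig)$membership
  comp <- comp[as.character(nodes$node_id)]

  edge_comp <- comp[edges$node_a]
  trees <- list()
  unattributed <- rep(TRUE, nrow(edges))

  for (cm in unique(comp)) {
    nodes_cm <- which(comp == cm)
    roots_cm <- nodes_cm[node_body[nodes_cm] > 0L]
    if (length(roots_cm) == 0L) next
    bodies_cm <- sort(unique(node_body[roots_cm]))
    e_idx <- which(edge_comp == cm)
    if (length(bodies_cm) == 1L) {
      owner <- rep(bodies_cm, length(e_idx))
    } else {
      dmat <- vapply(bodies_cm, function(b) {
        rs <- roots_cm[node_body[roots_cm] == b]
        d <- igraph::distances(ig, v = as.character(rs),
                               to = as.character(nodes$node_id))
        apply(d, 2, min)
      }, numeric(nrow(nodes)))
      d_edge <- vapply(seq_along(bodies_cm), function(k) {
        pmin(dmat[edges$node_a[e_idx], k], dmat[edges$node_b[e_idx], k])
      }, numeric(length(e_idx)))
      owner <- bodies_cm[max.col(-d_edge, ties.method = "first")]
    }
    unattributed[e_idx] <- FALSE
    for (b in unique(owner)) {
      bkey <- as.character(b)
      sel <- e_idx[owner == b]
      tr <- trees[[bkey]]
      if (is.null(tr)) {
        tr <- list(body_id = b, root_nodes = integer(0),
                   edges = edges[integer(0), ])
      }
      tr$root_nodes <- union(tr$root_nodes,
                             roots_cm[node_body[roots_cm] == b])
      tr$edges <- dplyr::bind_rows(tr$edges, edges[sel, ])
      trees[[bkey]] <- tr
    }
  }

  structure(list(trees = trees,
                 unattributed_edges = edges[unattributed, ],
                 graph = graph),
            class = "process_forest")
}

#' Label branch orders of a rooted process tree
#'
#' Segments incident to the soma (root nodes) are order 1; the order
#' increments at every junction crossed walking away from the soma. Orders
#' of 3 and deeper are folded into the tertiary count, matching the
#' three-order reporting convention.
#'
#' @param tree One element of a [assign_processes_to_cells()] `trees` list.
#' @return The tree with a `branch_order` column added to `edges` and an
#'   attached `counts` element: `n_primary`, `n_secondary`, `n_tertiary`,
#'   `n_segments`.
#' @export
order_branches <- function(tree) {
  if (is.null(tree$root_nodes) || length(tree$root_nodes) == 0L) {
    abort("cannot order branches of an unrooted (unattributed) tree.")
  }
  ed <- tree$edges
  n_e <- nrow(ed)
  order_e <- rep(NA_integer_, n_e)

  # BFS over edges, starting at all roots with order 1
  frontier <- lapply(tree$root_nodes, function(r) list(node = r, ord = 1L))
  while (length(frontier) > 0L) {
    f <- frontier[[1L]]; frontier[[1L]] <- NULL
    inc <- which(is.na(order_e) & (ed$node_a == f$node | ed$node_b == f$node))
    for (e in inc) {
      if (!is.na(order_e[e])) next
      order_e[e] <- f$ord
      far <- if (ed$node_a[e] == f$node) ed$node_b[e] else ed$node_a[e]
      frontier[[length(frontier) + 1L]] <- list(node = far, ord = f$ord + 1L)
    }
  }
  order_e[is.na(order_e)] <- 1L   # disconnected remnants: treat as primary
  tree$edges$branch_order <- order_e
  tree$counts <- list(n_primary = sum(order_e == 1L),
                      n_secondary = sum(order_e == 2L),
                      n_tertiary = sum(order_e >= 3L),
                      n_segments = n_e)
  tree
}
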