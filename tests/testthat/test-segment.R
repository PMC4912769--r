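params <- segmentation_params()

test_that("a blank field yields no bodies and no skeleton", {
  blank <- matrix(0.08, 200, 200)
  bod <- detect_cell_bodies(blank, params, 0.19)
  expect_equal(nrow(bod$bodies), 0)
  g <- extract_process_skeleton(blank, bod, params)
  expect_equal(nrow(g$edges), 0)
})

test_that("a bare disc gives one body, accurate area, and zero processes", {
  img <- matrix(0.08, 300, 300)
  d <- disc_mask(300, c(150, 150), 20)       # radius 20 px = 3.8 um
  img[d] <- 0.9
  bod <- detect_cell_bodies(img, params, 0.19)
  expect_equal(nrow(bod$bodies), 1)
  true_area <- pi * (20 * 0.19)^2
  expect_lt(abs(bod$bodies$body_area_um2 - true_area) / true_area, 0.1)
  expect_lt(abs(bod$bodies$centroid_x_um - 149.5 * 0.19), 0.4)
  expect_gt(bod$bodies$roundness, 0.9)
  g <- extract_process_skeleton(img, bod, params)
  f <- assign_processes_to_cells(g, bod, params)
  expect_length(f$trees, 0)
})

test_that("straight unbranched processes are recovered with true lengths", {
  # one soma with three straight 20 um processes at wide angles
  img <- matrix(0, 600, 600)
  ctr <- c(300, 300)
  img <- micromorph:::cpp_stamp_polyline(img, matrix(ctr, ncol = 2),
                                         3 / 0.19, 0.85)
  for (ang in c(0, 2.2, 4.2)) {
    pts <- cbind(ctr[1] + seq(0, 20 / 0.19, by = 2) * sin(ang),
                 ctr[2] + seq(0, 20 / 0.19, by = 2) * cos(ang))
    img <- micromorph:::cpp_stamp_polyline(img, pts, 0.25 / 0.19, 0.55)
  }
  img <- img + 0.08
  rec <- quantify_projection(img, params, 0.19)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_primary, 3L)
  expect_equal(rec$n_segments, 3L)
  expect_equal(rec$CI, 1)
  bod <- detect_cell_bodies(img, params, 0.19)
  g <- extract_process_skeleton(img, bod, params)
  f <- assign_processes_to_cells(g, bod, params)
  tr <- f$trees[[1]]
  # measured from the soma guard band to the tip: 20 um from the soma
  # surface, within a micrometre
  expect_true(all(abs(tr$edges$length_um -
                        (20 - 3 - params$body_detach_um)) < 1.5))
})

test_that("a Y-shaped process yields one junction and three segments", {
  img <- matrix(0, 500, 500)
  ctr <- c(250, 150)
  img <- micromorph:::cpp_stamp_polyline(img, matrix(ctr, ncol = 2),
                                         3 / 0.19, 0.85)
  stem <- cbind(rep(250, 60), seq(150, 268, by = 2))
  img <- micromorph:::cpp_stamp_polyline(img, stem, 1.4, 0.55)
  for (s in c(-1, 1)) {
    arm <- cbind(250 + s * seq(0, 60, by = 2), seq(268, 328, by = 2))
    img <- micromorph:::cpp_stamp_polyline(img, arm, 1.4, 0.55)
  }
  img <- img + 0.08
  rec <- quantify_projection(img, params, 0.19)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$n_primary, 1L)
  expect_equal(rec$n_secondary, 2L)
  expect_equal(rec$n_segments, 3L)
  expect_equal(rec$CI, 3)
})

test_that("rendered archetype cells reproduce ground-truth branch counts", {
  ap <- archetype_presets()
  for (nm in c("ramified_lowCI_lowCEA", "ramified_highCI_highCEA",
               "amoeboid")) {
    for (seed in 301:303) {
      cl <- generate_cell(ap[[nm]], seed = seed, centroid_um = c(50, 50))
      img <- render_cell_tile(cl)
      rec <- quantify_projection(img, params, 0.19)
      expect_equal(nrow(rec), 1)
      tr <- cl$truth
      expect_equal(rec$n_primary, tr$true_n_primary)
      expect_equal(rec$n_secondary, tr$true_n_secondary)
      expect_equal(rec$n_tertiary, tr$true_n_tertiary)
      expect_equal(rec$n_segments, tr$true_n_segments)
      expect_equal(rec$CI, tr$true_CI)
      # geometric criteria land near their analytic truths
      expect_lt(abs(rec$body_area_um2 - tr$true_body_area_um2) /
                  tr$true_body_area_um2, 0.1)
      if (tr$true_CEA_um2 > 0) {
        expect_lt(abs(rec$CEA_um2 - tr$true_CEA_um2) / tr$true_CEA_um2, 0.1)
      }
      expect_lt(abs(rec$cytoplasm_area_um2 - tr$true_cytoplasm_area_um2) /
                  tr$true_cytoplasm_area_um2, 0.15)
    }
  }
})

test_that("branch counts are invariant under image rotation", {
  cl <- generate_cell(archetype_presets()$ramified_lowCI_highCEA,
                      seed = 77, centroid_um = c(50, 50))
  img <- render_cell_tile(cl)
  r0 <- quantify_projection(img, params, 0.19)
  rot <- t(img)[ncol(img):1, ]              # 90 degree rotation
  r90 <- quantify_projection(rot, params, 0.19)
  expect_equal(r90$n_primary, r0$n_primary)
  expect_equal(r90$n_secondary, r0$n_secondary)
  expect_equal(r90$n_tertiary, r0$n_tertiary)
  expect_equal(r90$n_segments, r0$n_segments)
})

test_that("two-cell tiles attribute arbors to the right somata", {
  ap <- archetype_presets()
  c1 <- generate_cell(ap$ramified_lowCI_lowCEA, seed = 5,
                      centroid_um = c(45, 45))
  c2 <- generate_cell(ap$ramified_highCI_lowCEA, seed = 6,
                      centroid_um = c(125, 125))
  img <- matrix(0, 900, 900)
  for (cl in list(c1, c2)) {
    p <- cl$patch
    rows <- p$row0:(p$row0 + nrow(p$img) - 1L)
    cols <- p$col0:(p$col0 + ncol(p$img) - 1L)
    img[rows, cols] <- pmax(img[rows, cols], p$img)
  }
  img <- img + 0.08
  rec <- quantify_projection(img, params, 0.19)
  expect_equal(nrow(rec), 2)
  rec <- rec[order(rec$centroid_x_um), ]
  expect_equal(rec$n_segments[1], c1$truth$true_n_segments)
  expect_equal(rec$n_segments[2], c2$truth$true_n_segments)

  # conservation: every skeleton edge is either owned or unattributed
  bod <- detect_cell_bodies(img, params, 0.19)
  g <- extract_process_skeleton(img, bod, params)
  f <- assign_processes_to_cells(g, bod, params)
  owned <- sum(vapply(f$trees, function(t) nrow(t$edges), 1L))
  expect_equal(owned + nrow(f$unattributed_edges), nrow(g$edges))
})

test_that("distant skeleton components are flagged unattributed", {
  img <- matrix(0, 400, 400)
  img <- micromorph:::cpp_stamp_polyline(img, matrix(c(100, 100), ncol = 2),
                                         3 / 0.19, 0.85)
  # a free-floating fibre 30 um away from the soma
  fibre <- cbind(seq(300, 380, by = 2), seq(100, 180, by = 2))
  img <- micromorph:::cpp_stamp_polyline(img, fibre, 1.4, 0.55)
  img <- img + 0.08
  bod <- detect_cell_bodies(img, params, 0.19)
  g <- extract_process_skeleton(img, bod, params)
  f <- assign_processes_to_cells(g, bod, params)
  expect_length(f$trees, 0)
  expect_gt(nrow(f$unattributed_edges), 0)
  expect_error(order_branches(list(root_nodes = integer(0),
                                   edges = f$unattributed_edges)),
               "unrooted")
})

test_that("branch ordering follows the topology contract", {
  # hand-built tree: root -- j1, with two children, one of which branches
  edges <- tibble::tibble(
    edge_id = 1:5,
    node_a = c(1L, 2L, 2L, 4L, 4L),
    node_b = c(2L, 3L, 4L, 5L, 6L),
    length_um = rep(5, 5),
    pts = replicate(5, matrix(0, 2, 2), simplify = FALSE))
  tr <- order_branches(list(body_id = 1L, root_nodes = 1L, edges = edges))
  expect_equal(tr$edges$branch_order, c(1L, 2L, 2L, 3L, 3L))
  expect_equal(unlist(tr$counts),
               c(n_primary = 1L, n_secondary = 2L, n_tertiary = 2L,
                 n_segments = 5L))
})
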