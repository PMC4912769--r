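base_record <- function(body_area = 100, roundness = 0.9, x = 500, y = 500,
                        sv = 0L, id = "c1", endpoints = NULL) {
  tibble::tibble(cell_id = id, body_area_um2 = body_area,
                 roundness = roundness, centroid_x_um = x,
                 centroid_y_um = y, subvolume_index = sv,
                 endpoints_um = list(endpoints))
}

test_that("size and roundness outliers are rejected with reasons, bounds kept", {
  rec <- dplyr::bind_rows(
    base_record(9.9, 0.9, id = "small"),
    base_record(600, 0.9, id = "large"),
    base_record(100, 0.65, id = "flat"),
    base_record(10, 0.9, id = "at_min"),       # exactly 10: kept
    base_record(500, 0.9, id = "at_max"),      # exactly 500: kept
    base_record(100, 0.7, id = "at_round"),    # exactly 0.7: kept
    base_record(100, 0.9, id = "ok"))
  f <- filter_outliers(rec, filter_config())
  expect_setequal(f$kept$cell_id, c("at_min", "at_max", "at_round", "ok"))
  expect_equal(
    f$rejected$reject_reason[match(c("small", "large", "flat"),
                                   f$rejected$cell_id)],
    c("too_small", "too_large", "low_roundness"))
  # partition: kept and rejected tile the input
  expect_setequal(c(f$kept$cell_id, f$rejected$cell_id), rec$cell_id)
  # idempotence
  f2 <- filter_outliers(f$kept, filter_config())
  expect_equal(nrow(f2$rejected), 0)
  expect_equal(f2$kept, f$kept)
})

test_that("cells whose hull or soma touches the mosaic border are removed", {
  inner <- base_record(100, 0.9, x = 500, y = 500, id = "inner",
                       endpoints = rbind(c(480, 480), c(520, 520)))
  left <- base_record(100, 0.9, x = 30, y = 500, id = "left_clipped",
                      endpoints = rbind(c(-2, 500), c(60, 520)))
  soma_edge <- base_record(3000, 0.9, x = 10, y = 500, id = "soma_on_edge")
  rec <- dplyr::bind_rows(inner, left, soma_edge)
  kept <- remove_edge_cells(rec, 1000, 1000, filter_config())
  expect_equal(kept$cell_id, "inner")
  # a wider margin removes cells near, not just on, the border
  near <- base_record(100, 0.9, x = 18, y = 500, id = "near",
                      endpoints = rbind(c(12, 495), c(25, 505)))
  kept2 <- remove_edge_cells(dplyr::bind_rows(inner, near), 1000, 1000,
                             filter_config(edge_margin_um = 15))
  expect_equal(kept2$cell_id, "inner")
})

test_that("planted border-clipped cells are exactly the ones removed", {
  withr::with_seed(31, {
    w <- 800
    inner <- lapply(1:20, function(i) {
      x <- runif(1, 120, w - 120); y <- runif(1, 120, w - 120)
      base_record(100, .9, x, y, id = sprintf("in_%02d", i),
                  endpoints = cbind(x + runif(6, -30, 30),
                                    y + runif(6, -30, 30)))
    })
    clipped <- lapply(1:10, function(i) {
      x <- runif(1, 0, 25); y <- runif(1, 100, w - 100)
      # one extremity always beyond the left border: truly truncated
      base_record(100, .9, x, y, id = sprintf("clip_%02d", i),
                  endpoints = cbind(c(x - 30, x + runif(5, -20, 30)),
                                    y + runif(6, -30, 30)))
    })
    rec <- dplyr::bind_rows(c(inner, clipped))
    kept <- remove_edge_cells(rec, w, w, filter_config())
    expect_setequal(kept$cell_id, sprintf("in_%02d", 1:20))
  })
})

test_that("adjacent sub-volume duplicates merge, non-adjacent pairs survive", {
  rec <- dplyr::bind_rows(
    base_record(100, .9, 200, 200, sv = 0L, id = "a0"),
    base_record(120, .9, 201, 200, sv = 1L, id = "a1"),   # dup of a0, bigger
    base_record(100, .9, 400, 400, sv = 0L, id = "b0"),
    base_record(100, .9, 400, 401, sv = 2L, id = "b2"),   # non-adjacent
    base_record(100, .9, 600, 600, sv = 0L, id = "c0"),
    base_record(100, .9, 660, 600, sv = 1L, id = "c1"))   # 60 um apart
  out <- deduplicate_across_subvolumes(rec, filter_config())
  expect_setequal(out$cell_id, c("a1", "b0", "b2", "c0", "c1"))

  # tie on body area: the lower sub-volume index wins
  tie <- dplyr::bind_rows(
    base_record(100, .9, 200, 200, sv = 1L, id = "hi"),
    base_record(100, .9, 200, 201, sv = 0L, id = "lo"))
  out2 <- deduplicate_across_subvolumes(tie, filter_config())
  expect_equal(out2$cell_id, "lo")

  # no adjacent pair within the radius remains (exhaustive scan)
  pairs_left <- which(
    outer(out$subvolume_index, out$subvolume_index,
          function(a, b) abs(a - b) == 1) &
    outer(seq_len(nrow(out)), seq_len(nrow(out)), "<") &
    as.matrix(dist(cbind(out$centroid_x_um, out$centroid_y_um))) <= 5)
  expect_length(pairs_left, 0)
})

test_that("the full filter logs counts per stage", {
  rec <- dplyr::bind_rows(
    base_record(100, .9, 500, 500, id = "keep"),
    base_record(5, .9, 400, 400, id = "small"),
    base_record(100, .9, 2, 500, id = "edge"))
  res <- apply_population_filter(rec, 1000, 1000, filter_config())
  expect_equal(res$kept$cell_id, "keep")
  expect_equal(res$log$n_cells, c(3L, 2L, 1L, 1L))
})
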