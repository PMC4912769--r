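test_that("amoeboid cells have complexity index 1 and no branches", {
  am <- archetype_presets()$amoeboid
  for (s in 1:5) {
    cl <- generate_cell(am, seed = s, detail = "tree")
    expect_equal(cl$truth$true_CI, 1)
    expect_equal(cl$truth$true_n_secondary, 0L)
    expect_equal(cl$truth$true_n_segments, cl$truth$true_n_primary)
  }
})

test_that("a single forced bifurcation yields three segments and CI 3", {
  arch <- cell_archetype("forced", body_radius_um = 2.8, n_primary = 1L,
                         branch_prob_per_order = c(1, 0),
                         mean_segment_length_um = 8,
                         segment_length_sd_um = 1, max_order = 2L)
  cl <- generate_cell(arch, seed = 2, detail = "tree")
  expect_equal(cl$truth$true_n_segments, 3L)
  expect_equal(cl$truth$true_n_primary, 1L)
  expect_equal(cl$truth$true_CI, 3)
})

test_that("generation is deterministic per seed and detail level", {
  arch <- archetype_presets()$ramified_highCI_highCEA
  a <- generate_cell(arch, seed = 7)
  b <- generate_cell(arch, seed = 7)
  expect_identical(a$truth$segments[[1]], b$truth$segments[[1]])
  expect_identical(a$patch$img, b$patch$img)
  c_ <- generate_cell(arch, seed = 8)
  expect_false(identical(a$truth$true_n_segments, c_$truth$true_n_segments) &&
               identical(a$truth$true_CEA_um2, c_$truth$true_CEA_um2))
})

test_that("stored truth is self-consistent with a brute-force recount", {
  for (nm in names(archetype_presets())) {
    cl <- generate_cell(archetype_presets()[[nm]], seed = 13,
                        detail = "tree")
    tr <- cl$truth
    seg <- tr$segments[[1]]
    # recount orders and segments directly from the parent pointers
    depth <- integer(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      d <- 1L; p <- seg$parent_id[i]
      while (p != 0L) { d <- d + 1L; p <- seg$parent_id[seg$seg_id == p] }
      depth[i] <- d
    }
    expect_equal(sum(depth == 1), tr$true_n_primary)
    expect_equal(sum(depth == 2), tr$true_n_secondary)
    expect_equal(sum(depth >= 3), tr$true_n_tertiary)
    expect_equal(nrow(seg), tr$true_n_segments)
    expect_equal(tr$true_CI, nrow(seg) / sum(depth == 1))
    # CEA equals the brute-force hull area of the stored endpoints
    expect_lt(abs(tr$true_CEA_um2 -
                    brute_force_hull_area(tr$endpoints_um[[1]])),
              1e-9 * max(1, tr$true_CEA_um2))
    # endpoints are exactly the ends of terminal segments
    expect_equal(nrow(tr$endpoints_um[[1]]), sum(seg$terminal))
  }
})

test_that("rendered patches contain one connected component above background", {
  for (nm in c("ramified_lowCI_lowCEA", "amoeboid")) {
    cl <- generate_cell(archetype_presets()[[nm]], seed = 3)
    m <- cl$patch$img > 0.1
    lab <- EBImage::bwlabel(EBImage::Image(m * 1))
    expect_equal(max(lab), 1)
  }
})

test_that("tissue generation places, renders and reproduces cells", {
  spec <- tissue_spec(width_px = 1200L, height_px = 1200L, n_planes = 3L,
                      n_cells = 4L, min_cell_spacing_um = 50,
                      placement_margin_um = 40, noise_sd = 0.02, seed = 42)
  t1 <- generate_tissue(spec)
  t2 <- generate_tissue(spec)
  expect_equal(nrow(t1$truth), 4)
  expect_identical(t1$truth$true_CEA_um2, t2$truth$true_CEA_um2)
  expect_identical(t1$stack$planes, t2$stack$planes)
  # pairwise spacing respected
  d <- dist(cbind(t1$truth$centroid_x_um, t1$truth$centroid_y_um))
  expect_gte(min(d), 50)

  # empty tissue: background only, empty truth
  spec0 <- tissue_spec(width_px = 300L, height_px = 300L, n_planes = 3L,
                       n_cells = 0L, noise_sd = 0, seed = 1)
  t0 <- generate_tissue(spec0)
  expect_equal(nrow(t0$truth), 0)
  expect_true(all(vapply(t0$stack$planes,
                         function(p) all(p == 0.08), TRUE)))

  # an impossible packing names the achievable count
  spec_bad <- tissue_spec(width_px = 500L, height_px = 500L, n_planes = 3L,
                          n_cells = 50L, min_cell_spacing_um = 60,
                          placement_margin_um = 10, seed = 1)
  expect_error(generate_tissue(spec_bad), "could only place")
})

test_that("an all-amoeboid mixture yields only CI = 1 truth", {
  spec <- tissue_spec(width_px = 1500L, height_px = 1500L, n_planes = 3L,
                      n_cells = 8L, archetype_mix = c(0, 0, 0, 0, 1),
                      min_cell_spacing_um = 60, placement_margin_um = 30,
                      seed = 5)
  tt <- generate_tissue(spec)
  expect_true(all(tt$truth$true_CI == 1))
})

test_that("cohort treatment scales cytoplasm and regions order CEA", {
  co <- generate_cohort(n_control = 7, n_treated = 6,
                        cells_per_animal = 60, animal_effect_sd = 0.1,
                        detail = "counts", seed = 19)
  m <- tapply(co$true_cytoplasm_area_um2, co$condition, mean)
  expect_gt(m[["treated"]] / m[["control"]], 1.6)
  expect_lt(m[["treated"]] / m[["control"]], 2.4)

  # a null treatment leaves the two conditions exchangeable
  co0 <- generate_cohort(n_control = 5, n_treated = 5,
                         cells_per_animal = 60,
                         treatment_effect = list(cytoplasm_factor = 1),
                         animal_effect_sd = 0, detail = "counts", seed = 4)
  m0 <- tapply(co0$true_cytoplasm_area_um2, co0$condition, mean)
  expect_lt(abs(m0[["treated"]] / m0[["control"]] - 1), 0.1)

  # cerebellar mixtures carry smaller territories than cortical ones
  reg <- generate_cohort(n_control = 4, n_treated = 1,
                         regions = c("cerebellum", "frontal_cortex"),
                         cells_per_animal = 80, detail = "tree", seed = 11)
  ctrl <- reg[reg$condition == "control", ]
  cea <- tapply(ctrl$true_CEA_um2, ctrl$region, mean, na.rm = TRUE)
  expect_lt(cea[["cerebellum"]], cea[["frontal_cortex"]])
  ci <- tapply(ctrl$true_CI, ctrl$region, mean)
  expect_lt(ci[["cerebellum"]], ci[["frontal_cortex"]])

  expect_error(generate_cohort(regions = "thalamus"), "unknown region")
  expect_error(generate_cohort(n_control = 0), "1 animal")
})

test_that("truth tables convert to the measured-record column contract", {
  tt <- generate_cohort(n_control = 2, n_treated = 1, cells_per_animal = 10,
                        detail = "tree", seed = 2)
  rec <- truth_as_records(tt)
  expect_true(all(c("CI", "CEA_um2", "body_area_um2", "is_amoeboid",
                    "animal_id", "condition") %in% names(rec)))
  expect_equal(rec$CI, tt$true_CI)
  expect_equal(rec$is_amoeboid, tt$true_CI == 1)
})
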