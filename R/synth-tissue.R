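#' Specification of a synthetic tissue mosaic
#'
#' Geometry defaults copy the acquisition setup the pipeline is designed
#' for: 920 x 920 pixel fields at 0.19 um/pixel, 16 focal planes 2 um
#' apart. Cells are placed by rejection sampling under a minimum
#' centre-to-centre spacing so that, at the default spacing, arbors of
#' neighbouring cells never overlap and the ground truth stays unambiguous.
#'
#' @param width_px,height_px Mosaic size in pixels.
#' @param n_planes Number of focal planes.
#' @param pixel_size_um,z_step_um Physical calibration.
#' @param n_cells Number of cells to place.
#' @param archetype_mix Probability vector over `archetypes` (must sum to 1).
#' @param archetypes Named list of [cell_archetype()]s; defaults to
#'   [archetype_presets()].
#' @param background_level,noise_sd Background grey level and additive
#'   Gaussian noise per plane (`[0, 1]` scale). `noise_sd = 0` gives a
#'   noise-free render.
#' @param min_cell_spacing_um Minimum centroid spacing.
#' @param placement_margin_um Keep centroids at least this far from the
#'   mosaic border (set to 0 to allow border-clipped cells).
#' @param seed Integer seed driving the whole tissue.
#' @return Object of class `tissue_spec`.
#' @export
tissue_spec <- function(width_px = 920L, height_px = 920L,
                        n_planes = 16L,
                        pixel_size_um = 0.19, z_step_um = 2,
                        n_cells = 10L,
                        archetype_mix = c(0.25, 0.2, 0.2, 0.25, 0.1),
                        archetypes = archetype_presets(),
                        background_level = 0.08, noise_sd = 0.02,
                        min_cell_spacing_um = 70,
                        placement_margin_um = 36,
                        seed = 1L) {
  if (n_planes < 1) abort("`n_planes` must be >= 1.")
  if (min_cell_spacing_um < 0) abort("`min_cell_spacing_um` must be >= 0.")
  if (length(archetype_mix) != length(archetypes)) {
    abort("`archetype_mix` must have one entry per archetype.")
  }
  if (abs(sum(archetype_mix) - 1) > 1e-8) {
    abort("`archetype_mix` must sum to 1.")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         n_planes = as.integer(n_planes),
         pixel_size_um = pixel_size_um, z_step_um = z_step_um,
         n_cells = as.integer(n_cells),
         archetype_mix = archetype_mix, archetypes = archetypes,
         background_level = background_level, noise_sd = noise_sd,
         min_cell_spacing_um = min_cell_spacing_um,
         placement_margin_um = placement_margin_um,
         seed = as.integer(seed)),
    class = "tissue_spec")
}

#' Generate a synthetic tissue image stack with per-cell ground truth
#'
#' Each cell is assigned to one of three axial sub-volumes and rendered into
#' every focal plane of that sub-volume (so the sub-volume's
#' maximum-intensity projection recovers the cell exactly); plane
#' partitioning matches [split_and_project()]. Additive Gaussian noise and a
#' constant background are applied per plane.
#'
#' @param spec A [tissue_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth` (tibble, one
#'   row per cell including list-columns `endpoints_um` and `segments`).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_spec"))
  with_seed(spec$seed, {
    s <- spec$pixel_size_um
    w_um <- spec$width_px * s
    h_um <- spec$height_px * s
    centroids <- place_centroids(spec$n_cells, w_um, h_um,
                                 spec$min_cell_spacing_um,
                                 spec$placement_margin_um)
    planes <- lapply(seq_len(spec$n_planes),
                     function(i) matrix(0, spec$height_px, spec$width_px))
    n_sub <- min(3L, spec$n_planes)
    part <- subvolume_partition(spec$n_planes, n_sub)

    truths <- vector("list", spec$n_cells)
    if (spec$n_cells > 0) {
      arche_idx <- sample.int(length(spec$archetypes), spec$n_cells,
                              replace = TRUE, prob = spec$archetype_mix)
      subvol <- sample.int(n_sub, spec$n_cells, replace = TRUE) - 1L
      for (i in seq_len(spec$n_cells)) {
        cell <- generate_cell(spec$archetypes[[arche_idx[i]]],
                              centroid_um = centroids[i, ],
                              detail = "raster", pixel_size_um = s)
        truths[[i]] <- dplyr::mutate(cell$truth,
                                     cell_id = sprintf("cell_%04d", i),
                                     subvolume_index = subvol[i],
                                     .before = 1)
        p <- cell$patch
        rows <- p$row0:(p$row0 + nrow(p$img) - 1L)
        cols <- p$col0:(p$col0 + ncol(p$img) - 1L)
        keep_r <- rows >= 1L & rows <= spec$height_px
        keep_c <- cols >= 1L & cols <= spec$width_px
        for (pl in which(part == subvol[i] + 1L)) {
          planes[[pl]][rows[keep_r], cols[keep_c]] <-
            pmax(planes[[pl]][rows[keep_r], cols[keep_c]],
                 p$img[keep_r, keep_c, drop = FALSE])
        }
      }
    }
    for (pl in seq_along(planes)) {
      img <- planes[[pl]] + spec$background_level
      if (spec$noise_sd > 0) {
        img <- img + matrix(rnorm(length(img), 0, spec$noise_sd),
                            nrow(img), ncol(img))
      }
      planes[[pl]] <- clamp(img, 0, 1)
    }
    truth <- if (spec$n_cells > 0) dplyr::bind_rows(truths) else
      empty_truth_table()
    list(stack = image_stack(planes, pixel_size_um = s,
                             z_step_um = spec$z_step_um),
         truth = truth)
  })
}

empty_truth_table <- function() {
  tibble(cell_id = character(), subvolume_index = integer(),
         archetype = character(),
         centroid_x_um = numeric(), centroid_y_um = numeric(),
         true_body_area_um2 = numeric(), true_cytoplasm_area_um2 = numeric(),
         true_n_primary = integer(), true_n_secondary = integer(),
         true_n_tertiary = integer(), true_n_segments = integer(),
         true_total_length_um = numeric(), true_CI = numeric(),
         true_CEA_um2 = numeric(),
         endpoints_um = list(), segments = list())
}

# Branching-process sample of one cell's segment counts and lengths,
# without geometry: returns (n_primary, n_secondary, n_tertiary,
# n_segments, total_length, primary_length). Matches the per-order
# branching probabilities and truncated-normal segment lengths of
# grow_tree(), minus the spatial extent cap.
grow_counts <- function(arch) {
  decay <- 0.8
  n_ord <- integer(arch$max_order)
  n_ord[1] <- arch$n_primary
  total_len <- 0
  primary_len <- 0
  p <- arch$branch_prob_per_order
  for (o in seq_len(arch$max_order)) {
    if (n_ord[o] == 0L) break
    mu <- arch$mean_segment_length_um * decay^(o - 1)
    sdv <- arch$segment_length_sd_um * decay^(o - 1)
    lens <- clamp(rnorm(n_ord[o], mu, sdv), max(3.5, mu - 2 * sdv),
                  mu + 2 * sdv)
    total_len <- total_len + sum(lens)
    if (o == 1L) primary_len <- sum(lens)
    po <- if (o <= length(p)) p[o] else 0
    if (o < arch$max_order && po > 0) {
      n_ord[o + 1L] <- 2L * rbinom(1L, n_ord[o], po)
    }
  }
  n2 <- if (length(n_ord) >= 2) n_ord[2] else 0L
  n3 <- if (length(n_ord) >= 3) sum(n_ord[3:length(n_ord)]) else 0L
  c(n_ord[1], n2, n3, sum(n_ord), total_len, primary_len)
}

# Rejection-sampled centroids with a minimum spacing; errors with the
# achievable count when the requested density cannot be placed.
place_centroids <- function(n, w_um, h_um, spacing, margin) {
  out <- matrix(numeric(0), ncol = 2)
  if (n == 0) return(out)
  if (w_um - 2 * margin <= 0 || h_um - 2 * margin <= 0) {
    abort("placement margin leaves no room for cells")
  }
  tries_per_cell <- 2000L
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(tries_per_cell)) {
      p <- c(runif(1, margin, w_um - margin), runif(1, margin, h_um - margin))
      if (nrow(out) == 0 ||
          min(sqrt((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2)) >= spacing) {
        out <- rbind(out, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf(
        "could only place %d of %d cells at %.3g um spacing; reduce n_cells or spacing",
        i - 1L, n, spacing))
    }
  }
  unname(out)
}

#' Generate a multi-animal cohort with regional presets and treatment effect
#'
#' Control and treated animals are simulated per region. Treated animals'
#' archetypes have their cytoplasm-bearing parameters (soma area, process
#' stroke width) scaled by `treatment_effect$cytoplasm_factor`, emulating
#' the roughly two-fold cytoplasm enlargement seen after an inflammatory
#' challenge while leaving branching topology untouched. Each animal
#' additionally carries a lognormal size random effect (`animal_effect_sd`
#' on the log scale) so that animal-level summaries have biological, not
#' merely sampling, variance. Cells are generated truth-only by default;
#' `detail = "counts"` is fast enough for thousands of replicate cohorts.
#'
#' @param n_control,n_treated Animals per condition (>= 1).
#' @param regions Character vector of region preset names
#'   (see [region_presets()]).
#' @param cells_per_animal Cells generated per animal and region.
#' @param treatment_effect List with `cytoplasm_factor` (default 2).
#' @param animal_effect_sd Log-scale SD of the per-animal size effect.
#' @param detail Passed to [generate_cell()] (`"counts"` or `"tree"`).
#' @param seed Integer seed.
#' @return Tibble of cell-level truth records with `animal_id`, `condition`
#'   and `region` columns.
#' @export
generate_cohort <- function(n_control = 7L, n_treated = 6L,
                            regions = "uniform",
                            cells_per_animal = 50L,
                            treatment_effect = list(cytoplasm_factor = 2),
                            animal_effect_sd = 0.15,
                            detail = c("counts", "tree"),
                            seed = 1L) {
  detail <- match.arg(detail)
  if (n_control < 1 || n_treated < 1) abort("need >= 1 animal per condition.")
  presets <- region_presets()
  unknown <- setdiff(regions, names(presets))
  if (length(unknown) > 0) {
    abort(sprintf("unknown region preset(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  factor_cyto <- treatment_effect$cytoplasm_factor %||% 2
  archetypes <- archetype_presets()

  with_seed(seed, {
    out <- list()
    animals <- tibble(
      animal_id = c(sprintf("ctrl_%02d", seq_len(n_control)),
                    sprintf("trt_%02d", seq_len(n_treated))),
      condition = rep(c("control", "treated"), c(n_control, n_treated)))
    for (a in seq_len(nrow(animals))) {
      size_effect <- rlnorm(1, 0, animal_effect_sd)
      f <- size_effect *
        if (animals$condition[a] == "treated") factor_cyto else 1
      arch_a <- lapply(archetypes, scale_cytoplasm, factor = f)
      for (rg in regions) {
        mix <- presets[[rg]]$archetype_mix
        idx <- sample.int(length(arch_a), cells_per_animal,
                          replace = TRUE, prob = mix)
        tbl <- if (detail == "counts") {
          # light path: branching-process counts only, no geometry --
          # fast enough for thousands of replicate cohorts
          cm <- t(vapply(idx, function(k) grow_counts(arch_a[[k]]),
                         numeric(6)))
          arch_names <- names(arch_a)[idx]
          body <- vapply(idx, function(k) pi * arch_a[[k]]$body_radius_um^2,
                         1)
          thick <- vapply(idx, function(k) arch_a[[k]]$process_thickness_um,
                          1)
          tibble(
            archetype = arch_names,
            centroid_x_um = 0, centroid_y_um = 0,
            true_body_area_um2 = body,
            true_cytoplasm_area_um2 = body + cm[, 6] * thick,
            true_n_primary = as.integer(cm[, 1]),
            true_n_secondary = as.integer(cm[, 2]),
            true_n_tertiary = as.integer(cm[, 3]),
            true_n_segments = as.integer(cm[, 4]),
            true_total_length_um = cm[, 5],
            true_CI = cm[, 4] / cm[, 1],
            true_CEA_um2 = NA_real_)
        } else {
          dplyr::bind_rows(lapply(seq_len(cells_per_animal), function(i) {
            generate_cell(arch_a[[idx[i]]], detail = detail)$truth
          }))
        }
        out[[length(out) + 1L]] <- dplyr::mutate(
          tbl,
          cell_id = sprintf("%s_%s_%04d", animals$animal_id[a], rg,
                            seq_len(cells_per_animal)),
          animal_id = animals$animal_id[a],
          condition = animals$condition[a],
          region = rg, .before = 1)
      }
    }
    dplyr::bind_rows(out)
  })
}

#' Build a feature table from a ground-truth table
#'
#' Maps generator truth columns onto the measured-criteria column contract
#' consumed by the filtering, clustering and statistics stages, so cohort
#' simulations can exercise those stages without rendering or segmenting
#' images.
#'
#' @param truth Truth tibble from [generate_tissue()] or [generate_cohort()].
#' @return Tibble shaped like [measure_cells()] output.
#' @export
truth_as_records <- function(truth) {
  col_or <- function(nm, default) {
    if (nm %in% names(truth)) truth[[nm]] else default
  }
  tibble(
    cell_id = col_or("cell_id", sprintf("cell_%04d", seq_len(nrow(truth)))),
    animal_id = col_or("animal_id", NA_character_),
    condition = col_or("condition", NA_character_),
    region = col_or("region", NA_character_),
    subvolume_index = col_or("subvolume_index", 0L),
    centroid_x_um = truth$centroid_x_um,
    centroid_y_um = truth$centroid_y_um,
    body_area_um2 = truth$true_body_area_um2,
    cytoplasm_area_um2 = truth$true_cytoplasm_area_um2,
    roundness = 1,
    mean_intensity = NA_real_,
    n_primary = truth$true_n_primary,
    n_secondary = truth$true_n_secondary,
    n_tertiary = truth$true_n_tertiary,
    n_segments = truth$true_n_segments,
    n_ramifications = truth$true_n_segments,
    total_ramification_length_um = truth$true_total_length_um,
    CI = truth$true_CI,
    CEA_um2 = truth$true_CEA_um2,
    is_amoeboid = truth$true_CI == 1,
    endpoints_um = if ("endpoints_um" %in% names(truth)) truth$endpoints_um
                   else replicate(nrow(truth),
                                  matrix(numeric(0), ncol = 2),
                                  simplify = FALSE)
  )
}
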