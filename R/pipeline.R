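#' Read / write cell feature tables as CSV
#'
#' The `endpoints_um` list-column (process extremities backing the CEA and
#' the edge filter) is serialised as `x:y` pairs separated by `;` so the
#' table round-trips through plain CSV.
#'
#' @param records Cell records tibble.
#' @param path CSV path.
#' @return [write_records()]: `path` invisibly; [read_records()]: tibble.
#' @export
write_records <- function(records, path) {
  out <- records
  if ("endpoints_um" %in% names(out)) {
    out$endpoints_um <- vapply(out$endpoints_um, function(ep) {
      if (is.null(ep) || nrow(ep) == 0) return("")
      paste(sprintf("%.6g:%.6g", ep[, 1], ep[, 2]), collapse = ";")
    }, character(1))
  }
  if ("segments" %in% names(out)) out$segments <- NULL
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("endpoints_um" %in% names(out)) {
    out$endpoints_um <- lapply(out$endpoints_um, function(sv) {
      if (is.na(sv) || !nzchar(sv)) {
        return(matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("x", "y"))))
      }
      parts <- strsplit(strsplit(sv, ";", fixed = TRUE)[[1]], ":",
                        fixed = TRUE)
      m <- do.call(rbind, lapply(parts, as.numeric))
      colnames(m) <- c("x", "y")
      m
    })
  }
  as_tibble(out)
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects plus seeds and output options;
#' validated up front so misconfiguration fails before any computation.
#'
#' @param segmentation A [segmentation_params()].
#' @param filter A [filter_config()].
#' @param k,cluster_seed,n_init Clustering settings.
#' @param scanned_area_mm2 Scanned area used for densities (default the
#'   nominal per-region coverage of a 10 x 10 mosaic, about 3 mm^2).
#' @param out_dir Optional directory for CSV/YAML/PNG artefacts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = segmentation_params(),
                            filter = filter_config(),
                            k = 4L, cluster_seed = 0L, n_init = 10L,
                            scanned_area_mm2 = 3.03,
                            out_dir = NULL) {
  stopifnot(inherits(segmentation, "segmentation_params"),
            inherits(filter, "filter_config"))
  if (k < 2) abort("`k` must be >= 2.")
  structure(list(segmentation = segmentation, filter = filter,
                 k = as.integer(k), cluster_seed = as.integer(cluster_seed),
                 n_init = as.integer(n_init),
                 scanned_area_mm2 = scanned_area_mm2,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline on stacks or a pre-quantified feature table
#'
#' Orchestrates quantification (when image stacks are given), population
#' filtering, clustering, sub-population assignment, group statistics and
#' cartography, logging cell counts at every stage. All randomness flows
#' from `config$cluster_seed`; inputs are never modified.
#'
#' @param config A [pipeline_config()].
#' @param stacks Optional named list of [image_stack()] objects (names
#'   become `animal_id`s, or supply `metadata`).
#' @param records Optional pre-quantified feature table (used when
#'   `stacks` is `NULL`).
#' @param metadata Optional tibble with `animal_id`, `condition`, `region`
#'   per stack name.
#' @return List: `records_raw`, `records`, `rejected`, `cutoffs`, `model`,
#'   `subpop_frequencies`, `correlation_screen`, `cartography`, `log`.
#' @export
run_pipeline <- function(config, stacks = NULL, records = NULL,
                         metadata = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(stacks) && is.null(records)) {
    abort("supply `stacks` or `records`.")
  }

  if (!is.null(stacks)) {
    recs <- lapply(names(stacks) %||% seq_along(stacks), function(nm) {
      r <- quantify_stack(stacks[[nm]], config$segmentation)
      r$animal_id <- as.character(nm)
      if (!is.null(metadata)) {
        meta <- metadata[metadata$animal_id == nm, ]
        if (nrow(meta) == 1) {
          r$condition <- meta$condition
          r$region <- meta$region
        }
      }
      r
    })
    records <- dplyr::bind_rows(recs)
    dims <- dim(stacks[[1]]$planes[[1]])
    w_um <- dims[2] * stacks[[1]]$pixel_size_um
    h_um <- dims[1] * stacks[[1]]$pixel_size_um
  } else {
    w_um <- max(records$centroid_x_um) + 1
    h_um <- max(records$centroid_y_um) + 1
  }

  filt <- apply_population_filter(records, w_um, h_um, config$filter)
  kept <- filt$kept

  screen <- if (nrow(kept) >= 3) feature_correlation_screen(kept) else NULL

  control <- if (!all(is.na(kept$condition))) {
    kept[kept$condition %in% "control", ]
  } else kept
  cutoffs <- if (nrow(control[!control$is_amoeboid, ]) > 0) {
    compute_cutoffs(control)
  } else NULL
  if (!is.null(cutoffs)) kept <- assign_subpopulations(kept, cutoffs)

  model <- if (sum(!kept$is_amoeboid) >= config$k) {
    kmeans_ci_cea(kept, k = config$k, seed = config$cluster_seed,
                  n_init = config$n_init)
  } else NULL

  spf <- if (!is.null(cutoffs)) {
    by <- intersect(c("region", "condition"), names(kept))
    by <- by[vapply(by, function(cn) !all(is.na(kept[[cn]])), TRUE)]
    subpopulation_frequencies(kept, by = if (length(by)) by else NULL)
  } else NULL

  carto <- if (nrow(kept) > 0) render_cartography(kept, "gradient") else NULL

  log <- dplyr::bind_rows(
    filt$log,
    tibble(stage = "clustered",
           n_cells = if (is.null(model)) 0L else model$n_cells))

  res <- list(records_raw = records, records = kept,
              rejected = filt$rejected, cutoffs = cutoffs, model = model,
              subpop_frequencies = spf, correlation_screen = screen,
              cartography = carto, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(config$out_dir, "records_raw.csv"))
    write_records(kept, file.path(config$out_dir, "records_filtered.csv"))
    if (nrow(filt$rejected) > 0) {
      write_records(filt$rejected, file.path(config$out_dir, "rejected.csv"))
    }
    if (!is.null(model)) {
      write_cluster_model(model, file.path(config$out_dir, "model.yml"),
                          cutoffs)
    }
    if (!is.null(spf)) {
      readr::write_csv(spf, file.path(config$out_dir,
                                      "subpopulation_frequencies.csv"))
    }
    readr::write_csv(log, file.path(config$out_dir, "stage_counts.csv"))
    if (!is.null(carto)) {
      write_cartography(carto,
                        png_path = file.path(config$out_dir,
                                             "cartography.png"),
                        csv_path = file.path(config$out_dir,
                                             "cartography.csv"))
    }
  }
  res
}
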