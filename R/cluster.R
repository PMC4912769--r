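#' Screen the clustering features for collinearity
#'
#' Before clustering on (CI, CEA) the two features are checked for
#' correlation: Pearson and Spearman coefficients plus the loadings of a
#' two-feature principal component analysis on the standardised features.
#' A warning flag is raised when |Pearson r| exceeds 0.7, in which case the
#' two indexes would largely duplicate each other and a quadrant
#' sub-population reading would be misleading.
#'
#' @param records Cell records with `CI` and `CEA_um2` columns.
#' @return List: `pearson_r`, `spearman_rho`, `pca_loadings` (2 x 2
#'   matrix), `variance_explained`, `collinearity_warning`, `undefined`
#'   (TRUE when a feature is constant).
#' @export
feature_correlation_screen <- function(records) {
  x <- records$CI; y <- records$CEA_um2
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 cells to screen correlation.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_,
                pca_loadings = NULL, variance_explained = NULL,
                collinearity_warning = FALSE, undefined = TRUE))
  }
  r <- cor(x, y)
  rho <- cor(x, y, method = "spearman")
  p <- prcomp(cbind(CI = x, CEA = y), center = TRUE, scale. = TRUE)
  if (abs(r) > 0.7) {
    warn(sprintf("CI and CEA are strongly correlated (r = %.2f).", r))
  }
  list(pearson_r = r, spearman_rho = rho,
       pca_loadings = p$rotation,
       variance_explained = p$sdev^2 / sum(p$sdev^2),
       collinearity_warning = abs(r) > 0.7,
       undefined = FALSE)
}

# k-means++ seeding on a data matrix (rows = observations).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    probs <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' k-means phenotypic clustering on (CI, CEA)
#'
#' Cells are clustered on their complexity index and covered environment
#' area. Features are z-scored first (CEA is two to three orders of
#' magnitude larger than CI and would otherwise dominate the squared
#' distance); amoeboid cells (CI = 1) are excluded by default, following
#' the convention that they form their own phenotype. Lloyd's algorithm is
#' seeded with k-means++ and restarted `n_init` times; the solution with
#' the lowest total within-cluster sum of squares is kept and clusters are
#' renumbered by descending frequency (cluster 1 = most frequent).
#'
#' @param records Cell records with `CI`, `CEA_um2` and (optionally)
#'   `is_amoeboid`.
#' @param k Number of clusters.
#' @param seed Integer seed for the initialisations.
#' @param n_init Number of k-means++ restarts.
#' @param include_amoeboid Keep amoeboid cells in the clustering
#'   (sensitivity analysis).
#' @return Object of class `microglia_kmeans`: standardisation
#'   constants, centroids in standardised and raw units, per-cell labels
#'   (`NA` for excluded amoeboid cells), cluster frequencies and inertia.
#' @export
kmeans_ci_cea <- function(records, k = 4L, seed = 0L, n_init = 10L,
                          include_amoeboid = FALSE) {
  amoe <- if ("is_amoeboid" %in% names(records)) records$is_amoeboid
          else records$CI == 1
  use <- if (include_amoeboid) rep(TRUE, nrow(records)) else !amoe
  use <- use & is.finite(records$CI) & is.finite(records$CEA_um2)
  X_raw <- cbind(CI = records$CI[use], CEA_um2 = records$CEA_um2[use])
  if (nrow(X_raw) < k) abort("fewer usable cells than clusters.")

  mu <- colMeans(X_raw)
  sdv <- apply(X_raw, 2, sd)
  if (any(sdv == 0)) abort("a clustering feature is constant.")
  X <- sweep(sweep(X_raw, 2, mu), 2, sdv, "/")

  with_seed(seed, {
    best <- NULL
    n_failed <- 0L
    for (i in seq_len(n_init)) {
      fit <- tryCatch(
        kmeans(X, centers = kmeanspp_centers(X, k), iter.max = 100L,
               algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) NULL)
      if (is.null(fit)) { n_failed <- n_failed + 1L; next }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) {
      abort("k-means failed in every restart (degenerate data?).")
    }

    sizes <- tabulate(best$cluster, k)
    ord <- order(sizes, decreasing = TRUE)
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    labels_use <- relabel[best$cluster]
    centers_std <- best$centers[ord, , drop = FALSE]
    rownames(centers_std) <- NULL
    centers_raw <- sweep(sweep(centers_std, 2, sdv, "*"), 2, mu, "+")

    labels <- rep(NA_integer_, nrow(records))
    labels[use] <- labels_use

    structure(list(
      k = k, feature_names = c("CI", "CEA_um2"),
      center = mu, scale = sdv,
      centers_std = centers_std, centers_raw = centers_raw,
      labels = labels,
      frequencies = sizes[ord] / sum(sizes),
      tot_withinss = best$tot.withinss,
      n_cells = nrow(X_raw),
      n_failed_restarts = n_failed,
      include_amoeboid = include_amoeboid,
      seed = seed, n_init = n_init),
      class = "microglia_kmeans")
  })
}

#' @export
print.microglia_kmeans <- function(x, ...) {
  cat(sprintf("<microglia_kmeans> k = %d on (%s), %d cells\n", x$k,
              paste(x$feature_names, collapse = ", "), x$n_cells))
  cat("cluster frequencies:",
      paste0(sprintf("%.1f", 100 * x$frequencies), "%", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
tidy.microglia_kmeans <- function(x, ...) {
  tibble(cluster = seq_len(x$k),
         CI = x$centers_raw[, 1],
         CEA_um2 = x$centers_raw[, 2],
         frequency = x$frequencies,
         size = as.integer(round(x$frequencies * x$n_cells)))
}

#' @export
glance.microglia_kmeans <- function(x, ...) {
  tibble(k = x$k, n_cells = x$n_cells, tot_withinss = x$tot_withinss,
         n_failed_restarts = x$n_failed_restarts)
}

#' @export
augment.microglia_kmeans <- function(x, data, ...) {
  data$.cluster <- factor(x$labels)
  data
}

#' Predict cluster membership for new cells
#'
#' @param object A [kmeans_ci_cea()] model.
#' @param newdata Records with `CI` and `CEA_um2`.
#' @param ... Unused.
#' @return Integer cluster labels.
#' @export
predict.microglia_kmeans <- function(object, newdata, ...) {
  X <- cbind(newdata$CI, newdata$CEA_um2)
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  d <- vapply(seq_len(object$k), function(j) {
    rowSums(sweep(X, 2, object$centers_std[j, ])^2)
  }, numeric(nrow(X)))
  max.col(-d, ties.method = "first")
}

#' Sub-population cutoffs from the control group
#'
#' The high/low cutoff of each criterion is the arithmetic mean of that
#' criterion over the non-amoeboid control cells, pooled across animals.
#'
#' @param control_records Control-group cell records.
#' @return Object of class `subpop_cutoffs`: `ci_cutoff`,
#'   `cea_cutoff_um2`, `n_cells`.
#' @export
compute_cutoffs <- function(control_records) {
  amoe <- if ("is_amoeboid" %in% names(control_records))
    control_records$is_amoeboid else control_records$CI == 1
  r <- control_records[!amoe & is.finite(control_records$CI) &
                         is.finite(control_records$CEA_um2), ]
  if (nrow(r) == 0) abort("no non-amoeboid control cells.")
  structure(list(ci_cutoff = mean(r$CI),
                 cea_cutoff_um2 = mean(r$CEA_um2),
                 n_cells = nrow(r)),
            class = "subpop_cutoffs")
}

#' @export
print.subpop_cutoffs <- function(x, ...) {
  cat(sprintf("<subpop_cutoffs> CI > %.3g, CEA > %.4g um2 (n = %d control cells)\n",
              x$ci_cutoff, x$cea_cutoff_um2, x$n_cells))
  invisible(x)
}

#' Assign quadrant sub-populations
#'
#' Non-amoeboid cells are labelled by their position relative to the
#' control-mean cutoffs: SP1 = low CEA, low CI; SP2 = low CEA, high CI;
#' SP3 = high CEA, low CI; SP4 = high CEA, high CI. "High" means strictly
#' greater than the cutoff; cells exactly at a cutoff are labelled low.
#' Amoeboid cells (CI = 1) are labelled `"amoeboid"` whatever their CEA.
#'
#' @param records Cell records.
#' @param cutoffs A [compute_cutoffs()] result.
#' @return `records` with a `subpopulation` factor column
#'   (levels SP1-SP4, amoeboid).
#' @export
assign_subpopulations <- function(records, cutoffs) {
  stopifnot(inherits(cutoffs, "subpop_cutoffs"))
  if (!all(is.finite(c(cutoffs$ci_cutoff, cutoffs$cea_cutoff_um2)))) {
    abort("cutoffs must be finite.")
  }
  amoe <- if ("is_amoeboid" %in% names(records)) records$is_amoeboid
          else records$CI == 1
  hi_ci <- records$CI > cutoffs$ci_cutoff
  hi_cea <- records$CEA_um2 > cutoffs$cea_cutoff_um2
  lab <- dplyr::case_when(
    amoe ~ "amoeboid",
    !hi_cea & !hi_ci ~ "SP1",
    !hi_cea & hi_ci ~ "SP2",
    hi_cea & !hi_ci ~ "SP3",
    TRUE ~ "SP4")
  records$subpopulation <- factor(lab,
                                  levels = c("SP1", "SP2", "SP3", "SP4",
                                             "amoeboid"))
  records
}

#' Sub-population proportion tables
#'
#' Per-group proportions of SP1-SP4 among non-amoeboid cells (rows sum to
#' 1) with the amoeboid share of all cells reported separately.
#'
#' @param records Records carrying a `subpopulation` column (see
#'   [assign_subpopulations()]).
#' @param by Character vector of grouping columns (e.g. `c("region",
#'   "condition")`); `NULL` for one overall row.
#' @return Tibble: grouping columns, `n_cells`, `SP1`..`SP4` proportions,
#'   `amoeboid_frequency`.
#' @export
subpopulation_frequencies <- function(records, by = NULL) {
  if (!"subpopulation" %in% names(records)) {
    abort("run assign_subpopulations() first.")
  }
  grp <- if (is.null(by)) dplyr::group_by(records) else
    dplyr::group_by(records, dplyr::across(dplyr::all_of(by)))
  out <- dplyr::summarise(
    grp,
    n_cells = dplyr::n(),
    SP1 = sum(.data$subpopulation == "SP1"),
    SP2 = sum(.data$subpopulation == "SP2"),
    SP3 = sum(.data$subpopulation == "SP3"),
    SP4 = sum(.data$subpopulation == "SP4"),
    amoeboid_frequency = mean(.data$subpopulation == "amoeboid"),
    .groups = "drop")
  n_sp <- out$SP1 + out$SP2 + out$SP3 + out$SP4
  empty <- n_sp == 0
  if (any(empty)) {
    warn("groups without non-amoeboid cells omitted from proportions.")
  }
  for (cn in c("SP1", "SP2", "SP3", "SP4")) out[[cn]] <- out[[cn]] / n_sp
  out[!empty, , drop = FALSE]
}

#' Persist / restore a fitted clustering model
#'
#' Saves the standardisation, centroids and (optionally) cutoffs as YAML
#' so a control-fitted model can label treated cohorts later.
#'
#' @param model A [kmeans_ci_cea()] model.
#' @param path YAML file path.
#' @param cutoffs Optional [compute_cutoffs()] result stored alongside.
#' @return `path` (write) or a list with `model` stub and `cutoffs`
#'   (read), invisibly for the writer.
#' @export
write_cluster_model <- function(model, path, cutoffs = NULL) {
  obj <- list(k = model$k, feature_names = model$feature_names,
              center = as.list(model$center), scale = as.list(model$scale),
              centers_std = apply(model$centers_std, 1, as.list),
              frequencies = as.numeric(model$frequencies),
              seed = model$seed, n_init = model$n_init)
  if (!is.null(cutoffs)) {
    obj$cutoffs <- list(ci_cutoff = cutoffs$ci_cutoff,
                        cea_cutoff_um2 = cutoffs$cea_cutoff_um2,
                        n_cells = cutoffs$n_cells)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- yaml::read_yaml(path)
  model <- structure(list(
    k = obj$k, feature_names = unlist(obj$feature_names),
    center = unlist(obj$center), scale = unlist(obj$scale),
    centers_std = do.call(rbind, lapply(obj$centers_std, unlist)),
    frequencies = unlist(obj$frequencies),
    seed = obj$seed, n_init = obj$n_init),
    class = "microglia_kmeans")
  model$centers_raw <- sweep(sweep(model$centers_std, 2, model$scale, "*"),
                             2, model$center, "+")
  cutoffs <- if (!is.null(obj$cutoffs)) {
    structure(obj$cutoffs, class = "subpop_cutoffs")
  }
  list(model = model, cutoffs = cutoffs)
}

#' Scatter plot of a fitted clustering
#'
#' @param object A [kmeans_ci_cea()] model.
#' @param data The records the model was fitted on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.microglia_kmeans <- function(object, data, ...) {
  d <- data[!is.na(object$labels), ]
  d$.cluster <- factor(object$labels[!is.na(object$labels)])
  cent <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$CEA_um2, y = .data$CI,
                                  colour = .data$.cluster)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = cent,
                        ggplot2::aes(x = .data$CEA_um2, y = .data$CI),
                        colour = "black", shape = 3, size = 3,
                        inherit.aes = FALSE) +
    ggplot2::labs(x = "covered environment area (um^2)",
                  y = "complexity index", colour = "cluster") +
    ggplot2::theme_minimal()
}
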