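#' Summarise morphological criteria per animal
#'
#' Collapses a (filtered, deduplicated) feature table to one row per
#' animal, region and condition — the unit used by the conventional
#' statistical comparisons. Criteria are summarised over the ramified
#' (non-amoeboid) population by default; the amoeboid share is always
#' reported.
#'
#' @param records Cell records with `animal_id`, `condition`, `region`.
#' @param scanned_area_mm2 Optional scanned tissue area per animal and
#'   region; when given, an areal density column is added.
#' @param population `"ramified"` (default), `"amoeboid"` or `"all"`:
#'   which cells enter the per-criterion means/medians.
#' @return Tibble with per-criterion `mean_*` and `median_*` columns,
#'   `n_cells` and `amoeboid_frequency`.
#' @export
animal_summaries <- function(records, scanned_area_mm2 = NULL,
                             population = c("ramified", "amoeboid", "all")) {
  population <- match.arg(population)
  amoe <- if ("is_amoeboid" %in% names(records)) records$is_amoeboid
          else records$CI == 1
  sel <- switch(population, ramified = !amoe, amoeboid = amoe,
                all = rep(TRUE, nrow(records)))
  base <- dplyr::group_by(records, .data$animal_id, .data$condition,
                          .data$region)
  frac <- dplyr::summarise(base,
                           n_total = dplyr::n(),
                           amoeboid_frequency = mean(amoe[dplyr::cur_group_rows()]),
                           .groups = "drop")
  crit <- c("body_area_um2", "cytoplasm_area_um2", "CI", "CEA_um2",
            "mean_intensity")
  crit <- intersect(crit, names(records))
  sub <- dplyr::group_by(records[sel, ], .data$animal_id, .data$condition,
                         .data$region)
  out <- dplyr::summarise(
    sub,
    n_cells = dplyr::n(),
    dplyr::across(dplyr::all_of(crit),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       median = ~median(.x, na.rm = TRUE)),
                  .names = "{.fn}_{.col}"),
    .groups = "drop")
  out <- dplyr::left_join(out, frac,
                          by = c("animal_id", "condition", "region"))
  if (!is.null(scanned_area_mm2)) {
    out$density_cells_per_mm2 <- out$n_total / scanned_area_mm2
  }
  out
}

#' Two-group comparison with a normality gate
#'
#' Each group is checked for normality (Shapiro-Wilk at the 5 % level);
#' when both pass, a two-sided Student's t test (pooled variance) is used,
#' otherwise a two-sided exact Mann-Whitney test (exact for group sizes up
#' to 12 without ties, normal approximation with tie correction beyond).
#'
#' @param a,b Numeric vectors of per-animal values (>= 3 each).
#' @param alpha_normality Level of the Shapiro-Wilk gate.
#' @return One-row tibble: `test` (`"t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `n_a`, `n_b`, `shapiro_p_a`, `shapiro_p_b`.
#' @export
compare_two_groups <- function(a, b, alpha_normality = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    abort("need at least 3 animals per group.")
  }
  sw_a <- if (sd(a) == 0) 0 else shapiro.test(a)$p.value
  sw_b <- if (sd(b) == 0) 0 else shapiro.test(b)$p.value
  if (sw_a > alpha_normality && sw_b > alpha_normality) {
    ht <- t.test(a, b, var.equal = TRUE)
    test <- "t"
  } else {
    exact <- length(a) <= 12 && length(b) <= 12 &&
      !any(duplicated(c(a, b)))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact,
                                       correct = !exact))
    test <- "mann_whitney"
    if (is.nan(ht$p.value)) {
      # fully tied samples: the rank statistic sits at its null midpoint
      # and carries no evidence against the null
      ht$p.value <- 1
    }
  }
  tibble(test = test, statistic = unname(ht$statistic),
         p_value = ht$p.value, n_a = length(a), n_b = length(b),
         shapiro_p_a = sw_a, shapiro_p_b = sw_b)
}

#' Compare a criterion across three or more regions (Kruskal-Wallis)
#'
#' @param values Numeric vector of per-animal values.
#' @param groups Region labels, same length.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @export
compare_regions <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 3) {
    abort("need at least 3 groups for the inter-region comparison.")
  }
  ht <- kruskal.test(values, groups)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value, n_groups = nlevels(droplevels(groups)))
}

#' Chi-square comparison of sub-population count tables
#'
#' @param counts A 2 x m matrix of counts (conditions in rows,
#'   sub-populations in columns).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
compare_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) abort("`counts` must have exactly 2 rows.")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    abort(paste("a sub-population has expected count 0; pool sparse",
                "columns before testing."))
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Spearman correlation between two paired measurements
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return One-row tibble: `rho`, `p_value`, `n`, `undefined` (TRUE when a
#'   vector is constant).
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = length(x),
                  undefined = TRUE))
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x),
         undefined = FALSE)
}

#' Animals needed per group to resolve a mean difference
#'
#' Two-sample design with equal group sizes: the required number of
#' animals per group is
#' `n = ceiling( 2 (z_{1-alpha/2} + z_{1-beta})^2 sigma^2 / (mA - mB)^2 )`,
#' the normal-approximation sample-size formula with common standard
#' deviation `sigma`. At the defaults (two-sided alpha 0.05, power 0.90)
#' the multiplier `(z_{0.975} + z_{0.90})^2` is about 10.51.
#'
#' @param mean_a,mean_b Group means of the criterion (must differ).
#' @param sigma Common standard deviation (> 0).
#' @param alpha Two-sided type-I level.
#' @param power Target power `1 - beta`.
#' @return Integer: animals per group.
#' @examples
#' required_sample_size(74.4, 149.4, 42.2)   # 7
#' @export
required_sample_size <- function(mean_a, mean_b, sigma,
                                 alpha = 0.05, power = 0.90) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("`alpha` and `power` must be in (0, 1).")
  }
  delta <- mean_a - mean_b
  if (any(delta == 0)) {
    abort("group means are equal: no finite sample size resolves them.")
  }
  mult <- (qnorm(1 - alpha / 2) + qnorm(power))^2
  as.integer(ceiling(2 * mult * sigma^2 / delta^2))
}
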