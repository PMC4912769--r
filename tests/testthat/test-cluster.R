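test_that("correlation screen reports independence and flags collinearity", {
  sim <- simulate_feature_table(5000, seed = 17)
  scr <- feature_correlation_screen(sim)
  # CI and CEA are drawn from a quadrant mixture; rank correlation between
  # the two axes of an independent draw stays small
  expect_false(scr$undefined)
  expect_equal(dim(scr$pca_loadings), c(2, 2))

  ind <- tibble::tibble(CI = rnorm(5000, 5), CEA_um2 = rnorm(5000, 800, 100))
  expect_lt(abs(feature_correlation_screen(ind)$pearson_r), 0.1)

  coll <- tibble::tibble(CI = 1:100, CEA_um2 = 100 * (1:100))
  expect_warning(scr2 <- feature_correlation_screen(coll), "correlated")
  expect_true(scr2$collinearity_warning)
  expect_equal(scr2$pearson_r, 1)

  expect_error(feature_correlation_screen(tibble::tibble(CI = 1:2,
                                                         CEA_um2 = 1:2)),
               "3 cells")
  const <- tibble::tibble(CI = rep(2, 10), CEA_um2 = rnorm(10))
  expect_true(feature_correlation_screen(const)$undefined)
})

test_that("k-means recovers a separated four-component mixture", {
  sim <- simulate_feature_table(2000, mix = c(0.4, 0.25, 0.2, 0.15),
                                seed = 3)
  fit <- kmeans_ci_cea(sim, k = 4, seed = 0, n_init = 10)
  # match fitted clusters to generating components by majority vote
  tab <- table(sim$component, fit$labels)
  agreement <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(agreement, 0.99)
  expect_equal(sum(fit$frequencies), 1)
  # clusters reported most-frequent first
  expect_true(all(diff(fit$frequencies) <= 0))
})

test_that("k-means standardises features and is scale-stable", {
  sim <- simulate_feature_table(1200, seed = 8)
  f1 <- kmeans_ci_cea(sim, seed = 1)
  sim2 <- sim
  sim2$CEA_um2 <- sim2$CEA_um2 / 1000   # express CEA in mm^2-ish units
  f2 <- kmeans_ci_cea(sim2, seed = 1)
  expect_equal(f1$labels, f2$labels)
  expect_lt(f1$tot_withinss, f1$n_cells * 2)
})

test_that("degenerate clustering inputs fail loudly", {
  same <- tibble::tibble(CI = rep(2, 50), CEA_um2 = rep(100, 50),
                         is_amoeboid = FALSE)
  expect_error(kmeans_ci_cea(same), "constant|degenerate")
  few <- simulate_feature_table(3, seed = 1)
  expect_error(kmeans_ci_cea(few, k = 4), "fewer")
})

test_that("tidy/glance/augment/predict expose the fitted model", {
  sim <- simulate_feature_table(800, seed = 12)
  fit <- kmeans_ci_cea(sim, seed = 2)
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  expect_true(all(c("cluster", "CI", "CEA_um2", "frequency") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_cells, nrow(sim))
  aug <- augment(fit, sim)
  expect_s3_class(aug$.cluster, "factor")
  pred <- predict(fit, sim)
  expect_equal(pred, unname(fit$labels))
  p <- autoplot(fit, sim)
  expect_s3_class(p, "ggplot")
})

test_that("cutoffs are control means over non-amoeboid cells", {
  rec <- tibble::tibble(CI = c(2, 4, 1, 6), CEA_um2 = c(100, 300, 50, 700),
                        is_amoeboid = c(FALSE, FALSE, TRUE, FALSE))
  co <- compute_cutoffs(rec)
  expect_equal(co$ci_cutoff, mean(c(2, 4, 6)))
  expect_equal(co$cea_cutoff_um2, mean(c(100, 300, 700)))
  # order of records is irrelevant
  co2 <- compute_cutoffs(rec[c(3, 1, 4, 2), ])
  expect_equal(co2$ci_cutoff, co$ci_cutoff)
  expect_error(compute_cutoffs(rec[rec$is_amoeboid, ]), "non-amoeboid")
})

test_that("sub-population quadrants follow the cutoff sign convention", {
  co <- structure(list(ci_cutoff = 4, cea_cutoff_um2 = 500, n_cells = 10L),
                  class = "subpop_cutoffs")
  rec <- tibble::tibble(
    CI = c(3, 6, 3, 6, 1, 4, 6),
    CEA_um2 = c(300, 300, 900, 900, 900, 500, 500),
    is_amoeboid = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  out <- assign_subpopulations(rec, co)
  expect_equal(as.character(out$subpopulation),
               c("SP1", "SP2", "SP3", "SP4", "amoeboid",
                 "SP1",   # both exactly at cutoff: low
                 "SP2"))  # CEA at cutoff: low side
  # amoeboid never enters SP1-4 whatever its CEA
  expect_false(any(out$subpopulation[out$is_amoeboid] %in%
                     paste0("SP", 1:4)))
})

test_that("sub-population frequencies recover a planted mixture", {
  # recovery error averaged over replicate surveys (one draw at n = 2000
  # carries ~1-point binomial noise per sub-population)
  errs <- vapply(21:23, function(s) {
    sim <- simulate_feature_table(2000, mix = c(0.70, 0.18, 0.11, 0.02),
                                  seed = s)
    freq <- subpopulation_frequencies(
      assign_subpopulations(sim, compute_cutoffs(sim)))
    max(abs(c(freq$SP1, freq$SP2, freq$SP3, freq$SP4) -
              c(0.70, 0.18, 0.11, 0.02)))
  }, numeric(1))
  expect_lt(mean(errs), 0.03)

  sim <- simulate_feature_table(2000, mix = c(0.70, 0.18, 0.11, 0.02),
                                seed = 21)
  out <- assign_subpopulations(sim, compute_cutoffs(sim))
  freq <- subpopulation_frequencies(out)
  expect_equal(freq$SP1 + freq$SP2 + freq$SP3 + freq$SP4, 1)

  # proportions are invariant to record order, and grouped tables split
  out$region <- rep(c("a", "b"), length.out = nrow(out))
  f2 <- subpopulation_frequencies(out[sample(nrow(out)), ], by = "region")
  expect_equal(nrow(f2), 2)
  expect_equal(f2$SP1 + f2$SP2 + f2$SP3 + f2$SP4, c(1, 1))
})

test_that("cutoff sub-populations and k-means clusters agree on clean mixtures", {
  sim <- simulate_feature_table(2000, seed = 33)
  fit <- kmeans_ci_cea(sim, seed = 0)
  out <- assign_subpopulations(sim, compute_cutoffs(sim))
  tab <- table(out$subpopulation[!is.na(fit$labels)],
               fit$labels[!is.na(fit$labels)])
  agreement <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(agreement, 0.90)
})

test_that("a persisted model relabels new cohorts identically", {
  sim <- simulate_feature_table(600, seed = 44)
  fit <- kmeans_ci_cea(sim, seed = 5)
  co <- compute_cutoffs(sim)
  path <- withr::local_tempfile(fileext = ".yml")
  write_cluster_model(fit, path, cutoffs = co)
  back <- read_cluster_model(path)
  expect_equal(predict(back$model, sim), predict(fit, sim))
  expect_equal(back$cutoffs$ci_cutoff, co$ci_cutoff)
})
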