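test_that("sample-size calculator reproduces the published two-group designs", {
  # cytoplasm-area rows across the four regions
  expect_identical(required_sample_size(74.4, 149.4, 42.2), 7L)
  expect_identical(required_sample_size(62.4, 123.0, 33.0), 7L)
  expect_identical(required_sample_size(66.3, 129.2, 34.1), 7L)
  expect_identical(required_sample_size(123.4, 177.0, 37.9), 11L)
  # cerebellum complexity index, frontal-cortex and striatum territory area
  expect_identical(required_sample_size(4.5, 3.6, 0.5), 7L)
  expect_identical(required_sample_size(950, 1184, 349), 47L)
  expect_identical(required_sample_size(1378, 1499, 435), 272L)
})

test_that("sample-size formula is symmetric, monotone, and guarded", {
  expect_identical(required_sample_size(10, 20, 5),
                   required_sample_size(20, 10, 5))
  # doubling sigma quadruples the pre-ceiling n
  mult <- (qnorm(0.975) + qnorm(0.90))^2
  n1 <- 2 * mult * 5^2 / 10^2
  n2 <- 2 * mult * 10^2 / 10^2
  expect_equal(n2 / n1, 4)
  expect_gt(required_sample_size(10, 20, 10),
            required_sample_size(10, 20, 5))
  expect_lt(required_sample_size(10, 30, 5),
            required_sample_size(10, 20, 5))
  expect_error(required_sample_size(10, 10, 5), "equal")
  expect_error(required_sample_size(10, 20, 0), "sigma")
})

test_that("two-group comparison gates on normality and handles identical samples", {
  withr::with_seed(11, {
    a <- rnorm(8); b <- rnorm(8)
    res <- compare_two_groups(a, b)
    expect_equal(res$test, "t")

    skewed_a <- exp(rnorm(10, sd = 2)); skewed_b <- exp(rnorm(10, sd = 2))
    res2 <- compare_two_groups(skewed_a, skewed_b)
    expect_equal(res2$test, "mann_whitney")
  })
  # identical (constant) samples: rank test at its null midpoint, p = 1
  res3 <- compare_two_groups(c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(res3$test, "mann_whitney")
  expect_equal(res3$p_value, 1)
  expect_error(compare_two_groups(c(1, 2), c(1, 2, 3)), "3 animals")
})

test_that("Mann-Whitney U agrees with pair-counting enumeration at small n", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      a <- round(rnorm(6), 3); b <- round(rnorm(5) + 0.5, 3)
      u_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
      w <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
      expect_equal(unname(w$statistic), u_brute)
    }
  })
})

test_that("chi-square statistic equals the hand-computed sum over cells", {
  counts <- rbind(c(90, 10, 40, 60), c(50, 50, 45, 55))
  res <- compare_proportions(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  chi_brute <- sum((counts - expected)^2 / expected)
  expect_equal(res$statistic, chi_brute)
  expect_equal(res$df, 3)

  # equal distributions -> zero statistic, p = 1
  eq <- compare_proportions(rbind(c(50, 50), c(50, 50)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  # column permutation applied to both rows leaves the statistic unchanged
  perm <- compare_proportions(counts[, c(3, 1, 4, 2)])
  expect_equal(perm$statistic, res$statistic)

  expect_error(compare_proportions(rbind(c(1, 0), c(2, 0))), "pool")
  expect_error(compare_proportions(matrix(1, 3, 2)), "2 rows")
})

test_that("inter-region comparison uses Kruskal-Wallis and is order-invariant", {
  withr::with_seed(7, {
    v <- c(rnorm(7), rnorm(7) + 3, rnorm(7))
    g <- rep(c("a", "b", "c"), each = 7)
    r1 <- compare_regions(v, g)
    expect_lt(r1$p_value, 0.01)
    o <- sample(length(v))
    r2 <- compare_regions(v[o], g[o])
    expect_equal(r2$statistic, r1$statistic)
    # near-identical groups: tiny H, p near 1
    r3 <- compare_regions(rep(c(1, 2, 3, 4), 3), rep(c("a", "b", "c"), 4))
    expect_gt(r3$p_value, 0.9)
    expect_error(compare_regions(rnorm(10), rep(c("a", "b"), 5)), "3 groups")
  })
})

test_that("Spearman correlation hits the rank extremes and flags constants", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(correlate(x, x * 2 + 1)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  expect_true(correlate(rep(1, 5), rnorm(5))$undefined)
  withr::with_seed(5, {
    r <- correlate(rnorm(1000), rnorm(1000))
    expect_lt(abs(r$rho), 0.1)
  })
})

test_that("spearman rho matches the closed-form rank formula without ties", {
  withr::with_seed(41, {
    x <- sample(100, 12); y <- sample(100, 12)
    d <- rank(x) - rank(y)
    rho_formula <- 1 - 6 * sum(d^2) / (12 * (12^2 - 1))
    expect_equal(correlate(x, y)$rho, rho_formula)
  })
})

test_that("animal summaries aggregate per animal and carry amoeboid share", {
  rec <- truth_as_records(generate_cohort(n_control = 3, n_treated = 3,
                                          cells_per_animal = 25, seed = 9))
  s <- animal_summaries(rec, scanned_area_mm2 = 3.03)
  expect_equal(nrow(s), 6)
  expect_true(all(c("mean_CI", "median_CI", "mean_cytoplasm_area_um2",
                    "amoeboid_frequency", "density_cells_per_mm2") %in%
                    names(s)))
  one <- rec[rec$animal_id == s$animal_id[1] & !rec$is_amoeboid, ]
  expect_equal(s$mean_CI[1], mean(one$CI))
})
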