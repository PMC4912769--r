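#' Simulate a feature table from a four-component (CI, CEA) mixture
#'
#' Draws non-amoeboid cells from four bivariate Gaussian components placed
#' in the quadrants of the (complexity index, covered environment area)
#' plane, one per sub-population archetype, with an optional amoeboid
#' share pinned at CI = 1. Component means are separated by several
#' standard deviations so the mixture is recoverable both by k-means and
#' by control-mean quadrant cutoffs. Used to validate the clustering and
#' sub-population machinery against a known mixing proportion.
#'
#' @param n Number of cells.
#' @param mix Mixing proportions over the four components (SP1..SP4
#'   order: low/low, high CI, high CEA, high/high); normalised internally.
#' @param amoeboid_frequency Additional share of amoeboid cells.
#' @param ci_means,cea_means Component means (length 2: low, high).
#' @param ci_sd,cea_sd Component standard deviations.
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `component` (0 = amoeboid), `CI`,
#'   `CEA_um2`, `is_amoeboid`.
#' @export
simulate_feature_table <- function(n,
                                   mix = c(0.70, 0.18, 0.11, 0.02),
                                   amoeboid_frequency = 0,
                                   ci_means = c(3.0, 7.5),
                                   cea_means = c(380, 1500),
                                   ci_sd = 0.35,
                                   cea_sd = 60,
                                   seed = NULL) {
  if (length(mix) != 4 || any(mix < 0) || sum(mix) == 0) {
    abort("`mix` must be 4 non-negative proportions.")
  }
  mix <- mix / sum(mix)
  with_seed(seed, {
    amoe <- runif(n) < amoeboid_frequency
    comp <- integer(n)
    comp[!amoe] <- sample.int(4L, sum(!amoe), replace = TRUE, prob = mix)
    # component -> (CI level, CEA level): SP1 (-,-), SP2 (-,+CI), SP3 (+CEA,-), SP4 (+,+)
    hi_ci <- comp %in% c(2L, 4L)
    hi_cea <- comp %in% c(3L, 4L)
    ci <- ifelse(hi_ci, ci_means[2], ci_means[1]) + rnorm(n, 0, ci_sd)
    cea <- ifelse(hi_cea, cea_means[2], cea_means[1]) + rnorm(n, 0, cea_sd)
    ci <- pmax(ci, 1.05)
    cea <- pmax(cea, 1)
    ci[amoe] <- 1
    cea[amoe] <- pmax(rnorm(sum(amoe), 60, 15), 1)
    tibble(cell_id = sprintf("sim_%05d", seq_len(n)),
           component = comp,
           CI = ci, CEA_um2 = cea,
           is_amoeboid = amoe)
  })
}
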