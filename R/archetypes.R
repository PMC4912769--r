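#' Cell archetype: the generative parameters of one microglial phenotype
#'
#' An archetype bundles the parameters used by [generate_cell()] to grow a
#' synthetic microglial cell: soma size, number of primary ramifications,
#' per-order branching probabilities, segment-length distribution and
#' rendering intensities. The five stock archetypes (see
#' [archetype_presets()]) operationalise the four ramified phenotype
#' quadrants in the (complexity index, covered environment area) plane plus
#' the amoeboid form, whose branching probabilities are all zero so that its
#' complexity index is forced to 1 (no branch nodes).
#'
#' @param name Archetype label.
#' @param body_radius_um Soma radius (micrometres).
#' @param n_primary Number of primary ramifications leaving the soma.
#' @param branch_prob_per_order Probability that a segment of order `o`
#'   bifurcates at its distal end, indexed by `o`; orders beyond the vector
#'   never branch. All entries must be in `[0, 1]`.
#' @param mean_segment_length_um,segment_length_sd_um Mean and standard
#'   deviation of the order-1 segment length; deeper orders shrink by a
#'   factor 0.8 per order.
#' @param max_order Deepest branch order that may be generated.
#' @param process_thickness_um Drawn stroke width of processes.
#' @param intensity_body,intensity_process Rendered fluorescence levels on
#'   the `[0, 1]` grey scale.
#' @return An object of class `cell_archetype` (a validated list).
#' @examples
#' a <- archetype_presets()[["amoeboid"]]
#' a$branch_prob_per_order   # all zero: complexity index 1 by construction
#' @export
cell_archetype <- function(name,
                           body_radius_um,
                           n_primary,
                           branch_prob_per_order,
                           mean_segment_length_um,
                           segment_length_sd_um,
                           max_order = 4L,
                           process_thickness_um = 0.5,
                           intensity_body = 0.85,
                           intensity_process = 0.55) {
  stopifnot_scalar_number(body_radius_um, "body_radius_um", positive = TRUE)
  stopifnot_scalar_number(mean_segment_length_um, "mean_segment_length_um",
                          positive = TRUE)
  stopifnot_scalar_number(segment_length_sd_um, "segment_length_sd_um")
  stopifnot_scalar_number(process_thickness_um, "process_thickness_um",
                          positive = TRUE)
  if (!is.numeric(n_primary) || n_primary < 1 || n_primary != round(n_primary)) {
    abort("`n_primary` must be a positive integer.")
  }
  if (!is.numeric(branch_prob_per_order) ||
      any(branch_prob_per_order < 0 | branch_prob_per_order > 1)) {
    abort("`branch_prob_per_order` must be probabilities in [0, 1].")
  }
  if (max_order < 1) abort("`max_order` must be >= 1.")
  structure(
    list(name = name,
         body_radius_um = body_radius_um,
         n_primary = as.integer(n_primary),
         branch_prob_per_order = as.numeric(branch_prob_per_order),
         mean_segment_length_um = mean_segment_length_um,
         segment_length_sd_um = segment_length_sd_um,
         max_order = as.integer(max_order),
         process_thickness_um = process_thickness_um,
         intensity_body = intensity_body,
         intensity_process = intensity_process),
    class = "cell_archetype")
}

#' Stock archetypes for the four ramified phenotypes and the amoeboid form
#'
#' The four ramified archetypes are calibrated so that low/high complexity
#' index means roughly 4 vs 7-8 segments per primary ramification and
#' low/high covered environment area roughly 450 vs 1100 um^2, preserving
#' the orderings reported for real tissue (cerebellar microglia lower in
#' both indexes than cortical ones). The amoeboid archetype has a larger
#' soma, two short unbranched stubs and therefore complexity index exactly 1.
#'
#' @return Named list of [cell_archetype()] objects.
#' @export
archetype_presets <- function() {
  list(
    ramified_lowCI_lowCEA = cell_archetype(
      "ramified_lowCI_lowCEA", body_radius_um = 2.8, n_primary = 4L,
      branch_prob_per_order = c(0.70, 0.45, 0.25),
      mean_segment_length_um = 7.5, segment_length_sd_um = 1.2),
    ramified_lowCI_highCEA = cell_archetype(
      "ramified_lowCI_highCEA", body_radius_um = 3.0, n_primary = 5L,
      branch_prob_per_order = c(0.70, 0.45, 0.25),
      mean_segment_length_um = 11, segment_length_sd_um = 1.5),
    ramified_highCI_lowCEA = cell_archetype(
      "ramified_highCI_lowCEA", body_radius_um = 2.8, n_primary = 4L,
      branch_prob_per_order = c(0.85, 0.75, 0.50),
      mean_segment_length_um = 7.5, segment_length_sd_um = 1.2),
    ramified_highCI_highCEA = cell_archetype(
      "ramified_highCI_highCEA", body_radius_um = 3.0, n_primary = 5L,
      branch_prob_per_order = c(0.85, 0.75, 0.50),
      mean_segment_length_um = 11, segment_length_sd_um = 1.5),
    amoeboid = cell_archetype(
      "amoeboid", body_radius_um = 4.5, n_primary = 2L,
      branch_prob_per_order = c(0, 0, 0),
      mean_segment_length_um = 6.0, segment_length_sd_um = 1.0,
      max_order = 1L, process_thickness_um = 0.8)
  )
}

#' Region presets: archetype mixtures and densities per brain region
#'
#' Mixtures are calibrated only to preserve the qualitative regional
#' orderings seen in tissue: the cerebellum carries less complex microglia
#' with smaller territories and the highest amoeboid share, the frontal
#' cortex the densest and least amoeboid population. Mixture order follows
#' `names(archetype_presets())`.
#'
#' @return Named list with elements `archetype_mix` (probability vector over
#'   the five stock archetypes) and `density_cells_per_mm2`.
#' @export
region_presets <- function() {
  list(
    frontal_cortex = list(
      archetype_mix = c(0.25, 0.20, 0.20, 0.28, 0.07),
      density_cells_per_mm2 = 115),
    hippocampus = list(
      archetype_mix = c(0.30, 0.22, 0.15, 0.23, 0.10),
      density_cells_per_mm2 = 100),
    striatum = list(
      archetype_mix = c(0.25, 0.15, 0.20, 0.30, 0.10),
      density_cells_per_mm2 = 95),
    cerebellum = list(
      archetype_mix = c(0.62, 0.08, 0.10, 0.05, 0.15),
      density_cells_per_mm2 = 70),
    uniform = list(
      archetype_mix = c(0.2, 0.2, 0.2, 0.2, 0.2),
      density_cells_per_mm2 = 100)
  )
}

# Scale the cytoplasm-bearing parameters of an archetype by `factor`:
# soma radius by sqrt(factor) and process stroke width by factor, so both
# the body area and the primary-ramification cytoplasm area scale linearly.
scale_cytoplasm <- function(archetype, factor) {
  if (factor == 1) return(archetype)
  archetype$body_radius_um <- archetype$body_radius_um * sqrt(factor)
  archetype$process_thickness_um <- archetype$process_thickness_um * factor
  archetype
}

#' @export
print.cell_archetype <- function(x, ...) {
  cat(sprintf(
    "<cell_archetype> %s: soma r=%.2g um, %d primaries, branch p=(%s), seg %.2g+/-%.2g um\n",
    x$name, x$body_radius_um, x$n_primary,
    paste(format(x$branch_prob_per_order), collapse = ", "),
    x$mean_segment_length_um, x$segment_length_sd_um))
  invisible(x)
}
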