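#' Simulation configuration for the synthetic truth generator
#'
#' Bundles and validates every knob of the synthetic-genome generator. The
#' defaults emulate the study conditions of a lineage-specific ERV survey:
#' classical insertions flanked by 2–5 bp target-site duplications (TSDs),
#' solitary LTRs from LTR–LTR recombination, truncated copies, and
#' non-classical insertions (NCPIs) that replace a genomic segment and carry
#' 2–3 bp junction microhomology instead of a TSD.
#'
#' @param seed Integer seed driving all randomness.
#' @param ancestor_length_bp Total ancestral genome length (split over
#'   chromosomes).
#' @param n_chromosomes Number of chromosomes.
#' @param gc_fraction GC content of the ancestral background, in `[0, 1]`.
#' @param n_full_length,n_solo_ltr,n_truncated,n_ncpi Event counts per class.
#' @param n_decoy_shared Pre-divergence ("shared") elements planted in the
#'   ancestor before outgroup divergence, to exercise false-positive
#'   rejection. Default 0.
#' @param tsd_length_range Integer pair, TSD lengths sampled uniformly
#'   (default 2–5 bp).
#' @param ncpi_deletion_range_bp Integer pair, deletion sizes of NCPIs.
#' @param microhomology_range Integer pair, junction microhomology lengths
#'   (default 2–3 bp).
#' @param microhomology_prob Probability an NCPI carries microhomology (the
#'   remainder are blunt junctions).
#' @param ltr_mutation_rate Neutral substitution rate, substitutions per site
#'   per myr (e.g. `0.0025` = 0.25%/myr).
#' @param element_age_myr Age of planted elements in myr (scalar, recycled).
#'   Each LTR of an element accumulates `age * rate` expected substitutions
#'   per site independently.
#' @param outgroup_divergence Substitutions per site separating each outgroup
#'   from the ancestor.
#' @param min_spacing_bp Minimum distance between planted events (keeps 2-kb
#'   flanks event-free).
#' @param edge_margin_bp Events are kept this far from chromosome ends.
#'
#' @return A validated list of class `erv_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              ancestor_length_bp = 1e6,
                              n_chromosomes = 2L,
                              gc_fraction = 0.41,
                              n_full_length = 10L,
                              n_solo_ltr = 10L,
                              n_truncated = 3L,
                              n_ncpi = 2L,
                              n_decoy_shared = 0L,
                              tsd_length_range = c(2L, 5L),
                              ncpi_deletion_range_bp = c(100L, 2000L),
                              microhomology_range = c(2L, 3L),
                              microhomology_prob = 5 / 7,
                              ltr_mutation_rate = 0.0025,
                              element_age_myr = 1.5,
                              outgroup_divergence = 0.01,
                              min_spacing_bp = 5000L,
                              edge_margin_bp = 3000L) {
  cfg <- list(
    seed = as.integer(seed),
    ancestor_length_bp = as.integer(ancestor_length_bp),
    n_chromosomes = as.integer(n_chromosomes),
    gc_fraction = gc_fraction,
    n_full_length = as.integer(n_full_length),
    n_solo_ltr = as.integer(n_solo_ltr),
    n_truncated = as.integer(n_truncated),
    n_ncpi = as.integer(n_ncpi),
    n_decoy_shared = as.integer(n_decoy_shared),
    tsd_length_range = as.integer(tsd_length_range),
    ncpi_deletion_range_bp = as.integer(ncpi_deletion_range_bp),
    microhomology_range = as.integer(microhomology_range),
    microhomology_prob = microhomology_prob,
    ltr_mutation_rate = ltr_mutation_rate,
    element_age_myr = element_age_myr,
    outgroup_divergence = outgroup_divergence,
    min_spacing_bp = as.integer(min_spacing_bp),
    edge_margin_bp = as.integer(edge_margin_bp)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "erv_sim_config")
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$ancestor_length_bp > 0, "ancestor_length_bp must be positive")
  assert_that(cfg$n_chromosomes >= 1, "need at least one chromosome")
  assert_that(cfg$gc_fraction >= 0 && cfg$gc_fraction <= 1,
              "gc_fraction must be in [0, 1]")
  counts <- c(cfg$n_full_length, cfg$n_solo_ltr, cfg$n_truncated,
              cfg$n_ncpi, cfg$n_decoy_shared)
  assert_that(all(counts >= 0), "event counts must be non-negative")
  assert_that(length(cfg$tsd_length_range) == 2 &&
                cfg$tsd_length_range[1] >= 1 && cfg$tsd_length_range[2] <= 10 &&
                cfg$tsd_length_range[1] <= cfg$tsd_length_range[2],
              "tsd_length_range must be an increasing pair within [1, 10]")
  assert_that(all(cfg$ncpi_deletion_range_bp >= 0) &&
                cfg$ncpi_deletion_range_bp[1] <= cfg$ncpi_deletion_range_bp[2],
              "ncpi_deletion_range_bp must be a non-negative increasing pair")
  assert_that(all(cfg$microhomology_range >= 0) &&
                cfg$microhomology_range[1] <= cfg$microhomology_range[2],
              "microhomology_range must be a non-negative increasing pair")
  assert_that(cfg$ltr_mutation_rate >= 0 && cfg$outgroup_divergence >= 0 &&
                all(cfg$element_age_myr >= 0),
              "rates and ages must be non-negative")
  invisible(cfg)
}
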