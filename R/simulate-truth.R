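#' Simulate a genome pair set with planted ERV events and a truth ledger
#'
#' End-to-end synthetic data generator: draws an ancestral genome, optionally
#' plants pre-divergence ("shared decoy") elements, derives `k_outgroups`
#' outgroup genomes by neutral point mutation, then plants the configured
#' ingroup-specific events (full-length, solitary-LTR, truncated, NCPI) on
#' the ingroup lineage. Every planted event is recorded in a machine-readable
#' truth ledger with exact final coordinates, so downstream detection stages
#' can be scored without external data.
#'
#' Events are placed with at least `config$min_spacing_bp` pairwise spacing so
#' 2-kb flanks never overlap a neighbouring event.
#'
#' @param config An [simulation_config()].
#' @param consensus An [erv_consensus_set()]; a default two-subfamily set is
#'   built from the config seed when `NULL`.
#' @param k_outgroups Number of outgroup genomes.
#' @return An object of class `erv_truth_set`: a list with `ingroup`,
#'   `outgroups`, `ancestor` (post-decoy, pre-divergence), `ledger` (one row
#'   per ingroup event), `decoys` (ledger rows of shared elements, final
#'   ingroup coordinates), `consensus`, `config`, `chrom_lengths`.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 7, ancestor_length_bp = 2e5,
#'                          n_full_length = 2, n_solo_ltr = 2,
#'                          n_truncated = 1, n_ncpi = 1)
#' sim <- simulate_erv_truth(cfg, k_outgroups = 2)
#' nrow(sim$ledger)
simulate_erv_truth <- function(config, consensus = NULL, k_outgroups = 3L) {
  validate_sim_config(config)
  consensus <- consensus %||% erv_consensus_set(seed = sub_seed(config$seed, 7L))
  ancestor <- generate_ancestor(config)
  chrom_len0 <- setNames(Biostrings::width(ancestor), names(ancestor))

  # --- shared decoys: planted before the lineages split -------------------
  decoys <- new_event_row()
  if (config$n_decoy_shared > 0) {
    with_seed(sub_seed(config$seed, 11L), {
      sites <- sample_event_sites(
        tibble(category = rep("full_length", config$n_decoy_shared),
               deletion = 0L),
        chrom_len0, config
      )
      sites <- arrange(sites, .data$chrom, .data$site)
      off <- setNames(rep(0L, length(chrom_len0)), names(chrom_len0))
      for (i in seq_len(nrow(sites))) {
        ch <- sites$chrom[i]
        res <- plant_element(
          ancestor, ch, sites$site[i] + off[[ch]],
          consensus[sample.int(nrow(consensus), 1L), ],
          "full_length", config,
          event_id = sprintf("decoy%02d", i)
        )
        ancestor <- res$genome
        ev <- res$event
        # shared-ancestor coordinates (later decoys sort to the right, so the
        # position is final in the post-decoy ancestor)
        ev$insertion_point <- sites$site[i] + off[[ch]]
        ev$shared <- TRUE
        decoys <- bind_rows(decoys, ev)
        off[[ch]] <- off[[ch]] + ev$element_length + ev$tsd_len
      }
    })
  }
  chrom_len_anc <- setNames(Biostrings::width(ancestor), names(ancestor))

  outgroups <- if (k_outgroups >= 1) {
    derive_outgroups(ancestor, config, k_outgroups)
  } else list()

  # --- ingroup-specific events -------------------------------------------
  ingroup <- ancestor
  ledger <- new_event_row()
  with_seed(sub_seed(config$seed, 21L), {
    spec <- tibble(category = c(
      rep("full_length", config$n_full_length),
      rep("solo_ltr", config$n_solo_ltr),
      rep("truncated", config$n_truncated),
      rep("ncpi", config$n_ncpi)
    ))
    spec$deletion <- ifelse(
      spec$category == "ncpi",
      if (nrow(spec) > 0) sample(seq(config$ncpi_deletion_range_bp[1],
                                     max(config$ncpi_deletion_range_bp[1],
                                         config$ncpi_deletion_range_bp[2])),
                                 nrow(spec), replace = TRUE) else integer(),
      0L
    )
    # decoy loci also block placement
    blocked <- decoy_blocked_intervals(decoys, config)
    sites <- sample_event_sites(spec, chrom_len_anc, config, blocked)
    sites <- arrange(sites, .data$chrom, .data$site)
    offset <- setNames(rep(0L, length(chrom_len_anc)), names(chrom_len_anc))
    for (i in seq_len(nrow(sites))) {
      ch <- sites$chrom[i]
      cons_row <- consensus[sample.int(nrow(consensus), 1L), ]
      id <- sprintf("ev%03d", i)
      if (sites$category[i] == "ncpi") {
        res <- plant_ncpi(ingroup, ch, sites$site[i] + offset[[ch]], cons_row,
                          config, deletion_size = sites$deletion[i],
                          event_id = id)
        delta <- res$event$element_length - res$event$deletion_size_bp
      } else {
        res <- plant_element(ingroup, ch, sites$site[i] + offset[[ch]],
                             cons_row, sites$category[i], config,
                             event_id = id)
        delta <- res$event$element_length + res$event$tsd_len
      }
      ingroup <- res$genome
      ev <- res$event
      ev$insertion_point <- sites$site[i]  # ancestor coordinates
      ledger <- bind_rows(ledger, ev)
      offset[[ch]] <- offset[[ch]] + delta
    }
    # decoy coordinates shift under upstream ingroup insertions
    if (nrow(decoys) > 0) {
      for (j in seq_len(nrow(decoys))) {
        sh <- ledger_shift_at(ledger, decoys$chrom[j], decoys$insertion_point[j])
        for (col in c("start", "end", "ltr5_start", "ltr5_end",
                      "ltr3_start", "ltr3_end",
                      "internal_start", "internal_end")) {
          decoys[[col]][j] <- decoys[[col]][j] + sh
        }
      }
    }
  })

  structure(list(
    ingroup = ingroup, outgroups = outgroups, ancestor = ancestor,
    ledger = ledger, decoys = decoys, consensus = consensus, config = config,
    chrom_lengths = setNames(Biostrings::width(ingroup), names(ingroup))
  ), class = "erv_truth_set")
}

# total derived-genome shift accumulated by ingroup events upstream of an
# ancestor-coordinate position
ledger_shift_at <- function(ledger, chrom, anc_pos) {
  rows <- ledger[ledger$chrom == chrom & ledger$insertion_point < anc_pos, ]
  if (nrow(rows) == 0) return(0L)
  sum(ifelse(rows$category == "ncpi",
             rows$element_length - rows$deletion_size_bp,
             rows$element_length + rows$tsd_len))
}

# blocked intervals around decoys, in shared-ancestor coordinates
decoy_blocked_intervals <- function(decoys, config) {
  if (nrow(decoys) == 0) return(NULL)
  tibble(chrom = decoys$chrom,
         lo = decoys$start - config$min_spacing_bp,
         hi = decoys$end + config$min_spacing_bp)
}

# rejection-sample ancestor-coordinate insertion sites with pairwise spacing
sample_event_sites <- function(spec, chrom_len, config, blocked = NULL) {
  n <- nrow(spec)
  out <- tibble(category = spec$category, deletion = spec$deletion,
                chrom = character(n), site = integer(n),
                offset_applied = 0L)
  if (n == 0) return(out)
  iv <- blocked %||% tibble(chrom = character(), lo = integer(), hi = integer())
  margin <- config$edge_margin_bp
  sp <- config$min_spacing_bp
  chroms <- names(chrom_len)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(10000L)) {
      ch <- sample(chroms, 1L, prob = chrom_len)
      hi_max <- chrom_len[[ch]] - margin - spec$deletion[i]
      if (hi_max <= margin) next
      s <- sample.int(hi_max - margin, 1L) + margin
      lo <- s - sp
      hi <- s + spec$deletion[i] + sp
      clash <- iv$chrom == ch & iv$lo < hi & iv$hi > lo
      if (!any(clash)) {
        iv <- bind_rows(iv, tibble(chrom = ch, lo = lo, hi = hi))
        out$chrom[i] <- ch
        out$site[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not place all events; genome too small for the requested counts/spacing")
  }
  out
}
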