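# Non-classical insertions: TSD-absent, deletion-associated events, deletion
# sizing by orthologous comparison, and breakpoint microhomology scanning.

#' Call non-classical insertion candidates
#'
#' A locus is an NCPI candidate iff (a) no 2–5 bp TSD was detected AND (b)
#' the orthologous inter-flank interval in at least one mapped outgroup
#' exceeds the absence threshold — i.e. sequence present in the outgroup is
#' missing from the ingroup. Both conditions are required because 2-bp
#' duplications arise by chance in random flanks. TSD-absent loci with a
#' zero orthologous gap are retained as insertion-only NCPIs (deletion 0).
#'
#' @param anatomy Tibble from [anatomy_report()] (needs `locus_id`,
#'   `tsd_present`).
#' @param calls Output of [classify_loci()] (uses `calls` and the
#'   per-outgroup gap fields).
#' @param absence_threshold_bp Gap above this counts as an associated
#'   deletion (default 50, matching the specificity caller).
#' @return A tibble of candidates: `locus_id`, `tsd_absent`,
#'   `n_supporting_outgroups`, `max_gap_bp`, `callable`.
#' @export
call_ncpi_candidates <- function(anatomy, calls, absence_threshold_bp = 50L) {
  rows <- list()
  for (i in seq_len(nrow(calls$calls))) {
    lid <- calls$calls$locus_id[i]
    if (calls$calls$final_call[i] != "ingroup_specific") next
    an <- anatomy[anatomy$locus_id == lid, ]
    if (nrow(an) != 1) next
    per <- calls$calls$per_outgroup[[i]]
    mapped <- per[per$status == "element_absent" & !is.na(per$gap_bp), ]
    if (nrow(mapped) == 0) next  # not callable: no absent-status mapping
    gaps <- mapped$gap_bp
    deletion_support <- sum(gaps > absence_threshold_bp)
    if (!an$tsd_present) {
      rows[[length(rows) + 1L]] <- tibble(
        locus_id = lid,
        tsd_absent = TRUE,
        n_supporting_outgroups = deletion_support,
        max_gap_bp = max(gaps),
        callable = TRUE
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(locus_id = character(), tsd_absent = logical(),
                  n_supporting_outgroups = integer(), max_gap_bp = integer(),
                  callable = logical())
  }
  out
}

#' Size the deletion associated with an NCPI
#'
#' Per outgroup the deletion is the orthologous inter-flank span minus the
#' residual ingroup inter-flank span outside the element (zero when flanks
#' abut the element). The consensus is the median across outgroups;
#' disagreement above 10% of the consensus is flagged, and a single-outgroup
#' estimate carries a low-confidence flag.
#'
#' @param gaps_bp Integer vector of per-outgroup orthologous inter-flank
#'   gaps (negative gaps — overlapping flank hits — count as 0).
#' @param residual_bp Residual ingroup inter-flank span outside the element
#'   (default 0).
#' @return One-row tibble: `deletion_size_bp` (consensus),
#'   `per_outgroup_sizes` (list), `n_outgroups`, `discordant`,
#'   `low_confidence`.
#' @export
size_deletion <- function(gaps_bp, residual_bp = 0L) {
  assert_that(length(gaps_bp) >= 1, "need at least one mapped outgroup")
  sizes <- pmax(as.numeric(gaps_bp) - residual_bp, 0)
  cons <- median(sizes)
  spread <- if (length(sizes) > 1) max(sizes) - min(sizes) else 0
  # flag estimates the outgroups cannot agree on: more than 10 bp apart, or
  # more than 10% of the consensus size
  disc <- spread > 10 || (cons > 0 && spread / cons > 0.10)
  tibble(
    deletion_size_bp = cons,
    per_outgroup_sizes = list(sizes),
    n_outgroups = length(sizes),
    discordant = disc,
    low_confidence = length(sizes) < 2
  )
}

#' Scan a breakpoint junction for microhomology
#'
#' Longest exact overlap between the element terminus and the flanking
#' sequence at each breakpoint: upstream junction = suffix of the left flank
#' vs. prefix of the element; downstream junction = suffix of the element
#' vs. prefix of the right flank. Scanned up to `max_len` (default 10,
#' beyond the 2–3 bp typically observed, so the length distribution can be
#' examined).
#'
#' @param left_flank,right_flank Flanking sequences (ingroup).
#' @param element_seq The inserted element sequence (genomic orientation).
#' @param max_len Maximum overlap scanned.
#' @return One-row tibble: `left_len`, `left_seq`, `right_len`, `right_seq`,
#'   `max_len` (the larger of the two).
#' @export
scan_microhomology <- function(left_flank, element_seq, right_flank,
                               max_len = 10L) {
  ll <- suffix_prefix_overlap(left_flank, element_seq, max_len)
  rl <- suffix_prefix_overlap(element_seq, right_flank, max_len)
  tibble(
    left_len = ll,
    left_seq = if (ll > 0) substr(element_seq, 1L, ll) else NA_character_,
    right_len = rl,
    right_seq = if (rl > 0)
      substr(right_flank, 1L, rl) else NA_character_,
    max_len = max(ll, rl)
  )
}

#' Build the per-event NCPI table for a set of candidate loci
#'
#' @param candidates From [call_ncpi_candidates()].
#' @param loci The catalog (for element spans).
#' @param genome Ingroup genome.
#' @param calls [classify_loci()] output (per-outgroup gaps).
#' @param junction_bp Flank window used for microhomology scanning.
#' @return Tibble of `NcpiEvent` rows: `locus_id`, `deletion_size_bp`,
#'   breakpoints, microhomology fields, supporting outgroup count, flags.
#' @export
ncpi_events <- function(candidates, loci, genome, calls, junction_bp = 20L) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    lid <- candidates$locus_id[i]
    locus <- loci[loci$locus_id == lid, ]
    ci <- match(lid, calls$calls$locus_id)
    per <- calls$calls$per_outgroup[[ci]]
    gaps <- per$gap_bp[per$status == "element_absent" & !is.na(per$gap_bp)]
    sz <- size_deletion(gaps)
    chrom_seq <- genome[[locus$chrom]]
    lf <- as.character(Biostrings::subseq(
      chrom_seq, max(1L, locus$start - junction_bp + 1L), locus$start))
    rf <- as.character(Biostrings::subseq(
      chrom_seq, locus$end + 1L,
      min(length(chrom_seq), locus$end + junction_bp)))
    elem <- as.character(Biostrings::subseq(chrom_seq, locus$start + 1L,
                                            locus$end))
    mh <- scan_microhomology(lf, elem, rf)
    rows[[length(rows) + 1L]] <- tibble(
      locus_id = lid, tsd_absent = TRUE,
      deletion_size_bp = sz$deletion_size_bp,
      left_breakpoint = locus$start, right_breakpoint = locus$end,
      microhomology_len = mh$left_len, microhomology_seq = mh$left_seq,
      microhomology_len_right = mh$right_len,
      n_supporting_outgroups = sz$n_outgroups,
      discordant = sz$discordant, low_confidence = sz$low_confidence
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(locus_id = character(), tsd_absent = logical(),
                  deletion_size_bp = double(), left_breakpoint = integer(),
                  right_breakpoint = integer(), microhomology_len = integer(),
                  microhomology_seq = character(),
                  microhomology_len_right = integer(),
                  n_supporting_outgroups = integer(), discordant = logical(),
                  low_confidence = logical())
  }
  out
}

#' Summarize NCPI events
#'
#' Count, total deleted bases, mean deletion (half-up rounded to integer) and
#' range (max − min), the summary layout used for insertion-mediated-deletion
#' tables.
#'
#' @param events Tibble with a `deletion_size_bp` column (or a bare numeric
#'   vector of deletion sizes).
#' @return One-row tibble: `n_events`, `total_deletion_bp`,
#'   `mean_deletion_bp`, `range_deletion_bp`.
#' @export
#' @examples
#' ncpi_report(c(100, 200))
ncpi_report <- function(events) {
  sizes <- if (is.data.frame(events)) events$deletion_size_bp else events
  if (length(sizes) == 0) {
    return(tibble(n_events = 0L, total_deletion_bp = 0,
                  mean_deletion_bp = 0, range_deletion_bp = 0))
  }
  tibble(
    n_events = length(sizes),
    total_deletion_bp = sum(sizes),
    mean_deletion_bp = round_half_up(mean(sizes)),
    range_deletion_bp = max(sizes) - min(sizes)
  )
}
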