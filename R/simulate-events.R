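# Planting of ERV insertion events into a genome, with exact ground-truth
# bookkeeping. All coordinates are 0-based half-open on the genome the event
# is planted into; the orchestrator (simulate_erv_truth) tracks coordinate
# shifts when several events land on one chromosome.

new_event_row <- function() {
  tibble(
    event_id = character(), category = character(),
    structural_form = character(), chrom = character(),
    insertion_point = integer(), start = integer(), end = integer(),
    strand = character(), tsd = character(), tsd_len = integer(),
    deletion_size_bp = integer(), microhomology = character(),
    microhomology_len = integer(), subfamily = character(),
    planted_age_myr = double(), element_length = integer(),
    ltr5_start = integer(), ltr5_end = integer(),
    ltr3_start = integer(), ltr3_end = integer(),
    internal_start = integer(), internal_end = integer(),
    orf_gag = logical(), orf_pro = logical(),
    orf_pol = logical(), orf_env = logical(),
    shared = logical()
  )
}

# intact/disrupted per gene on a (possibly mutated/clipped) internal sequence,
# simple codon-run scan in the gene's own frame: a gene is intact when its
# longest stop-free run covers >= frac of the annotated gene length.
gene_intact_flags <- function(internal, gene_model, offset = 0L, frac = 0.95) {
  out <- setNames(rep(NA, 4), c("gag", "pro", "pol", "env"))
  n <- nchar(internal)
  for (i in seq_len(nrow(gene_model))) {
    g <- gene_model$gene[i]
    a <- gene_model$start[i] - offset
    b <- gene_model$end[i] - offset
    if (a < 0 || b > n) { out[g] <- NA; next }  # clipped away -> missing
    gseq <- substr0(internal, a, b)
    stops <- stop_codon_starts(gseq, 0L)
    # longest stop-free stretch (nt) between consecutive stop codons
    seg_starts <- c(1L, stops + 3L)
    seg_ends <- c(stops - 1L, nchar(gseq))
    run_len <- pmax(seg_ends - seg_starts + 1L, 0L)
    out[g] <- max(run_len) >= frac * (b - a)
  }
  out
}

# choose replacement bases at short junction windows so the realized
# hallmarks (TSD length, microhomology lengths) equal exactly what the
# ledger records; returns list(elem, right_head)
sanitize_ncpi_junction <- function(left_tail, elem, right_head, mh_len) {
  n <- nchar(left_tail)
  # plant the left-junction microhomology: element prefix := flank suffix
  if (mh_len > 0) {
    elem <- paste0(substr(left_tail, n - mh_len + 1L, n),
                   substr(elem, mh_len + 1L, nchar(elem)))
  }
  ok <- function(e, r) {
    suffix_prefix_overlap(left_tail, e, 10L) == mh_len &&
      suffix_prefix_overlap(e, r, 10L) == 0L &&
      suffix_prefix_overlap(left_tail, r, 6L) < 2L
  }
  if (ok(elem, right_head)) return(list(elem = elem, right_head = right_head))
  # brute-force the free bases: element base just after the microhomology and
  # the first two right-flank bases
  for (b1 in DNA_BASES) for (b2 in DNA_BASES) for (be in DNA_BASES) {
    e2 <- elem
    substr(e2, mh_len + 1L, mh_len + 1L) <- be
    r2 <- right_head
    substr(r2, 1L, 1L) <- b1
    substr(r2, 2L, 2L) <- b2
    if (ok(e2, r2)) return(list(elem = e2, right_head = r2))
  }
  abort("could not sanitize NCPI junction")  # not reachable for len>=3 flanks
}

#' Plant a classical ERV insertion event
#'
#' Inserts a full-length provirus, a solitary LTR, or a truncated copy at
#' `site`, duplicating the target site (TSD) as classical retroviral
#' integration does. Both LTRs are identical at integration and are then
#' mutated independently with `age_myr * ltr_mutation_rate` expected
#' substitutions per site (transition:transversion 2:1).
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param chrom Chromosome name.
#' @param site 0-based insertion point (the TSD is the `tsd_len` bases
#'   starting at `site`).
#' @param cons_row One row of an [erv_consensus_set()].
#' @param category One of `"full_length"`, `"solo_ltr"`, `"truncated"`.
#' @param config An [simulation_config()]; supplies TSD range, mutation rate
#'   and default age.
#' @param strand `"+"` or `"-"`; sampled if `NULL`.
#' @param tsd_len TSD length; sampled from `config$tsd_length_range` if
#'   `NULL`.
#' @param age_myr Element age; defaults to `config$element_age_myr`.
#' @param event_id Identifier recorded in the ledger row.
#' @return `list(genome = modified genome, event = one-row ledger tibble)`.
#' @export
plant_element <- function(genome, chrom, site, cons_row, category, config,
                          strand = NULL, tsd_len = NULL, age_myr = NULL,
                          event_id = "ev001") {
  assert_that(chrom %in% names(genome), "unknown chromosome")
  chrom_seq <- as.character(genome[[chrom]])
  L <- nchar(chrom_seq)
  assert_that(site > 10 && site < L - 10, "site outside usable genome range")
  assert_that(category %in% c("full_length", "solo_ltr", "truncated"),
              "unknown category")
  strand <- strand %||% sample(c("+", "-"), 1L)
  tsd_len <- tsd_len %||%
    sample(seq(config$tsd_length_range[1], config$tsd_length_range[2]), 1L)
  age_myr <- age_myr %||% config$element_age_myr
  p <- age_myr * config$ltr_mutation_rate

  ltr5 <- mutate_dna_chr(cons_row$ltr, p)
  ltr3 <- mutate_dna_chr(cons_row$ltr, p)
  internal <- mutate_dna_chr(cons_row$internal, p)
  gm <- cons_row$gene_model[[1]]

  # element-strand part list with local spans
  orf <- setNames(rep(NA, 4), c("gag", "pro", "pol", "env"))
  if (category == "full_length") {
    parts <- list(ltr5 = ltr5, internal = internal, ltr3 = ltr3)
    orf <- gene_intact_flags(internal, gm)
  } else if (category == "solo_ltr") {
    parts <- list(ltr5 = ltr5)
  } else {
    # clip from one end: keep one LTR plus part of the internal region
    side <- sample(c("5p", "3p"), 1L)
    keep <- floor(nchar(internal) * runif(1, 0.3, 0.8))
    if (side == "3p") {
      # 3'-truncated: 5'LTR + leading internal retained
      parts <- list(ltr5 = ltr5, internal = substr(internal, 1L, keep))
    } else {
      # 5'-truncated: trailing internal + 3'LTR retained
      parts <- list(internal = substr(internal, nchar(internal) - keep + 1L,
                                      nchar(internal)),
                    ltr3 = ltr3)
    }
  }
  elem <- paste(unlist(parts), collapse = "")
  if (strand == "-") elem <- revcomp_chr(elem)
  elen <- nchar(elem)

  tsd <- if (tsd_len > 0) substr0(chrom_seq, site, site + tsd_len) else ""
  left <- substr(chrom_seq, 1L, site + tsd_len)
  right <- substr(chrom_seq, site + 1L, L)
  derived <- paste0(left, elem, right)
  e_start <- site + tsd_len          # 0-based element start in derived coords
  e_end <- e_start + elen

  # junction hygiene: keep the realized TSD exactly tsd_len long. Chance
  # matches between the bases upstream of the target site and those
  # downstream of the second TSD copy can extend the apparent duplication
  # (periodic sequence); substitute downstream bases until the longest
  # apparent duplication equals the planted length.
  if (tsd_len > 0) {
    w <- 8L
    for (iter in seq_len(20L)) {
      lt <- substr0(derived, e_start - w, e_start)
      rh <- substr0(derived, e_end, min(e_end + w, nchar(derived)))
      realized <- suffix_prefix_overlap(lt, rh, w)
      if (realized <= tsd_len) break
      pos <- e_end + realized  # 1-based position of the last matched base
      cur <- substr(derived, pos, pos)
      avoid <- c(cur, substr(lt, nchar(lt), nchar(lt)),
                 substr(lt, nchar(lt) - 1L, nchar(lt) - 1L))
      substr(derived, pos, pos) <- setdiff(DNA_BASES, avoid)[1]
    }
  }

  # genomic spans of the parts (account for strand orientation)
  part_lens <- vapply(parts, nchar, integer(1))
  ord <- if (strand == "+") names(parts) else rev(names(parts))
  lens <- part_lens[ord]
  starts <- e_start + c(0L, cumsum(lens))[seq_along(lens)]
  spans <- tibble(part = ord, start = as.integer(starts),
                  end = as.integer(starts + lens))
  span_of <- function(p) {
    i <- match(p, spans$part)
    if (is.na(i)) c(NA_integer_, NA_integer_) else c(spans$start[i], spans$end[i])
  }
  s5 <- span_of("ltr5"); s3 <- span_of("ltr3"); si <- span_of("internal")

  genome[[chrom]] <- derived
  ev <- tibble(
    event_id = event_id, category = category, structural_form = category,
    chrom = chrom, insertion_point = as.integer(site),
    start = as.integer(e_start), end = as.integer(e_end), strand = strand,
    tsd = tsd, tsd_len = as.integer(tsd_len),
    deletion_size_bp = 0L, microhomology = NA_character_,
    microhomology_len = 0L, subfamily = cons_row$subfamily,
    planted_age_myr = age_myr, element_length = as.integer(elen),
    ltr5_start = s5[1], ltr5_end = s5[2],
    ltr3_start = s3[1], ltr3_end = s3[2],
    internal_start = si[1], internal_end = si[2],
    orf_gag = unname(orf["gag"]), orf_pro = unname(orf["pro"]),
    orf_pol = unname(orf["pol"]), orf_env = unname(orf["env"]),
    shared = FALSE
  )
  list(genome = genome, event = ev)
}

#' Plant a non-classical ERV insertion (NCPI)
#'
#' Replaces a genomic segment of `deletion_size` bases at `site` with the
#' element (full provirus or solitary LTR), without target-site duplication.
#' With probability `config$microhomology_prob` the upstream junction shares
#' a short microhomology between the flank end and the element start, as
#' expected from end-joining repair of a double-strand break.
#'
#' @inheritParams plant_element
#' @param deletion_size Deleted bases; sampled from
#'   `config$ncpi_deletion_range_bp` if `NULL`.
#' @param microhomology_len Junction microhomology length; sampled per config
#'   if `NULL` (0 = blunt junction).
#' @param structural_form `"full_length"` or `"solo_ltr"`; sampled if `NULL`.
#' @return `list(genome, event)` as for [plant_element()].
#' @export
plant_ncpi <- function(genome, chrom, site, cons_row, config,
                       deletion_size = NULL, microhomology_len = NULL,
                       structural_form = NULL, strand = NULL, age_myr = NULL,
                       event_id = "ev001") {
  assert_that(chrom %in% names(genome), "unknown chromosome")
  chrom_seq <- as.character(genome[[chrom]])
  L <- nchar(chrom_seq)
  deletion_size <- deletion_size %||%
    sample(seq(config$ncpi_deletion_range_bp[1],
               config$ncpi_deletion_range_bp[2]), 1L)
  assert_that(site > 10 && site + deletion_size < L - 10,
              "deletion window does not fit inside the chromosome")
  microhomology_len <- microhomology_len %||%
    (if (runif(1) < config$microhomology_prob)
       sample(seq(config$microhomology_range[1],
                  config$microhomology_range[2]), 1L) else 0L)
  structural_form <- structural_form %||%
    sample(c("full_length", "solo_ltr"), 1L, prob = c(3, 4))
  strand <- strand %||% sample(c("+", "-"), 1L)
  age_myr <- age_myr %||% config$element_age_myr
  p <- age_myr * config$ltr_mutation_rate

  ltr5 <- mutate_dna_chr(cons_row$ltr, p)
  if (structural_form == "full_length") {
    parts <- list(ltr5 = ltr5,
                  internal = mutate_dna_chr(cons_row$internal, p),
                  ltr3 = mutate_dna_chr(cons_row$ltr, p))
  } else {
    parts <- list(ltr5 = ltr5)
  }
  elem <- paste(unlist(parts), collapse = "")
  if (strand == "-") elem <- revcomp_chr(elem)

  left <- substr(chrom_seq, 1L, site)
  right <- substr(chrom_seq, site + deletion_size + 1L, L)
  fixed <- sanitize_ncpi_junction(
    left_tail = substr(left, max(1L, site - 19L), site),
    elem = elem,
    right_head = substr(right, 1L, min(20L, nchar(right))),
    mh_len = microhomology_len
  )
  elem <- fixed$elem
  right <- paste0(fixed$right_head, substr(right, nchar(fixed$right_head) + 1L,
                                           nchar(right)))
  elen <- nchar(elem)
  derived <- paste0(left, elem, right)
  e_start <- site
  e_end <- site + elen

  part_lens <- vapply(parts, nchar, integer(1))
  ord <- if (strand == "+") names(parts) else rev(names(parts))
  lens <- part_lens[ord]
  starts <- e_start + c(0L, cumsum(lens))[seq_along(lens)]
  spans <- tibble(part = ord, start = as.integer(starts),
                  end = as.integer(starts + lens))
  span_of <- function(pp) {
    i <- match(pp, spans$part)
    if (is.na(i)) c(NA_integer_, NA_integer_) else c(spans$start[i], spans$end[i])
  }
  s5 <- span_of("ltr5"); s3 <- span_of("ltr3"); si <- span_of("internal")

  # sanitation operates on the final (genomic-orientation) inserted sequence,
  # so the recorded microhomology is the genomic upstream-junction sequence
  # for either strand
  mh_seq <- if (microhomology_len > 0)
    substr(elem, 1L, microhomology_len) else NA_character_

  genome[[chrom]] <- derived
  ev <- tibble(
    event_id = event_id, category = "ncpi", structural_form = structural_form,
    chrom = chrom, insertion_point = as.integer(site),
    start = as.integer(e_start), end = as.integer(e_end), strand = strand,
    tsd = NA_character_, tsd_len = 0L,
    deletion_size_bp = as.integer(deletion_size),
    microhomology = mh_seq, microhomology_len = as.integer(microhomology_len),
    subfamily = cons_row$subfamily, planted_age_myr = age_myr,
    element_length = as.integer(elen),
    ltr5_start = s5[1], ltr5_end = s5[2],
    ltr3_start = s3[1], ltr3_end = s3[2],
    internal_start = si[1], internal_end = si[2],
    orf_gag = NA, orf_pro = NA, orf_pol = NA, orf_env = NA,
    shared = FALSE
  )
  list(genome = genome, event = ev)
}
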