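# Lineage specificity: extract flanks around each candidate locus, locate
# them in each outgroup genome by exact-k-mer seeding plus banded extension
# (pairwise alignment of the flank against a candidate window), and decide
# per locus whether the element is ingroup-specific, shared, or unresolved.

#' Extract flanking sequences of a locus
#'
#' Returns the sequences immediately outside the locus span (default 2 kb a
#' side), clipped at chromosome ends with the clip recorded.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param locus One catalog row (needs `chrom`, `start`, `end`).
#' @param flank_bp Flank length per side (>= 1).
#' @return A tibble with one row per side: `side`, `start`, `end` (0-based
#'   half-open), `seq`, `clipped`.
#' @export
extract_flanks <- function(genome, locus, flank_bp = 2000L) {
  assert_that(flank_bp >= 1, "flank_bp must be >= 1")
  assert_that(locus$chrom %in% names(genome), "locus chromosome not in genome")
  L <- length(genome[[locus$chrom]])
  assert_that(locus$start >= 0 && locus$end <= L && locus$start < locus$end,
              "locus span outside genome")
  ls <- max(0L, locus$start - flank_bp)
  rs <- locus$end
  re <- min(L, locus$end + flank_bp)
  chrom_seq <- genome[[locus$chrom]]
  tibble(
    side = c("left", "right"),
    start = c(ls, rs), end = c(locus$start, re),
    seq = c(as.character(Biostrings::subseq(chrom_seq, ls + 1L, locus$start)),
            as.character(Biostrings::subseq(chrom_seq, rs + 1L, re))),
    clipped = c(ls > locus$start - flank_bp, re < locus$end + flank_bp)
  )
}

# Seed index: exact k-mer hits of many query seeds against one genome, via a
# constant-width PDict scanned once per chromosome (both strands).
seed_hits <- function(seeds_tbl, genome, k) {
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds_tbl$kmer))
  out <- list()
  for (ch in names(genome)) {
    m <- Biostrings::matchPDict(pd, genome[[ch]])
    si <- Biostrings::startIndex(m)
    cnt <- lengths(si)
    if (sum(cnt) == 0) next
    idx <- rep.int(seq_along(cnt), cnt)
    st <- unlist(si, use.names = FALSE)
    out[[length(out) + 1L]] <- tibble(
      seed = idx, chrom = ch, pos = as.integer(st) - 1L
    )
  }
  if (length(out) == 0) return(tibble(seed = integer(), chrom = character(),
                                      pos = integer()))
  bind_rows(out)
}

#' Map locus flanks onto an outgroup genome
#'
#' Anchored local alignment: exact `k`-mer seeds sampled along each flank are
#' located genome-wide in one multi-pattern scan; the modal seed diagonal
#' nominates a candidate window, and the flank is then aligned against that
#' window (pattern-global alignment, so terminal mismatches do not trim the
#' mapped interval). A flank maps when alignment identity is at least
#' `min_identity` over at least `min_cov` of its length.
#'
#' @param flanks Tibble with columns `locus_id`, `side`, `seq` (e.g. built
#'   from [extract_flanks()] rows).
#' @param outgroup Named [Biostrings::DNAStringSet].
#' @param min_identity Minimum alignment identity (default 0.85).
#' @param min_cov Minimum aligned fraction of the flank (default 0.5).
#' @param k Seed length (default 16).
#' @param seed_stride Spacing of seed start positions along the flank.
#' @return A tibble per (locus_id, side): `mapped`, `chrom`, `start`, `end`
#'   (0-based half-open in the outgroup), `identity`, `coverage`.
#' @export
map_flanks <- function(flanks, outgroup, min_identity = 0.85, min_cov = 0.5,
                       k = 16L, seed_stride = 150L) {
  assert_that(all(nchar(flanks$seq) > 0), "flanks must be non-empty")
  seeds <- list()
  for (i in seq_len(nrow(flanks))) {
    s <- flanks$seq[i]
    starts <- unique(pmin(seq(1L, max(1L, nchar(s) - k + 1L), by = seed_stride),
                          nchar(s) - k + 1L))
    starts <- starts[starts >= 1]
    seeds[[i]] <- tibble(flank = i, offset = starts - 1L,
                         kmer = substring(s, starts, starts + k - 1L))
  }
  seeds <- bind_rows(seeds)
  seeds <- seeds[!grepl("[^ACGT]", seeds$kmer), ]
  hits <- seed_hits(seeds, outgroup, k)
  res <- list()
  for (i in seq_len(nrow(flanks))) {
    fl_seq <- flanks$seq[i]
    sub <- hits[seeds$flank[hits$seed] == i, ]
    row <- tibble(locus_id = flanks$locus_id[i], side = flanks$side[i],
                  mapped = FALSE, chrom = NA_character_,
                  start = NA_integer_, end = NA_integer_,
                  identity = NA_real_, coverage = NA_real_)
    if (nrow(sub) > 0) {
      # candidate flank start = hit position - seed offset; take the modal
      # (chrom, diagonal) cluster
      sub$diag <- sub$pos - seeds$offset[sub$seed]
      key <- paste(sub$chrom, round(sub$diag / 50))
      best_key <- names(sort(table(key), decreasing = TRUE))[1]
      cand <- sub[key == best_key, ]
      ch <- cand$chrom[1]
      est <- as.integer(round(median(cand$diag)))
      pad <- 100L
      w_lo <- max(0L, est - pad)
      w_hi <- min(length(outgroup[[ch]]), est + nchar(fl_seq) + pad)
      window <- Biostrings::subseq(outgroup[[ch]], w_lo + 1L, w_hi)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(fl_seq), window, type = "global-local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1),
        gapOpening = 5, gapExtension = 2
      )
      ident <- Biostrings::pid(pa) / 100
      subj <- Biostrings::subject(pa)
      s0 <- w_lo + Biostrings::start(subj) - 1L
      e0 <- w_lo + Biostrings::end(subj)
      cov <- Biostrings::nchar(pa) / nchar(fl_seq)
      if (ident >= min_identity && cov >= min_cov) {
        row$mapped <- TRUE
        row$chrom <- ch
        row$start <- as.integer(s0)
        row$end <- as.integer(e0)
        row$identity <- ident
        row$coverage <- min(cov, 1)
      }
    }
    res[[i]] <- row
  }
  bind_rows(res)
}

# identity of the best local alignment of `query` against `ref`, as a
# fraction of query length actually aligned, plus aligned query fraction
consensus_gap_match <- function(gap_seq, consensus_seqs, min_identity) {
  if (nchar(gap_seq) < 30) return(FALSE)
  # a 2-kb prefix is ample to recognize the element; keeps the local
  # alignment cheap for multi-kb gaps
  gap_seq <- substr(gap_seq, 1L, 2000L)
  queries <- list(Biostrings::DNAString(gap_seq),
                  Biostrings::reverseComplement(Biostrings::DNAString(gap_seq)))
  for (q in queries) for (cs in consensus_seqs) {
    pa <- Biostrings::pairwiseAlignment(
      q, Biostrings::DNAString(cs), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 5, gapExtension = 2
    )
    ident <- Biostrings::pid(pa) / 100
    covered <- Biostrings::nchar(pa) / nchar(gap_seq)
    if (ident >= min_identity && covered >= 0.5) return(TRUE)
  }
  FALSE
}

#' Call lineage specificity of one locus against mapped outgroups
#'
#' Per outgroup, the inter-flank gap at the orthologous position decides the
#' status: a gap no larger than `absence_threshold_bp` means the element is
#' absent there; a gap of at least `presence_margin` times the element length
#' whose sequence aligns to the element consensus means the element is
#' present (shared); a large gap that does not resemble the element is host
#' sequence missing from the ingroup (deletion evidence) and counts as
#' absent; anything else is ambiguous. Both flanks must map on the same
#' chromosome and strand within `10 * element_length` for a status call.
#'
#' Final call: `ingroup_specific` when at least one outgroup mapped and every
#' mapped outgroup lacks the element; `shared` when any outgroup carries it;
#' `unresolved` when no outgroup mapped.
#'
#' @param mappings Tibble of per-outgroup mapping rows for one locus:
#'   columns `outgroup`, `side`, `mapped`, `chrom`, `start`, `end`.
#' @param outgroups Named list of outgroup genomes (to extract gap sequence).
#' @param element_length Locus span length in the ingroup.
#' @param consensus_seqs Character vector of consensus element sequences
#'   (LTR and/or full provirus) for the gap-vs-element check.
#' @param presence_margin Fraction of `element_length` a gap must reach to
#'   count as element presence (default 0.5).
#' @param absence_threshold_bp Gap at or below this is element absence
#'   (default 50).
#' @param min_identity Identity for the gap-vs-consensus check.
#' @return A tibble with one row per outgroup (`status`, `gap_bp`, mapped
#'   interval) plus attributes; `final_call` is in the `final_call` column
#'   (same value every row).
#' @export
call_specificity <- function(mappings, outgroups, element_length,
                             consensus_seqs, presence_margin = 0.5,
                             absence_threshold_bp = 50L,
                             min_identity = 0.85) {
  out <- list()
  for (og in unique(mappings$outgroup)) {
    mm <- mappings[mappings$outgroup == og, ]
    left <- mm[mm$side == "left", ]
    right <- mm[mm$side == "right", ]
    status <- "unmapped"
    gap <- NA_integer_
    g_chrom <- NA_character_
    g_start <- NA_integer_
    g_end <- NA_integer_
    if (nrow(left) == 1 && nrow(right) == 1 && left$mapped && right$mapped &&
        identical(left$chrom, right$chrom)) {
      gap <- right$start - left$end
      if (abs(gap) <= 10 * element_length) {
        g_chrom <- left$chrom
        g_start <- left$end
        g_end <- right$start
        if (gap <= absence_threshold_bp) {
          status <- "element_absent"
        } else {
          gap_seq <- as.character(Biostrings::subseq(
            outgroups[[og]][[g_chrom]], g_start + 1L, g_end))
          is_elem <- consensus_gap_match(gap_seq, consensus_seqs, min_identity)
          if (is_elem && gap >= presence_margin * element_length) {
            status <- "element_present"
          } else if (is_elem) {
            status <- "unmapped"  # partial element-like gap: ambiguous
          } else {
            # host sequence present in outgroup, missing in ingroup:
            # element absent, with an associated deletion
            status <- "element_absent"
          }
        }
      }
    }
    out[[length(out) + 1L]] <- tibble(
      outgroup = og, status = status, gap_bp = gap,
      chrom = g_chrom, gap_start = g_start, gap_end = g_end
    )
  }
  res <- bind_rows(out)
  final <- if (any(res$status == "element_present")) {
    "shared"
  } else if (any(res$status == "element_absent")) {
    "ingroup_specific"
  } else {
    "unresolved"
  }
  mutate(res, final_call = final)
}

#' Classify every catalog locus as ingroup-specific or shared
#'
#' Batch driver: extracts flanks for all loci, maps them onto each outgroup,
#' and calls specificity per locus.
#'
#' @param genome Ingroup genome ([Biostrings::DNAStringSet]).
#' @param loci An `erv_catalog` from [defragment()].
#' @param outgroups Named list of outgroup genomes.
#' @param consensus An [erv_consensus_set()] (or tibble with `ltr`,
#'   `internal` columns) used for the gap-vs-element check.
#' @param flank_bp Flank length (default 2000).
#' @inheritParams call_specificity
#' @inheritParams map_flanks
#' @return A list with `calls` (one row per locus: `locus_id`, `final_call`,
#'   per-outgroup statuses nested in `per_outgroup`) and `mappings` (per
#'   locus x outgroup x side).
#' @export
classify_loci <- function(genome, loci, outgroups, consensus,
                          flank_bp = 2000L, min_identity = 0.85,
                          min_cov = 0.5, presence_margin = 0.5,
                          absence_threshold_bp = 50L, k = 16L) {
  cons_seqs <- c(consensus$ltr,
                 stats::na.omit(consensus$internal))
  flank_rows <- list()
  for (i in seq_len(nrow(loci))) {
    fl <- extract_flanks(genome, loci[i, ], flank_bp)
    fl$locus_id <- loci$locus_id[i]
    flank_rows[[i]] <- fl
  }
  flanks <- bind_rows(flank_rows)
  map_all <- list()
  for (og in names(outgroups)) {
    m <- map_flanks(flanks[, c("locus_id", "side", "seq")], outgroups[[og]],
                    min_identity = min_identity, min_cov = min_cov, k = k)
    m$outgroup <- og
    map_all[[og]] <- m
  }
  mappings <- bind_rows(map_all)
  calls <- list()
  for (i in seq_len(nrow(loci))) {
    lid <- loci$locus_id[i]
    mm <- mappings[mappings$locus_id == lid, ]
    res <- call_specificity(mm, outgroups,
                            element_length = loci$end[i] - loci$start[i],
                            consensus_seqs = cons_seqs,
                            presence_margin = presence_margin,
                            absence_threshold_bp = absence_threshold_bp,
                            min_identity = min_identity)
    calls[[i]] <- tibble(locus_id = lid, final_call = res$final_call[1],
                         n_mapped = sum(res$status != "unmapped"),
                         per_outgroup = list(res))
  }
  list(calls = bind_rows(calls), mappings = mappings, flanks = flanks)
}
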