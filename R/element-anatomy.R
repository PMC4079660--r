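# Per-locus anatomy: target-site duplications, LTR pairs, reading-frame
# screens for retrotransposition competence.

#' Detect the target-site duplication of a locus
#'
#' Classical retroviral integration duplicates 2–5 bp of the target site, so
#' an exact direct repeat ending immediately 5' of the element and beginning
#' immediately 3' of it is the hallmark of LTR-mediated insertion. The
#' longest such duplication with length in `[min_len, max_len]` is reported;
#' `max_len` defaults to 6 — one more than the classical range — so overlong
#' duplications are observed rather than silently capped.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param locus One catalog row (`chrom`, `start`, `end`).
#' @param min_len Minimum duplication length to call presence (default 2).
#' @param max_len Search window (default 6).
#' @return A one-row tibble: `present`, `length`, `sequence`,
#'   `search_window_bp`, `clipped` (flank shorter than the window at a
#'   chromosome end).
#' @export
detect_tsd <- function(genome, locus, min_len = 2L, max_len = 6L) {
  chrom_seq <- genome[[locus$chrom]]
  L <- length(chrom_seq)
  assert_that(locus$start >= 0 && locus$end <= L && locus$start < locus$end,
              "locus coordinates invalid")
  wl <- min(max_len, locus$start)
  wr <- min(max_len, L - locus$end)
  clipped <- wl < max_len || wr < max_len
  left <- if (wl > 0) as.character(
    Biostrings::subseq(chrom_seq, locus$start - wl + 1L, locus$start)) else ""
  right <- if (wr > 0) as.character(
    Biostrings::subseq(chrom_seq, locus$end + 1L, locus$end + wr)) else ""
  best <- 0L
  for (k in seq_len(min(nchar(left), nchar(right)))) {
    if (substr(left, nchar(left) - k + 1L, nchar(left)) ==
        substr(right, 1L, k)) best <- k
  }
  tibble(
    present = best >= min_len,
    length = if (best >= min_len) best else 0L,
    sequence = if (best >= min_len)
      substr(right, 1L, best) else NA_character_,
    search_window_bp = max_len,
    clipped = clipped
  )
}

#' Extract the LTR pair of a full-length locus
#'
#' Returns both LTR sequences oriented 5'→3' relative to the element strand
#' (minus-strand loci are reverse-complemented), ready for divergence dating.
#'
#' @param locus One catalog row with LTR spans
#'   (`ltr5_start`/`ltr5_end`/`ltr3_start`/`ltr3_end`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @return `list(ltr5 =, ltr3 =)` character sequences, or `NULL` when the
#'   locus is not full-length.
#' @export
pair_ltrs <- function(locus, genome) {
  if (!identical(locus$category, "full_length") ||
      is.na(locus$ltr5_start) || is.na(locus$ltr3_start)) {
    return(NULL)
  }
  chrom_seq <- genome[[locus$chrom]]
  g5 <- as.character(Biostrings::subseq(chrom_seq, locus$ltr5_start + 1L,
                                        locus$ltr5_end))
  g3 <- as.character(Biostrings::subseq(chrom_seq, locus$ltr3_start + 1L,
                                        locus$ltr3_end))
  if (identical(locus$strand, "-")) {
    list(ltr5 = revcomp_chr(g5), ltr3 = revcomp_chr(g3))
  } else {
    list(ltr5 = g5, ltr3 = g3)
  }
}

#' Screen internal reading frames for retrotransposition competence
#'
#' Translates the element-strand internal sequence in all three frames and
#' asks, per gene of the proviral gene model (*gag*, *pro*, *pol*, *env*),
#' whether some single-frame stop-free stretch covers at least
#' `intact_fraction` of the consensus gene length within (±10% positional
#' tolerance of) the expected span. A gene whose span lies outside the
#' available sequence is `missing`; one present but interrupted by stops or
#' frameshifts is `disrupted`. The element is retrotransposition-competent
#' (`rc_flag`) when all four genes are intact.
#'
#' @param internal_seq Element-strand internal sequence (character). `NA` or
#'   empty means no internal sequence: all genes `missing`.
#' @param gene_model Tibble `gene`, `start`, `end` (0-based half-open on the
#'   consensus internal sequence).
#' @param intact_fraction Coverage threshold (default 0.95).
#' @return A one-row tibble: per-gene status columns (`gag`, `pro`, `pol`,
#'   `env`), `rc_flag`, and per-gene longest-ORF fractions in a list-column
#'   `orf_fraction`.
#' @export
screen_orfs <- function(internal_seq, gene_model, intact_fraction = 0.95) {
  genes <- c("gag", "pro", "pol", "env")
  status <- setNames(rep("missing", 4), genes)
  fractions <- setNames(rep(0, 4), genes)
  if (!is.na(internal_seq) && nzchar(internal_seq)) {
    n <- nchar(internal_seq)
    tol <- 0.10
    # stop-free intervals per frame, in nt coordinates (0-based half-open)
    frame_runs <- lapply(0:2, function(f) {
      stops <- stop_codon_starts(internal_seq, f)
      run_starts <- c(f, stops + 2L)          # 0-based start after each stop
      run_ends <- c(stops - 1L, n)            # 0-based end before each stop
      tibble(start = run_starts, end = pmax(run_ends, run_starts))
    })
    for (i in seq_len(nrow(gene_model))) {
      g <- gene_model$gene[i]
      glen <- gene_model$end[i] - gene_model$start[i]
      a <- gene_model$start[i]
      b <- gene_model$end[i]
      # positional tolerance: the span counts as present if the sequence
      # reaches to within 10% of the gene length of its boundaries
      if (a > n - (1 - tol) * glen || b - tol * glen > n || b - a <= 0) {
        status[g] <- "missing"
        next
      }
      cov <- 0
      for (runs in frame_runs) {
        ol <- pmin(runs$end, b) - pmax(runs$start, a)
        cov <- max(cov, max(c(ol, 0)))
      }
      fractions[g] <- cov / glen
      status[g] <- if (cov >= intact_fraction * glen) "intact" else "disrupted"
    }
  }
  tibble(
    gag = status[["gag"]], pro = status[["pro"]],
    pol = status[["pol"]], env = status[["env"]],
    rc_flag = all(status == "intact"),
    orf_fraction = list(fractions)
  )
}

#' Per-locus anatomy report
#'
#' Runs TSD detection, LTR pairing (with per-element 5'↔3' LTR divergence)
#' and the reading-frame screen over a catalog of ingroup-specific loci.
#'
#' @param genome Ingroup genome.
#' @param loci An `erv_catalog`.
#' @param consensus An [erv_consensus_set()] supplying gene models per
#'   subfamily.
#' @param intact_fraction Passed to [screen_orfs()].
#' @return A tibble, one row per locus: TSD fields, `ltr_divergence` (K2P
#'   between the two LTRs, `NA` for non-full-length), per-gene statuses,
#'   `rc_flag`.
#' @export
anatomy_report <- function(genome, loci, consensus, intact_fraction = 0.95) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    tsd <- detect_tsd(genome, locus)
    lp <- pair_ltrs(locus, genome)
    ltr_div <- NA_real_
    if (!is.null(lp)) {
      al <- align_pair(lp$ltr5, lp$ltr3)
      ltr_div <- k2p(al[1], al[2])$d
    }
    internal_seq <- NA_character_
    if (!is.na(locus$internal_start)) {
      s <- as.character(Biostrings::subseq(genome[[locus$chrom]],
                                           locus$internal_start + 1L,
                                           locus$internal_end))
      internal_seq <- if (identical(locus$strand, "-")) revcomp_chr(s) else s
    }
    gm_row <- match(locus$subfamily, consensus$subfamily)
    orf <- if (!is.na(gm_row)) {
      screen_orfs(internal_seq, consensus$gene_model[[gm_row]],
                  intact_fraction)
    } else {
      screen_orfs(NA_character_, tibble(gene = character(), start = integer(),
                                        end = integer()))
    }
    rows[[i]] <- tibble(
      locus_id = locus$locus_id, category = locus$category,
      tsd_present = tsd$present, tsd_len = tsd$length,
      tsd_seq = tsd$sequence, ltr_divergence = ltr_div,
      gag = orf$gag, pro = orf$pro, pol = orf$pol, env = orf$env,
      rc_flag = orf$rc_flag
    )
  }
  bind_rows(rows)
}
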