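#' Parse a RepeatMasker .out annotation file
#'
#' Reads the standard 15-column whitespace-delimited format (three header
#' lines, then one row per repeat fragment). Query coordinates are converted
#' from 1-based inclusive to 0-based half-open; strand `C` becomes `-`.
#'
#' @param path Path to a `.out` file.
#' @param name_filter Optional regular expression; rows whose repeat name
#'   does not match are dropped (the classical `repName = "PtERV"`-style
#'   filter). `NULL` keeps everything.
#' @return A tibble of repeat hits: `hit_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `repeat_name`, `repeat_class`,
#'   `divergence_pct`, `rm_id`.
#' @export
#' @examples
#' \dontrun{
#' hits <- parse_repeatmasker_out("genome.fa.out", name_filter = "^PtERV|^CERV")
#' }
parse_repeatmasker_out <- function(path, name_filter = NULL) {
  lines <- readLines(path)
  empty_cols <- tibble(
    hit_id = integer(), chrom = character(), start = integer(),
    end = integer(), strand = character(), repeat_name = character(),
    repeat_class = character(), divergence_pct = double(), rm_id = character()
  )
  if (length(lines) <= 3) return(empty_cols)
  body_idx <- seq(4L, length(lines))
  rows <- list()
  for (k in body_idx) {
    ln <- trimws(lines[k])
    if (ln == "") next
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < 14L) {
      abort(sprintf("malformed .out row at line %d: expected >= 14 fields, got %d",
                    k, length(f)))
    }
    start1 <- suppressWarnings(as.integer(f[6]))
    end1 <- suppressWarnings(as.integer(f[7]))
    div <- suppressWarnings(as.numeric(f[2]))
    if (is.na(start1) || is.na(end1) || start1 > end1) {
      abort(sprintf("malformed .out row at line %d: bad coordinates", k))
    }
    strand <- if (f[9] %in% c("C", "-")) "-" else "+"
    rows[[length(rows) + 1L]] <- tibble(
      chrom = f[5], start = start1 - 1L, end = end1, strand = strand,
      repeat_name = f[10], repeat_class = f[11], divergence_pct = div,
      rm_id = f[length(f)]
    )
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0) return(empty_cols)
  if (!is.null(name_filter)) {
    hits <- filter(hits, grepl(name_filter, .data$repeat_name))
  }
  mutate(hits, hit_id = row_number(), .before = 1)
}

# classify a merged run of fragments into a structural category
classify_fragment_run <- function(kinds) {
  n_ltr <- sum(kinds == "ltr")
  n_int <- sum(kinds == "internal")
  first_last_ltr <- length(kinds) >= 3 && kinds[1] == "ltr" &&
    kinds[length(kinds)] == "ltr" && n_int >= 1
  if (first_last_ltr && n_ltr == 2) return("full_length")
  if (n_ltr == 1 && n_int == 0) return("solo_ltr")
  if (n_int >= 1 && n_ltr <= 1) return("truncated")
  "unknown"
}

#' Defragment repeat hits into candidate proviral loci
#'
#' Merges same-strand, same-family LTR/internal fragments whose gaps are at
#' most `max_gap_bp` into single loci and assigns each a structural category:
#' `full_length` (LTR–internal–LTR), `solo_ltr` (a single LTR),
#' `truncated` (internal sequence with at most one LTR), or `unknown`
#' (anything else, e.g. two LTRs with no internal sequence, or inconsistent
#' family labels).
#'
#' Hits whose repeat name matches neither the LTR nor the internal pattern are
#' dropped with a warning. When one fragment is nested inside another, the
#' longer fragment is kept.
#'
#' @param hits Tibble from [parse_repeatmasker_out()].
#' @param max_gap_bp Maximum intra-locus gap between fragments (default
#'   1000).
#' @param ltr_pattern,internal_pattern Regular expressions telling LTR from
#'   internal fragments by repeat name.
#' @return A tibble of loci (`locus_id`, `chrom`, `start`, `end`, `strand`,
#'   `category`, `subfamily`, LTR and internal spans, `n_hits`,
#'   `member_hit_ids` list-column), classed `erv_catalog`.
#' @export
defragment <- function(hits, max_gap_bp = 1000L,
                       ltr_pattern = "[-_]LTR$",
                       internal_pattern = "[-_](int|I)$") {
  kinds <- dplyr::case_when(
    grepl(ltr_pattern, hits$repeat_name) ~ "ltr",
    grepl(internal_pattern, hits$repeat_name) ~ "internal",
    TRUE ~ "unknown"
  )
  if (any(kinds == "unknown")) {
    warn(sprintf("ignoring %d hit(s) with unrecognized repeat names (e.g. %s)",
                 sum(kinds == "unknown"),
                 hits$repeat_name[kinds == "unknown"][1]))
  }
  hits <- hits[kinds != "unknown", ]
  hits$kind <- kinds[kinds != "unknown"]
  hits$family <- sub("[-_](LTR|int|I)$", "", hits$repeat_name)
  hits <- arrange(hits, .data$chrom, .data$strand, .data$start, -.data$end)

  loci <- list()
  for (grp in split(hits, interaction(hits$chrom, hits$strand, drop = TRUE))) {
    grp <- arrange(grp, .data$start, -.data$end)
    # drop fragments nested inside a longer fragment (keep the longer)
    keep <- rep(TRUE, nrow(grp))
    max_end <- -1L
    for (i in seq_len(nrow(grp))) {
      if (grp$end[i] <= max_end) keep[i] <- FALSE
      max_end <- max(max_end, grp$end[i])
    }
    grp <- grp[keep, ]
    # chain fragments with gap <= max_gap_bp
    run_id <- cumsum(c(1L, (grp$start[-1] - grp$end[-nrow(grp)]) > max_gap_bp))
    for (run in split(grp, run_id)) {
      fam <- unique(run$family)
      subfam <- if (length(fam) == 1L) fam else {
        tb <- sort(table(run$family), decreasing = TRUE)
        if (length(tb) > 1 && tb[1] == tb[2]) NA_character_ else names(tb)[1]
      }
      category <- classify_fragment_run(run$kind)
      if (category == "full_length" && length(fam) > 1L) category <- "unknown"
      # merge adjacent internal fragments into one run
      int <- run[run$kind == "internal", ]
      ltr <- run[run$kind == "ltr", ]
      plus <- run$strand[1] == "+"
      ltr5 <- ltr3 <- c(NA_integer_, NA_integer_)
      if (nrow(ltr) == 2) {
        ltr5 <- if (plus) c(ltr$start[1], ltr$end[1]) else c(ltr$start[2], ltr$end[2])
        ltr3 <- if (plus) c(ltr$start[2], ltr$end[2]) else c(ltr$start[1], ltr$end[1])
      } else if (nrow(ltr) == 1) {
        # single LTR: orient by position relative to internal sequence
        before_int <- nrow(int) == 0 || ltr$start[1] < min(int$start)
        five_prime <- (plus && before_int) || (!plus && !before_int)
        if (five_prime) ltr5 <- c(ltr$start[1], ltr$end[1])
        else ltr3 <- c(ltr$start[1], ltr$end[1])
      }
      loci[[length(loci) + 1L]] <- tibble(
        chrom = run$chrom[1], start = min(run$start), end = max(run$end),
        strand = run$strand[1], category = category, subfamily = subfam,
        ltr5_start = ltr5[1], ltr5_end = ltr5[2],
        ltr3_start = ltr3[1], ltr3_end = ltr3[2],
        internal_start = if (nrow(int)) min(int$start) else NA_integer_,
        internal_end = if (nrow(int)) max(int$end) else NA_integer_,
        n_hits = nrow(run), member_hit_ids = list(run$hit_id)
      )
    }
  }
  out <- arrange(bind_rows(loci), .data$chrom, .data$start)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), category = character(),
                  subfamily = character(), ltr5_start = integer(),
                  ltr5_end = integer(), ltr3_start = integer(),
                  ltr3_end = integer(), internal_start = integer(),
                  internal_end = integer(), n_hits = integer(),
                  member_hit_ids = list())
  }
  out <- mutate(out, locus_id = sprintf("locus%04d", row_number()), .before = 1)
  class(out) <- c("erv_catalog", class(out))
  out
}

#' Summarize a locus catalog by structural category
#'
#' @param loci An `erv_catalog` from [defragment()].
#' @return A tibble of per-category counts with a `total` row appended.
#' @export
#' @examples
#' loci <- tibble::tibble(category = c("full_length", "solo_ltr", "solo_ltr"))
#' catalog_summary(loci)
catalog_summary <- function(loci) {
  cats <- c("full_length", "solo_ltr", "truncated", "unknown")
  counts <- vapply(cats, function(k) sum(loci$category == k), integer(1))
  bind_rows(
    tibble(category = cats, n = unname(counts)),
    tibble(category = "total", n = sum(counts))
  )
}

#' Write loci as BED6
#'
#' @param loci An `erv_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  bed <- tibble(loci$chrom, loci$start, loci$end, loci$locus_id, 0L,
                loci$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
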