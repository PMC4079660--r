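# Emission of the synthetic annotation in RepeatMasker .out dialect, plus
# FASTA / JSON round-trip of a simulated truth set.

#' Emit a RepeatMasker-style .out annotation for planted events
#'
#' Writes the standard 15-column whitespace-delimited `.out` format (three
#' header lines, 1-based inclusive query coordinates, `C` for minus strand,
#' repeat begin/end/(left) order swapped on `C` rows) with LTR and internal
#' regions listed as separate fragments, exactly as RepeatMasker reports
#' proviruses. Shared decoy elements are annotated too — a repeat annotator
#' does not know lineage specificity.
#'
#' @param ledger Ledger tibble (ingroup events, optionally with decoys bound).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param path Output file path.
#' @param split_internal If `TRUE`, the internal region of the first
#'   full-length event is emitted as two fragments separated by
#'   `split_gap_bp`, to exercise defragmentation.
#' @param split_gap_bp Gap between the two internal fragments.
#' @return `path`, invisibly.
#' @export
emit_repeatmasker_out <- function(ledger, chrom_lengths, path,
                                  split_internal = FALSE, split_gap_bp = 60L) {
  rows <- list()
  split_done <- FALSE
  for (i in seq_len(nrow(ledger))) {
    ev <- ledger[i, ]
    div <- round(ev$planted_age_myr * 100 * 0.0025, 1)
    frags <- list()
    add <- function(kind, s, e) {
      frags[[length(frags) + 1L]] <<- tibble(kind = kind, start = s, end = e)
    }
    if (!is.na(ev$ltr5_start)) add("LTR", ev$ltr5_start, ev$ltr5_end)
    if (!is.na(ev$internal_start)) {
      if (split_internal && !split_done &&
          (ev$internal_end - ev$internal_start) > 3L * split_gap_bp) {
        mid <- (ev$internal_start + ev$internal_end) %/% 2L
        add("int", ev$internal_start, mid - split_gap_bp %/% 2L)
        add("int", mid + split_gap_bp %/% 2L, ev$internal_end)
        split_done <- TRUE
      } else {
        add("int", ev$internal_start, ev$internal_end)
      }
    }
    if (!is.na(ev$ltr3_start)) add("LTR", ev$ltr3_start, ev$ltr3_end)
    frags <- arrange(bind_rows(frags), .data$start)
    for (j in seq_len(nrow(frags))) {
      fr <- frags[j, ]
      rname <- paste0(ev$subfamily, "-", fr$kind)
      rlen <- fr$end - fr$start
      qleft <- chrom_lengths[[ev$chrom]] - fr$end
      if (ev$strand == "+") {
        rep_cols <- c("1", as.character(rlen), "(0)")
        strand_chr <- "+"
      } else {
        rep_cols <- c("(0)", as.character(rlen), "1")
        strand_chr <- "C"
      }
      rows[[length(rows) + 1L]] <- c(
        "1000", format(div, nsmall = 1), "0.0", "0.0",
        ev$chrom, as.character(fr$start + 1L), as.character(fr$end),
        paste0("(", qleft, ")"), strand_chr, rname, "LTR/ERV1",
        rep_cols, as.character(i)
      )
    }
  }
  header <- c(
    "   SW   perc perc perc  query     position in query           matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end          (left)   repeat    class/family   begin end   (left)  ID",
    ""
  )
  body <- vapply(rows, function(r) paste(format(r, width = 6), collapse = " "),
                 character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated truth set to disk
#'
#' Emits the ingroup genome, each outgroup genome and the subfamily consensus
#' set as FASTA, the repeat annotation as RepeatMasker `.out`, and the truth
#' ledger (events, decoys, configuration) as JSON. Output is byte-identical
#' for a fixed config seed.
#'
#' @param sim An `erv_truth_set` from [simulate_erv_truth()].
#' @param dir Output directory (created if absent).
#' @param split_internal Passed to [emit_repeatmasker_out()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_truth_set <- function(sim, dir, split_internal = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ingroup = file.path(dir, "ingroup.fa"),
    annotation = file.path(dir, "annotation.out"),
    consensus = file.path(dir, "consensus.fa"),
    ledger = file.path(dir, "truth_ledger.json")
  )
  Biostrings::writeXStringSet(sim$ingroup, paths[["ingroup"]])
  for (nm in names(sim$outgroups)) {
    p <- file.path(dir, paste0(nm, ".fa"))
    Biostrings::writeXStringSet(sim$outgroups[[nm]], p)
    paths[[nm]] <- p
  }
  write_consensus_fasta(sim$consensus, paths[["consensus"]])
  emit_repeatmasker_out(bind_rows(sim$ledger, sim$decoys), sim$chrom_lengths,
                        paths[["annotation"]], split_internal = split_internal)
  jsonlite::write_json(
    list(
      config = unclass(sim$config),
      chrom_lengths = as.list(sim$chrom_lengths),
      events = sim$ledger,
      decoys = sim$decoys
    ),
    paths[["ledger"]], auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(paths)
}

#' Read a truth ledger written by [write_truth_set()]
#'
#' @param path Path to `truth_ledger.json`.
#' @return A list with `config`, `chrom_lengths`, `events` and `decoys`
#'   tibbles.
#' @export
read_truth_ledger <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$events <- as_tibble(x$events)
  x$decoys <- as_tibble(x$decoys)
  x$chrom_lengths <- unlist(x$chrom_lengths)
  x
}
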