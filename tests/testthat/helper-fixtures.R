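# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# small simulated truth set with one shared decoy; used by several files
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    cfg <- simulation_config(
      seed = 42, ancestor_length_bp = 5e5, n_chromosomes = 2,
      n_full_length = 3, n_solo_ltr = 3, n_truncated = 2, n_ncpi = 2,
      n_decoy_shared = 1, outgroup_divergence = 0.01
    )
    .fixture_env$sim <- simulate_erv_truth(cfg, k_outgroups = 2)
  }
  .fixture_env$sim
}

# catalog + specificity calls on the small sim (computed once)
small_pipeline <- function() {
  if (is.null(.fixture_env$pipe)) {
    sim <- small_sim()
    out_path <- tempfile(fileext = ".out")
    emit_repeatmasker_out(dplyr::bind_rows(sim$ledger, sim$decoys),
                          sim$chrom_lengths, out_path)
    hits <- parse_repeatmasker_out(out_path)
    .fixture_env$pipe <- run_erv_pipeline(sim$ingroup, hits, sim$outgroups,
                                          sim$consensus)
  }
  .fixture_env$pipe
}

# join catalog loci to ledger events by exact coordinates
match_loci_to_ledger <- function(catalog, sim) {
  led <- dplyr::bind_rows(sim$ledger, sim$decoys)
  dplyr::inner_join(as.data.frame(catalog)[, c("locus_id", "chrom", "start",
                                               "end", "category")],
                    led, by = c("chrom", "start", "end"),
                    suffix = c("_catalog", "_truth"))
}

# write a minimal RepeatMasker .out file from a fragment tibble
write_rm_out <- function(frags, path = tempfile(fileext = ".out")) {
  header <- c("   SW   perc perc perc  query  position in query  matching",
              "score   div. del. ins.  sequence begin end (left)  repeat",
              "")
  rows <- vapply(seq_len(nrow(frags)), function(i) {
    f <- frags[i, ]
    strand <- if (f$strand == "-") "C" else "+"
    rep_cols <- if (strand == "+") c("1", "400", "(0)") else c("(0)", "400", "1")
    paste(c("1000", "1.0", "0.0", "0.0", f$chrom, f$start1, f$end1, "(5000)",
            strand, f$name, "LTR/ERV1", rep_cols, f$id), collapse = "  ")
  }, character(1))
  writeLines(c(header, rows), path)
  path
}

# random DNA string helper for tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
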