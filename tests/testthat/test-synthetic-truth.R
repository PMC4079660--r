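# The synthetic truth generator: determinism, composition, planted-event
# bookkeeping, and the emitted annotation.

test_that("ancestor generation is deterministic, seed-sensitive, and honours GC", {
  cfg <- function(seed, len, gc) {
    simulation_config(seed = seed, ancestor_length_bp = len, n_chromosomes = 1,
                      gc_fraction = gc, n_full_length = 0, n_solo_ltr = 0,
                      n_truncated = 0, n_ncpi = 0)
  }
  g1 <- generate_ancestor(cfg(1, 10000, 0.5))
  g1b <- generate_ancestor(cfg(1, 10000, 0.5))
  g2 <- generate_ancestor(cfg(2, 10000, 0.5))
  expect_identical(as.character(g1), as.character(g1b))
  expect_false(identical(as.character(g1), as.character(g2)))
  expect_equal(sum(Biostrings::width(g1)), 10000)

  gat <- generate_ancestor(cfg(1, 5000, 0))
  expect_false(grepl("[GC]", as.character(gat[[1]])))

  big <- generate_ancestor(cfg(3, 100000, 0.41))
  gc_obs <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 100000
  expect_lt(abs(gc_obs - 0.41), 0.02)

  expect_error(simulation_config(ancestor_length_bp = -5), "positive")
})

test_that("classical planting duplicates the target site and zero age gives identical LTRs", {
  cfg <- simulation_config(seed = 5, ancestor_length_bp = 5e4,
                           n_chromosomes = 1)
  genome <- generate_ancestor(cfg)
  cons <- erv_consensus_set("FAM1", seed = 3, ltr_length = 300,
                            gene_lengths = c(gag = 300, pro = 150, pol = 300,
                                             env = 300))
  set.seed(9)
  res <- plant_element(genome, "chr1", 20000L, cons[1, ], "full_length", cfg,
                       strand = "+", tsd_len = 4L, age_myr = 0)
  ev <- res$event
  chrom <- res$genome[[1]]
  tsd_left <- as.character(Biostrings::subseq(chrom, ev$start - 3, ev$start))
  tsd_right <- as.character(Biostrings::subseq(chrom, ev$end + 1, ev$end + 4))
  expect_equal(nchar(ev$tsd), 4)
  expect_equal(tsd_left, ev$tsd)
  expect_equal(tsd_right, ev$tsd)
  # age 0: both LTRs identical to consensus
  ltr5 <- as.character(Biostrings::subseq(chrom, ev$ltr5_start + 1, ev$ltr5_end))
  ltr3 <- as.character(Biostrings::subseq(chrom, ev$ltr3_start + 1, ev$ltr3_end))
  expect_identical(ltr5, ltr3)
  expect_identical(ltr5, cons$ltr[1])

  set.seed(10)
  solo <- plant_element(genome, "chr1", 20000L, cons[1, ], "solo_ltr", cfg,
                        strand = "+", tsd_len = 2L, age_myr = 0)
  expect_equal(solo$event$category, "solo_ltr")
  expect_equal(solo$event$element_length, 300L)
})

test_that("NCPI planting removes the segment and plants exact junction microhomology", {
  cfg <- simulation_config(seed = 6, ancestor_length_bp = 5e4,
                           n_chromosomes = 1)
  genome <- generate_ancestor(cfg)
  cons <- erv_consensus_set("FAM1", seed = 3, ltr_length = 300,
                            gene_lengths = c(gag = 300, pro = 150, pol = 300,
                                             env = 300))
  set.seed(11)
  res <- plant_ncpi(genome, "chr1", 20000L, cons[1, ], cfg,
                    deletion_size = 500L, microhomology_len = 3L,
                    structural_form = "solo_ltr", strand = "+", age_myr = 0)
  ev <- res$event
  # derived genome is shorter by deletion minus element
  expect_equal(length(res$genome[[1]]) - length(genome[[1]]),
               ev$element_length - 500L)
  # the deleted segment is gone: sequence after element continues at site+500
  after <- as.character(Biostrings::subseq(res$genome[[1]], ev$end + 1,
                                           ev$end + 100))
  orig <- as.character(Biostrings::subseq(genome[[1]], 20000 + 500 + 1,
                                          20000 + 500 + 100))
  expect_equal(substr(after, 3, 100), substr(orig, 3, 100))
  # junction microhomology is exactly as planted
  lf <- as.character(Biostrings::subseq(res$genome[[1]], ev$start - 19,
                                        ev$start))
  el <- as.character(Biostrings::subseq(res$genome[[1]], ev$start + 1, ev$end))
  rf <- as.character(Biostrings::subseq(res$genome[[1]], ev$end + 1,
                                        ev$end + 20))
  mh <- scan_microhomology(lf, el, rf)
  expect_equal(mh$left_len, 3L)
  expect_equal(mh$left_seq, ev$microhomology)

  # boundary: zero deletion, blunt junction
  set.seed(12)
  res0 <- plant_ncpi(genome, "chr1", 20000L, cons[1, ], cfg,
                     deletion_size = 0L, microhomology_len = 0L,
                     structural_form = "solo_ltr", strand = "+", age_myr = 0)
  expect_equal(res0$event$deletion_size_bp, 0L)
  expect_true(is.na(res0$event$microhomology))
  tsd <- detect_tsd(res0$genome, res0$event)
  expect_false(tsd$present)
})

test_that("outgroup derivation matches the configured divergence and zero divergence is identity", {
  cfg0 <- simulation_config(seed = 8, ancestor_length_bp = 1e5,
                            n_chromosomes = 1, outgroup_divergence = 0)
  anc <- generate_ancestor(cfg0)
  og0 <- derive_outgroups(anc, cfg0, k = 1)
  expect_identical(as.character(og0[[1]]), as.character(anc))

  cfg1 <- simulation_config(seed = 8, ancestor_length_bp = 1e5,
                            n_chromosomes = 1, outgroup_divergence = 0.01)
  og1 <- derive_outgroups(anc, cfg1, k = 2)
  mism <- function(a, b) {
    va <- strsplit(as.character(a[[1]]), "")[[1]]
    vb <- strsplit(as.character(b[[1]]), "")[[1]]
    mean(va != vb)
  }
  # direct count against the binomial expectation (sampling without
  # replacement gives exactly the drawn number of changed sites)
  expect_lt(abs(mism(anc, og1[[1]]) - 0.01), 0.001)
  expect_lt(abs(mism(anc, og1[[2]]) - 0.01), 0.001)
  # outgroups are independent draws
  expect_false(identical(as.character(og1[[1]]), as.character(og1[[2]])))
})

test_that("the ledger matches configured event counts and its invariants hold", {
  sim <- small_sim()
  cfg <- sim$config
  expect_equal(nrow(sim$ledger),
               cfg$n_full_length + cfg$n_solo_ltr + cfg$n_truncated +
                 cfg$n_ncpi)
  expect_equal(nrow(sim$decoys), cfg$n_decoy_shared)
  led <- sim$ledger
  is_ncpi <- led$category == "ncpi"
  expect_true(all(is.na(led$tsd[is_ncpi])))
  expect_true(all(led$deletion_size_bp[is_ncpi] >= 0))
  expect_true(all(led$deletion_size_bp[!is_ncpi] == 0))
  expect_true(all(led$tsd_len[!is_ncpi] >= cfg$tsd_length_range[1]))
  expect_true(all(led$tsd_len[!is_ncpi] <= cfg$tsd_length_range[2]))
  # coordinates lie within the derived genome
  for (i in seq_len(nrow(led))) {
    expect_lte(led$end[i], sim$chrom_lengths[[led$chrom[i]]])
    expect_gt(led$start[i], 0)
  }
  # pairwise spacing: no two events within min_spacing of each other
  by_chrom <- split(led, led$chrom)
  for (grp in by_chrom) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) > 1) {
      gaps <- grp$start[-1] - grp$end[-nrow(grp)]
      expect_true(all(gaps > 0))
    }
  }
})

test_that("truth-set output is byte-identical under a fixed seed", {
  cfg <- simulation_config(seed = 99, ancestor_length_bp = 1e5,
                           n_chromosomes = 1, n_full_length = 1,
                           n_solo_ltr = 1, n_truncated = 0, n_ncpi = 1)
  d1 <- file.path(tempdir(), "ts1")
  d2 <- file.path(tempdir(), "ts2")
  write_truth_set(simulate_erv_truth(cfg, k_outgroups = 1), d1)
  write_truth_set(simulate_erv_truth(cfg, k_outgroups = 1), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("emitted annotation has RepeatMasker row structure per event class", {
  sim <- small_sim()
  path <- tempfile(fileext = ".out")
  emit_repeatmasker_out(sim$ledger, sim$chrom_lengths, path,
                        split_internal = TRUE, split_gap_bp = 60L)
  hits <- parse_repeatmasker_out(path)
  led <- sim$ledger
  rmid_of <- function(ev) which(led$event_id == ev)
  for (i in seq_len(nrow(led))) {
    n_frag <- sum(hits$rm_id == as.character(i))
    expected <- switch(led$category[i],
      solo_ltr = 1L,
      full_length = 3L,
      truncated = 2L,
      ncpi = if (led$structural_form[i] == "solo_ltr") 1L else 3L
    )
    # split mode adds one fragment to exactly one full-length element
    expect_true(n_frag == expected || n_frag == expected + 1L)
  }
  # the split internal appears as two rows with a gap <= configured split gap
  int_rows <- hits[grepl("-int$", hits$repeat_name), ]
  split_groups <- split(int_rows, int_rows$rm_id)
  n_split <- sum(vapply(split_groups, nrow, integer(1)) == 2)
  expect_equal(n_split, 1L)
  two <- split_groups[[which(vapply(split_groups, nrow, integer(1)) == 2)]]
  expect_lte(two$start[2] - two$end[1], 60L)
})
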