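# RepeatMasker parsing, defragmentation into loci, and catalog summaries.

frag_row <- function(chrom, start1, end1, name, strand = "+", id = "1") {
  tibble::tibble(chrom = chrom, start1 = start1, end1 = end1, name = name,
                 strand = strand, id = id)
}

test_that("parser converts coordinates, filters by name, and rejects malformed rows", {
  p <- write_rm_out(frag_row("chr1", 1001, 1400, "PtERV1-LTR"))
  hits <- parse_repeatmasker_out(p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1000L)   # 1-based inclusive -> 0-based half-open
  expect_equal(hits$end, 1400L)
  expect_equal(hits$strand, "+")

  # header-only file
  empty <- write_rm_out(frag_row("x", 1, 2, "y")[0, ])
  expect_equal(nrow(parse_repeatmasker_out(empty)), 0)

  # name filter keeps matching rows only
  p2 <- write_rm_out(dplyr::bind_rows(
    frag_row("chr1", 100, 500, "PtERV1-LTR"),
    frag_row("chr1", 9000, 9400, "AluY")
  ))
  expect_equal(nrow(parse_repeatmasker_out(p2, name_filter = "^PtERV|^CERV")), 1)
  expect_equal(nrow(parse_repeatmasker_out(p2)), 2)

  # malformed row errors name the line
  bad <- tempfile()
  writeLines(c("h", "h", "", "only three fields"), bad)
  expect_error(parse_repeatmasker_out(bad), "line 4")

  # C-strand rows parse as minus strand
  p3 <- write_rm_out(frag_row("chr1", 100, 500, "PtERV1-LTR", strand = "-"))
  expect_equal(parse_repeatmasker_out(p3)$strand, "-")
})

test_that("a synthetic annotation with 693 matching rows yields 693 hits", {
  rows <- frag_row("chr1", seq(1, by = 10000, length.out = 693),
                   seq(400, by = 10000, length.out = 693), "PtERV1-LTR")
  p <- write_rm_out(rows)
  expect_equal(nrow(parse_repeatmasker_out(p, name_filter = "^PtERV")), 693)
})

# brute-force oracle: merge intervals on gap <= max_gap, per chrom+strand
merge_oracle <- function(hits, max_gap) {
  n_loci <- 0
  for (grp in split(hits, paste(hits$chrom, hits$strand))) {
    grp <- grp[order(grp$start), ]
    if (nrow(grp) == 0) next
    n_loci <- n_loci + 1 +
      sum((grp$start[-1] - grp$end[-nrow(grp)]) > max_gap)
  }
  n_loci
}

test_that("defragmentation assembles the canonical structures", {
  mk <- function(...) parse_repeatmasker_out(write_rm_out(dplyr::bind_rows(...)))

  # LTR-int-LTR, zero gaps -> one full-length locus
  full <- mk(frag_row("chr1", 1001, 1400, "F-LTR"),
             frag_row("chr1", 1401, 5000, "F-int"),
             frag_row("chr1", 5001, 5400, "F-LTR"))
  loci <- defragment(full)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$category, "full_length")
  expect_equal(loci$ltr5_start, 1000L)
  expect_equal(loci$ltr3_end, 5400L)

  # isolated LTR -> solo
  solo <- mk(frag_row("chr1", 1001, 1400, "F-LTR"),
             frag_row("chr1", 99001, 99400, "F-LTR"))
  expect_equal(defragment(solo)$category, c("solo_ltr", "solo_ltr"))

  # internal + one LTR -> truncated
  tr <- mk(frag_row("chr1", 1001, 4000, "F-int"),
           frag_row("chr1", 4001, 4400, "F-LTR"))
  expect_equal(defragment(tr)$category, "truncated")

  # two LTRs, no internal -> unknown (not solo)
  unk <- mk(frag_row("chr1", 1001, 1400, "F-LTR"),
            frag_row("chr1", 1601, 2000, "F-LTR"))
  expect_equal(defragment(unk)$category, "unknown")

  # split internal with a 50-bp gap still merges under max_gap 500;
  # cross-check the locus count with a brute-force interval merge
  split_int <- mk(frag_row("chr1", 1001, 1400, "F-LTR"),
                  frag_row("chr1", 1401, 3000, "F-int"),
                  frag_row("chr1", 3051, 5000, "F-int"),
                  frag_row("chr1", 5001, 5400, "F-LTR"))
  loci <- defragment(split_int, max_gap_bp = 500)
  expect_equal(nrow(loci), merge_oracle(split_int, 500))
  expect_equal(loci$category, "full_length")

  # inconsistent family labels across LTR-int-LTR -> unknown
  mixed <- mk(frag_row("chr1", 1001, 1400, "A-LTR"),
              frag_row("chr1", 1401, 5000, "B-int"),
              frag_row("chr1", 5001, 5400, "B-LTR"))
  expect_equal(defragment(mixed)$category, "unknown")

  # unknown repeat names are dropped with a warning
  noisy <- mk(frag_row("chr1", 1001, 1400, "F-LTR"),
              frag_row("chr1", 50001, 50400, "WeirdRepeat"))
  expect_warning(out <- defragment(noisy), "unrecognized")
  expect_equal(nrow(out), 1)
})

test_that("defragmentation keeps every hit exactly once and is idempotent at locus level", {
  sim <- small_sim()
  path <- tempfile(fileext = ".out")
  emit_repeatmasker_out(dplyr::bind_rows(sim$ledger, sim$decoys),
                        sim$chrom_lengths, path, split_internal = TRUE)
  hits <- parse_repeatmasker_out(path)
  loci <- defragment(hits)
  used <- sort(unlist(loci$member_hit_ids))
  expect_equal(used, sort(hits$hit_id))           # no hit lost or duplicated
  # locus count equals planted event count (fragment-split mode on)
  expect_equal(nrow(loci), nrow(sim$ledger) + nrow(sim$decoys))
  # a second pass over the merged spans creates no further merging
  expect_equal(nrow(loci), merge_oracle(hits, 1000))
})

test_that("catalog summary counts categories and totals", {
  loci <- tibble::tibble(category = c(rep("full_length", 121),
                                      rep("solo_ltr", 110),
                                      rep("truncated", 22),
                                      rep("unknown", 3)))
  s <- catalog_summary(loci)
  expect_equal(s$n[s$category == "total"], 256)
  expect_equal(s$n[s$category == "full_length"], 121)

  empty <- catalog_summary(loci[0, , drop = FALSE])
  expect_true(all(empty$n == 0))
})

test_that("category recovery on simulated annotation is exact", {
  sim <- small_sim()
  pipe <- small_pipeline()
  m <- match_loci_to_ledger(pipe$catalog, sim)
  expect_equal(nrow(m), nrow(sim$ledger) + nrow(sim$decoys))
  non_ncpi <- m[m$category_truth != "ncpi", ]
  expect_equal(non_ncpi$category_catalog, non_ncpi$structural_form)
  ncpi <- m[m$category_truth == "ncpi", ]
  expect_equal(ncpi$category_catalog, ncpi$structural_form)
})
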