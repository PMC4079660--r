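# K2P distance, age calibration, subfamily assignment, consensus building.

# mutate with a given number of transitions/transversions at fixed positions
apply_muts <- function(seq, pos_ts, pos_tv) {
  v <- strsplit(seq, "")[[1]]
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- c(A = "C", G = "C", C = "A", T = "A")
  v[pos_ts] <- ts[v[pos_ts]]
  v[pos_tv] <- tv[v[pos_tv]]
  paste(v, collapse = "")
}

test_that("k2p matches the closed form and handles gaps and saturation", {
  expect_equal(k2p("ACGTACGT", "ACGTACGT")$d, 0)

  # 100 sites, 10 transitions, 5 transversions:
  # d = -1/2 ln(1 - 2*0.10 - 0.05) - 1/4 ln(1 - 2*0.05)
  set.seed(1)
  a <- rand_dna(100)
  b <- apply_muts(a, 1:10, 11:15)
  res <- k2p(a, b)
  expect_equal(res$P, 0.10)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(round(res$d, 4), 0.1702)

  # gap columns are excluded
  res2 <- k2p("AC-TACGTAC", "ACGT-CGTAC")
  expect_equal(res2$sites_compared, 8)
  expect_equal(res2$d, 0)
  # ambiguity codes are excluded like gaps
  expect_equal(k2p("ACNT", "ACGT")$sites_compared, 3)

  expect_error(k2p("----", "ACGT"), "no comparable")
  # saturation: everything a transversion
  expect_error(k2p("AAAA", "CCCC"), "saturated")
})

test_that("k2p equals an independent evaluation on random pairs and dominates p-distance", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (rep in 1:200) {
    a <- rand_dna(120)
    n_mut <- sample(1:25, 1)
    pos <- sample(120, n_mut)
    n_ts <- sample(0:n_mut, 1)
    b <- apply_muts(a, pos[seq_len(n_ts)], pos[-seq_len(n_ts)])
    ours <- k2p(a, b)
    bin <- ape::as.DNAbin(t(sapply(list(a, b),
                                   function(s) strsplit(tolower(s), "")[[1]])))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(ours$d, ref, tolerance = 1e-12)
    # the multiple-hit correction can only inflate the raw mismatch fraction
    expect_gte(ours$d + 1e-15, ours$P + ours$Q)
  }
})

test_that("age calibration follows the two-rate formula with fixed 1.3 ratio", {
  a <- estimate_age(0.0052)
  expect_equal(a$age_young_myr, 1.00)
  expect_equal(a$age_old_myr, 1.30)
  expect_equal(estimate_age(0)$age_old_myr, 0)
  # linear: doubling d doubles both bounds
  a2 <- estimate_age(0.0104)
  expect_equal(a2$age_young_myr, 2 * a$age_young_myr)
  expect_equal(a2$age_old_myr, 2 * a$age_old_myr)
  # ratio identity for arbitrary positive divergences
  ds <- c(0.001, 0.0123, 0.037, 0.044, 0.2)
  ages <- estimate_age(ds)
  expect_equal(ages$age_old_myr / ages$age_young_myr, rep(1.3, 5),
               tolerance = 1e-12)
  expect_error(estimate_age(-0.1), "non-negative")
  # broom-style accessors
  expect_equal(nrow(tidy(ages)), 5)
  expect_equal(glance(ages)$n, 5)
})

test_that("subfamily assignment recovers the generating consensus and breaks ties lexicographically", {
  cons <- erv_consensus_set(c("CERV1", "CERV2"), seed = 2, ltr_length = 400,
                            gene_lengths = c(gag = 300, pro = 150,
                                             pol = 300, env = 300))
  set.seed(5)
  correct <- 0
  n <- 60
  for (i in seq_len(n)) {
    truth <- sample(1:2, 1)
    ltr <- ervtrace:::mutate_dna_chr(cons$ltr[truth], 0.05)
    asg <- assign_subfamily(ltr, cons)
    correct <- correct + (asg$subfamily == cons$subfamily[truth])
  }
  expect_gte(correct / n, 0.99)

  # equidistant tie -> lexicographically first label, flagged
  tied <- cons[c(1, 1), ]
  tied$subfamily <- c("ZFAM", "AFAM")
  asg <- assign_subfamily(tied$ltr[1], tied)
  expect_equal(asg$subfamily, "AFAM")
  expect_true(asg$tie)

  # closure: the label always comes from the consensus set
  expect_true(asg$subfamily %in% tied$subfamily)
})

test_that("subfamily statistics: pair means, lengths, and age brackets", {
  # two identical LTRs -> zero distance, zero age
  s <- tibble::tibble(subfamily = "X", seq = c("ACGTACGTAC", "ACGTACGTAC"))
  st <- subfamily_statistics(s, aligned = TRUE)
  expect_equal(st$mean_pairwise_d, 0)
  expect_equal(st$age_young_myr, 0)

  # singleton subfamily -> distance not available
  one <- subfamily_statistics(tibble::tibble(subfamily = "Y", seq = "ACGT"))
  expect_true(is.na(one$mean_pairwise_d))

  # mean LTR length is plain arithmetic
  two <- tibble::tibble(subfamily = "Z",
                        seq = c(rand_dna(409), rand_dna(379)))
  expect_equal(subfamily_statistics(two)$mean_length, 394)
})

test_that("dating recovers a planted age of 2 myr from replicate LTR pairs", {
  # 100 LTR pairs, length 400, T = 2 myr at 0.23 %/site/myr per lineage:
  # expected pair divergence 2 T r = 0.0092
  set.seed(11)
  T_myr <- 2
  r <- 0.0023
  d_hat <- replicate(100, {
    anc <- rand_dna(400)
    a <- ervtrace:::mutate_dna_chr(anc, T_myr * r)
    b <- ervtrace:::mutate_dna_chr(anc, T_myr * r)
    k2p(a, b)$d
  })
  expect_lt(abs(mean(d_hat) - 2 * T_myr * r) / (2 * T_myr * r), 0.10)
  # the calibration interval built from the replicate-mean divergence
  # brackets the true age (0.23 lies between the 0.20 and 0.26 rates)
  age <- estimate_age(mean(d_hat))
  expect_lte(age$age_young_myr, T_myr)
  expect_gte(age$age_old_myr, T_myr)
})

test_that("consensus building takes majorities, IUPAC ties, and is idempotent on copies", {
  expect_equal(build_consensus(c("ACGT", "ACGA", "ACGT")), "ACGT")
  # column {A, G} -> R
  expect_equal(build_consensus(c("AAGT", "AGGT")), "ARGT")
  # n copies of one sequence -> that sequence
  expect_equal(build_consensus(rep("GATTACA", 5)), "GATTACA")
  # all-gap columns are dropped
  expect_equal(build_consensus(c("AC-T", "AC-T")), "ACT")
  expect_error(build_consensus(character()), "at least two")

  # reference-anchored alignment handles shifted copies well enough for
  # near-identical inputs
  base <- rand_dna(200)
  seqs <- c(base, ervtrace:::mutate_dna_chr(base, 0.02),
            ervtrace:::mutate_dna_chr(base, 0.02))
  al <- align_ltr_set(seqs)
  expect_true(all(nchar(al) == 200))
  cons <- build_consensus(al)
  expect_gt(mean(strsplit(cons, "")[[1]] == strsplit(base, "")[[1]]), 0.97)
})
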