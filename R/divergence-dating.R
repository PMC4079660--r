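# Kimura-2-parameter LTR divergence, subfamily assignment, and age
# calibration under two neutral substitution rates.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

# global pairwise alignment of two sequences; returns the two aligned strings
align_pair <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1),
    gapOpening = 5, gapExtension = 2
  )
  c(as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
}

#' Kimura-2-parameter distance between two aligned sequences
#'
#' Columns containing a gap or an ambiguous base are excluded (the
#' "without-INDEL" convention); over the remaining columns the transition
#' proportion `P` and transversion proportion `Q` give
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' @param a,b Aligned sequences of equal length (characters; `-` for gaps).
#' @return A one-row tibble: `P`, `Q`, `d`, `sites_compared`.
#' @export
#' @examples
#' k2p("ACGTACGT", "ACGTACGA")$d
k2p <- function(a, b) {
  assert_that(nchar(a) == nchar(b), "sequences must be aligned (equal length)")
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- va %in% DNA_BASES & vb %in% DNA_BASES
  va <- va[ok]
  vb <- vb[ok]
  n <- length(va)
  if (n == 0) abort("no comparable (gap- and ambiguity-free) sites")
  diff <- va != vb
  ts <- diff & ((va %in% PURINES & vb %in% PURINES) |
                  (va %in% PYRIMIDINES & vb %in% PYRIMIDINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort("saturated distance: log argument non-positive")
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  tibble(P = P, Q = Q, d = d, sites_compared = n)
}

#' Calibrate an LTR divergence into an age interval
#'
#' The two LTRs of a provirus are identical at integration and then
#' accumulate mutations independently, so their divergence is `2 r T`. With
#' the two neutral-rate calibrations of 0.26 and 0.20 % per site per myr the
#' age interval is `d / (2 * 0.0026)` to `d / (2 * 0.0020)` myr; the
#' old/young ratio is 1.3 for any positive divergence.
#'
#' @param d K2P divergence per site (scalar or vector, >= 0).
#' @param rate_fast,rate_slow Calibration rates in substitutions per site per
#'   myr.
#' @return An `erv_age` tibble: `d`, `age_young_myr`, `age_old_myr`.
#' @export
#' @examples
#' estimate_age(0.0052)
estimate_age <- function(d, rate_fast = 0.0026, rate_slow = 0.0020) {
  assert_that(all(d >= 0, na.rm = TRUE), "divergence must be non-negative")
  out <- tibble(
    d = d,
    age_young_myr = d / (2 * rate_fast),
    age_old_myr = d / (2 * rate_slow)
  )
  class(out) <- c("erv_age", class(out))
  attr(out, "rates") <- c(fast = rate_fast, slow = rate_slow)
  out
}

#' @export
tidy.erv_age <- function(x, ...) {
  as_tibble(unclass(x)[c("d", "age_young_myr", "age_old_myr")])
}

#' @export
glance.erv_age <- function(x, ...) {
  tibble(
    n = nrow(x),
    mean_d = mean(x$d, na.rm = TRUE),
    mean_age_young_myr = mean(x$age_young_myr, na.rm = TRUE),
    mean_age_old_myr = mean(x$age_old_myr, na.rm = TRUE)
  )
}

#' Assign an LTR sequence to its closest consensus subfamily
#'
#' Globally aligns the LTR against each subfamily consensus LTR and picks the
#' minimal K2P distance; ties break lexicographically by label and are
#' flagged.
#'
#' @param ltr_seq Character LTR sequence.
#' @param consensus An [erv_consensus_set()] (needs `subfamily`, `ltr`).
#' @return A one-row tibble: `subfamily`, `distance`, `margin` (distance gap
#'   to the runner-up, `NA` with a single consensus), `tie`.
#' @export
assign_subfamily <- function(ltr_seq, consensus) {
  assert_that(nrow(consensus) >= 1, "need at least one consensus")
  ds <- vapply(seq_len(nrow(consensus)), function(i) {
    al <- align_pair(ltr_seq, consensus$ltr[i])
    tryCatch(k2p(al[1], al[2])$d, error = function(e) NA_real_)
  }, double(1))
  if (all(is.na(ds))) {
    return(tibble(subfamily = NA_character_, distance = NA_real_,
                  margin = NA_real_, tie = FALSE))
  }
  ord <- order(ds, consensus$subfamily)
  best <- ord[1]
  second <- if (length(ord) > 1) ds[ord[2]] else NA_real_
  tie <- !is.na(second) && isTRUE(all.equal(ds[best], second))
  tibble(subfamily = consensus$subfamily[best], distance = ds[best],
         margin = second - ds[best], tie = tie)
}

#' Per-subfamily divergence, length and age statistics
#'
#' For each subfamily: number of LTRs, mean LTR length, mean pairwise K2P
#' distance over all unordered pairs (NA for singletons), and the calibrated
#' age interval from the mean distance.
#'
#' @param ltrs Tibble with columns `subfamily` and `seq` (LTR sequences).
#' @param aligned If `TRUE` the sequences within a subfamily are already
#'   aligned (equal length); otherwise each pair is globally aligned first.
#' @return A tibble, one row per subfamily: `n_ltrs`, `mean_length`,
#'   `mean_pairwise_d`, `age_young_myr`, `age_old_myr`.
#' @export
subfamily_statistics <- function(ltrs, aligned = FALSE) {
  rows <- list()
  for (sf in unique(ltrs$subfamily)) {
    ss <- ltrs$seq[ltrs$subfamily == sf]
    n <- length(ss)
    mean_len <- mean(nchar(gsub("-", "", ss)))
    d <- NA_real_
    if (n >= 2) {
      pair_d <- c()
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        al <- if (aligned) c(ss[i], ss[j]) else align_pair(ss[i], ss[j])
        pair_d <- c(pair_d, k2p(al[1], al[2])$d)
      }
      d <- mean(pair_d)
    }
    age <- estimate_age(ifelse(is.na(d), 0, d))
    rows[[length(rows) + 1L]] <- tibble(
      subfamily = sf, n_ltrs = n, mean_length = mean_len,
      mean_pairwise_d = d,
      age_young_myr = ifelse(is.na(d), NA_real_, age$age_young_myr),
      age_old_myr = ifelse(is.na(d), NA_real_, age$age_old_myr)
    )
  }
  arrange(bind_rows(rows), .data$subfamily)
}

#' Majority-rule consensus of aligned sequences
#'
#' Per column: majority base; ties yield the IUPAC ambiguity code of the tied
#' set; all-gap columns are dropped; gaps never outvote bases.
#'
#' @param seqs Character vector of aligned sequences (equal lengths, `-` for
#'   gaps).
#' @return The consensus sequence (character scalar).
#' @export
#' @examples
#' build_consensus(c("ACGT", "ACGA", "ACGT"))
build_consensus <- function(seqs) {
  assert_that(length(seqs) >= 2, "need at least two sequences")
  assert_that(length(unique(nchar(seqs))) == 1, "sequences must be aligned")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    col <- col[col %in% DNA_BASES]
    if (length(col) == 0) return("")
    tb <- table(col)
    winners <- sort(names(tb)[tb == max(tb)])
    IUPAC_FROM_SET[[paste(winners, collapse = "")]]
  })
  paste(cons, collapse = "")
}

#' Reference-anchored multiple alignment of near-identical sequences
#'
#' Aligns every sequence globally to the first and projects it onto the
#' reference columns (insertions relative to the reference are dropped).
#' Intended for LTR sets at >= 85% identity, not as a general MSA tool.
#'
#' @param seqs Character vector (>= 2 sequences).
#' @return Character vector of aligned sequences, all the reference length.
#' @export
align_ltr_set <- function(seqs) {
  assert_that(length(seqs) >= 2, "need at least two sequences")
  ref <- seqs[1]
  out <- c(ref, vapply(seqs[-1], function(s) {
    al <- align_pair(ref, s)
    ra <- strsplit(al[1], "", fixed = TRUE)[[1]]
    sa <- strsplit(al[2], "", fixed = TRUE)[[1]]
    keep <- ra != "-"
    paste(sa[keep], collapse = "")
  }, character(1)))
  unname(out)
}
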