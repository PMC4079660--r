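#' Generate an ancestral genome
#'
#' Draws i.i.d. bases at the configured GC fraction, split evenly over
#' `n_chromosomes` chromosomes named `chr1..chrN`. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config An [simulation_config()] object.
#' @return A named [Biostrings::DNAStringSet] of chromosome sequences.
#' @export
#' @examples
#' g <- generate_ancestor(simulation_config(seed = 1, ancestor_length_bp = 1e4))
#' sum(Biostrings::width(g))
generate_ancestor <- function(config) {
  validate_sim_config(config)
  n <- config$n_chromosomes
  len <- config$ancestor_length_bp
  per <- rep(len %/% n, n)
  per[seq_len(len %% n)] <- per[seq_len(len %% n)] + 1L
  with_seed(sub_seed(config$seed, 1L), {
    seqs <- vapply(per, random_dna, character(1), gc = config$gc_fraction)
  })
  Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(n))))
}

# Point-mutate a DNAString genome chromosome at per-site probability p,
# ts:tv = 2:1. Operates via replaceLetterAt for speed on Mb-scale sequences.
mutate_dna_set <- function(genome, p) {
  if (p <= 0) return(genome)
  out <- lapply(seq_along(genome), function(i) {
    s <- genome[[i]]
    n <- length(s)
    m <- rbinom(1L, n, min(p, 1))
    if (m == 0L) return(s)
    at <- sort(sample.int(n, m))
    old <- as.character(Biostrings::extractAt(s, IRanges::IRanges(at, at)))
    is_ts <- runif(m) < 2 / 3
    new <- vapply(seq_len(m), function(j) {
      b <- old[j]
      if (!b %in% DNA_BASES) return(b)
      if (is_ts[j]) TRANSITION[[b]] else sample(TRANSVERSIONS[[b]], 1L)
    }, character(1))
    Biostrings::replaceLetterAt(s, at, new)
  })
  Biostrings::DNAStringSet(setNames(
    vapply(out, as.character, character(1)), names(genome)
  ))
}

#' Derive outgroup genomes from an ancestor
#'
#' Each outgroup is the ancestor carrying independent point mutations at
#' `config$outgroup_divergence` substitutions per site (transition:transversion
#' 2:1) and none of the ingroup-specific planted events. Decoy (shared)
#' elements planted in the ancestor before this step are therefore present in
#' every outgroup.
#'
#' @param ancestor A [Biostrings::DNAStringSet] (usually from
#'   [generate_ancestor()], possibly with shared decoys planted).
#' @param config An [simulation_config()].
#' @param k Number of outgroups (>= 1).
#' @return A list of `k` DNAStringSet genomes named `outgroup1..k`.
#' @export
derive_outgroups <- function(ancestor, config, k = 3L) {
  validate_sim_config(config)
  assert_that(k >= 1, "k must be >= 1")
  out <- lapply(seq_len(k), function(i) {
    with_seed(sub_seed(config$seed, 100L + i), {
      mutate_dna_set(ancestor, config$outgroup_divergence)
    })
  })
  setNames(out, paste0("outgroup", seq_len(k)))
}
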