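---
title: "Detecting and dating lineage-specific endogenous retrovirus insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating lineage-specific endogenous retrovirus insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervtrace)
library(dplyr)
```

## The problem

Endogenous retroviruses (ERVs) are LTR retroelements fixed or segregating in
vertebrate genomes. When a provirus integrates, its two long terminal repeats
(LTRs) are identical and the integration reaction duplicates 2–5 bp of the
target site on both sides (the target-site duplication, TSD). Afterwards the
copy decays: the LTR pair diverges at the neutral rate, LTR–LTR homologous
recombination can excise the internal *gag*–*pro*–*pol*–*env* genes and leave
a solitary LTR, and point mutations disrupt the reading frames. A minority of
insertions instead arrive "non-classically": the element sits in place of a
deleted stretch of host sequence, without a TSD, often with 2–3 bp of
microhomology at the breakpoint junctions — the signature of double-strand
break repair by end joining.

`ervtrace` turns the comparative-genomics workflow for surveying such
lineage-specific insertions into a reusable, tested pipeline:

1. **Catalog** — parse RepeatMasker annotation and defragment LTR/internal
   hits into candidate proviral loci with a structural category
   (full-length / solitary LTR / truncated / unknown).
2. **Lineage filter** — extract 2 kb of flanking sequence per side, locate
   the flanks in one or more outgroup genomes, and call each locus
   ingroup-specific, shared, or unresolved.
3. **Anatomy** — detect TSDs, pair LTRs, screen reading frames for
   retrotransposition competence.
4. **Dating** — assign subfamilies against LTR consensus sequences, compute
   Kimura-2-parameter (K2P) divergence, and calibrate ages.
5. **NCPI** — find TSD-absent, deletion-associated insertions, size the
   deletion against the outgroups, and scan junctions for microhomology.
6. **Reports** — polymorphism, per-family and per-chromosome summaries.

Because the real survey requires multi-gigabase reference genomes, the
package carries its own synthetic-genome generator that plants ground-truth
events and records them in a machine-readable truth ledger; the entire
pipeline is validated against that ledger.

## The synthetic truth generator

`simulation_config()` + `simulate_erv_truth()` emulate the study design: an
ancestral genome shared by the ingroup and the outgroups; post-divergence
insertions on the ingroup branch only; neutral divergence of the outgroups.

What is emulated, and the defaults:

* **Ancestral background**: i.i.d. bases at a configurable GC fraction
  (default 0.41, a mammalian-like value). No repeats other than the planted
  elements, so 2-kb flanks are unique with probability ~1 — this stands in
  for the survey's manual triage of ambiguous flanks, and is why we enforce
  placement spacing (≥ 5 kb) rather than a genome-wide flank-identity scan.
* **Classical insertions** (`full_length`, `solo_ltr`, `truncated`): TSD
  length uniform on 2–5 bp, both flanking copies exact; both LTRs identical
  at planting, then mutated independently with `element_age_myr ×
  ltr_mutation_rate` expected substitutions per site (defaults 1.5 myr,
  0.25 %/myr) at a transition:transversion ratio of 2:1 — the asymmetry
  makes K2P estimation (P ≠ Q) non-trivial. Truncated copies keep one LTR
  plus 30–80% of the internal region.
* **Non-classical insertions** (`ncpi`): the element replaces a deleted
  segment (default 100–2000 bp; real deletions reach tens of kb, scaled down
  to keep simulated genomes small), with probability 5/7 of carrying a 2–3 bp
  upstream-junction microhomology, otherwise blunt.
* **Outgroups**: the ancestor with independent point mutations at
  `outgroup_divergence` substitutions per site (default 0.01, roughly the
  great-ape range). Optional "decoy" elements planted *before* divergence
  appear in both lineages and must be rejected as shared.
* **Consensus subfamilies**: `erv_consensus_set()` builds proviruses with a
  400-bp LTR and an internal region carrying stop-free *gag* (1500 nt),
  *pro* (450), *pol* (3300) and *env* (1950) genes separated by short
  spacers (~8.3 kb total, matching the 8.6–9 kb range of real chimpanzee
  ERV consensus elements).

**Junction hygiene.** Exact-recovery tests are only well-posed if the
realized junction hallmarks equal the recorded ones. In random sequence a
chance 2-bp "TSD" appears at ~1/16 of blunt junctions, and a planted k-bp TSD
can appear (k+1)-bp long whenever the neighbouring bases happen to extend the
repeat. The generator therefore adjusts single bases immediately outside each
junction until the realized longest duplication (and each junction's realized
microhomology) equals exactly what the ledger records. This changes at most a
few bases per event and none of the orthologous coordinates.

What the generator deliberately does **not** model: flank indels, nested or
overlapping insertions, segmental duplications, repeat-rich flanks, GC
heterogeneity, and recombination. Passing the round-trip tests therefore
shows the algorithms are correct under clean mappable conditions, not that
the thresholds are tuned for real repeat-dense genomes.

## Catalog: defragmentation

RepeatMasker reports a provirus as separate LTR / internal / LTR rows, and
often splits the internal region further. `defragment()` chains same-strand,
same-family fragments whose gaps are ≤ `max_gap_bp` and classifies the
merged run. The default `max_gap_bp = 1000` sits well below the simulator's
5-kb spacing and above its fragment splits; it is exposed because the right
value for a real genome depends on the annotation's fragmentation.

Two deliberate rules: a locus with two LTRs but no internal sequence is
`unknown`, not `solo_ltr` (that structure is genuinely ambiguous), and when
fragments are nested the longer one wins (a deterministic tie-break).

## Lineage filter

`map_flanks()` locates each flank by exact 16-mer seeding (one multi-pattern
scan per outgroup chromosome) followed by a pattern-global alignment against
the candidate window, so terminal mismatches do not trim the mapped interval
and the inter-flank gap is measured exactly. A flank maps at ≥ 85% identity
over ≥ 50% of its length; both flanks must land on one chromosome, same
strand, within 10× the element length.

`call_specificity()` then reads the orthologous inter-flank gap:

* gap ≤ 50 bp → **element absent** (the flanks abut; classical insertions
  give a small negative gap equal to the TSD length);
* large gap that aligns to the element consensus (either orientation, ≥ 85%
  identity) and reaches ≥ 50% of the element length → **element present**
  (a shared, pre-divergence insertion);
* large gap that does *not* resemble the element → host sequence present in
  the outgroup but missing from the ingroup: the element is **absent** and
  the gap is recorded — this is exactly the footprint of a
  deletion-associated non-classical insertion, so these loci stay eligible
  for NCPI calling rather than being discarded as ambiguous;
* element-like gap below the presence margin → ambiguous (`unmapped`).

The element-vs-gap alignment check prevents mistaking an unrelated insertion
at the orthologous position for presence of *this* element. One outgroup is
permitted (reduced stringency); the survey design used three.

## Anatomy

`detect_tsd()` scans up to 6 bp — one more than the classical 2–5 range — so
overlong duplications are observed rather than capped. Because a ≥ 2 bp
duplication arises by chance at ~1/16 of random junctions, **TSD absence is
never used alone**: NCPI calling also requires the orthologous gap evidence
above.

`screen_orfs()` translates the element-strand internal sequence in all three
frames (retroviral genes are co-oriented with the element, so the opposite
strand is not searched) and calls a gene intact when a single-frame
stop-free stretch covers ≥ 95% of the consensus gene length. The 0.95
threshold is this package's choice — published screens say "intact" without
quantifying — and is exposed as `intact_fraction`. All four genes intact
sets `rc_flag`, the retrotransposition-competence screen.

## Dating

`k2p()` implements the Kimura-2-parameter distance
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` with gap and ambiguity columns
excluded (the "without indel" convention; ambiguity codes are treated like
gaps, the conservative reading). Saturation (non-positive log arguments) and
zero comparable sites are errors, not NaNs.

`estimate_age()` converts a divergence into an age interval using the two
neutral-rate calibrations of 0.26 and 0.20 % per site per myr. Both LTRs
mutate independently, so `T = d / (2r)`; the old/young bound ratio is
0.26/0.20 = 1.3 exactly, for any positive divergence. The divergence fed in
is explicit: for a single element it is the 5′↔3′ LTR distance of that
element, for a subfamily the mean over all unordered LTR pairs
(`subfamily_statistics()`). Rho-statistic network dating is out of scope;
when published ages disagree with `d/(2r)` applied to a published mean
distance, the discrepancy traces to that methodological difference, which
this package does not attempt to reproduce.

Multiple alignment for consensus building (`align_ltr_set()`) is
reference-anchored: every sequence is globally aligned to the first and
projected onto its columns, dropping insertions relative to the reference.
For LTR sets at ≥ 85% identity this is adequate; it is not a general MSA
tool. `build_consensus()` takes per-column majorities, writes IUPAC codes on
ties, and drops all-gap columns.

## NCPI detection

A locus is an NCPI candidate iff no 2–5 bp TSD was detected **and** the
locus is ingroup-specific with mapped flanks; the associated deletion per
outgroup is the orthologous inter-flank gap (zero-gap candidates are kept as
insertion-only NCPIs). The consensus deletion is the median across
outgroups — robust to a lineage-specific indel in one outgroup — flagged
when estimates disagree by more than 10 bp or 10%, and flagged
low-confidence with a single outgroup. `scan_microhomology()` reports the
longest exact flank/element overlap at each junction, scanned to 10 bp so
the length distribution around the typical 2–3 bp can be examined. Whether
the deletion preceded or accompanied the insertion is not inferable from
sequence; the package records the sizes and does not attempt to resolve
timing.

## Polymorphism and reports

`classify_locus_polymorphism()` counts distinct non-missing allelic states
(absent / solitary LTR / full element) per locus: 1 = fixed, 2 = dimorphic,
3 = trimorphic. Missing genotypes are excluded rather than imputed — a PCR
panel simply shows bands or not. Percentages round half-up to one decimal,
matching printed-table conventions. The reference assembly is not counted as
an extra pseudo-individual by default. `family_summary()` and
`density_table()` produce the per-subfamily structure table and the
insertions-per-Mbp chromosome profile.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 7, ancestor_length_bp = 5e5,
                         n_chromosomes = 2, n_full_length = 3, n_solo_ltr = 3,
                         n_truncated = 2, n_ncpi = 2, n_decoy_shared = 1)
sim <- simulate_erv_truth(cfg, k_outgroups = 2)

out <- tempfile(fileext = ".out")
emit_repeatmasker_out(bind_rows(sim$ledger, sim$decoys), sim$chrom_lengths, out)
res <- run_erv_pipeline(sim$ingroup, parse_repeatmasker_out(out),
                        sim$outgroups, sim$consensus)
glance(res)
#> # A tibble: 1 x 7
#>   n_loci n_ingroup_specific n_shared n_unresolved n_full_length n_ncpi  n_rc
#> 1     11                 10        1            0             4      2     1
```

The decoy is called `shared` and drops out; the ten ingroup events are
recovered with their exact categories, TSDs, deletion sizes and
microhomologies (see `tests/testthat/` for the full round-trip checks, and
the repository's `scripts/acceptance.R` for the measured recovery rates).

## Numerical and scale choices

* Alignment scoring: match +1, mismatch −1, gap open 5, extend 2 — generic
  high-identity settings; identities in play are ≥ 85%.
* Seeding: 16-mers every 150 bp along a 2-kb flank (~13 seeds); at 2%
  divergence each seed survives with probability 0.98^16 ≈ 0.72, so a flank
  essentially never loses all seeds. The modal seed diagonal nominates the
  window.
* Validation problem sizes: round-trip tests run on 0.5-Mb genomes; the
  property suite runs 97 planted events on a 10-Mb, four-chromosome genome
  with three outgroups — large enough that every stage sees dozens of loci,
  small enough to iterate on quickly. Parameter-recovery uses 100 replicate
  400-bp LTR pairs at a planted age of 2 myr; the replicate-mean divergence
  recovers 2Tr within a few percent and its calibration interval brackets
  the true age. A single 400-bp pair cannot do that: at d ≈ 0.009 the
  interval spans only ~0.0024 in divergence while one pair's sampling noise
  is ~0.005, so per-pair age intervals at this length are reported but
  should not be over-read.
* Determinism: every random step derives from `simulation_config(seed=)`;
  the global RNG state is saved and restored around each draw, and repeated
  runs write byte-identical FASTA/.out/JSON.

## Known limitations

* The lineage filter assumes colinear outgroups (no inversions spanning a
  flank pair) and unique flanks; paralogous flanks return `unresolved`
  rather than a guess.
* Deletion sizes are exact only up to outgroup-lineage indels near the
  locus, which the simulator does not generate; on real data the median
  across ≥ 2 outgroups plus the discordance flag is the guard.
* The reading-frame screen checks stop-free coverage, not protein function,
  and the gene model must come from the subfamily consensus.
* Thresholds (85% identity, 50-bp absence gap, 0.5 presence margin, 0.95
  intact fraction) are package defaults surfaced in the API, chosen for
  clean synthetic data and the high-identity great-ape regime; they are the
  knobs to revisit first on other clades.
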