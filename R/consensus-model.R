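#' Build a synthetic ERV subfamily consensus set
#'
#' Constructs one consensus element per subfamily with the canonical
#' 5'LTR–internal–3'LTR proviral architecture. The internal region carries
#' four stop-free coding genes (*gag*, *pro*, *pol*, *env*) laid out
#' sequentially with short non-coding spacers, so reading-frame screens have a
#' defined ground truth. Gene lengths approximate the 8.6–9 kb proviruses of
#' chimpanzee-specific ERV families.
#'
#' @param subfamilies Character vector of subfamily labels.
#' @param seed Integer seed; the set is deterministic given the seed.
#' @param ltr_length Integer LTR length per subfamily (recycled).
#' @param gene_lengths Named integer vector of coding lengths (nt, multiples
#'   of 3) for `gag`, `pro`, `pol`, `env`.
#' @param utr5,utr3,spacer Non-coding segment lengths inside the internal
#'   region.
#' @param gc GC fraction of non-coding parts.
#'
#' @return A tibble with one row per subfamily: `subfamily`, `ltr`,
#'   `internal` (character sequences), `ltr_length`, `internal_length`, and a
#'   `gene_model` list-column (tibble of `gene`, `start`, `end` 0-based
#'   half-open on the internal sequence).
#' @export
#' @examples
#' cs <- erv_consensus_set(c("CERV1", "CERV2"), seed = 1)
#' cs$ltr_length
erv_consensus_set <- function(subfamilies = c("CERV1", "CERV2"),
                              seed = 1L,
                              ltr_length = 400L,
                              gene_lengths = c(gag = 1500L, pro = 450L,
                                               pol = 3300L, env = 1950L),
                              utr5 = 150L, utr3 = 150L, spacer = 25L,
                              gc = 0.5) {
  assert_that(length(subfamilies) >= 1, "need at least one subfamily label")
  assert_that(all(gene_lengths %% 3 == 0), "gene lengths must be codon multiples")
  ltr_length <- rep_len(as.integer(ltr_length), length(subfamilies))
  with_seed(seed, {
    rows <- purrr::map(seq_along(subfamilies), function(i) {
      ltr <- random_dna(ltr_length[i], gc)
      parts <- list(utr5 = random_dna(utr5, gc))
      model <- list()
      pos <- utr5
      genes <- c("gag", "pro", "pol", "env")
      for (g in genes) {
        len <- gene_lengths[[g]]
        cod <- random_coding(len)
        parts[[g]] <- cod
        model[[g]] <- tibble(gene = g, start = pos, end = pos + len)
        pos <- pos + len
        if (g != "env") {
          parts[[paste0("sp_", g)]] <- random_dna(spacer, gc)
          pos <- pos + spacer
        }
      }
      parts$utr3 <- random_dna(utr3, gc)
      internal <- paste(unlist(parts), collapse = "")
      tibble(
        subfamily = subfamilies[i],
        ltr = ltr,
        internal = internal,
        ltr_length = nchar(ltr),
        internal_length = nchar(internal),
        gene_model = list(bind_rows(model))
      )
    })
    bind_rows(rows)
  })
}

# stop-free random coding sequence of length n (n %% 3 == 0)
random_coding <- function(n) {
  stopifnot(n %% 3 == 0)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n / 3, replace = TRUE), collapse = "")
}

# full proviral sequence for one consensus row
consensus_provirus <- function(cons_row) {
  paste0(cons_row$ltr, cons_row$internal, cons_row$ltr)
}

#' Write a consensus set to FASTA
#'
#' Emits `<subfamily>-LTR` and `<subfamily>-int` records, the naming
#' convention used by repeat libraries for LTR and internal proviral parts.
#'
#' @param cons A consensus set from [erv_consensus_set()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(cons, path) {
  seqs <- c(
    setNames(cons$ltr, paste0(cons$subfamily, "-LTR")),
    setNames(cons$internal, paste0(cons$subfamily, "-int"))
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a consensus FASTA into LTR/internal tibble form
#'
#' Expects `<subfamily>-LTR` / `<subfamily>-int` record names (as written by
#' [write_consensus_fasta()], matching repeat-library conventions).
#'
#' @param path FASTA path.
#' @return A tibble with `subfamily`, `ltr`, `internal`, lengths; rows lacking
#'   an internal record get `internal = NA` (LTR-only consensus).
#' @export
read_consensus_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- names(ss)
  fam <- sub("[-_](LTR|int|I)$", "", nm)
  kind <- ifelse(grepl("[-_]LTR$", nm), "ltr", "internal")
  df <- tibble(subfamily = fam, kind = kind, seq = as.character(ss))
  df <- tidyr::pivot_wider(df, names_from = "kind", values_from = "seq")
  if (!"internal" %in% names(df)) df$internal <- NA_character_
  mutate(df,
    ltr_length = nchar(.data$ltr),
    internal_length = ifelse(is.na(.data$internal), NA_integer_, nchar(.data$internal))
  )
}
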