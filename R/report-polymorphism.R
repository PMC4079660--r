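# Polymorphism summaries of genotype matrices (locus x individual allelic
# states), per-family tables, and chromosomal insertion density.

VALID_STATES <- c("absent", "solo_ltr", "full_length", "missing")

#' Read a genotype table
#'
#' Long-format TSV with columns `locus_id`, `individual`, `state`
#' (`absent` / `solo_ltr` / `full_length` / `missing`).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_genotypes <- function(path) {
  gt <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
  bad <- setdiff(unique(gt$state), VALID_STATES)
  assert_that(length(bad) == 0,
              paste("invalid genotype states:", paste(bad, collapse = ", ")))
  gt
}

#' Classify the allelic polymorphism of one locus
#'
#' LTR retroelement loci can segregate in three forms (trimorphism): element
#' absent, full element present, solitary LTR present. Counting the distinct
#' non-missing states over individuals: 1 state = `fixed`, 2 = `dimorphic`,
#' 3 = `trimorphic`. Missing genotypes are excluded, not imputed.
#'
#' @param states Character vector of per-individual states.
#' @return `"fixed"`, `"dimorphic"`, `"trimorphic"`, or `NA` when fewer than
#'   two individuals are non-missing.
#' @export
#' @examples
#' classify_locus_polymorphism(c("full_length", "solo_ltr", "full_length"))
classify_locus_polymorphism <- function(states) {
  assert_that(all(states %in% VALID_STATES),
              "states must be absent/solo_ltr/full_length/missing")
  obs <- states[states != "missing"]
  if (length(obs) < 2) return(NA_character_)
  c("fixed", "dimorphic", "trimorphic")[length(unique(obs))]
}

#' Polymorphism rate over a set of assayed loci
#'
#' A locus is polymorphic when it is dimorphic or trimorphic. The percent is
#' half-up rounded to one decimal, the printed-table convention.
#'
#' @param genotypes Long tibble (`locus_id`, `individual`, `state`),
#'   optionally with a `family` column.
#' @param family Optional family label to filter on.
#' @return One-row tibble: `n_polymorphic`, `n_assayed`, `percent`.
#' @export
#' @examples
#' gt <- tidyr::expand_grid(locus_id = paste0("L", 1:4),
#'                          individual = paste0("ind", 1:3))
#' gt$state <- "full_length"
#' gt$state[1] <- "absent"
#' polymorphism_rate(gt)
polymorphism_rate <- function(genotypes, family = NULL) {
  if (!is.null(family) && "family" %in% names(genotypes)) {
    genotypes <- filter(genotypes, .data$family == !!family)
  }
  per_locus <- genotypes |>
    group_by(.data$locus_id) |>
    summarise(class = classify_locus_polymorphism(.data$state),
              .groups = "drop") |>
    filter(!is.na(.data$class))
  n_assayed <- nrow(per_locus)
  if (n_assayed == 0) {
    return(tibble(n_polymorphic = NA_integer_, n_assayed = 0L,
                  percent = NA_real_))
  }
  n_poly <- sum(per_locus$class %in% c("dimorphic", "trimorphic"))
  tibble(
    n_polymorphic = n_poly, n_assayed = n_assayed,
    percent = round_half_up(100 * n_poly / n_assayed, 1)
  )
}

#' Per-subfamily and per-family structure summary
#'
#' For each subfamily: copy number, full-length count, solitary-LTR count,
#' truncated/unknown counts, mean LTR length; per family the solitary-LTR
#' percentage `100 * sum(solo) / sum(copies)` (half-up, one decimal).
#'
#' @param loci Catalog tibble with `category` and `subfamily` columns.
#' @param family_of Optional named character vector mapping subfamily →
#'   family; unmapped subfamilies form their own family.
#' @param ltr_lengths Optional named numeric vector of mean LTR length per
#'   subfamily (reported as-is when provided; otherwise computed from LTR
#'   spans if present).
#' @return A list with `subfamilies` (one row per subfamily) and `families`
#'   (copy number, solo count, `solo_percent`).
#' @export
family_summary <- function(loci, family_of = NULL, ltr_lengths = NULL) {
  mean_ltr_len <- function(df) {
    lens <- c(df$ltr5_end - df$ltr5_start, df$ltr3_end - df$ltr3_start)
    if (all(is.na(lens))) NA_real_ else round_half_up(mean(lens, na.rm = TRUE))
  }
  sub <- loci |>
    group_by(subfamily = .data$subfamily) |>
    summarise(
      copy_number = n(),
      n_full_length = sum(.data$category == "full_length"),
      n_solo_ltr = sum(.data$category == "solo_ltr"),
      n_truncated = sum(.data$category == "truncated"),
      n_unknown = sum(.data$category == "unknown"),
      .groups = "drop"
    )
  if (!is.null(ltr_lengths)) {
    sub$mean_ltr_length <- unname(ltr_lengths[sub$subfamily])
  } else if (all(c("ltr5_start", "ltr5_end") %in% names(loci))) {
    sub$mean_ltr_length <- vapply(sub$subfamily, function(sf) {
      mean_ltr_len(loci[!is.na(loci$subfamily) & loci$subfamily == sf, ])
    }, double(1))
  } else {
    sub$mean_ltr_length <- NA_real_
  }
  fam_label <- if (is.null(family_of)) sub$subfamily else {
    ifelse(is.na(family_of[sub$subfamily]), sub$subfamily,
           family_of[sub$subfamily])
  }
  fam <- sub |>
    mutate(family = fam_label) |>
    group_by(.data$family) |>
    summarise(
      copy_number = sum(.data$copy_number),
      n_full_length = sum(.data$n_full_length),
      n_solo_ltr = sum(.data$n_solo_ltr),
      .groups = "drop"
    ) |>
    mutate(solo_percent = round_half_up(100 * .data$n_solo_ltr /
                                          .data$copy_number, 1))
  list(subfamilies = sub, families = fam)
}

#' Chromosomal insertion density table
#'
#' Per chromosome: count per structural category, chromosome length, and
#' density in insertions per Mbp.
#'
#' @param loci Catalog tibble (`chrom`, `category`).
#' @param chrom_lengths Named vector of chromosome lengths in bp (> 0).
#' @return A tibble, one row per chromosome, classed `erv_density`.
#' @export
density_table <- function(loci, chrom_lengths) {
  assert_that(all(chrom_lengths > 0), "chromosome lengths must be positive")
  unknown <- setdiff(unique(loci$chrom), names(chrom_lengths))
  assert_that(length(unknown) == 0,
              paste("loci on unknown chromosome(s):",
                    paste(unknown, collapse = ", ")))
  cats <- c("full_length", "solo_ltr", "truncated", "unknown")
  rows <- lapply(names(chrom_lengths), function(ch) {
    sub <- loci[loci$chrom == ch, ]
    cnt <- vapply(cats, function(k) sum(sub$category == k), integer(1))
    tibble(
      chrom = ch,
      n_full_length = cnt[["full_length"]], n_solo_ltr = cnt[["solo_ltr"]],
      n_truncated = cnt[["truncated"]], n_unknown = cnt[["unknown"]],
      n_total = nrow(sub),
      length_bp = unname(chrom_lengths[ch]),
      density_per_mbp = nrow(sub) / (unname(chrom_lengths[ch]) / 1e6)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("erv_density", class(out))
  out
}
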