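# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# transversion partners of each base
TRANSVERSIONS <- list(
  A = c("C", "T"), G = c("C", "T"),
  C = c("A", "G"), T = c("A", "G")
)

# IUPAC code for a set of bases (sorted, comma-free)
IUPAC_FROM_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

#' Run code with a locally fixed RNG seed
#'
#' Saves and restores the global RNG state, so simulations are deterministic
#' for a given seed without clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# derive a reproducible sub-seed, kept inside 32-bit integer range
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1299709 + offset * 104729) %% 2147483587L)
}

# random DNA string of length n (character scalar)
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# reverse complement of a character DNA string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# point-mutate a character DNA string: each site substituted with
# probability p; transitions twice as likely as each class of transversion
# (ts:tv = 2:1 overall).
mutate_dna_chr <- function(x, p) {
  n <- nchar(x)
  if (n == 0L || p <= 0) return(x)
  m <- rbinom(1L, n, min(p, 1))
  if (m == 0L) return(x)
  pos <- sample.int(n, m)
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  is_ts <- runif(m) < 2 / 3
  for (i in seq_len(m)) {
    b <- v[pos[i]]
    if (!b %in% DNA_BASES) next
    v[pos[i]] <- if (is_ts[i]) TRANSITION[[b]] else sample(TRANSVERSIONS[[b]], 1L)
  }
  paste(v, collapse = "")
}

# substring helpers on 0-based half-open coordinates
substr0 <- function(x, start0, end0) substr(x, start0 + 1L, end0)

# half-up rounding (printed-percentage convention)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

# longest exact overlap: suffix of `a` equal to prefix of `b`, up to max_len
suffix_prefix_overlap <- function(a, b, max_len = 10L) {
  kmax <- min(max_len, nchar(a), nchar(b))
  best <- 0L
  for (k in seq_len(kmax)) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) best <- k
  }
  best
}

# stop codon positions (1-based nt offset of codon start) in frame f (0,1,2)
stop_codon_starts <- function(seq, frame) {
  n <- nchar(seq)
  starts <- seq.int(1L + frame, n - 2L, by = 3L)
  if (length(starts) == 0L) return(integer())
  cods <- substring(seq, starts, starts + 2L)
  starts[cods %in% c("TAA", "TAG", "TGA")]
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}
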