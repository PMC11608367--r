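#' Round half away from zero
#'
#' Reported means and percentage ratios are rounded half-up to match the
#' conventional formatting of cohort tables (e.g. 33.82, 74.62), rather
#' than with R's round-half-even rule.
#'
#' @param x Numeric vector (non-negative in all pipeline uses).
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half-up to `digits` places.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

# Deterministic integer seed derived from a sequence of integer labels.
# Horner scheme over a Mersenne prime; all intermediates stay < 2^53 so the
# arithmetic is exact in doubles.  Used to give every species and gene its
# own reproducible RNG stream.
mix_seed <- function(...) {
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (x in c(...)) {
    h <- (h * 48271 + (as.numeric(x) %% m) + 1) %% m
  }
  as.integer(h)
}

# shared 0-row hit table so every scanner path returns identical columns
empty_hits <- function() {
  tibble::tibble(
    protein_id = character(), gene_id = character(), species_id = character(),
    start = integer(), end = integer(), dtype = character(),
    spacer1 = integer(), spacer2 = integer(),
    cys_positions = list(), domain_seq = character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
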