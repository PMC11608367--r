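# Per-position amino-acid frequency profiles for fixed-length domain types.
#
# Only the fixed-length complete types (IVa 25, IVb 26, IVc 28, IV4 28)
# can be profiled: same-type domains share their length exactly, so
# stacking is positional and no aligner is involved.  IVe and IVp vary in
# length and are excluded.

#' Stack same-type domain sequences into a residue matrix
#'
#' @param hits Hit tibble whose rows all carry the requested type.
#' @param dtype One of `"IVa"`, `"IVb"`, `"IVc"`, `"IV4"`.
#' @return Character matrix, one row per domain (input order), one column
#'   per position.
#' @export
stack_domains <- function(hits, dtype) {
  if (!dtype %in% names(FIXED_LENGTH_TYPES)) {
    stop("dtype must be fixed-length (IVa, IVb, IVc, IV4); got ", dtype,
      call. = FALSE
    )
  }
  if (nrow(hits) == 0) {
    return(matrix(character(0), nrow = 0, ncol = FIXED_LENGTH_TYPES[[dtype]]))
  }
  if (!all(hits$dtype == dtype)) {
    stop("mixed domain types in stack; all hits must be ", dtype,
      call. = FALSE
    )
  }
  len <- FIXED_LENGTH_TYPES[[dtype]]
  if (!all(nchar(hits$domain_seq) == len)) {
    stop("domain_seq length mismatch for type ", dtype, call. = FALSE)
  }
  do.call(rbind, strsplit(hits$domain_seq, "", fixed = TRUE))
}

#' Build a positional frequency profile
#'
#' Counts each of the 20 standard residues plus `X` at every position of a
#' stacked same-type domain cohort, and normalises by the number of
#' domains.  `X` occupies its own column and counts in the denominator —
#' unknown residues depress conservation, they never inflate it — but can
#' never be the reported modal residue.
#'
#' @param stack Residue matrix from [stack_domains()] (at least one row).
#' @param dtype Domain type of the stack.
#' @param group_label Stratum label (`"eudicots"`, `"monocots"`,
#'   `"non-angiosperms"`, `"all"`, ...).
#' @return A `FrequencyProfile`: list with `dtype`, `group_label`,
#'   `length`, `n_domains`, `counts` (length x 21 integer matrix) and
#'   `frequencies` (same shape; every row sums to 1).
#' @export
build_profile <- function(stack, dtype, group_label = "all") {
  if (nrow(stack) == 0) {
    stop("cannot build a profile from an empty stack", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(stack)), AA_ALPHABET21)
  if (length(bad) > 0) {
    stop("stack contains non-residue characters: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(stack)
  counts <- t(vapply(
    seq_len(ncol(stack)),
    function(j) tabulate(factor(stack[, j], levels = AA_ALPHABET21),
      nbins = length(AA_ALPHABET21)
    ),
    integer(length(AA_ALPHABET21))
  ))
  colnames(counts) <- AA_ALPHABET21
  rownames(counts) <- seq_len(nrow(counts))
  structure(
    list(
      dtype = dtype, group_label = group_label,
      length = ncol(stack), n_domains = n,
      counts = counts, frequencies = counts / n
    ),
    class = "FrequencyProfile"
  )
}

#' @export
print.FrequencyProfile <- function(x, ...) {
  cat(sprintf(
    "FrequencyProfile: type %s, stratum '%s', %d positions, %d domains\n",
    x$dtype, x$group_label, x$length, x$n_domains
  ))
  cons <- conserved_positions(x, 0.9)
  if (nrow(cons) > 0) {
    cat("positions conserved > 90%:",
      paste(sprintf("%s-%d (%.2f)", cons$residue, cons$position,
        cons$frequency
      ), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call conserved positions of a profile
#'
#' A position is conserved when its modal standard residue exceeds the
#' threshold strictly; ties at the mode are broken alphabetically.  `X` is
#' never reported as a modal residue.
#'
#' @param profile A `FrequencyProfile`.
#' @param threshold Fraction in (0, 1]; the field's convention for
#'   "highly conserved" is 0.90.
#' @return Tibble `position` (1-based within the domain), `residue`,
#'   `frequency`, sorted by position.
#' @export
conserved_positions <- function(profile, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  freq <- profile$frequencies[, AA_STANDARD, drop = FALSE]
  modal_idx <- apply(freq, 1, which.max) # first max = alphabetical tie-break
  modal_freq <- freq[cbind(seq_len(nrow(freq)), modal_idx)]
  keep <- modal_freq > threshold
  tibble::tibble(
    position = which(keep),
    residue = AA_STANDARD[modal_idx[keep]],
    frequency = modal_freq[keep]
  )
}

#' Build group-stratified profiles for one domain type
#'
#' Strata follow the three-way split used for angiosperm-wide comparisons:
#' `eudicots`, `monocots`, and `non-angiosperms` (gymnosperm,
#' marchantiophyta, bryophyta, lycopodiophyta, charophyta, chlorophytae
#' combined), plus `all`.  The basal angiosperm is kept out of
#' "non-angiosperms" and contributes only to `all`, so the three strata
#' sum to `all` minus any basal-angiosperm domains.  Strata with no
#' domains are dropped.
#'
#' @param hits Hit tibble.
#' @param species_info Species table.
#' @param dtype Fixed-length domain type.
#' @return Named list of `FrequencyProfile` objects.
#' @export
group_profiles <- function(hits, species_info, dtype) {
  h <- hits[hits$dtype == dtype, , drop = FALSE]
  grp <- species_info$group[match(h$species_id, species_info$species_id)]
  if (anyNA(grp) && nrow(h) > 0) {
    stop("hit species missing from species table: ",
      paste(unique(h$species_id[is.na(grp)]), collapse = ", "),
      call. = FALSE
    )
  }
  strata <- list(
    eudicots = grp == "eudicots",
    monocots = grp == "monocots",
    `non-angiosperms` = grp %in% NON_ANGIOSPERM_GROUPS,
    all = rep(TRUE, nrow(h))
  )
  out <- list()
  for (label in names(strata)) {
    sel <- h[strata[[label]], , drop = FALSE]
    if (nrow(sel) == 0) next
    out[[label]] <- build_profile(stack_domains(sel, dtype), dtype, label)
  }
  out
}

#' Flatten a profile to long format
#'
#' One row per (position, residue): the layout written to profile TSVs.
#'
#' @param profile A `FrequencyProfile`.
#' @return Tibble `dtype`, `group_label`, `position`, `residue`, `count`,
#'   `frequency`.
#' @export
profile_long <- function(profile) {
  grid <- expand.grid(
    position = seq_len(profile$length),
    residue = AA_ALPHABET21,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    dtype = profile$dtype,
    group_label = profile$group_label,
    position = grid$position,
    residue = grid$residue,
    count = as.integer(profile$counts[cbind(grid$position,
      match(grid$residue, AA_ALPHABET21))]),
    frequency = profile$frequencies[cbind(grid$position,
      match(grid$residue, AA_ALPHABET21))]
  )
}
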