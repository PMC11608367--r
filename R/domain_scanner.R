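# Class-IV zinc-finger grammar scanner.
#
# Coordinates: every start/end and cysteine position in a hit table is
# 0-based, half-open [start, end), matching the TSV output convention.
# Positions *inside* a domain (C-1 ... C-26 etc.) are 1-based wherever they
# are reported to the user, which is how the field narrates them.

# spacer1/spacer2 -> type lookup; spacer counts residues strictly between
# consecutive anchor cysteines, so CX2CX18CX2C spans 26 residues with
# cysteines at internal 1-based positions 1, 4, 23, 26.
.SPACER_TABLE <- list(
  IVa = list(s1 = 2L, s2 = 17L),
  IVb = list(s1 = 2L, s2 = 18L),
  IVc = list(s1 = 2L, s2 = 20L),
  IV4 = list(s1 = 4L, s2 = 18L)
)

#' Classify a cysteine-spacer pair into a domain type
#'
#' The complete class-IV types are defined by the residue counts strictly
#' between the first/second and second/third cysteines: (2,17) IVa,
#' (2,18) IVb, (2,20) IVc, (4,18) IV4.  The elastic type IVe keeps the
#' canonical CX2C flanks but an inner spacer of 16, 19 or 21 — the inner
#' lengths in 16–21 not claimed by a named type.  Any other combination is
#' not a class-IV domain and returns `NA`.
#'
#' @param spacer1,spacer2 Non-negative integer spacer lengths.
#' @return One of `"IVa"`, `"IVb"`, `"IVc"`, `"IV4"`, `"IVe"`, or
#'   `NA_character_` (not an error: "no type" is a value).
#' @export
classify_spacers <- function(spacer1, spacer2) {
  stopifnot(length(spacer1) == 1, length(spacer2) == 1,
    spacer1 >= 0, spacer2 >= 0)
  if (spacer1 == 2) {
    if (spacer2 == 17) return("IVa")
    if (spacer2 == 18) return("IVb")
    if (spacer2 == 20) return("IVc")
    if (spacer2 %in% c(16L, 19L, 21L)) return("IVe")
    return(NA_character_)
  }
  if (spacer1 == 4 && spacer2 == 18) return("IV4")
  NA_character_
}

.hit_row <- function(start0, end0, cys0, sp1, sp2, dtype, sequence) {
  tibble::tibble(
    protein_id = NA_character_, gene_id = NA_character_,
    species_id = NA_character_,
    start = as.integer(start0), end = as.integer(end0), dtype = dtype,
    spacer1 = as.integer(sp1), spacer2 = as.integer(sp2),
    cys_positions = list(as.integer(cys0)),
    domain_seq = substr(sequence, start0 + 1, end0)
  )
}

#' Enumerate all complete class-IV candidates in a sequence
#'
#' Every cysteine quadruple i < j < k < l with j-i-1 in `{2,4}`,
#' k-j-1 in `[16,21]` and l-k-1 == 2 that classifies to a type is emitted —
#' including mutually overlapping parses from nested cysteines, which are
#' resolved later by [resolve_overlaps()].  `X` never matches a cysteine
#' anchor.
#'
#' @param sequence Upper-case amino-acid string.
#' @return Hit tibble sorted by (start, end); identifier columns are `NA`
#'   at this level (filled by [scan_protein()]).
#' @export
enumerate_complete_candidates <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cys <- which(chars == "C")
  if (length(cys) < 4) return(empty_hits())
  is_c <- logical(n)
  is_c[cys] <- TRUE
  rows <- list()
  for (j in cys) {
    for (i in c(j - 3L, j - 5L)) { # spacer1 = 2 or 4
      if (i < 1 || !is_c[i]) next
      ks <- cys[cys >= j + 17L & cys <= j + 22L] # spacer2 in [16, 21]
      for (k in ks) {
        l <- k + 3L # spacer3 == 2
        if (l > n || !is_c[l]) next
        dt <- classify_spacers(j - i - 1L, k - j - 1L)
        if (is.na(dt)) next
        rows[[length(rows) + 1]] <- .hit_row(
          i - 1L, l, c(i, j, k, l) - 1L, j - i - 1L, k - j - 1L, dt, sequence
        )
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$start, .data$end)
}

# High-conservation residue profiles used to filter partial-domain
# candidates: offsets are relative to the second (c2) and third (c3)
# anchor cysteine of the complete reference type, so a template with any
# subset of anchors can be scored by anchoring the cysteines it still has.
.IVP_CONSENSUS <- list(
  IVb = list(
    c2 = c(`5` = "T", `6` = "P", `8` = "W", `9` = "R", `11` = "G",
           `12` = "P", `14` = "G"),
    c3 = c(`-1` = "L", `1` = "N", `2` = "A")
  ),
  IVc = list(
    c2 = c(`1` = "G", `7` = "T", `8` = "P", `10` = "M", `11` = "R",
           `12` = "R", `13` = "G", `14` = "P", `16` = "G"),
    c3 = c(`-3` = "R", `-1` = "L", `1` = "N", `2` = "A")
  )
)

# count reference-consensus matches inside [start1, end1] (1-based,
# inclusive), anchoring at whichever of c2/c3 the template retains;
# returns the best score over the IVb and IVc references
.consensus_score <- function(chars, start1, end1, c2_abs, c3_abs) {
  best <- 0L
  for (ref in .IVP_CONSENSUS) {
    s <- 0L
    if (!is.na(c2_abs)) {
      off <- as.integer(names(ref$c2))
      pos <- c2_abs + off
      ok <- pos >= start1 & pos <= end1
      s <- s + sum(chars[pos[ok]] == ref$c2[ok])
    }
    if (!is.na(c3_abs)) {
      off <- as.integer(names(ref$c3))
      pos <- c3_abs + off
      ok <- pos >= start1 & pos <= end1
      s <- s + sum(chars[pos[ok]] == ref$c3[ok])
    }
    best <- max(best, s)
  }
  best
}

#' Find partial-domain (type IVp) candidates
#'
#' Partial domains are complete class-IV domains that have lost anchor
#' cysteines.  Three templates are searched, with m in the spacer window
#' (default 12–21):
#'
#' * `C X{m} C X{2} C` — first anchor cysteine missing;
#' * `C X{2} C X{m}`   — C-terminal cysteine pair missing (the m-window
#'   must itself be cysteine-free; the maximal such m is reported);
#' * `C X{2} C X{m} C` — final cysteine missing.
#'
#' A template match is reported only where (i) its span does not intersect
#' any exclusion interval (the spans of retained complete hits), and
#' (ii) it passes a consensus filter: at least `min_consensus` matches to
#' the high-conservation residues of the complete reference types (IVb or
#' IVc, whichever scores better), aligned by anchoring the cysteines the
#' template still has to their counterparts.  `X` never counts as a
#' consensus match.
#'
#' For partial hits `spacer1`/`spacer2` record the gaps between the
#' cysteines actually present; a missing gap is `NA`.
#'
#' @param sequence Upper-case amino-acid string.
#' @param exclusion Data frame with 0-based half-open `start`, `end`
#'   columns (may have zero rows).
#' @param min_consensus Minimum consensus matches to keep a candidate
#'   (default 4).
#' @param spacer_window Inclusive `c(min, max)` for m (default `c(12, 21)`).
#' @return Hit tibble of `IVp` candidates sorted by (start, end).
#' @export
find_partial_candidates <- function(sequence, exclusion = NULL,
                                    min_consensus = 4,
                                    spacer_window = c(12L, 21L)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cys <- which(chars == "C")
  if (length(cys) < 2) return(empty_hits())
  wmin <- spacer_window[1]
  wmax <- spacer_window[2]
  ex_start <- ex_end <- integer(0)
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    ex_start <- exclusion$start
    ex_end <- exclusion$end
  }
  excluded <- function(s0, e0) any(s0 < ex_end & ex_start < e0)
  rows <- list()
  emit <- function(i, cys_abs, sp1, sp2, end1, c2_abs, c3_abs) {
    s0 <- i - 1L
    e0 <- end1
    if (excluded(s0, e0)) return(invisible(NULL))
    if (.consensus_score(chars, i, end1, c2_abs, c3_abs) < min_consensus) {
      return(invisible(NULL))
    }
    rows[[length(rows) + 1]] <<- .hit_row(
      s0, e0, cys_abs - 1L, sp1, sp2, "IVp", sequence
    )
    invisible(NULL)
  }
  is_c <- logical(n)
  is_c[cys] <- TRUE
  for (i in cys) {
    # (a) C X{m} C X{2} C : anchors c2, c3, c4
    ks <- cys[cys >= i + wmin + 1L & cys <= i + wmax + 1L]
    for (k in ks) {
      l <- k + 3L
      if (l <= n && is_c[l]) {
        emit(i, c(i, k, l), k - i - 1L, 2L, l, c2_abs = i, c3_abs = k)
      }
    }
    j <- i + 3L # C X{2} C prefix shared by (b) and (c)
    if (j > n || !is_c[j]) next
    # (c) C X{2} C X{m} C : anchors c1, c2, c3
    ks <- cys[cys >= j + wmin + 1L & cys <= j + wmax + 1L]
    for (k in ks) {
      emit(i, c(i, j, k), 2L, k - j - 1L, k, c2_abs = j, c3_abs = k)
    }
    # (b) C X{2} C X{m} : anchors c1, c2; maximal cysteine-free m
    after <- cys[cys > j]
    lim <- if (length(after) > 0) min(after) - j - 1L else n - j
    m <- min(wmax, lim, n - j)
    if (m >= wmin) {
      emit(i, c(i, j), 2L, NA_integer_, j + m, c2_abs = j, c3_abs = NA)
    }
  }
  if (length(rows) == 0) return(empty_hits())
  dplyr::arrange(dplyr::bind_rows(rows), .data$start, .data$end)
}

#' Resolve overlapping candidates into a disjoint hit set
#'
#' Greedy selection: candidates are ranked complete before partial, then by
#' type priority IVb > IVc > IVa > IV4 > IVe > IVp (the two dominant
#' biological types first), then by smaller start, then smaller end.  A
#' candidate is accepted iff it shares no residue with any already-accepted
#' hit.  The rule is deterministic and documented, rather than the "first
#' match wins" of an unspecified regex engine.
#'
#' @param candidates Hit tibble (any order).
#' @return Pairwise-disjoint hit tibble sorted by start.
#' @export
resolve_overlaps <- function(candidates) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(
    match(candidates$dtype, DTYPE_PRIORITY),
    candidates$start, candidates$end
  )
  acc_start <- acc_end <- numeric(0)
  keep <- integer(0)
  for (idx in ord) {
    s <- candidates$start[idx]
    e <- candidates$end[idx]
    if (!any(s < acc_end & acc_start < e)) {
      keep <- c(keep, idx)
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  out <- candidates[keep, , drop = FALSE]
  dplyr::arrange(out, .data$start, .data$end)
}

#' Scan one protein for GATA domains
#'
#' Pipeline per sequence: enumerate complete candidates, resolve their
#' overlaps, search the remaining sequence for partial (IVp) templates,
#' and merge into a disjoint hit list sorted by start.  Identical input
#' always yields an identical hit list.
#'
#' @param record One protein record: a one-row tibble or a list with
#'   `protein_id`, `gene_id`, `species_id`, `sequence`.
#' @param min_consensus,spacer_window Passed to
#'   [find_partial_candidates()].
#' @return Hit tibble with identifier columns filled.
#' @export
scan_protein <- function(record, min_consensus = 4,
                         spacer_window = c(12L, 21L)) {
  sequence <- record$sequence[[1]]
  complete <- resolve_overlaps(enumerate_complete_candidates(sequence))
  partial <- find_partial_candidates(
    sequence, exclusion = complete,
    min_consensus = min_consensus, spacer_window = spacer_window
  )
  hits <- resolve_overlaps(dplyr::bind_rows(complete, partial))
  if (nrow(hits) > 0) {
    hits$protein_id <- record$protein_id[[1]]
    hits$gene_id <- record$gene_id[[1]]
    hits$species_id <- record$species_id[[1]]
  }
  hits
}

#' Scan a set of protein records
#'
#' @param records Protein records ([read_fasta()]).
#' @param min_consensus,spacer_window Passed to [scan_protein()].
#' @return Combined hit tibble (possibly 0 rows), in record order.
#' @export
scan_proteins <- function(records, min_consensus = 4,
                          spacer_window = c(12L, 21L)) {
  if (nrow(records) == 0) return(empty_hits())
  out <- lapply(seq_len(nrow(records)), function(i) {
    scan_protein(records[i, ], min_consensus, spacer_window)
  })
  dplyr::bind_rows(out)
}

#' Write / read a hit table as TSV
#'
#' `cys_positions` is serialised as a comma-joined list of 0-based
#' positions.
#'
#' @param hits Hit tibble.
#' @param path TSV path.
#' @return `write_hits_tsv()`: invisibly, `path`; `read_hits_tsv()`: the
#'   hit tibble.
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- hits
  flat$cys_positions <- vapply(
    hits$cys_positions, function(x) paste(x, collapse = ","), character(1)
  )
  utils::write.table(flat, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = ""
  )
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", quote = "",
    colClasses = c(
      protein_id = "character", gene_id = "character",
      species_id = "character", start = "integer", end = "integer",
      dtype = "character", spacer1 = "integer", spacer2 = "integer",
      cys_positions = "character", domain_seq = "character"
    )
  )
  df$cys_positions <- lapply(
    strsplit(df$cys_positions, ",", fixed = TRUE), as.integer
  )
  tibble::as_tibble(df)
}
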