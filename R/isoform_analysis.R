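# Alternative-splicing structure per gene: form counts, UTR-only AS,
# and AS-driven domain-type changes.

.COMPLETE_TYPES <- c("IVb", "IVc", "IVa", "IV4", "IVe")

#' Detect UTR-restricted alternative splicing
#'
#' A gene's AS is called UTR-only when all of its protein isoforms are
#' byte-identical: the coding region is untouched and the variants can
#' only differ in untranslated regions.  This is a protein-level proxy —
#' transcript models are not available from protein FASTA.
#'
#' @param group One isoform group (one row of [build_isoform_groups()]
#'   output, or a list with `isoform_ids` and `n_forms`).
#' @param records Protein records covering the group's isoforms.
#' @return `TRUE`/`FALSE`.  Calling this on a single-isoform gene is
#'   undefined and raises an error.
#' @export
detect_utr_only <- function(group, records) {
  ids <- group$isoform_ids[[1]]
  if (length(ids) < 2) {
    stop("detect_utr_only is undefined for a single-isoform gene",
      call. = FALSE
    )
  }
  seqs <- records$sequence[match(ids, records$protein_id)]
  if (anyNA(seqs)) {
    stop("isoform(s) missing from records: ",
      paste(ids[is.na(seqs)], collapse = ", "),
      call. = FALSE
    )
  }
  all(seqs == seqs[1])
}

# multiset comparison helpers ---------------------------------------------

.type_multiset <- function(x) sort(x)

.is_strict_submultiset <- function(a, b) {
  if (length(a) >= length(b)) return(FALSE)
  ta <- table(a)
  tb <- table(b)
  extra <- setdiff(names(ta), names(tb))
  if (length(extra) > 0) return(FALSE)
  all(as.integer(ta) <= as.integer(tb[names(ta)]))
}

#' Classify the AS-driven domain-type change of a gene
#'
#' Compares the multiset of domain types carried by each isoform:
#'
#' * `partial_conversion` — some isoform carries a partial (IVp) domain
#'   while another carries a complete type, and the multisets differ: a
#'   complete domain has been truncated by splicing;
#' * `domain_loss` — one isoform's multiset is a strict sub-multiset of
#'   another's: a domain disappears entirely;
#' * `other_change` — multisets differ in any other way;
#' * `none` — all isoforms carry the same types.
#'
#' Precedence when several apply: partial_conversion > domain_loss >
#' other_change.  Multisets are compared without coordinate projection:
#' isoform-to-isoform coordinate maps do not exist without a genome
#' alignment.
#'
#' @param group One isoform group with at least two isoforms.
#' @param hits Hit tibble covering the group's isoforms (hits of other
#'   proteins are ignored).
#' @return One of `"none"`, `"partial_conversion"`, `"domain_loss"`,
#'   `"other_change"`.
#' @export
domain_change_events <- function(group, hits) {
  ids <- group$isoform_ids[[1]]
  if (length(ids) < 2) {
    stop("domain_change_events needs at least two isoforms", call. = FALSE)
  }
  ms <- lapply(ids, function(id) {
    .type_multiset(hits$dtype[hits$protein_id == id])
  })
  all_equal <- all(vapply(ms, identical, logical(1), y = ms[[1]]))
  if (all_equal) return("none")
  has_ivp <- vapply(ms, function(x) "IVp" %in% x, logical(1))
  has_complete <- vapply(
    ms, function(x) any(x %in% .COMPLETE_TYPES), logical(1)
  )
  # partial on one isoform, complete on a *different* isoform
  conversion <- any(vapply(seq_along(ms), function(i) {
    has_ivp[i] && any(has_complete[-i])
  }, logical(1)))
  if (conversion) return("partial_conversion")
  loss <- any(vapply(seq_along(ms), function(i) {
    any(vapply(seq_along(ms), function(j) {
      i != j && .is_strict_submultiset(ms[[i]], ms[[j]])
    }, logical(1)))
  }, logical(1)))
  if (loss) return("domain_loss")
  "other_change"
}

#' Annotate isoform groups with AS flags
#'
#' Adds `utr_only` (NA for single-isoform genes) and `change_event`
#' (`"none"` for single-isoform genes) to an isoform-group table.
#'
#' @param groups Output of [build_isoform_groups()].
#' @param records Protein records.
#' @param hits Hit tibble for the same records.
#' @return `groups` with `utr_only` and `change_event` columns.
#' @export
annotate_isoform_groups <- function(groups, records, hits) {
  n <- nrow(groups)
  utr <- rep(NA, n)
  ev <- rep("none", n)
  for (i in seq_len(n)) {
    if (groups$n_forms[i] >= 2) {
      g <- groups[i, ]
      utr[i] <- detect_utr_only(g, records)
      ev[i] <- domain_change_events(g, hits)
    }
  }
  groups$utr_only <- utr
  groups$change_event <- ev
  groups
}

#' Distribution of AS-form counts by taxonomic group
#'
#' Counts genes with two or more protein isoforms, cross-tabulated by
#' number of forms (rows 2..max observed) and taxonomic group (the nine
#' lineages), with a row-total and a percentage-of-all-AS-genes column
#' (half-up, 2 decimals).
#'
#' @param groups Isoform groups ([build_isoform_groups()]).
#' @param species_info Species table ([read_species_table()]).
#' @return Tibble with `n_forms`, one column per group, `total`,
#'   `ratio_pct`.  Zero rows when no gene has 2+ forms.
#' @export
as_form_distribution <- function(groups, species_info) {
  as_genes <- groups[groups$n_forms >= 2, , drop = FALSE]
  if (nrow(as_genes) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(integer(0)), rep(list(integer(0)), length(GATA_GROUPS)),
        list(integer(0)), list(numeric(0))),
      c("n_forms", GATA_GROUPS, "total", "ratio_pct")
    ))
    return(out)
  }
  grp <- species_info$group[match(as_genes$species_id, species_info$species_id)]
  if (anyNA(grp)) {
    stop("species missing from species table: ",
      paste(unique(as_genes$species_id[is.na(grp)]), collapse = ", "),
      call. = FALSE
    )
  }
  tab <- table(
    factor(as_genes$n_forms, levels = 2:max(as_genes$n_forms)),
    factor(grp, levels = GATA_GROUPS)
  )
  counts <- tibble::as_tibble(as.data.frame.matrix(tab))
  counts <- dplyr::mutate(counts, dplyr::across(dplyr::everything(), as.integer))
  out <- dplyr::bind_cols(
    tibble::tibble(n_forms = as.integer(rownames(tab))), counts
  )
  as_form_distribution_from_counts(out)
}

#' Finish an AS-form distribution table from its per-group cells
#'
#' Adds the row totals and the percentage-of-total ratio column to a table
#' of per-group AS-gene counts; used both by [as_form_distribution()] and
#' to recompute the ratio column of an externally tabulated survey.
#'
#' @param counts Tibble/data frame with `n_forms` plus one column per
#'   taxonomic group.
#' @param total_as_genes Denominator for the ratio column; defaults to the
#'   table's own grand total.
#' @return The table with `total` and `ratio_pct` columns appended.
#' @export
as_form_distribution_from_counts <- function(counts,
                                             total_as_genes = NULL) {
  grp_cols <- intersect(GATA_GROUPS, names(counts))
  cells <- as.matrix(counts[, grp_cols, drop = FALSE])
  total <- as.integer(rowSums(cells))
  denom <- total_as_genes %||% sum(total)
  out <- tibble::as_tibble(counts)
  out$total <- total
  out$ratio_pct <- if (denom > 0) round_half_up(100 * total / denom) else
    rep(NA_real_, length(total))
  out
}

#' Per-gene domain-type change table
#'
#' One row per multi-isoform gene whose isoforms do not all share the same
#' domain-type multiset: gene identity, number of forms, how many IVb, IVc
#' and IVp domains its isoforms carry in total, and the change class.
#'
#' @param groups Isoform groups.
#' @param hits Hit tibble.
#' @param records Protein records.
#' @return Tibble `gene_id`, `species_id`, `n_forms`, `n_IVb`, `n_IVc`,
#'   `n_IVp`, `change_event`.
#' @export
domain_change_table <- function(groups, hits, records) {
  ann <- annotate_isoform_groups(groups, records, hits)
  chg <- ann[ann$change_event != "none", , drop = FALSE]
  count_type <- function(ids, t) {
    sum(hits$dtype[hits$protein_id %in% ids] == t)
  }
  tibble::tibble(
    gene_id = chg$gene_id,
    species_id = chg$species_id,
    n_forms = chg$n_forms,
    n_IVb = vapply(chg$isoform_ids, count_type, integer(1), t = "IVb"),
    n_IVc = vapply(chg$isoform_ids, count_type, integer(1), t = "IVc"),
    n_IVp = vapply(chg$isoform_ids, count_type, integer(1), t = "IVp"),
    change_event = chg$change_event
  )
}
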