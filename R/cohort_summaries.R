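# Cohort-level summary tables: per-species counts, domain-type counts and
# ratios by taxonomic group, gene-count and length statistics, genus and
# order aggregations.
#
# Conventions shared by every reported statistic:
# * domain totals count every isoform's hits separately — a gene with
#   three isoforms each carrying one IVb contributes three IVb domains,
#   since the cohort is tallied at the transcription-factor (isoform)
#   level, not the gene level;
# * count "bands" are closed intervals ("between 15 and 40" includes both
#   15 and 40);
# * means and percentage ratios are rounded half-up to 2 decimals.

#' Per-species gene / isoform summary
#'
#' @param records Protein records ([read_fasta()]).
#' @param groups Isoform groups; built from `records` when omitted.
#' @return Tibble, one row per species present: `species_id`, `n_genes`,
#'   `n_tfs` (protein isoforms), `n_as_genes` (genes with 2+ forms),
#'   `n_as_tfs` (isoforms belonging to those genes).
#' @export
species_summary <- function(records, groups = NULL) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      species_id = character(), n_genes = integer(), n_tfs = integer(),
      n_as_genes = integer(), n_as_tfs = integer()
    ))
  }
  groups <- groups %||% build_isoform_groups(records)
  tf <- records |>
    dplyr::count(.data$species_id, name = "n_tfs")
  g <- groups |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_as_genes = sum(.data$n_forms >= 2),
      n_as_tfs = sum(.data$n_forms[.data$n_forms >= 2]),
      .groups = "drop"
    )
  dplyr::left_join(g, tf, by = "species_id") |>
    dplyr::select("species_id", "n_genes", "n_tfs", "n_as_genes", "n_as_tfs") |>
    dplyr::arrange(.data$species_id)
}

#' Domain-type by taxonomic-group count table
#'
#' Cross-tabulates resolved domain hits by type (rows, all six types) and
#' group (columns, all nine lineages), and derives per-type percentage
#' ratios of the grand total.
#'
#' @param hits Hit tibble.
#' @param species_info Species table; every hit's species must be present.
#' @return A `GroupDomainTable`; see [group_domain_table_from_counts()].
#' @export
group_domain_table <- function(hits, species_info) {
  grp <- species_info$group[match(hits$species_id, species_info$species_id)]
  if (anyNA(grp) && nrow(hits) > 0) {
    stop("hit references species absent from species table: ",
      paste(unique(hits$species_id[is.na(grp)]), collapse = ", "),
      call. = FALSE
    )
  }
  counts <- table(
    factor(hits$dtype, levels = DOMAIN_TYPES),
    factor(grp, levels = GATA_GROUPS)
  )
  counts <- matrix(as.integer(counts),
    nrow = length(DOMAIN_TYPES),
    dimnames = list(DOMAIN_TYPES, GATA_GROUPS)
  )
  group_domain_table_from_counts(counts)
}

#' Assemble a GroupDomainTable from its cell counts
#'
#' The ratio step is separated from counting so an externally tabulated
#' count matrix (e.g. a transcribed published survey table) can be pushed
#' through the identical arithmetic: ratio = type total / grand total x
#' 100, rounded half-up to 2 decimals.
#'
#' @param counts Integer matrix, domain types in rows, groups in columns.
#' @return A `GroupDomainTable`: list with `counts`, `dtype_totals`,
#'   `group_totals`, `grand_total`, `ratio_pct`.
#' @export
group_domain_table_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must have domain types as row names", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  grand <- sum(counts)
  structure(
    list(
      counts = counts,
      dtype_totals = rowSums(counts),
      group_totals = colSums(counts),
      grand_total = grand,
      ratio_pct = domain_type_ratios(counts)
    ),
    class = "GroupDomainTable"
  )
}

#' Percentage ratio of each domain type
#'
#' @param counts Count matrix (types x groups) or a `GroupDomainTable`.
#' @return Named numeric vector: type total / grand total x 100, half-up,
#'   2 decimals.  Sums to 100 within rounding slack.
#' @export
domain_type_ratios <- function(counts) {
  if (inherits(counts, "GroupDomainTable")) counts <- counts$counts
  tot <- rowSums(counts)
  grand <- sum(tot)
  if (grand == 0) {
    return(stats::setNames(rep(NA_real_, length(tot)), names(tot)))
  }
  round_half_up(100 * tot / grand)
}

#' @export
print.GroupDomainTable <- function(x, ...) {
  cat(sprintf("GroupDomainTable: %d domains\n", x$grand_total))
  m <- cbind(x$counts, total = x$dtype_totals, ratio_pct = x$ratio_pct)
  print(m)
  invisible(x)
}

#' @export
as.data.frame.GroupDomainTable <- function(x, ...) {
  data.frame(
    dtype = rownames(x$counts), x$counts,
    total = x$dtype_totals, ratio_pct = x$ratio_pct,
    row.names = NULL, check.names = FALSE
  )
}

.band_stats <- function(x, band) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  inb <- x >= band[1] & x <= band[2]
  list(
    min = min(x), max = max(x),
    mean = round_half_up(mean(x)),
    n_in_band = sum(inb),
    fraction_in_band = sum(inb) / length(x)
  )
}

#' Gene-count statistics over a set of taxonomic groups
#'
#' @param summaries Per-species summaries ([species_summary()]), or any
#'   tibble with `species_id` and `n_genes`.
#' @param species_info Species table.
#' @param groups Character vector of group names to include.
#' @param band Closed interval `c(lo, hi)` for the in-band count.
#' @return List `min`, `max`, `mean` (half-up, 2 decimals), `n_in_band`,
#'   `fraction_in_band`, `n_species`.
#' @export
gene_count_stats <- function(summaries, species_info, groups,
                             band = c(15, 40)) {
  if (length(groups) == 0) stop("empty group set", call. = FALSE)
  keep_sp <- species_info$species_id[species_info$group %in% groups]
  x <- summaries$n_genes[summaries$species_id %in% keep_sp]
  if (length(x) == 0) {
    stop("no species found for group set: ", paste(groups, collapse = ", "),
      call. = FALSE
    )
  }
  c(.band_stats(x, band), list(n_species = length(x)))
}

#' Sequence-length statistics over a set of taxonomic groups
#'
#' Same semantics as [gene_count_stats()], but over the amino-acid lengths
#' of the individual protein isoforms.
#'
#' @param records Protein records.
#' @param species_info Species table.
#' @param groups Character vector of group names to include.
#' @param band Closed interval `c(lo, hi)`.
#' @return List `min`, `max`, `mean`, `n_in_band`, `fraction_in_band`,
#'   `n_tfs`.
#' @export
length_stats <- function(records, species_info, groups,
                         band = c(100, 400)) {
  if (length(groups) == 0) stop("empty group set", call. = FALSE)
  keep_sp <- species_info$species_id[species_info$group %in% groups]
  x <- records$length[records$species_id %in% keep_sp]
  if (length(x) == 0) {
    stop("no records found for group set: ", paste(groups, collapse = ", "),
      call. = FALSE
    )
  }
  c(.band_stats(x, band), list(n_tfs = length(x)))
}

#' Genus-level aggregation of gene counts
#'
#' @param summaries Per-species summaries.
#' @param species_info Species table with `genus` populated.
#' @return Tibble, one row per genus in lexicographic order: `genus`,
#'   `n_species`, `min_genes`, `max_genes`, `mean_genes` (2 decimals).
#' @export
genus_aggregation <- function(summaries, species_info) {
  df <- dplyr::inner_join(
    summaries,
    species_info[, c("species_id", "genus")],
    by = "species_id"
  )
  if (nrow(df) == 0) {
    return(tibble::tibble(
      genus = character(), n_species = integer(), min_genes = integer(),
      max_genes = integer(), mean_genes = numeric()
    ))
  }
  df |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      min_genes = min(.data$n_genes),
      max_genes = max(.data$n_genes),
      mean_genes = round_half_up(mean(.data$n_genes)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$genus)
}

#' Order-level aggregation of gene counts and domain types
#'
#' Angiosperm species aggregate under their taxonomic order;
#' non-angiosperm lineages (which carry no order in the species table)
#' aggregate under their group name.  A domain type is listed for a unit
#' iff at least one hit of that type occurs among its species.
#'
#' @param summaries Per-species summaries.
#' @param hits Hit tibble.
#' @param species_info Species table.
#' @return Tibble `unit`, `n_species`, `mean_genes` (2 decimals),
#'   `dtypes` (comma-joined, in reporting order; empty string when none).
#' @export
order_aggregation <- function(summaries, hits, species_info) {
  unit_of <- function(sp_ids) {
    i <- match(sp_ids, species_info$species_id)
    ifelse(
      species_info$group[i] %in% ANGIOSPERM_GROUPS &
        nzchar(species_info$order[i]),
      species_info$order[i],
      species_info$group[i]
    )
  }
  if (nrow(summaries) == 0) {
    return(tibble::tibble(
      unit = character(), n_species = integer(), mean_genes = numeric(),
      dtypes = character()
    ))
  }
  s <- summaries
  s$unit <- unit_of(s$species_id)
  h <- hits
  per_unit_types <- if (nrow(h) > 0) {
    h$unit <- unit_of(h$species_id)
    h |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(
        dtypes = paste(
          DOMAIN_TYPES[DOMAIN_TYPES %in% unique(.data$dtype)],
          collapse = ","
        ),
        .groups = "drop"
      )
  } else {
    tibble::tibble(unit = character(), dtypes = character())
  }
  s |>
    dplyr::group_by(.data$unit) |>
    dplyr::summarise(
      n_species = dplyr::n(),
      mean_genes = round_half_up(mean(.data$n_genes)),
      .groups = "drop"
    ) |>
    dplyr::left_join(per_unit_types, by = "unit") |>
    dplyr::mutate(dtypes = dplyr::coalesce(.data$dtypes, "")) |>
    dplyr::arrange(.data$unit)
}
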