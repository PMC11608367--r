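#' Read protein sequences with gene/species identity from FASTA
#'
#' Headers carry the protein identifier as the first whitespace-delimited
#' token, optionally followed by `gene=<id>` and `species=<id>` tokens.
#' A missing `gene=` defaults the gene id to the protein id (the protein is
#' its gene's only known isoform); a missing `species=` defaults to `"NA"`.
#'
#' Sequences are restricted to the 20 standard amino-acid letters plus `X`
#' (unknown residue).  Ambiguity codes (`B`, `Z`), non-standard residues
#' (`U`, `O`), stops (`*`) and lower-case letters are rejected with the
#' offending line number: loud failure beats silent corruption.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with one row per entry, in file order: `protein_id`,
#'   `gene_id`, `species_id`, `sequence`, `length`.
#' @seealso [write_fasta()], [build_isoform_groups()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble::tibble(
      protein_id = character(), gene_id = character(),
      species_id = character(), sequence = character(), length = integer()
    ))
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) NULL
  )
  if (is.null(aa)) {
    .fasta_diagnose(path) # stops with a line-numbered message
    stop("could not parse FASTA file: ", path, call. = FALSE)
  }
  seqs <- as.character(aa)
  bad <- grep(sprintf("[^%s]", paste(AA_ALPHABET21, collapse = "")), seqs)
  if (length(bad) > 0 || any(nchar(seqs) == 0)) {
    .fasta_diagnose(path)
  }

  tokens <- strsplit(trimws(names(aa)), "\\s+")
  field <- function(key) {
    vapply(tokens, function(tok) {
      hit <- grep(paste0("^", key, "="), tok, value = TRUE)
      if (length(hit) == 0) NA_character_ else
        sub(paste0("^", key, "="), "", hit[1])
    }, character(1), USE.NAMES = FALSE)
  }
  protein_id <- vapply(tokens, `[`, character(1), 1L, USE.NAMES = FALSE)
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup) > 0) {
    stop("duplicate protein_id in FASTA: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  gene_id <- field("gene")
  gene_id <- ifelse(is.na(gene_id), protein_id, gene_id)
  species_id <- field("species")
  species_id <- ifelse(is.na(species_id), "NA", species_id)
  tibble::tibble(
    protein_id = protein_id, gene_id = gene_id, species_id = species_id,
    sequence = unname(seqs), length = unname(nchar(seqs))
  )
}

# Line-by-line scan used only on the error path, to attach a line number to
# the first offending character or empty record.
.fasta_diagnose <- function(path) {
  lines <- readLines(path, warn = FALSE)
  allowed <- paste(AA_ALPHABET21, collapse = "")
  current_header_line <- NA_integer_
  has_body <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!is.na(current_header_line) && !has_body) {
        stop("empty sequence for entry at line ", current_header_line,
          " in ", path,
          call. = FALSE
        )
      }
      current_header_line <- i
      has_body <- FALSE
    } else if (nzchar(trimws(ln))) {
      has_body <- TRUE
      hit <- regexpr(sprintf("[^%s]", allowed), ln)
      if (hit > 0) {
        stop(
          "invalid residue '", substr(ln, hit, hit), "' at line ", i,
          " of ", path, " (allowed: 20 standard amino acids and X)",
          call. = FALSE
        )
      }
    }
  }
  if (!is.na(current_header_line) && !has_body) {
    stop("empty sequence for entry at line ", current_header_line, " in ",
      path,
      call. = FALSE
    )
  }
  invisible(NULL)
}

#' Write protein records to FASTA
#'
#' Emits `>{protein_id} gene={gene_id} species={species_id}` headers with
#' sequences wrapped at 60 columns.  [read_fasta()] inverts the output
#' exactly, so a write/read round trip is the identity on
#' (`protein_id`, `gene_id`, `species_id`, `sequence`).
#'
#' @param records Tibble of protein records as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- sprintf(
    "%s gene=%s species=%s",
    records$protein_id, records$gene_id, records$species_id
  )
  tryCatch(
    Biostrings::writeXStringSet(x, path, width = 60L),
    error = function(e) {
      stop("cannot write FASTA to ", path, ": ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(path)
}

#' Read the species metadata table
#'
#' Tab-delimited with a header row and columns `species_id`, `name`,
#' `group`, `order`, `genus` (extra columns are kept).  `group` must be one
#' of the nine recognised lineages ([GATA_GROUPS]); `order` may be empty
#' (non-angiosperm lineages are aggregated by group, not order).  An empty
#' `genus` is filled with the first whitespace-delimited token of `name`.
#'
#' @param path Path to the TSV file.
#' @return A tibble keyed by `species_id`, one row per species.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) {
    stop("species table does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path,
    sep = "\t", quote = "", check.names = FALSE,
    colClasses = "character", na.strings = NULL
  )
  needed <- c("species_id", "name", "group")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("species table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"order" %in% names(df)) df$order <- ""
  if (!"genus" %in% names(df)) df$genus <- ""
  df$order[df$order %in% c("-", "NA")] <- ""
  bad <- setdiff(unique(df$group), GATA_GROUPS)
  if (length(bad) > 0) {
    stop(
      "unknown taxonomic group(s): ", paste(bad, collapse = ", "),
      "; legal values are: ", paste(GATA_GROUPS, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- df$species_id[duplicated(df$species_id)]
  if (length(dup) > 0) {
    stop("duplicate species_id: ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  blank <- !nzchar(df$genus)
  df$genus[blank] <- vapply(
    strsplit(df$name[blank], "\\s+"), function(x) x[1] %||% "",
    character(1)
  )
  tibble::as_tibble(df[, c("species_id", "name", "group", "order", "genus",
    setdiff(names(df), c("species_id", "name", "group", "order", "genus")))])
}

#' Read an explicit gene-to-isoform map
#'
#' Optional TSV (columns `gene_id`, `protein_id`) that overrides the
#' `gene=` tokens carried in FASTA headers, for exports where gene identity
#' is distributed separately.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_id`, `protein_id`.
#' @export
read_isoform_map <- function(path) {
  df <- utils::read.delim(path,
    sep = "\t", quote = "", colClasses = "character",
    na.strings = NULL
  )
  if (!all(c("gene_id", "protein_id") %in% names(df))) {
    stop("isoform map needs columns gene_id, protein_id", call. = FALSE)
  }
  dup <- df$protein_id[duplicated(df$protein_id)]
  if (length(dup) > 0) {
    stop("protein_id mapped to more than one gene: ",
      paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(df[, c("gene_id", "protein_id")])
}

#' Override header-derived gene ids with an isoform map
#'
#' @param records Protein records ([read_fasta()]).
#' @param map Tibble from [read_isoform_map()].
#' @return `records` with `gene_id` replaced where the map names the protein.
#' @export
apply_isoform_map <- function(records, map) {
  i <- match(records$protein_id, map$protein_id)
  hit <- !is.na(i)
  records$gene_id[hit] <- map$gene_id[i[hit]]
  records
}

#' Group isoforms by gene
#'
#' One group per distinct (`species_id`, `gene_id`) pair; the group size is
#' the gene's number of protein isoforms (its alternative-splicing forms at
#' the protein level).  Output order is deterministic: lexicographic by
#' species then gene.
#'
#' @param records Protein records ([read_fasta()]).
#' @return Tibble with `gene_id`, `species_id`, `isoform_ids` (list column)
#'   and `n_forms`.  `sum(n_forms)` always equals `nrow(records)`.
#' @export
build_isoform_groups <- function(records) {
  records |>
    dplyr::group_by(.data$species_id, .data$gene_id) |>
    dplyr::summarise(
      isoform_ids = list(.data$protein_id),
      n_forms = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species_id, .data$gene_id) |>
    dplyr::select("gene_id", "species_id", "isoform_ids", "n_forms")
}
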