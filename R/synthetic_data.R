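# Planted-motif synthetic proteome generator.
#
# Emulates a plant transcription-factor database export: species sampled
# per taxonomic group, genes per species, 1-12 protein isoforms per gene
# (mostly 1), 1-5 planted zinc-finger domains per protein on a random
# background, a realistic domain-type mixture, and alternative-splicing
# scenarios (UTR-only, truncation to a partial domain, whole-domain loss,
# benign).  Every planted domain is recorded in a truth table so the
# scanner, the isoform analysis and the cohort summaries can all be
# checked against known ground truth.
#
# RNG streams are split hierarchically (per species, then per gene), so
# enlarging one group leaves every other species' sequences untouched.

.EUDICOT_ORDERS <- c(
  "Apiales", "Asterales", "Brassicales", "Caryophyllales", "Cucurbitales",
  "Ericales", "Fabales", "Fagales", "Gentianales", "Lamiales",
  "Malpighiales", "Malvales", "Myrtales", "Proteales", "Ranunculales",
  "Rosales", "Sapindales", "Saxifragales", "Solanales", "Vitales"
)
.MONOCOT_ORDERS <- c(
  "Alismatales", "Arecales", "Asparagales", "Poales", "Zingiberales"
)

# fixed-length domain blueprints: cysteine anchors plus the
# high-conservation consensus positions planted at probability p
.domain_template <- function(dtype, spacer2 = NULL) {
  n_off <- c(5L, 6L, 8L, 9L, 11L, 12L, 14L)
  n_res <- c("T", "P", "W", "R", "G", "P", "G")
  c_off <- c(-1L, 1L, 2L)
  c_res <- c("L", "N", "A")
  if (dtype == "IVb") {
    cys <- c(1L, 4L, 23L, 26L)
  } else if (dtype == "IVc") {
    cys <- c(1L, 4L, 25L, 28L)
    cons <- stats::setNames(
      c("G", "T", "P", "M", "R", "R", "G", "P", "G", "R", "L", "N", "A"),
      c(5, 11, 12, 14, 15, 16, 17, 18, 20, 22, 24, 26, 27)
    )
    return(list(len = 28L, cys = cys, consensus = cons))
  } else if (dtype == "IVa") {
    cys <- c(1L, 4L, 22L, 25L)
  } else if (dtype == "IV4") {
    cys <- c(1L, 6L, 25L, 28L)
  } else if (dtype == "IVe") {
    s2 <- spacer2 %||% sample(c(16L, 19L, 21L), 1)
    if (!s2 %in% c(16L, 19L, 21L)) {
      stop("IVe inner spacer must be 16, 19 or 21", call. = FALSE)
    }
    cys <- c(1L, 4L, 5L + s2, 8L + s2)
  } else {
    stop("no fixed-length template for type ", dtype, call. = FALSE)
  }
  pos <- c(cys[2] + n_off, cys[3] + c_off)
  res <- c(n_res, c_res)
  keep <- !pos %in% cys & pos >= 1 & pos <= cys[4]
  list(
    len = cys[4], cys = cys,
    consensus = stats::setNames(res[keep], pos[keep])
  )
}

#' Plant one synthetic domain sequence
#'
#' Cysteines sit at the type's anchor positions with probability 1; each
#' high-conservation consensus position takes its consensus residue with
#' probability `conservation`, otherwise a uniform non-cysteine residue;
#' all remaining positions are uniform non-cysteine.  Draws from the
#' current RNG state.
#'
#' A partial domain (`dtype = "IVp"`) is planted by building a complete
#' IVb domain and deleting anchor cysteines (first cysteine, the
#' C-terminal pair, or the final cysteine, chosen at random), mirroring
#' the reading of partial domains as incomplete canonical domains.
#'
#' @param dtype Domain type (`IVa`, `IVb`, `IVc`, `IV4`, `IVe`, `IVp`).
#' @param conservation Probability p for each consensus position.
#' @param spacer2 Inner spacer for IVe (16, 19 or 21; sampled when NULL).
#' @return Character string of the planted domain.
#' @export
plant_domain <- function(dtype, conservation = 0.95, spacer2 = NULL) {
  .plant_one(dtype, conservation, spacer2)$seq
}

# internal planting: also reports anchors and, for IVp, where the scanner
# will anchor the surviving template (truth_rel, 0-based offset within the
# planted block)
.plant_one <- function(dtype, conservation = 0.95, spacer2 = NULL) {
  if (dtype == "IVp") {
    d <- .plant_one("IVb", conservation)
    chars <- strsplit(d$seq, "", fixed = TRUE)[[1]]
    mode <- sample(c("drop_first", "drop_cterm_pair", "drop_last"), 1)
    gone <- switch(mode,
      drop_first = d$cys[1],
      drop_cterm_pair = d$cys[3:4],
      drop_last = d$cys[4]
    )
    chars[gone] <- sample(AA_NON_CYS, length(gone), replace = TRUE)
    truth_rel <- if (mode == "drop_first") d$cys[2] - 1L else 0L
    return(list(
      seq = paste(chars, collapse = ""), len = d$len,
      cys = setdiff(d$cys, gone), dtype = "IVp", truth_rel = truth_rel
    ))
  }
  tpl <- .domain_template(dtype, spacer2)
  chars <- sample(AA_NON_CYS, tpl$len, replace = TRUE)
  chars[tpl$cys] <- "C"
  pos <- as.integer(names(tpl$consensus))
  hit <- stats::runif(length(pos)) < conservation
  chars[pos[hit]] <- tpl$consensus[hit]
  list(
    seq = paste(chars, collapse = ""), len = tpl$len,
    cys = tpl$cys, dtype = dtype, truth_rel = 0L
  )
}

#' Configuration of the synthetic proteome generator
#'
#' Defaults emulate the published 165-species survey cohort: per-group
#' species counts, per-group gene-count ranges and means, the observed
#' AS-form distribution (about 6.9% of genes have 2+ forms, mostly 2-4),
#' 1-5 domains per protein (97% single), the observed domain-type mixture
#' (IVb 74.6%, IVc 17.2%, IVp 5.8%, IVe 1.2%, IV4 0.7%, IVa 0.5%), and
#' AS scenario frequencies (UTR-only 105/329, truncation 20/329, loss
#' 8/329, benign otherwise).  `scale` shrinks the per-group species counts
#' proportionally for smaller benchmark cohorts.
#'
#' @param seed Integer master seed; fully determines the output.
#' @param scale Multiplier on the per-group species counts (each group
#'   keeps at least one species).
#' @param species_per_group Named integer vector over [GATA_GROUPS].
#' @param gene_count_range Named list of `c(min, max)` per group.
#' @param gene_count_mean Named numeric vector of per-group means.
#' @param as_form_probs Probability of 1..12 isoforms per gene.
#' @param domain_count_probs Probability of 1..5 domains per protein.
#' @param dtype_mixture Named probabilities over the six types.
#' @param conservation Consensus-position conservation p (cysteines are
#'   always 1).
#' @param length_range List with `angiosperm` and `non_angiosperm`
#'   `c(min, max)` protein lengths.
#' @param background `"cys_free"` (no background cysteines, so planted
#'   truth is exactly recoverable) or `"natural"` (background cysteines at
#'   `natural_cys_freq`).
#' @param natural_cys_freq Background cysteine frequency for `"natural"`.
#' @param as_scenario_probs Probabilities of `utr_only`,
#'   `truncation_to_IVp`, `domain_loss`, `benign` for multi-isoform genes.
#' @param min_domain_gap Minimum residues between planted domains; the
#'   default keeps planted domains far enough apart that no cysteine
#'   quadruple can span two of them.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(
    seed = 1L,
    scale = 1,
    species_per_group = c(
      eudicots = 100L, monocots = 39L, basal_angiosperm = 1L,
      gymnosperm = 5L, marchantiophyta = 1L, bryophyta = 2L,
      lycopodiophyta = 1L, charophyta = 1L, chlorophytae = 15L
    ),
    gene_count_range = list(
      eudicots = c(2L, 125L), monocots = c(6L, 73L),
      basal_angiosperm = c(20L, 20L), gymnosperm = c(4L, 19L),
      marchantiophyta = c(6L, 6L), bryophyta = c(15L, 15L),
      lycopodiophyta = c(8L, 8L), charophyta = c(10L, 10L),
      chlorophytae = c(5L, 15L)
    ),
    gene_count_mean = c(
      eudicots = 33.82, monocots = 29.28, basal_angiosperm = 20,
      gymnosperm = 8.6, marchantiophyta = 6, bryophyta = 15,
      lycopodiophyta = 8, charophyta = 10, chlorophytae = 8.07
    ),
    as_form_probs = c(4433, 216, 58, 33, 6, 5, 2, 2, 0, 5, 0, 2) / 4762,
    domain_count_probs = c(5184, 111, 32, 6, 2) / 5335,
    dtype_mixture = c(
      IVb = 4131, IVc = 950, IVp = 323, IV4 = 40, IVa = 26, IVe = 66
    ) / 5536,
    conservation = 0.95,
    length_range = list(
      angiosperm = c(100L, 400L), non_angiosperm = c(250L, 800L)
    ),
    background = c("cys_free", "natural"),
    natural_cys_freq = 0.017,
    as_scenario_probs = c(
      utr_only = 105, truncation_to_IVp = 20, domain_loss = 8, benign = 196
    ) / 329,
    min_domain_gap = 25L) {
  background <- match.arg(background)
  if (scale != 1) {
    species_per_group <- stats::setNames(
      pmax(1L, as.integer(round(species_per_group * scale))),
      names(species_per_group)
    )
  }
  stopifnot(
    setequal(names(species_per_group), GATA_GROUPS),
    setequal(names(gene_count_range), GATA_GROUPS),
    setequal(names(gene_count_mean), GATA_GROUPS),
    length(as_form_probs) == 12,
    length(domain_count_probs) == 5,
    setequal(names(dtype_mixture), DOMAIN_TYPES),
    conservation >= 0, conservation <= 1,
    min_domain_gap >= 0
  )
  for (v in list(as_form_probs, domain_count_probs, dtype_mixture,
    as_scenario_probs)) {
    if (abs(sum(v) - 1) > 1e-9) {
      stop("probability vector does not sum to 1", call. = FALSE)
    }
  }
  structure(
    list(
      seed = as.integer(seed), species_per_group = species_per_group,
      gene_count_range = gene_count_range, gene_count_mean = gene_count_mean,
      as_form_probs = as_form_probs, domain_count_probs = domain_count_probs,
      dtype_mixture = dtype_mixture, conservation = conservation,
      length_range = length_range, background = background,
      natural_cys_freq = natural_cys_freq,
      as_scenario_probs = as_scenario_probs,
      min_domain_gap = as.integer(min_domain_gap)
    ),
    class = "SyntheticConfig"
  )
}

.background_chars <- function(n, config) {
  if (n <= 0) return(character(0))
  if (config$background == "cys_free") {
    sample(AA_NON_CYS, n, replace = TRUE)
  } else {
    q <- config$natural_cys_freq
    p <- stats::setNames(rep((1 - q) / 19, 20), AA_STANDARD)
    p["C"] <- q
    sample(AA_STANDARD, n, replace = TRUE, prob = p)
  }
}

# one gene: sample isoform count, domains, background; apply AS scenario;
# return protein records and per-isoform truth rows
.generate_gene <- function(config, group, species_id, gene_id) {
  n_forms <- sample(1:12, 1, prob = config$as_form_probs)
  n_dom <- sample(1:5, 1, prob = config$domain_count_probs)
  dts <- sample(names(config$dtype_mixture), n_dom,
    replace = TRUE,
    prob = config$dtype_mixture
  )
  doms <- lapply(dts, .plant_one, conservation = config$conservation)
  dlens <- vapply(doms, function(d) d$len, integer(1))
  gap <- config$min_domain_gap
  lr <- if (group %in% ANGIOSPERM_GROUPS) {
    config$length_range$angiosperm
  } else {
    config$length_range$non_angiosperm
  }
  need <- sum(dlens) + gap * (n_dom - 1L)
  if (need > lr[2]) {
    stop(
      "cannot place ", n_dom, " domains in a protein of at most ", lr[2],
      " residues (gene ", gene_id, ")",
      call. = FALSE
    )
  }
  len <- sample(lr[1]:lr[2], 1)
  if (len < need) len <- need + sample(0:min(20L, lr[2] - need), 1)
  slack <- len - need
  offsets <- sort(sample(0:slack, n_dom, replace = TRUE))
  starts <- offsets + c(0L, cumsum(dlens[-n_dom] + gap)) # 0-based
  chars <- .background_chars(len, config)
  for (i in seq_len(n_dom)) {
    chars[(starts[i] + 1):(starts[i] + dlens[i])] <-
      strsplit(doms[[i]]$seq, "", fixed = TRUE)[[1]]
  }
  base_truth <- tibble::tibble(
    start = starts + vapply(doms, function(d) d$truth_rel, integer(1)),
    dtype = vapply(doms, function(d) d$dtype, character(1))
  )

  scenario <- "none"
  iso_chars <- list(chars)
  iso_truth <- list(base_truth)
  if (n_forms >= 2) {
    scenario <- sample(names(config$as_scenario_probs), 1,
      prob = config$as_scenario_probs
    )
    complete_idx <- which(dts != "IVp")
    if (scenario == "truncation_to_IVp" && length(complete_idx) == 0) {
      scenario <- "benign" # nothing truncatable; record what was applied
    }
    for (t in 2:n_forms) iso_chars[[t]] <- chars
    for (t in 2:n_forms) iso_truth[[t]] <- base_truth
    if (scenario == "truncation_to_IVp") {
      k <- if (length(complete_idx) == 1) complete_idx else
        sample(complete_idx, 1)
      d <- doms[[k]]
      s <- starts[k]
      mode <- sample(c("drop_first", "drop_cterm_pair"), 1)
      gone <- if (mode == "drop_first") d$cys[1] else d$cys[3:4]
      v <- iso_chars[[2]]
      v[s + gone] <- sample(AA_NON_CYS, length(gone), replace = TRUE)
      iso_chars[[2]] <- v
      tr <- iso_truth[[2]]
      tr$dtype[k] <- "IVp"
      tr$start[k] <- if (mode == "drop_first") s + d$cys[2] - 1L else s
      iso_truth[[2]] <- tr
    } else if (scenario == "domain_loss") {
      k <- sample.int(n_dom, 1)
      span <- (starts[k] + 1):(starts[k] + dlens[k])
      iso_chars[[2]] <- iso_chars[[2]][-span]
      tr <- iso_truth[[2]]
      shift <- tr$start > starts[k]
      tr$start[shift] <- tr$start[shift] - dlens[k]
      iso_truth[[2]] <- tr[-k, , drop = FALSE]
    } else if (scenario == "benign") {
      for (t in 2:n_forms) {
        iso_chars[[t]] <- c(
          iso_chars[[t]],
          .background_chars(sample(5:40, 1), config)
        )
      }
    } # utr_only: identical copies already in place
  }

  protein_ids <- sprintf("%s_p%02d", gene_id, seq_len(n_forms))
  records <- tibble::tibble(
    protein_id = protein_ids,
    gene_id = gene_id,
    species_id = species_id,
    sequence = vapply(iso_chars, paste, character(1), collapse = ""),
    length = vapply(iso_chars, length, integer(1))
  )
  truth <- dplyr::bind_rows(lapply(seq_len(n_forms), function(t) {
    tr <- iso_truth[[t]]
    if (nrow(tr) == 0) return(NULL)
    tibble::tibble(
      protein_id = protein_ids[t], gene_id = gene_id,
      species_id = species_id, start = tr$start, dtype = tr$dtype
    )
  }))
  list(
    records = records, truth_domains = truth,
    n_forms = n_forms, scenario = scenario
  )
}

.generate_species <- function(config, group, gi, si, species_id, n_sp_group) {
  pool <- max(1L, ceiling(n_sp_group * 0.6))
  genus <- sprintf(
    "Genus%s%02d", toupper(substr(group, 1, 2)), sample.int(pool, 1)
  )
  ord <- switch(group,
    eudicots = sample(.EUDICOT_ORDERS, 1),
    monocots = sample(.MONOCOT_ORDERS, 1),
    basal_angiosperm = "Amborellales",
    ""
  )
  rng <- config$gene_count_range[[group]]
  mu <- config$gene_count_mean[[group]]
  n_genes <- if (rng[2] > rng[1]) {
    rng[1] + stats::rbinom(1, rng[2] - rng[1], (mu - rng[1]) / (rng[2] - rng[1]))
  } else {
    rng[1]
  }
  genes <- lapply(seq_len(n_genes), function(j) {
    gene_id <- sprintf("%s_g%04d", species_id, j)
    withr::with_seed(
      mix_seed(config$seed, gi, si, j),
      .generate_gene(config, group, species_id, gene_id)
    )
  })
  list(
    species = tibble::tibble(
      species_id = species_id,
      name = paste(genus, sprintf("sp%03d", si)),
      group = group, order = ord, genus = genus
    ),
    records = dplyr::bind_rows(lapply(genes, `[[`, "records")),
    truth_domains = dplyr::bind_rows(lapply(genes, `[[`, "truth_domains")),
    truth_genes = tibble::tibble(
      gene_id = vapply(genes, function(g) g$records$gene_id[1], character(1)),
      species_id = species_id,
      n_forms = vapply(genes, `[[`, integer(1), "n_forms"),
      scenario = vapply(genes, `[[`, character(1), "scenario")
    )
  )
}

#' Generate a synthetic proteome with ground truth
#'
#' @param config A `SyntheticConfig` from [synthetic_config()].
#' @return List with `records` (protein tibble as from [read_fasta()]),
#'   `species` (species table as from [read_species_table()]), and `truth`
#'   — a list of tibbles: `domains` (per planted domain and isoform:
#'   `protein_id`, `gene_id`, `species_id`, 0-based `start`, `dtype`),
#'   `genes` (`gene_id`, `species_id`, `n_forms`, `scenario`), `species`
#'   (`species_id`, `group`, `n_genes`).  The same seed always yields a
#'   byte-identical dataset.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  per_species <- list()
  idx <- 0L
  for (gi in seq_along(GATA_GROUPS)) {
    g <- GATA_GROUPS[gi]
    n_sp <- config$species_per_group[[g]]
    if (n_sp < 1) next
    for (si in seq_len(n_sp)) {
      idx <- idx + 1L
      sid <- sprintf("s%03d", idx)
      per_species[[idx]] <- withr::with_seed(
        mix_seed(config$seed, gi, si),
        .generate_species(config, g, gi, si, sid, n_sp)
      )
    }
  }
  species <- dplyr::bind_rows(lapply(per_species, `[[`, "species"))
  truth_genes <- dplyr::bind_rows(lapply(per_species, `[[`, "truth_genes"))
  truth_species <- species[, c("species_id", "group")]
  truth_species$n_genes <- vapply(
    per_species, function(x) nrow(x$truth_genes), integer(1)
  )
  list(
    records = dplyr::bind_rows(lapply(per_species, `[[`, "records")),
    species = species,
    truth = list(
      domains = dplyr::bind_rows(lapply(per_species, `[[`, "truth_domains")),
      genes = truth_genes,
      species = truth_species
    ),
    config = config
  )
}

#' Write a generated dataset to disk
#'
#' Emits `proteins.fasta`, `species.tsv` and the truth tables
#' (`truth_domains.tsv`, `truth_genes.tsv`, `truth_species.tsv`) into a
#' directory.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "proteins.fasta"),
    species = file.path(dir, "species.tsv"),
    truth_domains = file.path(dir, "truth_domains.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_species = file.path(dir, "truth_species.tsv")
  )
  write_fasta(dataset$records, paths["fasta"])
  wt <- function(df, p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(dataset$species, paths["species"])
  wt(dataset$truth$domains, paths["truth_domains"])
  wt(dataset$truth$genes, paths["truth_genes"])
  wt(dataset$truth$species, paths["truth_species"])
  invisible(paths)
}
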