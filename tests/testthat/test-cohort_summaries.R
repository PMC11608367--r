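# the bundled survey fixtures: per-species counts and per-group domain
# type counts transcribed from the published 165-species plant GATA cohort
species_fixture <- function() {
  p <- system.file("extdata", "plant_gata_species_counts.tsv",
    package = "gatascan")
  tibble::as_tibble(utils::read.delim(p, colClasses = c(
    species_id = "character", name = "character", group = "character",
    order = "character", genus = "character"
  ), na.strings = NULL))
}

domain_counts_fixture <- function() {
  p <- system.file("extdata", "gata_domain_type_counts.tsv",
    package = "gatascan")
  df <- utils::read.delim(p, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$dtype
  m
}

test_that("species summary counts genes, isoforms and AS genes", {
  recs <- tibble::tibble(
    protein_id = c("a1", "b1", "b2", "b3", "c1"),
    gene_id = c("g1", "g2", "g2", "g2", "g3"),
    species_id = c("sA", "sA", "sA", "sA", "sB"),
    sequence = "ACD", length = 3L
  )
  s <- species_summary(recs)
  expect_equal(s$species_id, c("sA", "sB"))
  expect_equal(s$n_genes, c(2L, 1L))
  expect_equal(s$n_tfs, c(4L, 1L))
  expect_equal(s$n_as_genes, c(1L, 0L))
  expect_equal(s$n_as_tfs, c(3L, 0L))
  expect_equal(sum(s$n_tfs), nrow(recs))

  empty <- recs[0, ]
  expect_equal(nrow(species_summary(empty)), 0)
})

test_that("domain-type ratios reproduce the published survey column", {
  gdt <- group_domain_table_from_counts(domain_counts_fixture())
  expect_equal(gdt$grand_total, 5536L)
  expect_equal(
    gdt$ratio_pct[c("IVb", "IVc", "IVp", "IV4", "IVa", "IVe")],
    c(IVb = 74.62, IVc = 17.16, IVp = 5.83, IV4 = 0.72, IVa = 0.47,
      IVe = 1.19)
  )
  expect_lt(abs(sum(gdt$ratio_pct) - 100), 0.05)
  # internal consistency: recomputing from the cells gives the same column
  expect_equal(domain_type_ratios(gdt$counts), gdt$ratio_pct)
})

test_that("group-domain table counts hits once per (type, group) cell", {
  hits <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"), gene_id = c("g1", "g2", "g3"),
    species_id = "sA", start = 0L, end = 26L, dtype = "IVb",
    spacer1 = 2L, spacer2 = 18L, cys_positions = list(integer(0)),
    domain_seq = ""
  )
  sp <- mk_species("sA", "monocots")
  gdt <- group_domain_table(hits, sp)
  expect_equal(gdt$counts["IVb", "monocots"], 3L)
  expect_equal(gdt$grand_total, 3L)
  expect_equal(unname(gdt$ratio_pct["IVb"]), 100)
  expect_equal(sum(gdt$counts), gdt$grand_total)

  bad <- hits
  bad$species_id <- "zz"
  expect_error(group_domain_table(bad, sp), "absent.*zz")

  none <- group_domain_table(hits[0, ], sp)
  expect_equal(none$grand_total, 0L)
  expect_true(all(is.na(none$ratio_pct)))
})

test_that("gene-count statistics reproduce the survey aggregates", {
  sp <- species_fixture()
  summaries <- sp[, c("species_id", "n_genes")]
  eud <- gene_count_stats(summaries, sp, "eudicots")
  expect_equal(eud$mean, 33.82)
  expect_equal(eud$n_species, 100L)
  expect_equal(eud$min, 2L) # fewest genes among eudicots
  expect_equal(eud$max, 125L) # most genes among eudicots
  mono <- gene_count_stats(summaries, sp, "monocots")
  expect_equal(mono$mean, 29.28)
  expect_equal(mono$n_species, 39L)

  ang <- gene_count_stats(summaries, sp, c("eudicots", "monocots"),
    band = c(15, 40))
  expect_equal(ang$n_species, 139L)

  expect_error(gene_count_stats(summaries, sp, character(0)), "empty")
  expect_error(gene_count_stats(summaries, sp, "gymnosperm"[0]), "empty")
})

test_that("bands are inclusive on both ends", {
  sp <- mk_species(paste0("s", 1:4), rep("eudicots", 4))
  summaries <- tibble::tibble(
    species_id = paste0("s", 1:4), n_genes = c(14L, 15L, 40L, 41L)
  )
  st <- gene_count_stats(summaries, sp, "eudicots", band = c(15, 40))
  expect_equal(st$n_in_band, 2L)
  expect_equal(st$fraction_in_band, 0.5)

  recs <- tibble::tibble(
    protein_id = paste0("p", 1:4), gene_id = paste0("g", 1:4),
    species_id = "s1",
    sequence = strrep("A", c(100L, 250L, 400L, 401L)),
    length = c(100L, 250L, 400L, 401L)
  )
  ls <- length_stats(recs, sp, "eudicots", band = c(100, 400))
  expect_equal(ls$n_in_band, 3L)
  expect_equal(ls$min, 100L)
  expect_equal(ls$max, 401L)
})

test_that("genus aggregation spans species of the same genus", {
  sp <- tibble::tibble(
    species_id = c("s1", "s2", "s3"),
    name = c("Arabidopsis halleri", "Arabidopsis thaliana", "Oryza sativa"),
    group = c("eudicots", "eudicots", "monocots"),
    order = c("Brassicales", "Brassicales", "Poales"),
    genus = c("Arabidopsis", "Arabidopsis", "Oryza")
  )
  summaries <- tibble::tibble(
    species_id = c("s1", "s2", "s3"), n_genes = c(22L, 30L, 26L)
  )
  g <- genus_aggregation(summaries, sp)
  expect_equal(g$genus, c("Arabidopsis", "Oryza")) # lexicographic
  expect_equal(g$n_species, c(2L, 1L))
  expect_equal(g$min_genes[1], 22L)
  expect_equal(g$max_genes[1], 30L)
  expect_equal(g$mean_genes, c(26, 26))
})

test_that("order aggregation keys angiosperms by order, others by group", {
  sp <- tibble::tibble(
    species_id = c("s1", "s2", "s3"),
    name = c("A a", "B b", "C c"),
    group = c("eudicots", "eudicots", "bryophyta"),
    order = c("Rosales", "Rosales", ""),
    genus = c("A", "B", "C")
  )
  summaries <- tibble::tibble(
    species_id = c("s1", "s2", "s3"), n_genes = c(10L, 20L, 8L)
  )
  hits <- tibble::tibble(
    protein_id = c("p1", "p2", "p3"), gene_id = c("g1", "g2", "g3"),
    species_id = c("s1", "s1", "s2"), start = 0L, end = 26L,
    dtype = c("IVb", "IVb", "IVp"), spacer1 = 2L, spacer2 = 18L,
    cys_positions = list(integer(0)), domain_seq = ""
  )
  tab <- order_aggregation(summaries, hits, sp)
  expect_equal(sort(tab$unit), c("Rosales", "bryophyta"))
  ros <- tab[tab$unit == "Rosales", ]
  expect_equal(ros$n_species, 2L)
  expect_equal(ros$mean_genes, 15)
  expect_equal(ros$dtypes, "IVb,IVp") # reporting order, deduplicated
  expect_equal(tab$dtypes[tab$unit == "bryophyta"], "")
})

test_that("cohort invariants hold on generated data", {
  ds <- generate_dataset(synthetic_config(seed = 77, scale = 0.06))
  hits <- scan_proteins(ds$records)
  groups <- build_isoform_groups(ds$records)
  summaries <- species_summary(ds$records, groups)
  expect_equal(sum(summaries$n_tfs), nrow(ds$records))
  expect_equal(sum(summaries$n_genes), nrow(groups))
  expect_equal(
    summaries$n_genes[order(summaries$species_id)],
    ds$truth$species$n_genes[order(ds$truth$species$species_id)]
  )
  gdt <- group_domain_table(hits, ds$species)
  expect_equal(gdt$grand_total, nrow(hits))
  expect_equal(domain_type_ratios(gdt$counts), gdt$ratio_pct)
})
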