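test_that("spacer classification follows the type table exactly", {
  cases <- list(
    list(2, 17, "IVa"), list(2, 18, "IVb"), list(2, 20, "IVc"),
    list(4, 18, "IV4"), list(2, 16, "IVe"), list(2, 19, "IVe"),
    list(2, 21, "IVe"), list(4, 20, NA_character_),
    list(2, 15, NA_character_), list(2, 22, NA_character_),
    list(3, 18, NA_character_), list(0, 18, NA_character_)
  )
  for (cs in cases) {
    expect_identical(
      classify_spacers(cs[[1]], cs[[2]]), cs[[3]],
      label = sprintf("classify_spacers(%d, %d)", cs[[1]], cs[[2]])
    )
  }
  expect_error(classify_spacers(-1, 18))
})

test_that("complete-candidate enumeration matches forced and empty cases", {
  ivb <- paste0("C", "AA", "C", strrep("G", 18), "C", "AA", "C")
  h <- enumerate_complete_candidates(ivb)
  expect_equal(nrow(h), 1)
  expect_equal(h$dtype, "IVb")
  expect_equal(h$start, 0L)
  expect_equal(h$end, 26L)
  expect_equal(h$cys_positions[[1]], c(0L, 3L, 22L, 25L))
  expect_equal(h$domain_seq, ivb)

  expect_equal(nrow(enumerate_complete_candidates("MKTAYIAKQRGA")), 0)
  expect_equal(nrow(enumerate_complete_candidates("")), 0)
})

test_that("scanner equals exhaustive quadruple enumeration on random sequences", {
  withr::with_seed(4021, {
    for (i in 1:150) {
      s <- random_cys_rich_seq(sample(30:300, 1))
      got <- enumerate_complete_candidates(s)
      want <- brute_force_complete(s)
      expect_equal(
        as.data.frame(got[, c("start", "end", "dtype", "spacer1", "spacer2")]),
        want,
        ignore_attr = TRUE, label = paste("sequence", i)
      )
    }
  })
})

test_that("complete-hit length identity holds on random sequences", {
  withr::with_seed(99, {
    for (i in 1:50) {
      h <- enumerate_complete_candidates(random_cys_rich_seq(250))
      if (nrow(h) == 0) next
      expect_equal(h$end - h$start, 4L + h$spacer1 + h$spacer2 + 2L)
      expect_true(all(vapply(h$cys_positions, length, 1L) == 4))
    }
  })
})

test_that("partial templates find known exemplar shapes", {
  # region shaped like a complete domain that lost its first cysteine:
  # C X15 C X2 C, with the reference consensus residues present
  inner <- strrep("A", 15)
  inner <- paste0(
    substr(inner, 1, 4), "T", "P", "A", "W", "R", "A", "G", "P",
    substr(inner, 13, 15)
  ) # consensus at spacer-aligned offsets
  seq_a <- paste0(strrep("M", 10), "C", inner, "C", "AA", "C", strrep("M", 10))
  h <- find_partial_candidates(seq_a, exclusion = NULL)
  expect_gte(nrow(h), 1)
  expect_true(all(h$dtype == "IVp"))
  expect_true(10L %in% h$start)

  # C-terminal pair missing: C X2 C X{m} with no downstream cysteine;
  # consensus residues at their spacer-aligned offsets from the 2nd C
  core <- paste0("C", "AA", "C", "AAAA", "TP", "A", "WR", "A", "GP")
  seq_b <- paste0(strrep("M", 6), core, strrep("A", 4))
  hb <- find_partial_candidates(seq_b, exclusion = NULL)
  expect_gte(nrow(hb), 1)
  expect_equal(hb$start[1], 6L)

  # without the consensus residues the same template is rejected
  seq_c <- paste0(strrep("M", 10), "C", strrep("A", 15), "C", "AA", "C",
    strrep("M", 10))
  expect_equal(nrow(find_partial_candidates(seq_c, exclusion = NULL)), 0)
})

test_that("partial search respects exclusion intervals", {
  ivb <- plant_domain("IVb", conservation = 1)
  s <- paste0(strrep("M", 5), ivb, strrep("M", 5))
  comp <- resolve_overlaps(enumerate_complete_candidates(s))
  expect_equal(nrow(comp), 1)
  # the complete span would otherwise match partial templates internally
  expect_gte(nrow(find_partial_candidates(s, exclusion = NULL)), 1)
  expect_equal(nrow(find_partial_candidates(s, exclusion = comp)), 0)
})

test_that("overlap resolution is greedy by completeness, priority, position", {
  mk <- function(start, end, dtype) {
    tibble::tibble(
      protein_id = NA_character_, gene_id = NA_character_,
      species_id = NA_character_, start = start, end = end, dtype = dtype,
      spacer1 = NA_integer_, spacer2 = NA_integer_,
      cys_positions = list(integer(0)), domain_seq = ""
    )
  }
  # disjoint: both kept
  two <- dplyr::bind_rows(mk(0L, 26L, "IVb"), mk(40L, 66L, "IVb"))
  expect_equal(nrow(resolve_overlaps(two)), 2)
  # overlapping IVb and IVe: priority keeps IVb
  ov <- dplyr::bind_rows(mk(5L, 29L, "IVe"), mk(0L, 26L, "IVb"))
  res <- resolve_overlaps(ov)
  expect_equal(res$dtype, "IVb")
  # complete beats partial regardless of position
  cp <- dplyr::bind_rows(mk(0L, 20L, "IVp"), mk(10L, 36L, "IVc"))
  expect_equal(resolve_overlaps(cp)$dtype, "IVc")

  # property: equals an independent restatement of the ranking
  withr::with_seed(777, {
    for (i in 1:40) {
      n <- sample(1:12, 1)
      st <- sample(0:80, n, replace = TRUE)
      cand <- mk(
        as.integer(st), as.integer(st + sample(10:30, n, replace = TRUE)),
        sample(c("IVb", "IVc", "IVa", "IV4", "IVe", "IVp"), n, replace = TRUE)
      )
      got <- resolve_overlaps(cand)
      want <- brute_force_resolve(
        as.data.frame(cand[, c("start", "end", "dtype")])
      )
      expect_equal(got$start, want$start)
      expect_equal(got$dtype, want$dtype)
      # pairwise disjoint
      if (nrow(got) > 1) {
        expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
      }
    }
  })
})

test_that("scan_protein recovers planted domains at known offsets", {
  withr::with_seed(314, {
    ivb <- plant_domain("IVb", conservation = 1)
    ivc <- plant_domain("IVc", conservation = 1)
    bg <- function(n) paste(sample(
      setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C"),
      n, replace = TRUE
    ), collapse = "")
    s <- paste0(bg(40), ivb, bg(54), ivc, bg(30))
    h <- scan_protein(as_record(s))
    expect_equal(h$start, c(40L, 120L))
    expect_equal(h$dtype, c("IVb", "IVc"))
    expect_equal(h$protein_id, c("p1", "p1"))

    # a planted C X4 C X18 C X2 C parses as IV4
    iv4 <- plant_domain("IV4", conservation = 1)
    h4 <- scan_protein(as_record(paste0(bg(12), iv4, bg(12))))
    expect_equal(h4$dtype, "IV4")
    expect_equal(h4$start, 12L)
  })
  expect_equal(nrow(scan_protein(as_record("MKTAYIAKQRG"))), 0)
})

test_that("scanning is deterministic and hits are pairwise disjoint", {
  withr::with_seed(2718, {
    seqs <- replicate(25, random_cys_rich_seq(sample(50:300, 1)))
  })
  for (s in seqs) {
    h1 <- scan_protein(as_record(s))
    h2 <- scan_protein(as_record(s))
    expect_identical(h1, h2)
    if (nrow(h1) > 1) {
      expect_true(all(h1$start[-1] >= h1$end[-nrow(h1)]))
    }
  }
})

test_that("hit tables survive the TSV round trip", {
  withr::with_seed(42, {
    ds <- generate_dataset(synthetic_config(seed = 42, scale = 0.03))
  })
  hits <- scan_proteins(ds$records)
  expect_gt(nrow(hits), 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  back <- read_hits_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(hits))
})
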