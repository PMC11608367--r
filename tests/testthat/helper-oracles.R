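# Independent oracles, kept deliberately naive: exhaustive enumeration and
# a plain re-statement of the ranking rule, written without reference to
# the scanner internals.

# exhaustive complete-candidate enumeration over all cysteine quadruples
brute_force_complete <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cys <- which(chars == "C")
  out <- data.frame(
    start = integer(0), end = integer(0), dtype = character(0),
    spacer1 = integer(0), spacer2 = integer(0)
  )
  if (length(cys) < 4) return(out)
  quads <- utils::combn(cys, 4)
  for (q in seq_len(ncol(quads))) {
    i <- quads[1, q]; j <- quads[2, q]; k <- quads[3, q]; l <- quads[4, q]
    s1 <- j - i - 1; s2 <- k - j - 1; s3 <- l - k - 1
    if (s3 != 2) next
    dt <- if (s1 == 2 && s2 == 17) "IVa"
      else if (s1 == 2 && s2 == 18) "IVb"
      else if (s1 == 2 && s2 == 20) "IVc"
      else if (s1 == 4 && s2 == 18) "IV4"
      else if (s1 == 2 && s2 %in% c(16, 19, 21)) "IVe"
      else NA_character_
    if (is.na(dt)) next
    out <- rbind(out, data.frame(
      start = i - 1L, end = l, dtype = dt,
      spacer1 = s1, spacer2 = s2
    ))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

# plain restatement of the greedy overlap-resolution ranking
brute_force_resolve <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  prio <- c(IVb = 1, IVc = 2, IVa = 3, IV4 = 4, IVe = 5, IVp = 6)
  cand <- cand[order(prio[cand$dtype], cand$start, cand$end), , drop = FALSE]
  chosen <- cand[0, , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, , drop = FALSE]
    clash <- FALSE
    if (nrow(chosen) > 0) {
      clash <- any(row$start < chosen$end & chosen$start < row$end)
    }
    if (!clash) chosen <- rbind(chosen, row)
  }
  chosen[order(chosen$start, chosen$end), , drop = FALSE]
}

# random test sequence with elevated cysteine frequency
random_cys_rich_seq <- function(len, cys_freq = 0.08) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
    "Q", "R", "S", "T", "V", "W", "Y")
  p <- rep((1 - cys_freq) / 19, 20)
  p[aa == "C"] <- cys_freq
  paste(sample(aa, len, replace = TRUE, prob = p), collapse = "")
}

# minimal record constructor for scanner-level tests
as_record <- function(sequence, protein_id = "p1", gene_id = "g1",
                      species_id = "s1") {
  tibble::tibble(
    protein_id = protein_id, gene_id = gene_id, species_id = species_id,
    sequence = sequence, length = nchar(sequence)
  )
}

# canonical hit comparison key used by round-trip tests
hit_key <- function(df) paste(df$protein_id, df$start, df$dtype)

# tiny species table covering ids s1..sn with chosen groups
mk_species <- function(ids, groups, orders = "") {
  tibble::tibble(
    species_id = ids,
    name = paste("Genus", ids),
    group = groups,
    order = orders,
    genus = "Genus"
  )
}
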