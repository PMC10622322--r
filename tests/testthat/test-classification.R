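# a small controlled proteome used across classification tests:
#   G1 reference + two haplotypes, G2 reference sharing one peptide with G1
make_micro_db <- function() {
  refs <- rbind(
    protein_record("P1", "AAADEFGHKLLLMNQSTRVVWYAADEK", "reference", gene_id = "G1"),
    protein_record("P2", "LLLMNQSTRCCCDEFGHK", "reference", gene_id = "G2")
  )
  haps <- data.frame(
    parent_accession = c("P1", "P1"),
    haplotype_id = c("h1", "h2"),
    substitutions = c("4D>N;6F>S", "4D>N"),
    frequency = c(0.3, 0.2), stringsAsFactors = FALSE
  )
  suppressMessages(build_target_database(refs, haps, NULL))
}

test_that("variant class is the minimum substitution burden (downgrade rule)", {
  expect_equal(classify_variant_status(c(2L)), "multivariant")
  expect_equal(classify_variant_status(c(1L, 0L)), "canonical")
  expect_equal(classify_variant_status(c(2L, 1L)), "single_variant")
  expect_equal(classify_variant_status(c(3L, 2L)), "multivariant")
})

test_that("specificity classes follow the gene/record definitions", {
  expect_equal(classify_specificity(c("G1", "G2"), c("A", "B")), "nonspecific")
  expect_equal(classify_specificity(c("G1", "G1"), c("P1", "P1-h1")),
               "protein_specific")
  expect_equal(classify_specificity("G1", "P1-h1"), "proteoform_specific")
})

test_that("the peptide index groups occurrences and the downgrade applies", {
  db <- make_micro_db()
  occ <- build_peptide_index(digest_records(db), db)
  cls <- classify_peptides(occ)
  # shared canonical peptide across G1 and G2 is nonspecific
  shared <- cls[cls$peptide == "LLLMNQSTR", ]
  expect_equal(shared$specificity_class, "nonspecific")
  expect_equal(shared$variant_class, "canonical")
  # the 4D>N;6F>S peptide of h1 is downgraded by h2's single-variant copy:
  # h1's AAANESGHK (2 subs) vs h2's AAANEFGHK (1 sub) are different strings,
  # but h1's 4D>N-only missed forms coincide with h2 -> check burden math
  v <- cls[cls$peptide == "AAANESGHK", ]
  expect_equal(v$variant_class, "multivariant")
  s <- cls[cls$peptide == "AAANEFGHK", ]
  expect_equal(s$variant_class, "single_variant")
})

test_that("index size equals the distinct-peptide set union", {
  db <- make_micro_db()
  peps <- digest_records(db)
  occ <- build_peptide_index(peps, db)
  expect_setequal(unique(occ$peptide), unique(peps$peptide))
  expect_equal(nrow(classify_peptides(occ)), length(unique(peps$peptide)))
})

test_that("classification matches the brute-force enumerator on micro-proteomes", {
  set.seed(41)
  for (trial in 1:5) {
    # 5 genes, up to 4 haplotypes each
    refs <- list(); haps <- list()
    for (g in 1:5) {
      acc <- paste0("P", g)
      seq <- random_protein(sample(60:120, 1))
      refs[[g]] <- protein_record(acc, seq, "reference",
                                  gene_id = paste0("G", g))
      chars <- strsplit(seq, "")[[1]]
      for (h in seq_len(sample(0:4, 1))) {
        pos <- sort(sample(nchar(seq), sample(1:3, 1)))
        alts <- vapply(pos, function(p)
          sample(setdiff(AA_STANDARD, chars[p]), 1), "")
        haps[[length(haps) + 1L]] <- data.frame(
          parent_accession = acc, haplotype_id = paste0("h", h),
          substitutions = paste0(pos, chars[pos], ">", alts, collapse = ";"),
          frequency = round(runif(1, 0.01, 0.3), 6),
          stringsAsFactors = FALSE)
      }
    }
    db <- suppressMessages(build_target_database(
      bind_records(refs), do.call(rbind, haps), NULL))
    occ <- build_peptide_index(digest_records(db), db)
    got <- classify_peptides(occ)
    got <- got[order(got$peptide), c("peptide", "variant_class",
                                     "specificity_class")]
    oracle_in <- data.frame(accession = db$accession, gene_unit = db$gene_id,
                            sequence = db$sequence,
                            substitutions = db$substitutions,
                            stringsAsFactors = FALSE)
    want <- oracle_classify(oracle_in)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("adding an occurrence never upgrades the variant class", {
  ord <- c(canonical = 0L, single_variant = 1L, multivariant = 2L)
  set.seed(43)
  for (i in 1:200) {
    counts <- sample(0:3, sample(1:5, 1), replace = TRUE)
    base <- classify_variant_status(counts)
    more <- classify_variant_status(c(counts, sample(0:3, 1)))
    expect_lte(ord[[more]], ord[[base]])
  }
})

test_that("substitution discoverability distinguishes single, multi and either", {
  # planted pair in one K/R-free fragment -> multi_only for both
  refs <- protein_record("P1", "AAAKCDEFGHILMNQRSTVWYAAAK", "reference",
                         gene_id = "G1")
  haps <- data.frame(parent_accession = "P1", haplotype_id = "h1",
                     substitutions = "7E>Q;11I>V", frequency = 0.4,
                     stringsAsFactors = FALSE)
  subs <- data.frame(parent_accession = "P1",
                     variant_id = c("rs1", "rs2"),
                     position = c(7L, 11L), ref = c("E", "I"),
                     alt = c("Q", "V"), stringsAsFactors = FALSE)
  db <- build_target_database(refs, haps, NULL)
  occ <- build_peptide_index(digest_records(db), db)
  cls <- classify_peptides(occ)
  disc <- substitution_discoverability(occ, cls, subs)
  expect_equal(disc$category, c("multi_only", "multi_only"))

  # substitutions in adjacent fragments: single at 0 MC, multi at 1 MC -> either
  refs2 <- protein_record("P2", "AADEFGHIKLMNQSTVWYAK", "reference",
                          gene_id = "G2")
  haps2 <- data.frame(parent_accession = "P2", haplotype_id = "h1",
                      substitutions = "4E>D;12N>S", frequency = 0.4,
                      stringsAsFactors = FALSE)
  subs2 <- data.frame(parent_accession = "P2",
                      variant_id = c("rs3", "rs4"),
                      position = c(4L, 12L), ref = c("E", "N"),
                      alt = c("D", "S"), stringsAsFactors = FALSE)
  db2 <- build_target_database(refs2, haps2, NULL)
  occ2 <- build_peptide_index(digest_records(db2), db2)
  cls2 <- classify_peptides(occ2)
  disc2 <- substitution_discoverability(occ2, cls2, subs2)
  expect_equal(disc2$category, c("either", "either"))

  # substitution only reachable in out-of-range peptides -> not_discoverable
  refs3 <- protein_record("P3", "AAKCDKAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAK",
                          "reference", gene_id = "G3")
  haps3 <- data.frame(parent_accession = "P3", haplotype_id = "h1",
                      substitutions = "4C>S", frequency = 0.2,
                      stringsAsFactors = FALSE)
  subs3 <- data.frame(parent_accession = "P3", variant_id = "rs5",
                      position = 4L, ref = "C", alt = "S",
                      stringsAsFactors = FALSE)
  db3 <- build_target_database(refs3, haps3, NULL)
  occ3 <- build_peptide_index(digest_records(db3), db3)
  cls3 <- classify_peptides(occ3)
  disc3 <- substitution_discoverability(occ3, cls3, subs3)
  expect_equal(disc3$category, "not_discoverable")
})

test_that("frequency stratification flags haplotypes beating the reference", {
  haps <- data.frame(
    parent_accession = c("P1", "P1", "P2", "P2"),
    haplotype_id = c("h1", "h2", "h1", "h2"),
    substitutions = c("5A>G", "5A>G;9L>V", "3F>Y", "8T>S"),
    frequency = c(0.45, 0.10, 0.35, 0.05), stringsAsFactors = FALSE
  )
  disc <- data.frame(
    parent_accession = c("P1", "P1", "P2", "P2"),
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    position = c(5L, 9L, 3L, 8L), ref = c("A", "L", "F", "T"),
    alt = c("G", "V", "Y", "S"),
    category = c("single_only", "multi_only", "single_only", "single_only"),
    stringsAsFactors = FALSE
  )
  out <- frequency_stratify(disc, haps)
  # P1 reference frequency 0.45: h1 (0.45) is not strictly greater,
  # P2 reference frequency 0.60: neither haplotype beats it
  expect_equal(out$substitutions$more_frequent_than_reference,
               c(FALSE, FALSE, FALSE, FALSE))
  haps$frequency <- c(0.50, 0.10, 0.35, 0.05)  # now P1 ref = 0.40 < h1
  out2 <- frequency_stratify(disc, haps)
  expect_equal(out2$substitutions$more_frequent_than_reference,
               c(TRUE, FALSE, FALSE, FALSE))
  # aggregate over the 3 single-discoverable subs: 1 of 3 flagged
  expect_equal(unname(out2$aggregate["single_discoverable"]), 1 / 3)
  expect_equal(unname(out2$aggregate["multi_discoverable"]), 0)
})
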