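#' Build the global peptide occurrence index
#'
#' Joins the digestion output of every non-decoy record with record
#' metadata and deduplicates occurrences: a peptide found at the same span
#' of the same record at several missed-cleavage levels counts once (the
#' lowest level is kept) — spans, not missed-cleavage levels, define
#' mapping. Contaminant occurrences are flagged and, lacking a gene
#' annotation, each contaminant accession acts as its own gene unit for
#' specificity (a peptide shared with a contaminant is nonspecific); they
#' never carry substitutions.
#'
#' @param peptides Digestion output ([digest_records()]) of all target
#'   records.
#' @param records The record data frame the peptides were digested from.
#' @return Occurrence data frame: one row per (peptide, accession, span),
#'   with columns `peptide`, `accession`, `kind`, `gene_unit`, `gene_id`,
#'   `ref_accession` (the reference the span projects onto), `start`,
#'   `end`, `missed_cleavages`, `n_subs`, `substitutions`.
#' @export
build_peptide_index <- function(peptides, records) {
  records <- records[records$kind != "decoy", , drop = FALSE]
  peptides <- peptides[peptides$accession %in% records$accession, , drop = FALSE]
  meta <- records[, c("accession", "kind", "gene_id", "parent_accession")]
  occ <- merge(peptides, meta, by = "accession", sort = FALSE)
  occ$gene_unit <- ifelse(occ$kind == "contaminant",
                          paste0("cont:", occ$accession), occ$gene_id)
  occ$ref_accession <- ifelse(occ$kind == "haplotype",
                              occ$parent_accession, occ$accession)
  key <- paste(occ$peptide, occ$accession, occ$start, occ$end)
  occ <- occ[order(key, occ$missed_cleavages), , drop = FALSE]
  occ <- occ[!duplicated(paste(occ$peptide, occ$accession, occ$start, occ$end)), ,
             drop = FALSE]
  rownames(occ) <- NULL
  occ[, c("peptide", "accession", "kind", "gene_unit", "gene_id",
          "ref_accession", "start", "end", "missed_cleavages", "n_subs",
          "substitutions")]
}

#' Variant class of one occurrence set
#'
#' The class of a peptide is the *minimum* substitution burden over every
#' database sequence containing it (the downgrade rule): a peptide that is
#' multivariant with respect to one haplotype but canonical with respect to
#' another protein is classified canonical; multivariant in one haplotype
#' and single-variant in another gives single-variant. Substitutions lying
#' in a peptide that was downgraded below their own burden are not
#' considered discoverable through that peptide.
#'
#' @param n_subs Integer vector: substitution count of each occurrence of
#'   the peptide.
#' @return `"canonical"`, `"single_variant"` or `"multivariant"`.
#' @export
classify_variant_status <- function(n_subs) {
  stopifnot(length(n_subs) > 0L)
  m <- min(n_subs)
  if (m == 0L) "canonical" else if (m == 1L) "single_variant" else "multivariant"
}

#' Specificity class of one occurrence set
#'
#' Nonspecific peptides map to products of more than one gene;
#' protein-specific peptides map to several sequence records that are all
#' products of one gene (e.g. a reference and one of its haplotypes);
#' proteoform-specific peptides map to exactly one record, identifying a
#' single form of the protein.
#'
#' @param gene_units Character vector: gene unit of each occurrence.
#' @param accessions Character vector: record accession of each occurrence.
#' @return `"nonspecific"`, `"protein_specific"` or `"proteoform_specific"`.
#' @export
classify_specificity <- function(gene_units, accessions) {
  stopifnot(length(gene_units) == length(accessions), length(gene_units) > 0L)
  if (length(unique(gene_units)) > 1L) return("nonspecific")
  if (length(unique(accessions)) > 1L) return("protein_specific")
  "proteoform_specific"
}

#' Classify every peptide of the index
#'
#' @param occ Occurrence index from [build_peptide_index()].
#' @return Data frame with one row per unique peptide: `peptide`,
#'   `variant_class`, `specificity_class`, `min_subs` (the substitution
#'   burden realising the variant class), `n_genes`, `n_records`.
#' @export
classify_peptides <- function(occ) {
  if (nrow(occ) == 0L) {
    return(data.frame(peptide = character(0), variant_class = character(0),
                      specificity_class = character(0), min_subs = integer(0),
                      n_genes = integer(0), n_records = integer(0),
                      stringsAsFactors = FALSE))
  }
  split_idx <- split(seq_len(nrow(occ)), occ$peptide)
  out <- lapply(names(split_idx), function(p) {
    i <- split_idx[[p]]
    data.frame(
      peptide = p,
      variant_class = classify_variant_status(occ$n_subs[i]),
      specificity_class = classify_specificity(occ$gene_unit[i], occ$accession[i]),
      min_subs = min(occ$n_subs[i]),
      n_genes = length(unique(occ$gene_unit[i])),
      n_records = length(unique(occ$accession[i])),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# explode occurrence substitution strings into one row per substitution,
# carrying the occurrence burden and the peptide's class burden
explode_occurrence_subs <- function(occ, classes) {
  v <- occ[occ$n_subs > 0L, , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(peptide = character(0), ref_accession = character(0),
                      position = integer(0), ref = character(0),
                      alt = character(0), n_subs = integer(0),
                      min_subs = integer(0), stringsAsFactors = FALSE))
  }
  parsed <- parse_substitutions(v$substitutions)
  n_each <- vapply(parsed, nrow, 1L)
  idx <- rep(seq_len(nrow(v)), n_each)
  subs <- do.call(rbind, parsed)
  out <- data.frame(
    peptide = v$peptide[idx],
    ref_accession = v$ref_accession[idx],
    position = subs$position,
    ref = subs$ref,
    alt = subs$alt,
    n_subs = v$n_subs[idx],
    stringsAsFactors = FALSE
  )
  out$min_subs <- classes$min_subs[match(out$peptide, classes$peptide)]
  out
}

#' Discoverability category of every substitution
#'
#' A substitution can be identified through a peptide only if that peptide
#' was not downgraded below the occurrence's own substitution burden. Over
#' all such non-downgraded in-range peptides, a substitution is
#' `single_only` if every one is single-variant, `multi_only` if every one
#' is multivariant (e.g. two substitutions always sharing a tryptic
#' peptide), `either` if both kinds exist (typically depending on the
#' number of missed cleavages), and `not_discoverable` if no non-downgraded
#' in-range peptide contains it.
#'
#' @param occ Occurrence index.
#' @param classes Output of [classify_peptides()].
#' @param substitutions Substitution table: `parent_accession`,
#'   `variant_id`, `position`, `ref`, `alt` (and optionally
#'   `allele_frequency`); defines the substitution universe so that
#'   substitutions absent from every retained peptide are reported as
#'   `not_discoverable`.
#' @return The substitution table with an added `category` column.
#' @export
substitution_discoverability <- function(occ, classes, substitutions) {
  ex <- explode_occurrence_subs(occ, classes)
  ex <- ex[ex$n_subs == ex$min_subs, , drop = FALSE]   # non-downgraded only
  key <- paste(ex$ref_accession, ex$position, ex$ref, ex$alt)
  single <- unique(key[ex$min_subs == 1L])
  multi <- unique(key[ex$min_subs >= 2L])
  skey <- paste(substitutions$parent_accession, substitutions$position,
                substitutions$ref, substitutions$alt)
  in_s <- skey %in% single
  in_m <- skey %in% multi
  substitutions$category <- ifelse(
    in_s & in_m, "either",
    ifelse(in_s, "single_only", ifelse(in_m, "multi_only", "not_discoverable"))
  )
  substitutions
}

#' Stratify substitutions by haplotype frequency relative to the reference
#'
#' Flags a substitution when some haplotype carrying it is predicted to be
#' strictly more frequent than the reference haplotype of the same protein
#' (reference frequency = 1 minus the sum of that protein's haplotype
#' frequencies). The aggregate fraction of flagged substitutions is
#' reported separately for substitutions discoverable in single-variant
#' peptides (`single_only` or `either`) and in multivariant peptides
#' (`multi_only` or `either`).
#'
#' @param discoverability Output of [substitution_discoverability()].
#' @param haplotypes Haplotype table (`parent_accession`, `haplotype_id`,
#'   `substitutions`, `frequency`).
#' @return A list: `substitutions` (input plus logical
#'   `more_frequent_than_reference`) and `aggregate` (named numeric with
#'   `single_discoverable` and `multi_discoverable` fractions, `NaN` when
#'   the group is empty).
#' @export
frequency_stratify <- function(discoverability, haplotypes) {
  if (is.null(haplotypes$parent_accession)) {
    haplotypes$parent_accession <- haplotypes$protein_id
  }
  ref_freq <- tapply(haplotypes$frequency, haplotypes$parent_accession,
                     function(f) 1 - sum(f, na.rm = TRUE))
  parsed <- parse_substitutions(haplotypes$substitutions)
  n_each <- vapply(parsed, nrow, 1L)
  idx <- rep(seq_len(nrow(haplotypes)), n_each)
  hap_sub <- if (length(idx) > 0L) {
    cbind(do.call(rbind, parsed),
          data.frame(parent_accession = haplotypes$parent_accession[idx],
                     frequency = haplotypes$frequency[idx],
                     stringsAsFactors = FALSE))
  } else {
    data.frame(position = integer(0), ref = character(0), alt = character(0),
               parent_accession = character(0), frequency = numeric(0))
  }
  dkey <- paste(discoverability$parent_accession, discoverability$position,
                discoverability$ref, discoverability$alt)
  hkey <- paste(hap_sub$parent_accession, hap_sub$position, hap_sub$ref,
                hap_sub$alt)
  flag <- vapply(seq_along(dkey), function(i) {
    freqs <- hap_sub$frequency[hkey == dkey[i]]
    freqs <- freqs[!is.na(freqs)]
    if (length(freqs) == 0L) return(NA)
    # strictly greater, with a 1e-9 guard so float noise cannot flip a tie
    any(freqs > ref_freq[[discoverability$parent_accession[i]]] + 1e-9)
  }, logical(1))
  no_freq <- is.na(flag)
  if (any(no_freq)) {
    message(sum(no_freq),
            " substitution(s) without frequency excluded from aggregates")
  }
  discoverability$more_frequent_than_reference <- flag
  grp_frac <- function(cats) {
    sel <- discoverability$category %in% cats & !no_freq
    if (!any(sel)) return(NaN)
    mean(discoverability$more_frequent_than_reference[sel])
  }
  list(
    substitutions = discoverability,
    aggregate = c(
      single_discoverable = grp_frac(c("single_only", "either")),
      multi_discoverable = grp_frac(c("multi_only", "either"))
    )
  )
}
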