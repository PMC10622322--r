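# residue masks for one reference protein: which residues are covered by
# non-downgraded variant-containing peptides and by substitution-free ones
coverage_masks <- function(len, occ_protein, classes) {
  variant <- logical(len)
  canonical <- logical(len)
  if (nrow(occ_protein) > 0L) {
    min_subs <- classes$min_subs[match(occ_protein$peptide, classes$peptide)]
    for (i in seq_len(nrow(occ_protein))) {
      span <- (occ_protein$start[i] + 1L):occ_protein$end[i]
      if (occ_protein$n_subs[i] >= 1L && occ_protein$n_subs[i] == min_subs[i]) {
        variant[span] <- TRUE
      } else if (occ_protein$n_subs[i] == 0L) {
        canonical[span] <- TRUE
      }
    }
  }
  list(variant = variant, canonical = canonical)
}

# occurrences projecting onto a given reference accession
occ_for_reference <- function(occ, accession) {
  occ[occ$ref_accession == accession & occ$kind != "contaminant", , drop = FALSE]
}

#' Residue-level proteome coverage partition
#'
#' Partitions the residues of every reference protein into three classes:
#' `variant_mapped` (covered by at least one non-downgraded discoverable
#' peptide whose occurrence contains a substitution product),
#' `canonical_only` (covered by substitution-free peptides but by no such
#' variant peptide), and `not_discoverable` (in no retained peptide at
#' all — the surrounding tryptic fragments are too short or too long).
#' Haplotypes are length-preserving, so haplotype peptide spans project
#' positionally onto reference coordinates. Nonspecific peptides contribute
#' coverage to every gene they map to, so aggregate coverage carries the
#' usual shared-peptide double-counting caveat. Aggregate percentages are
#' residue-weighted over all reference residues.
#'
#' @param references Reference record data frame.
#' @param occ Occurrence index from [build_peptide_index()].
#' @param classes Output of [classify_peptides()].
#' @return A list with `per_protein` (data frame: accession, length and the
#'   three percentages, summing to 100 per protein) and `aggregate` (named
#'   numeric percentages).
#' @export
residue_coverage <- function(references, occ, classes) {
  per <- lapply(seq_len(nrow(references)), function(i) {
    acc <- references$accession[i]
    len <- nchar(references$sequence[i])
    m <- coverage_masks(len, occ_for_reference(occ, acc), classes)
    v <- sum(m$variant)
    c_only <- sum(m$canonical & !m$variant)
    data.frame(
      accession = acc, length = len,
      variant_mapped = 100 * v / len,
      canonical_only = 100 * c_only / len,
      not_discoverable = 100 * (len - v - c_only) / len,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  tot <- sum(per$length)
  agg <- c(
    variant_mapped = sum(per$variant_mapped * per$length) / tot,
    canonical_only = sum(per$canonical_only * per$length) / tot,
    not_discoverable = sum(per$not_discoverable * per$length) / tot
  )
  list(per_protein = per, aggregate = agg)
}

#' Observed versus predicted residue coverage
#'
#' Applies the [residue_coverage()] partition logic restricted to a set of
#' confidently identified peptides, reporting identified next to predicted
#' coverage per class. Identified coverage can never exceed predicted
#' coverage. Identified peptides mapping to several genes (nonspecific) are
#' counted separately since their gene of origin cannot be resolved.
#'
#' @param identified_peptides Character vector of peptide sequences passing
#'   the confidence threshold.
#' @param references,occ,classes As in [residue_coverage()].
#' @return List with `per_protein` (predicted and identified percentages
#'   per class), `aggregate`, and `n_nonspecific_identified`.
#' @export
identified_coverage <- function(identified_peptides, references, occ, classes) {
  unknown <- setdiff(identified_peptides, occ$peptide)
  if (length(unknown) > 0L) {
    message(length(unknown), " identified peptide(s) absent from the index, skipped")
    identified_peptides <- setdiff(identified_peptides, unknown)
  }
  occ_id <- occ[occ$peptide %in% identified_peptides, , drop = FALSE]
  per <- lapply(seq_len(nrow(references)), function(i) {
    acc <- references$accession[i]
    len <- nchar(references$sequence[i])
    mp <- coverage_masks(len, occ_for_reference(occ, acc), classes)
    mi <- coverage_masks(len, occ_for_reference(occ_id, acc), classes)
    data.frame(
      accession = acc, length = len,
      predicted_variant = 100 * sum(mp$variant) / len,
      identified_variant = 100 * sum(mi$variant) / len,
      predicted_canonical = 100 * sum(mp$canonical & !mp$variant) / len,
      identified_canonical = 100 * sum(mi$canonical & !mp$variant) / len,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  tot <- sum(per$length)
  agg <- c(
    predicted_variant = sum(per$predicted_variant * per$length) / tot,
    identified_variant = sum(per$identified_variant * per$length) / tot,
    predicted_canonical = sum(per$predicted_canonical * per$length) / tot,
    identified_canonical = sum(per$identified_canonical * per$length) / tot
  )
  cls_id <- classes[classes$peptide %in% identified_peptides, , drop = FALSE]
  list(
    per_protein = per,
    aggregate = agg,
    n_nonspecific_identified = sum(cls_id$specificity_class == "nonspecific")
  )
}

#' Substitutions identified by confident PSMs
#'
#' A substitution counts as identified in a sample iff at least one
#' confident PSM maps to a non-downgraded peptide occurrence containing its
#' alternative allele; PSMs to downgraded peptides identify nothing. The
#' summary stratifies identified substitutions by their discoverability
#' category and reports per-sample counts.
#'
#' @param psms Data frame of confident PSMs with columns `sample_id` and
#'   `peptide`.
#' @param occ,classes As elsewhere.
#' @param discoverability Output of [substitution_discoverability()]
#'   (optional; adds the category breakdown).
#' @return List with `identified` (sample_id, parent_accession, position,
#'   ref, alt, category) and `per_sample` counts.
#' @export
summarize_identified_substitutions <- function(psms, occ, classes,
                                               discoverability = NULL) {
  ex <- explode_occurrence_subs(occ, classes)
  ex <- ex[ex$n_subs == ex$min_subs, , drop = FALSE]
  hits <- merge(psms[, c("sample_id", "peptide")], ex, by = "peptide")
  hits <- hits[!duplicated(paste(hits$sample_id, hits$ref_accession,
                                 hits$position, hits$ref, hits$alt)), ,
               drop = FALSE]
  names(hits)[names(hits) == "ref_accession"] <- "parent_accession"
  if (!is.null(discoverability)) {
    hits$category <- discoverability$category[match(
      paste(hits$parent_accession, hits$position, hits$ref, hits$alt),
      paste(discoverability$parent_accession, discoverability$position,
            discoverability$ref, discoverability$alt))]
  } else {
    hits$category <- ifelse(hits$min_subs >= 2L, "multi_only", "single_only")
  }
  if (nrow(hits) > 0L) {
    per_sample <- as.data.frame(table(sample_id = hits$sample_id),
                                stringsAsFactors = FALSE)
    names(per_sample)[2L] <- "n_substitutions"
  } else {
    per_sample <- data.frame(sample_id = character(0),
                             n_substitutions = integer(0))
  }
  list(
    identified = hits[, c("sample_id", "parent_accession", "position",
                          "ref", "alt", "category")],
    per_sample = per_sample
  )
}

#' Evidence for heterozygosity in identified peptides
#'
#' For a diploid genome both alleles of a variant can be present in one
#' sample. A gene is flagged in a sample when two confident peptides of
#' that sample overlap the same variant position of the same protein with
#' different residues — e.g. a multivariant peptide carrying the
#' alternative allele and a second peptide carrying the reference allele.
#' Identifying the same peptide twice is not evidence; nor are the two
#' allele peptides seen in different samples.
#'
#' @param psms Confident PSM data frame (`sample_id`, `peptide`).
#' @param occ Occurrence index.
#' @param substitutions Substitution table (`parent_accession`, `position`,
#'   `ref`, `alt`) defining the variant positions to inspect.
#' @param records Record data frame (to map accessions to genes).
#' @return Data frame: `sample_id`, `gene_id`, `parent_accession`,
#'   `position`, `alleles` (`/`-joined residues observed), `n_peptides`.
#' @export
heterozygosity_evidence <- function(psms, occ, substitutions, records) {
  occ_id <- occ[occ$peptide %in% unique(psms$peptide) &
                  occ$kind != "contaminant", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(occ_id))) {
    o <- occ_id[i, ]
    subs_here <- substitutions[substitutions$parent_accession == o$ref_accession, ,
                               drop = FALSE]
    if (nrow(subs_here) == 0L) next
    pos0 <- subs_here$position - 1L
    inside <- pos0 >= o$start & pos0 < o$end
    if (!any(inside)) next
    sh <- subs_here[inside, , drop = FALSE]
    residue <- substring(o$peptide, sh$position - o$start,
                         sh$position - o$start)
    rows[[length(rows) + 1L]] <- data.frame(
      parent_accession = o$ref_accession, position = sh$position,
      residue = residue, peptide = o$peptide, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      parent_accession = character(0), position = integer(0),
                      alleles = character(0), n_peptides = integer(0),
                      stringsAsFactors = FALSE))
  }
  site <- do.call(rbind, rows)
  obs <- merge(unique(psms[, c("sample_id", "peptide")]), site, by = "peptide")
  obs <- unique(obs[, c("sample_id", "parent_accession", "position",
                        "residue", "peptide")])
  grp <- split(obs, paste(obs$sample_id, obs$parent_accession, obs$position))
  flagged <- lapply(grp, function(g) {
    if (length(unique(g$residue)) < 2L) return(NULL)
    data.frame(
      sample_id = g$sample_id[1L],
      gene_id = records$gene_id[match(g$parent_accession[1L], records$accession)],
      parent_accession = g$parent_accession[1L],
      position = g$position[1L],
      alleles = paste(sort(unique(g$residue)), collapse = "/"),
      n_peptides = length(unique(g$peptide)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, flagged)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), gene_id = character(0),
                      parent_accession = character(0), position = integer(0),
                      alleles = character(0), n_peptides = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
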