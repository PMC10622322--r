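#' Construct a protein record
#'
#' A protein record is one entry of the sequence database: a reference
#' protein, a protein haplotype (reference plus a set of co-occurring amino
#' acid substitutions), a sample contaminant, or a decoy. Records are stored
#' as rows of an ordinary data frame so that whole databases can be
#' manipulated with base R; `stop_junctions` is a list column holding the
#' 0-based positions where a translated stop symbol was removed from the
#' sequence (see [strip_stop_symbols()]).
#'
#' @param accession Unique record identifier.
#' @param sequence Residue string (upper case).
#' @param kind One of `"reference"`, `"haplotype"`, `"contaminant"`,
#'   `"decoy"`.
#' @param gene_id Gene identifier; specificity classes are defined over
#'   genes, not accessions. Contaminants and decoys may leave it `NA`.
#' @param parent_accession For haplotypes, the accession of the reference
#'   record the substitutions were applied to; for decoys, the shuffled
#'   target.
#' @param haplotype_id Haplotype identifier (haplotype records only).
#' @param substitutions `;`-joined `posREF>ALT` string (haplotype records
#'   only; positions are 1-based on the parent).
#' @param frequency Population frequency of the haplotype, in `[0, 1]`.
#' @param stop_junctions Integer vector of 0-based junction positions.
#' @return A one-row data frame.
#' @export
protein_record <- function(accession, sequence,
                           kind = c("reference", "haplotype", "contaminant", "decoy"),
                           gene_id = NA_character_,
                           parent_accession = NA_character_,
                           haplotype_id = NA_character_,
                           substitutions = "",
                           frequency = NA_real_,
                           stop_junctions = integer(0)) {
  kind <- match.arg(kind)
  stopifnot(length(accession) == 1L, length(sequence) == 1L)
  df <- data.frame(
    accession = as.character(accession),
    gene_id = as.character(gene_id),
    sequence = toupper(as.character(sequence)),
    kind = kind,
    parent_accession = as.character(parent_accession),
    haplotype_id = as.character(haplotype_id),
    substitutions = as.character(substitutions),
    frequency = as.numeric(frequency),
    stringsAsFactors = FALSE
  )
  df$stop_junctions <- list(as.integer(stop_junctions))
  df
}

# rbind a list of record data frames, tolerating the list column
bind_records <- function(lst) {
  lst <- lst[vapply(lst, NROW, 1L) > 0L]
  if (length(lst) == 0L) {
    return(protein_record("x", "A")[0L, ])
  }
  do.call(rbind, lst)
}

#' Remove stop symbols from a translated sequence
#'
#' Some reference proteomes contain translated stop codons (`*`) inside
#' protein sequences. For compatibility with search engines these symbols
#' are removed, and the positions of the removals (stop junctions) are
#' recorded so that peptides spanning a junction can be excluded from the
#' digestion output: such peptides would contain a stop codon and cannot be
#' observed.
#'
#' A junction is reported as the 0-based index, in the *cleaned* sequence,
#' of the residue immediately following the removed stop run. A run of
#' consecutive stop symbols collapses to a single junction; leading stops
#' yield junction 0 and trailing stops a junction equal to the cleaned
#' length (which no peptide can cross).
#'
#' @param raw_sequence Residue string, possibly containing `*`.
#' @return A list with elements `sequence` (cleaned string) and
#'   `stop_junctions` (sorted integer vector of 0-based junction positions).
#' @examples
#' strip_stop_symbols("AAAAK*CCCCK") # junction at 5
#' @export
strip_stop_symbols <- function(raw_sequence) {
  stopifnot(length(raw_sequence) == 1L)
  chars <- strsplit(raw_sequence, "", fixed = TRUE)[[1]]
  is_stop <- chars == "*"
  if (!any(is_stop)) {
    return(list(sequence = raw_sequence, stop_junctions = integer(0)))
  }
  # junction = count of retained residues strictly before each stop run
  kept_before <- cumsum(!is_stop) - as.integer(!is_stop)
  run_start <- is_stop & !c(FALSE, is_stop[-length(is_stop)])
  junctions <- sort(unique(kept_before[run_start]))
  list(
    sequence = paste(chars[!is_stop], collapse = ""),
    stop_junctions = as.integer(junctions)
  )
}

#' Apply a haplotype's substitutions to a reference record
#'
#' Builds the protein haplotype sequence by replacing the reference residue
#' with the alternative residue at every substituted position. Substitutions
#' are length-preserving (no indels), so the haplotype sequence has exactly
#' the parent's length and haplotype peptide spans project positionally onto
#' reference coordinates.
#'
#' Every substitution is validated against the parent: if the reference
#' residue recorded for a substitution does not match the parent sequence,
#' the haplotype table and the FASTA disagree and an error naming the
#' position and residues is raised.
#'
#' @param reference A one-row reference record (see [protein_record()]).
#' @param haplotype A list or one-row data frame with fields `haplotype_id`,
#'   `substitutions` (`posREF>ALT`, `;`-joined, or a parsed data frame) and
#'   `frequency`.
#' @return A one-row haplotype record whose accession is
#'   `"<parent>-<haplotype_id>"`.
#' @examples
#' ref <- protein_record("P1", "VLWLDEIQQAVDDANVDKDR", "reference", gene_id = "G1")
#' hap <- list(haplotype_id = "h1", substitutions = "13D>E;18K>E", frequency = 0.3)
#' apply_substitutions(ref, hap)$sequence
#' @export
apply_substitutions <- function(reference, haplotype) {
  stopifnot(nrow(reference) == 1L, reference$kind == "reference")
  subs <- haplotype$substitutions
  if (is.character(subs)) subs <- parse_substitutions(subs)[[1]]
  if (is.list(subs) && !is.data.frame(subs)) subs <- subs[[1]]
  seq <- reference$sequence
  n <- nchar(seq)
  if (nrow(subs) > 0L) {
    if (any(subs$position < 1L | subs$position > n)) {
      stop("substitution position outside parent '", reference$accession,
           "' (length ", n, ")")
    }
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    have <- chars[subs$position]
    bad <- have != subs$ref
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("reference residue mismatch on '", reference$accession,
           "' at position ", subs$position[i], ": expected ", subs$ref[i],
           ", found ", have[i])
    }
    chars[subs$position] <- subs$alt
    seq <- paste(chars, collapse = "")
  }
  rec <- protein_record(
    accession = paste0(reference$accession, "-", haplotype$haplotype_id),
    sequence = seq,
    kind = "haplotype",
    gene_id = reference$gene_id,
    parent_accession = reference$accession,
    haplotype_id = as.character(haplotype$haplotype_id),
    substitutions = format_substitutions(subs),
    frequency = as.numeric(haplotype$frequency),
    stop_junctions = reference$stop_junctions[[1L]]
  )
  rec
}

#' Revert a haplotype record to its reference sequence
#'
#' Swaps `ref` and `alt` of every substitution and applies them again;
#' useful for consistency checks (applying then reverting must reproduce
#' the reference exactly).
#'
#' @param sequence Haplotype residue string.
#' @param substitutions `posREF>ALT` string or parsed data frame (positions
#'   refer to the shared coordinate system).
#' @return The reference residue string.
#' @export
revert_substitutions <- function(sequence, substitutions) {
  subs <- substitutions
  if (is.character(subs)) subs <- parse_substitutions(subs)[[1]]
  if (nrow(subs) == 0L) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (any(chars[subs$position] != subs$alt)) {
    stop("alt residue mismatch while reverting substitutions")
  }
  chars[subs$position] <- subs$ref
  paste(chars, collapse = "")
}
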