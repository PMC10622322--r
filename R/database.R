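#' Assemble the target protein database
#'
#' Combines reference records, protein haplotypes (constructed by applying
#' each haplotype's substitution set to its parent reference) and sample
#' contaminants into one record table. Haplotypes identical in sequence to
#' their reference (empty substitution set) or to a previously assembled
#' haplotype of the same protein are kept in the database — redundancy is
#' resolved by peptide classification, not by dropping entries — but they
#' are flagged in the `redundant` column and reported.
#'
#' @param references Record data frame of kind `"reference"`.
#' @param haplotypes Haplotype table: data frame with columns
#'   `parent_accession` (or `protein_id`), `haplotype_id`, `substitutions`
#'   (`posREF>ALT`, `;`-joined) and `frequency`.
#' @param contaminants Record data frame of kind `"contaminant"` (optional).
#' @return Record data frame with one row per reference, per
#'   reference-times-haplotype, and per contaminant, plus a logical
#'   `redundant` column.
#' @export
build_target_database <- function(references, haplotypes = NULL,
                                  contaminants = NULL) {
  recs <- list()
  references$redundant <- FALSE
  recs$ref <- references
  if (!is.null(haplotypes) && nrow(haplotypes) > 0L) {
    if (is.null(haplotypes$parent_accession)) {
      haplotypes$parent_accession <- haplotypes$protein_id
    }
    missing <- setdiff(haplotypes$parent_accession, references$accession)
    if (length(missing) > 0L) {
      stop("haplotypes reference unknown proteins: ",
           paste(unique(missing), collapse = ", "))
    }
    hap_rows <- lapply(seq_len(nrow(haplotypes)), function(i) {
      h <- haplotypes[i, , drop = FALSE]
      ref <- references[references$accession == h$parent_accession, , drop = FALSE]
      apply_substitutions(ref, h)
    })
    haps <- bind_records(hap_rows)
    key <- paste(haps$parent_accession, haps$sequence)
    ref_key <- paste(references$accession, references$sequence)
    haps$redundant <- duplicated(key) | key %in% ref_key
    if (any(haps$redundant)) {
      message(sum(haps$redundant), " redundant haplotype record(s) flagged: ",
              paste(utils::head(haps$accession[haps$redundant], 5L),
                    collapse = ", "))
    }
    recs$hap <- haps
  }
  if (!is.null(contaminants) && nrow(contaminants) > 0L) {
    contaminants$redundant <- FALSE
    recs$cont <- contaminants
  }
  db <- do.call(rbind, recs)
  rownames(db) <- NULL
  if (anyDuplicated(db$accession)) {
    stop("duplicate accessions in target database: ",
         paste(unique(db$accession[duplicated(db$accession)]), collapse = ", "))
  }
  db
}

# FASTA header for one record, bit-exact dialect used by the whole package
fasta_header <- function(rec) {
  switch(rec$kind,
    reference = sprintf(">ref|%s|gene=%s", rec$accession, rec$gene_id),
    haplotype = sprintf(">hap|%s|gene=%s subs=%s freq=%.6f",
                        rec$accession, rec$gene_id, rec$substitutions,
                        rec$frequency),
    contaminant = sprintf(">cont|%s", rec$accession),
    stop("unknown record kind: ", rec$kind)
  )
}

#' Write a record database as FASTA
#'
#' Headers follow a fixed dialect so that haplotype metadata round-trips
#' through the file: `>ref|ACC|gene=G`, `>hap|ACC-hK|gene=G subs=...
#' freq=0.123456`, `>cont|ACC`, and decoys prefix `decoy_` to the header of
#' the record they shuffle.
#'
#' @param records Record data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(records, path) {
  headers <- vapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    if (rec$kind == "decoy") {
      paste0(">decoy_", sub("^>", "", fasta_header(
        data.frame(
          accession = sub("^decoy_", "", rec$accession),
          gene_id = rec$gene_id, kind = rec$decoy_source_kind,
          substitutions = rec$substitutions, frequency = rec$frequency,
          stringsAsFactors = FALSE
        )[1L, ])))
    } else {
      fasta_header(rec[1L, ])
    }
  }, "")
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- sub("^>", "", headers)
  Biostrings::writeXStringSet(seqs, filepath = path, width = 60L)
  invisible(path)
}

#' Read a database FASTA written by [write_database_fasta()]
#'
#' Parses the header dialect back into a record data frame; haplotype
#' substitution sets and frequencies survive the round trip exactly (the
#' frequency at 6 decimal places).
#'
#' @param path FASTA file.
#' @return Record data frame.
#' @export
read_database_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  rows <- lapply(seq_along(headers), function(i) {
    h <- headers[[i]]
    s <- as.character(seqs[[i]])
    is_decoy <- startsWith(h, "decoy_")
    core <- if (is_decoy) sub("^decoy_", "", h) else h
    rec <- if (startsWith(core, "ref|")) {
      m <- regmatches(core, regexec("^ref\\|([^|]+)\\|gene=(\\S+)", core))[[1]]
      protein_record(m[2], s, "reference", gene_id = m[3])
    } else if (startsWith(core, "hap|")) {
      m <- regmatches(core, regexec(
        "^hap\\|([^|]+)\\|gene=(\\S+) subs=(\\S*) freq=([0-9.eE+-]+)", core))[[1]]
      acc <- m[2]
      protein_record(acc, s, "haplotype", gene_id = m[3],
                     parent_accession = sub("-h[0-9]+$", "", acc),
                     haplotype_id = sub("^.*-(h[0-9]+)$", "\\1", acc),
                     substitutions = m[4], frequency = as.numeric(m[5]))
    } else if (startsWith(core, "cont|")) {
      protein_record(sub("^cont\\|", "", core), s, "contaminant")
    } else {
      stop("unrecognized FASTA header: ", h)
    }
    if (is_decoy) {
      rec$decoy_source_kind <- rec$kind
      rec$kind <- "decoy"
      rec$parent_accession <- rec$accession
      rec$accession <- paste0("decoy_", rec$accession)
    }
    rec
  })
  same_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(same_cols, names(r))) r[[cl]] <- NA_character_
    r[, same_cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# reverse each cleavage-delimited segment, keeping a terminal K/R in place
reverse_segments <- function(sequence, rule = "trypsin") {
  bounds <- fragment_bounds(sequence, rule)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_len(nrow(bounds))) {
    seg <- chars[(bounds[i, "start"] + 1L):bounds[i, "end"]]
    n <- length(seg)
    if (seg[n] %in% c("K", "R")) {
      if (n > 1L) seg[1:(n - 1L)] <- rev(seg[1:(n - 1L)])
    } else {
      seg <- rev(seg)
    }
    out <- c(out, seg)
  }
  paste(out, collapse = "")
}

# random permutation of the non-terminal residues of each segment
shuffle_segments <- function(sequence, rule = "trypsin") {
  bounds <- fragment_bounds(sequence, rule)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_len(nrow(bounds))) {
    seg <- chars[(bounds[i, "start"] + 1L):bounds[i, "end"]]
    n <- length(seg)
    if (seg[n] %in% c("K", "R")) {
      if (n > 2L) seg[1:(n - 1L)] <- sample(seg[1:(n - 1L)])
    } else if (n > 1L) {
      seg <- sample(seg)
    }
    out <- c(out, seg)
  }
  paste(out, collapse = "")
}

#' Generate decoy records by segment reversal with collision avoidance
#'
#' One decoy per target record, produced by reversing the residues of each
#' tryptic segment while keeping the segment-terminal K/R in place (the
#' strategy popularised by DecoyPyrat). Any decoy whose in-range tryptic
#' peptides (length window, up to `max_missed` missed cleavages) collide
#' with a target peptide is re-shuffled (seeded permutation of segment
#' interiors) up to `max_attempts` times; decoys still colliding after that
#' are kept and the residual collisions reported via a warning. Residue
#' composition and length of each protein are preserved.
#'
#' @param targets Target record data frame (references, haplotypes,
#'   contaminants).
#' @param rule Cleavage rule.
#' @param max_missed,length_range Digestion parameters used for the
#'   collision check.
#' @param max_attempts Re-shuffle attempts per colliding decoy.
#' @param seed Integer seed making the shuffles reproducible.
#' @return Decoy record data frame (accessions prefixed `decoy_`), with an
#'   attribute `"collisions"` counting target-colliding decoy peptides that
#'   could not be removed.
#' @export
generate_decoys <- function(targets, rule = "trypsin", max_missed = 2L,
                            length_range = c(8L, 40L), max_attempts = 10L,
                            seed = 1L) {
  stopifnot(nrow(targets) > 0L)
  target_peps <- unique(digest_records(targets, max_missed, length_range, rule)$peptide)
  target_set <- new.env(parent = emptyenv())
  for (p in target_peps) assign(p, TRUE, envir = target_set)
  residual <- 0L
  withr::with_seed(seed, {
    decoys <- lapply(seq_len(nrow(targets)), function(i) {
      rec <- targets[i, , drop = FALSE]
      dseq <- reverse_segments(rec$sequence, rule)
      attempt <- 0L
      repeat {
        drec <- protein_record(paste0("decoy_", rec$accession), dseq, "decoy",
                               gene_id = rec$gene_id,
                               parent_accession = rec$accession,
                               stop_junctions = rec$stop_junctions[[1L]])
        peps <- digest(drec, max_missed, length_range, rule)$peptide
        hits <- vapply(peps, function(p) exists(p, envir = target_set,
                                                inherits = FALSE), logical(1))
        if (!any(hits) || attempt >= max_attempts) {
          if (any(hits)) residual <<- residual + sum(hits)
          drec$substitutions <- rec$substitutions
          drec$frequency <- rec$frequency
          drec$decoy_source_kind <- rec$kind
          return(drec)
        }
        attempt <- attempt + 1L
        dseq <- shuffle_segments(rec$sequence, rule)
      }
    })
  })
  out <- bind_records(decoys)
  if (residual > 0L) {
    warning(residual, " decoy peptide(s) still collide with targets after ",
            max_attempts, " shuffling attempts")
  }
  attr(out, "collisions") <- residual
  out
}
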