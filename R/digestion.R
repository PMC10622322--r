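#' Tryptic cleavage sites of a sequence
#'
#' Returns the 0-based residue positions after which trypsin cleaves. Under
#' the default rule a position `i` is a site iff the residue at `i` is K or
#' R and a following residue exists and is not P (the canonical proline
#' exception, matching the common search-engine default). The C-terminus of
#' the protein terminates the last peptide but is not itself a site.
#'
#' @param sequence Residue string.
#' @param rule `"trypsin"` (K/R not before P) or `"strict_kr"` (K/R
#'   regardless of the following residue).
#' @return Sorted integer vector of 0-based cleavage positions.
#' @examples
#' cleavage_sites("ACKPD")          # integer(0): K before P suppressed
#' cleavage_sites("AAAAKCCCCKDDDD") # 4, 9
#' @export
cleavage_sites <- function(sequence, rule = c("trypsin", "strict_kr")) {
  rule <- match.arg(rule)
  n <- nchar(sequence)
  if (n < 2L) return(integer(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  is_kr <- chars %in% c("K", "R")
  sites <- which(is_kr[-n])                      # 1-based, residue has a successor
  if (rule == "trypsin") {
    sites <- sites[chars[sites + 1L] != "P"]
  }
  as.integer(sites - 1L)                         # 0-based
}

# fully cleaved fragment boundaries as 0-based half-open intervals
fragment_bounds <- function(sequence, rule = "trypsin") {
  sites <- cleavage_sites(sequence, rule)
  starts <- c(0L, sites + 1L)
  ends <- c(sites + 1L, nchar(sequence))
  cbind(start = starts, end = ends)
}

#' In silico tryptic digestion of a protein record
#'
#' Enumerates every fully tryptic peptide formed by concatenating
#' `1..(max_missed + 1)` consecutive fully cleaved fragments, then filters
#' to the retained length window (inclusive). Peptides whose span crosses a
#' stop junction (see [strip_stop_symbols()]) or that contain a
#' non-standard residue are excluded. For haplotype records the
#' substitutions falling inside each peptide span are annotated, which
#' downstream classification uses to assign variant classes.
#'
#' Spans are 0-based half-open on the record's own sequence; because
#' haplotypes are length-preserving, haplotype spans also index the parent
#' reference.
#'
#' @param record One-row record data frame ([protein_record()]).
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @param length_range Inclusive peptide length window, default `c(8, 40)`.
#' @param rule Cleavage rule, see [cleavage_sites()].
#' @return Data frame with columns `accession`, `peptide`, `start`, `end`,
#'   `missed_cleavages`, `n_subs`, `substitutions`.
#' @export
digest <- function(record, max_missed = 2L, length_range = c(8L, 40L),
                   rule = "trypsin") {
  stopifnot(nrow(record) == 1L, nzchar(record$sequence))
  seq <- record$sequence
  bounds <- fragment_bounds(seq, rule)
  nfrag <- nrow(bounds)
  starts <- integer(0); ends <- integer(0); mc <- integer(0)
  for (k in 0:max_missed) {
    if (nfrag - k < 1L) break
    i <- seq_len(nfrag - k)
    starts <- c(starts, bounds[i, "start"])
    ends <- c(ends, bounds[i + k, "end"])
    mc <- c(mc, rep.int(k, length(i)))
  }
  len <- ends - starts
  keep <- len >= length_range[1L] & len <= length_range[2L]
  # stop junctions: peptide containing residues on both sides of a junction
  junctions <- record$stop_junctions[[1L]]
  if (length(junctions) > 0L && any(keep)) {
    crosses <- vapply(which(keep), function(i) {
      any(junctions > starts[i] & junctions < ends[i])
    }, logical(1))
    keep[keep] <- !crosses
  }
  starts <- starts[keep]; ends <- ends[keep]; mc <- mc[keep]
  peptide <- substring(seq, starts + 1L, ends)
  std <- !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), peptide)
  starts <- starts[std]; ends <- ends[std]; mc <- mc[std]
  peptide <- peptide[std]

  subs <- parse_substitutions(record$substitutions)[[1L]]
  n_subs <- integer(length(peptide))
  sub_str <- character(length(peptide))
  if (nrow(subs) > 0L && length(peptide) > 0L) {
    pos0 <- subs$position - 1L
    for (i in seq_along(peptide)) {
      inside <- pos0 >= starts[i] & pos0 < ends[i]
      n_subs[i] <- sum(inside)
      sub_str[i] <- format_substitutions(subs[inside, , drop = FALSE])
    }
  }
  data.frame(
    accession = rep.int(record$accession, length(peptide)),
    peptide = peptide,
    start = as.integer(starts),
    end = as.integer(ends),
    missed_cleavages = as.integer(mc),
    n_subs = n_subs,
    substitutions = sub_str,
    stringsAsFactors = FALSE
  )
}

#' Digest every record of a database
#'
#' @param records Record data frame.
#' @inheritParams digest
#' @return Row-bound digestion output of [digest()] for every record.
#' @export
digest_records <- function(records, max_missed = 2L, length_range = c(8L, 40L),
                           rule = "trypsin") {
  out <- lapply(seq_len(nrow(records)), function(i) {
    digest(records[i, , drop = FALSE], max_missed = max_missed,
           length_range = length_range, rule = rule)
  })
  if (length(out) == 0L) {
    return(digest(protein_record("x", "AAAAKAAAAK"), max_missed, length_range)[0L, ])
  }
  do.call(rbind, out)
}
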