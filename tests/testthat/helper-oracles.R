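# Independent brute-force oracles. These deliberately avoid the package's
# own digestion/classification/FDR code paths: sites come from a regex,
# peptides from exhaustive substring enumeration, classes from plain loops.

# 0-based tryptic cleavage positions via regex lookahead
oracle_sites <- function(seq) {
  m <- gregexpr("[KR](?=[^P])", seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# all substrings whose boundaries are cleavage-consistent with <= max_missed
# internal sites, filtered to the length window; returns start/end/peptide
oracle_digest <- function(seq, max_missed = 2L, length_range = c(8L, 40L)) {
  L <- nchar(seq)
  sites <- oracle_sites(seq)
  site_ind <- logical(L)
  site_ind[sites + 1L] <- TRUE
  cum <- cumsum(site_ind)
  n_sites_below <- function(p) if (p <= 0L) 0L else cum[p]  # sites < p (0-based)
  starts <- c(0L, sites + 1L)
  ends <- c(sites + 1L, L)
  grid <- expand.grid(start = starts, end = ends)
  grid <- grid[grid$end - grid$start >= length_range[1L] &
                 grid$end - grid$start <= length_range[2L], , drop = FALSE]
  if (nrow(grid) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      peptide = character(0), missed_cleavages = integer(0)))
  }
  # internal sites: 0-based positions in [start, end-2]
  internal <- mapply(function(s, e) {
    n_sites_below(e - 1L) - n_sites_below(s)
  }, grid$start, grid$end)
  grid <- grid[internal <= max_missed, , drop = FALSE]
  grid$missed_cleavages <- internal[internal <= max_missed]
  grid$peptide <- substring(seq, grid$start + 1L, grid$end)
  rownames(grid) <- NULL
  grid[order(grid$start, grid$end), c("start", "end", "peptide", "missed_cleavages")]
}

# brute-force classification of a micro-proteome: records is a data frame
# with accession, gene_unit, sequence, substitutions (posREF>ALT on the
# record's own coordinates, ";"-joined, "" for none)
oracle_classify <- function(records, max_missed = 2L, length_range = c(8L, 40L)) {
  occ <- list()
  for (i in seq_len(nrow(records))) {
    peps <- oracle_digest(records$sequence[i], max_missed, length_range)
    if (nrow(peps) == 0L) next
    peps <- peps[!duplicated(peps[, c("start", "end")]), , drop = FALSE]
    sub_str <- records$substitutions[i]
    pos0 <- integer(0)
    if (nzchar(sub_str)) {
      parts <- strsplit(sub_str, ";", fixed = TRUE)[[1L]]
      pos0 <- as.integer(sub("^([0-9]+).*$", "\\1", parts)) - 1L
    }
    peps$n_subs <- vapply(seq_len(nrow(peps)), function(j) {
      sum(pos0 >= peps$start[j] & pos0 < peps$end[j])
    }, integer(1))
    peps$accession <- records$accession[i]
    peps$gene_unit <- records$gene_unit[i]
    occ[[length(occ) + 1L]] <- peps
  }
  occ <- do.call(rbind, occ)
  out <- list()
  for (p in unique(occ$peptide)) {
    o <- occ[occ$peptide == p, , drop = FALSE]
    m <- min(o$n_subs)
    vc <- if (m == 0L) "canonical" else if (m == 1L) "single_variant" else "multivariant"
    sc <- if (length(unique(o$gene_unit)) > 1L) "nonspecific"
      else if (length(unique(o$accession)) > 1L) "protein_specific"
      else "proteoform_specific"
    out[[p]] <- data.frame(peptide = p, variant_class = vc,
                           specificity_class = sc, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$peptide), ]
}

# brute-force target-decoy q-values: min FDR over all thresholds at or
# below each PSM's score
oracle_qvalues <- function(score, label) {
  thresholds <- sort(unique(score))
  fdr_at <- vapply(thresholds, function(s) {
    t <- sum(score >= s & label == "target")
    d <- sum(score >= s & label == "decoy")
    if (t == 0L) 1 else min(1, d / t)
  }, numeric(1))
  vapply(score, function(s) min(fdr_at[thresholds <= s]), numeric(1))
}

# random protein sequence with trypsin-realistic K/R content
random_protein <- function(len) {
  other <- setdiff(haplopept::AA_STANDARD, c("K", "R"))
  paste(sample(c(other, "K", "R"), len, replace = TRUE,
               prob = c(rep(0.8 / 18, 18), 0.1, 0.1)), collapse = "")
}
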