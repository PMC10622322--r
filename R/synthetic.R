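#' Configuration of the synthetic proteome generator
#'
#' The generator emulates the inputs of a haplotype-aware proteogenomic
#' study: reference proteins, phased sets of amino acid substitutions
#' (haplotypes) with population frequencies restricted to common alleles
#' (minor allele frequency at least 1% by default), a fraction of
#' substitutions that replace a K/R and thereby destroy a tryptic cleavage
#' site, and planted haplotypes guaranteed to place two substitutions in
#' one tryptic peptide (multivariant peptides) so downstream stages can be
#' validated against a ground-truth manifest.
#'
#' @param n_proteins Number of reference proteins.
#' @param protein_length_range Inclusive residue-count interval.
#' @param substitution_density Background substitutions per 100 residues
#'   (planted substitutions come on top).
#' @param haplotypes_per_protein Target number of haplotypes per protein
#'   (upper bound: haplotypes with an empty substitution set are not
#'   fabricated).
#' @param n_planted_pairs Number of planted substitution pairs, each
#'   guaranteed to fall in one tryptic peptide of its planted haplotype;
#'   every planted pair contributes one multivariant peptide and two
#'   `multi_only` substitutions to the manifest.
#' @param frequency_distribution List with `shape1`, `shape2` (Beta
#'   parameters of raw haplotype frequencies) and `max_total` (total
#'   haplotype mass per protein; the remainder is the reference haplotype
#'   frequency).
#' @param min_allele_frequency Lower bound on haplotype frequencies
#'   (default 0.01, i.e. common variation only).
#' @param cleavage_site_loss_rate Proportion of background substitutions
#'   that replace a K or R.
#' @param seed Integer seed; identical configurations produce
#'   byte-identical outputs.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 30L,
                             protein_length_range = c(150L, 400L),
                             substitution_density = 1.0,
                             haplotypes_per_protein = 3L,
                             n_planted_pairs = 5L,
                             frequency_distribution = list(shape1 = 1, shape2 = 4,
                                                           max_total = 0.9),
                             min_allele_frequency = 0.01,
                             cleavage_site_loss_rate = 0.1,
                             seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    protein_length_range = as.integer(protein_length_range),
    substitution_density = substitution_density,
    haplotypes_per_protein = as.integer(haplotypes_per_protein),
    n_planted_pairs = as.integer(n_planted_pairs),
    frequency_distribution = frequency_distribution,
    min_allele_frequency = min_allele_frequency,
    cleavage_site_loss_rate = cleavage_site_loss_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_proteins < 1L) stop("n_proteins must be positive")
  if (cfg$protein_length_range[1L] < 50L ||
      diff(cfg$protein_length_range) < 0L) {
    stop("protein_length_range must be an increasing interval of lengths >= 50")
  }
  if (cfg$substitution_density < 0) stop("substitution_density must be >= 0")
  if (cfg$substitution_density == 0 && cfg$cleavage_site_loss_rate > 0 &&
      cfg$haplotypes_per_protein > 0L) {
    stop("impossible configuration: cleavage_site_loss_rate > 0 requires a ",
         "positive substitution_density")
  }
  if (cfg$min_allele_frequency <= 0 || cfg$min_allele_frequency > 1) {
    stop("min_allele_frequency must be in (0, 1]")
  }
  if (cfg$cleavage_site_loss_rate < 0 || cfg$cleavage_site_loss_rate > 1) {
    stop("cleavage_site_loss_rate must be in [0, 1]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# residue sampler: uniform over the 20 residues with K and R boosted to 10%
# each so random tryptic peptides have realistic lengths
sample_residues <- function(n) {
  other <- setdiff(AA_STANDARD, c("K", "R"))
  probs <- c(rep(0.8 / 18, 18), 0.1, 0.1)
  sample(c(other, "K", "R"), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic reference proteome with phased haplotypes
#'
#' Produces reference protein records, a haplotype table, a substitution
#' table and a ground-truth manifest. Each planted pair rewrites a short
#' region of a protein into a clean tryptic fragment (preceded by K, ending
#' in R, no internal K/R, length 14-26) and places two substitutions inside
#' it, carried by one dedicated haplotype; by construction the pair can
#' only be observed in a multivariant peptide, whatever the number of
#' missed cleavages. Background substitutions (never inside planted
#' regions) are distributed over additional haplotypes; a configurable
#' fraction of them replaces a K/R, removing a cleavage site. Alternative
#' alleles are never K, R or P, so substitutions destroy but never create
#' cleavage sites. Per-substitution allele frequencies are the summed
#' frequencies of the haplotypes carrying the substitution.
#'
#' @param config A [synthetic_config()].
#' @return List: `records` (reference records), `haplotypes`,
#'   `substitutions` (`parent_accession`, `variant_id`, `position`, `ref`,
#'   `alt`, `allele_frequency`), and `manifest` (list with
#'   `planted_multivariant_peptides` and `planted_substitution_classes`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_proteome_impl(config))
}

generate_proteome_impl <- function(config) {
  fd <- config$frequency_distribution
  alt_pool <- setdiff(AA_STANDARD, c("K", "R", "P"))
  refs <- list(); haps <- list(); subs <- list()
  planted_pep <- list(); planted_cls <- list()
  plant_protein <- rep(seq_len(config$n_proteins),
                       length.out = max(config$n_planted_pairs, 0L))
  variant_counter <- 0L
  new_variant_id <- function() {
    variant_counter <<- variant_counter + 1L
    sprintf("rs%06d", variant_counter)
  }

  for (p in seq_len(config$n_proteins)) {
    acc <- sprintf("SYN%04d", p)
    gene <- sprintf("GENE%04d", p)
    len <- sample(config$protein_length_range[1L]:config$protein_length_range[2L], 1L)
    chars <- sample_residues(len)

    # ---- planted multivariant windows -----------------------------------
    n_plants <- sum(plant_protein == p)
    reserved <- logical(len)        # no background substitution may land here
    plant_sub_rows <- list(); plant_windows <- list()
    for (k in seq_len(n_plants)) {
      w <- sample(14:26, 1L)
      ok <- FALSE
      for (try in 1:200) {
        start <- sample(2:(len - w - 1L), 1L)   # 1-based start of fragment
        if (!any(reserved[max(1L, start - 2L):min(len, start + w + 1L)])) {
          ok <- TRUE; break
        }
      }
      if (!ok) next
      # fragment occupies [start, start + w - 1]; preceded by K, ends in R
      chars[start - 1L] <- "K"
      interior <- start:(start + w - 2L)
      chars[interior] <- sample(setdiff(alt_pool, "P"), length(interior),
                                replace = TRUE)
      chars[start + w - 1L] <- "R"
      if (start + w <= len && chars[start + w] == "P") chars[start + w] <- "A"
      reserved[max(1L, start - 2L):min(len, start + w)] <- TRUE
      pos_pair <- sort(sample(interior, 2L))
      alts <- vapply(pos_pair, function(q) {
        sample(setdiff(alt_pool, c("P", chars[q])), 1L)
      }, "")
      plant_sub_rows[[k]] <- data.frame(
        parent_accession = acc,
        variant_id = c(new_variant_id(), new_variant_id()),
        position = pos_pair, ref = chars[pos_pair], alt = alts,
        stringsAsFactors = FALSE
      )
      plant_windows[[k]] <- c(start = start, w = w)
    }

    # ---- background substitutions ---------------------------------------
    n_bg <- round(config$substitution_density / 100 * len)
    kr_pos <- which(chars %in% c("K", "R") & !reserved)
    free_pos <- which(!(chars %in% c("K", "R")) & !reserved)
    bg_rows <- list()
    for (b in seq_len(n_bg)) {
      lose_site <- stats::runif(1) < config$cleavage_site_loss_rate &&
        length(kr_pos) > 0L
      if (lose_site) {
        q <- sample(kr_pos, 1L); kr_pos <- setdiff(kr_pos, q)
      } else {
        if (length(free_pos) == 0L) break
        q <- sample(free_pos, 1L); free_pos <- setdiff(free_pos, q)
      }
      bg_rows[[b]] <- data.frame(
        parent_accession = acc, variant_id = new_variant_id(),
        position = q, ref = chars[q],
        alt = sample(setdiff(alt_pool, chars[q]), 1L),
        stringsAsFactors = FALSE
      )
    }
    bg <- if (length(bg_rows) > 0L) do.call(rbind, bg_rows) else NULL

    # ---- haplotypes ------------------------------------------------------
    hap_rows <- list()
    h_idx <- 0L
    for (k in seq_along(plant_sub_rows)) {
      if (is.null(plant_sub_rows[[k]])) next
      h_idx <- h_idx + 1L
      hap_rows[[length(hap_rows) + 1L]] <- data.frame(
        parent_accession = acc, haplotype_id = paste0("h", h_idx),
        substitutions = format_substitutions(plant_sub_rows[[k]]),
        stringsAsFactors = FALSE
      )
    }
    n_bg_hap <- max(0L, config$haplotypes_per_protein - h_idx)
    if (!is.null(bg) && nrow(bg) > 0L) {
      for (k in seq_len(n_bg_hap)) {
        take <- stats::runif(nrow(bg)) < 0.5
        if (!any(take)) take[sample(nrow(bg), 1L)] <- TRUE
        h_idx <- h_idx + 1L
        hap_rows[[length(hap_rows) + 1L]] <- data.frame(
          parent_accession = acc, haplotype_id = paste0("h", h_idx),
          substitutions = format_substitutions(bg[take, , drop = FALSE]),
          stringsAsFactors = FALSE
        )
      }
    }
    hap <- if (length(hap_rows) > 0L) do.call(rbind, hap_rows) else NULL
    if (!is.null(hap)) {
      raw <- pmax(stats::rbeta(nrow(hap), fd$shape1, fd$shape2),
                  config$min_allele_frequency)
      if (sum(raw) > fd$max_total) raw <- raw / sum(raw) * fd$max_total
      hap$frequency <- round(pmax(raw, config$min_allele_frequency), 6L)
    }

    seq_str <- paste(chars, collapse = "")
    refs[[p]] <- protein_record(acc, seq_str, "reference", gene_id = gene)
    if (!is.null(hap)) haps[[length(haps) + 1L]] <- hap
    prot_subs <- rbind(do.call(rbind, plant_sub_rows), bg)
    if (!is.null(prot_subs) && nrow(prot_subs) > 0L) {
      subs[[length(subs) + 1L]] <- prot_subs
    }

    # ---- manifest entries for the plants --------------------------------
    hap_counter <- 0L
    for (k in seq_along(plant_sub_rows)) {
      psr <- plant_sub_rows[[k]]
      if (is.null(psr)) next
      hap_counter <- hap_counter + 1L
      win <- plant_windows[[k]]
      frag <- chars[win["start"]:(win["start"] + win["w"] - 1L)]
      local <- psr$position - win["start"] + 1L
      frag[local] <- psr$alt
      planted_pep[[length(planted_pep) + 1L]] <- data.frame(
        peptide = paste(frag, collapse = ""),
        parent_accession = acc,
        haplotype_id = paste0("h", hap_counter),
        stringsAsFactors = FALSE
      )
      psr$expected_category <- "multi_only"
      planted_cls[[length(planted_cls) + 1L]] <- psr
    }
  }

  records <- bind_records(refs)
  haplotypes <- if (length(haps) > 0L) do.call(rbind, haps) else
    data.frame(parent_accession = character(0), haplotype_id = character(0),
               substitutions = character(0), frequency = numeric(0),
               stringsAsFactors = FALSE)
  substitutions <- if (length(subs) > 0L) do.call(rbind, subs) else
    data.frame(parent_accession = character(0), variant_id = character(0),
               position = integer(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  rownames(haplotypes) <- rownames(substitutions) <- NULL

  # keep only substitutions carried by at least one haplotype; the rest are
  # not part of the haplotype world and would have no allele frequency
  if (nrow(substitutions) > 0L) {
    carried <- unlist(lapply(seq_len(nrow(haplotypes)), function(i) {
      p <- parse_substitutions(haplotypes$substitutions[i])[[1L]]
      paste(haplotypes$parent_accession[i], p$position)
    }))
    substitutions <- substitutions[
      paste(substitutions$parent_accession, substitutions$position) %in% carried, ,
      drop = FALSE]
    rownames(substitutions) <- NULL
  }

  # allele frequency of a substitution = summed carrier-haplotype frequency
  if (nrow(substitutions) > 0L) {
    parsed <- parse_substitutions(haplotypes$substitutions)
    n_each <- vapply(parsed, nrow, 1L)
    idx <- rep(seq_len(nrow(haplotypes)), n_each)
    carrier <- data.frame(
      key = paste(haplotypes$parent_accession[idx],
                  do.call(rbind, parsed)$position),
      frequency = haplotypes$frequency[idx], stringsAsFactors = FALSE
    )
    af <- tapply(carrier$frequency, carrier$key, sum)
    substitutions$allele_frequency <- as.numeric(
      af[paste(substitutions$parent_accession, substitutions$position)])
  }

  manifest <- list(
    planted_multivariant_peptides =
      if (length(planted_pep) > 0L) do.call(rbind, planted_pep) else
        data.frame(peptide = character(0), parent_accession = character(0),
                   haplotype_id = character(0), stringsAsFactors = FALSE),
    planted_substitution_classes =
      if (length(planted_cls) > 0L) do.call(rbind, planted_cls) else
        data.frame(parent_accession = character(0), variant_id = character(0),
                   position = integer(0), ref = character(0),
                   alt = character(0), expected_category = character(0),
                   stringsAsFactors = FALSE)
  )
  rownames(manifest$planted_multivariant_peptides) <- NULL
  rownames(manifest$planted_substitution_classes) <- NULL
  list(records = records, haplotypes = haplotypes,
       substitutions = substitutions, manifest = manifest)
}

#' Generate synthetic contaminant records
#'
#' Random protein sequences flagged as contaminants, standing in for the
#' usual list of common sample contaminants (keratins, trypsin, ...).
#'
#' @param n Number of contaminants (0 allowed).
#' @param seed Integer seed.
#' @param length_range Sequence length interval.
#' @return Record data frame of kind `"contaminant"`.
#' @export
generate_contaminants <- function(n, seed = 1L, length_range = c(100L, 300L)) {
  stopifnot(n >= 0L)
  if (n == 0L) return(protein_record("x", "A")[0L, ])
  withr::with_seed(seed, {
    bind_records(lapply(seq_len(n), function(i) {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      protein_record(sprintf("CONT%03d", i),
                     paste(sample_residues(len), collapse = ""),
                     "contaminant")
    }))
  })
}

# reversed-but-terminal decoy peptide used for planted false matches
decoy_peptide <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n > 2L) chars[1:(n - 1L)] <- rev(chars[1:(n - 1L)])
  paste(chars, collapse = "")
}

#' Simulate peptide-spectrum matches with a known ground truth
#'
#' Every true PSM pairs a peptide with a noisy copy of its own predicted
#' spectrum: multiplicative log-normal intensity noise (sdlog =
#' `noise_level`), uniform m/z jitter bounded by `10 * min(noise_level, 1)`
#' ppm (inside the 10 ppm matching tolerance), spurious peaks placed away
#' from any predicted peak, and Gaussian retention-time noise. Planted
#' false matches pair such an observed spectrum with a decoy peptide (the
#' reversed-but-terminal permutation of a different simulated peptide) and
#' are labeled `decoy`, feeding the target-decoy machinery. Because a search
#' engine reports the *best* random match, which shares peaks with the
#' spectrum by selection, a minority (30%) of the decoy peptide's predicted
#' ions are planted into the false spectrum with unrelated intensities; the
#' false matches therefore have several matched peaks whose intensities
#' disagree with the prediction, as real decoy PSMs do. The search score is
#' the matched-peak fraction times the angular similarity, so true matches
#' score higher in distribution than planted false ones.
#'
#' @param peptides Character vector of peptide sequences (or a data frame
#'   with columns `peptide` and `accession`).
#' @param predictor Deterministic predictor ([toy_predictor()]).
#' @param noise_level Nonnegative noise proportion; 0 gives exact copies of
#'   the predictions.
#' @param decoy_fraction Fraction of the final PSM set that is planted
#'   false (0 gives no planted false matches).
#' @param seed Integer seed.
#' @param n_samples Number of sample identifiers to cycle PSMs over.
#' @return List: `psms` (PSM table), `spectra` (named list of observed
#'   [spectrum()] objects), `manifest` (list with `planted_true_psm_ids`
#'   and `planted_false_psm_ids`).
#' @export
simulate_psms <- function(peptides, predictor = toy_predictor(),
                          noise_level = 0.2, decoy_fraction = 0.5,
                          seed = 1L, n_samples = 1L) {
  if (noise_level < 0) stop("noise_level must be >= 0")
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("decoy_fraction must be in [0, 1)")
  }
  if (is.data.frame(peptides)) {
    acc <- peptides$accession
    peptides <- peptides$peptide
  } else {
    acc <- rep(NA_character_, length(peptides))
  }
  stopifnot(length(peptides) > 0L)
  withr::with_seed(seed, {
    jitter_ppm <- 10 * min(noise_level, 1)
    make_observed <- function(peptide, id, overlay_pred = NULL) {
      pred <- predictor$predict_spectrum(peptide)
      int <- ifelse(is.na(pred$intensity),
                    stats::runif(length(pred$intensity), 10, 40),
                    pred$intensity)
      int <- int * stats::rlnorm(length(int), 0, noise_level)
      mz <- pred$mz * (1 + stats::runif(length(pred$mz), -jitter_ppm,
                                        jitter_ppm) * 1e-6)
      n_spur <- round(noise_level * length(mz))
      if (n_spur > 0L) {
        lo <- min(pred$mz) - 50; hi <- max(pred$mz) + 50
        spur <- numeric(0)
        while (length(spur) < n_spur) {
          cand <- stats::runif(n_spur, lo, hi)
          far <- vapply(cand, function(x) {
            all(abs(x - pred$mz) / pred$mz > 30e-6)
          }, logical(1))
          spur <- c(spur, cand[far])
        }
        spur <- spur[seq_len(n_spur)]
        mz <- c(mz, spur)
        int <- c(int, stats::runif(n_spur, 5, 30))
      }
      if (!is.null(overlay_pred)) {
        # emulate the selection effect of a search engine's best random
        # match: a minority of the assigned peptide's predicted ions are
        # present in the spectrum, with unrelated intensities
        o_mz <- overlay_pred$mz[!is.na(overlay_pred$intensity)]
        n_ov <- max(3L, round(0.3 * length(o_mz)))
        take <- sample(o_mz, min(n_ov, length(o_mz)))
        take <- take[vapply(take, function(x) all(abs(x - mz) / x > 30e-6),
                            logical(1))]
        med <- stats::median(overlay_pred$intensity, na.rm = TRUE)
        mz <- c(mz, take * (1 + stats::runif(length(take), -2, 2) * 1e-6))
        int <- c(int, stats::runif(length(take), 0.2, 2) * med)
      }
      o <- order(mz)
      rt <- predictor$predict_rt(peptide) +
        stats::rnorm(1, 0, 60 * noise_level)
      spectrum(mz[o], int[o], retention_time = rt, id = id)
    }
    n_true <- length(peptides)
    n_false <- if (decoy_fraction > 0) {
      round(decoy_fraction * n_true / (1 - decoy_fraction))
    } else 0L
    spectra <- list(); rows <- list()
    for (i in seq_len(n_true)) {
      id <- sprintf("spec_true_%04d", i)
      spectra[[id]] <- make_observed(peptides[i], id)
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = id, peptide = peptides[i],
        accessions = ifelse(is.na(acc[i]), "", acc[i]),
        sample_id = sprintf("S%d", (i - 1L) %% n_samples + 1L),
        label = "target", ground_truth = "true", stringsAsFactors = FALSE
      )
    }
    if (n_false > 0L) {
      src <- sample(seq_len(n_true), n_false, replace = n_false > n_true)
      for (j in seq_len(n_false)) {
        id <- sprintf("spec_false_%04d", j)
        dp <- decoy_peptide(peptides[src[j]])
        spectra[[id]] <- make_observed(peptides[src[j]], id,
                                       overlay_pred = predictor$predict_spectrum(dp))
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_id = id, peptide = dp,
          accessions = "decoy_synthetic",
          sample_id = sprintf("S%d", (j - 1L) %% n_samples + 1L),
          label = "decoy", ground_truth = "planted_false",
          stringsAsFactors = FALSE
        )
      }
    }
    psms <- do.call(rbind, rows)
    # search score: matched-peak fraction times angular similarity
    score <- vapply(seq_len(nrow(psms)), function(i) {
      obs <- spectra[[psms$spectrum_id[i]]]
      pred <- predictor$predict_spectrum(psms$peptide[i])
      mt <- match_peaks(obs, pred, 10)
      a <- angular_similarity(mt)
      if (is.na(a)) return(0)
      n_pred <- sum(!is.na(pred$intensity))
      a * mt$n / n_pred
    }, numeric(1))
    psms$score <- score
    manifest <- list(
      planted_true_psm_ids = psms$spectrum_id[psms$ground_truth == "true"],
      planted_false_psm_ids = psms$spectrum_id[psms$ground_truth == "planted_false"]
    )
    list(psms = psms, spectra = spectra, manifest = manifest)
  })
}
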