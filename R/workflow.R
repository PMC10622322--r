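#' Pipeline run configuration
#'
#' Defaults reproduce the standard study settings: up to 2 missed
#' cleavages, peptides of 8-40 residues, 10 ppm fragment matching, 1%
#' PSM-level FDR.
#'
#' @param out_dir Output directory for stage files.
#' @param synthetic A [synthetic_config()] describing the generated world.
#' @param n_contaminants Number of synthetic contaminants.
#' @param max_missed,length_range,rule Digestion parameters.
#' @param tolerance_ppm,fdr_threshold QC parameters.
#' @param noise_level,decoy_fraction PSM simulation parameters.
#' @param stages Character vector of stages to run, in dependency order
#'   from `"simulate"`, `"build_db"`, `"digest"`, `"classify"`,
#'   `"coverage"`, `"qc"`.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("haplopept_run_"),
                       synthetic = synthetic_config(),
                       n_contaminants = 5L,
                       max_missed = 2L, length_range = c(8L, 40L),
                       rule = "trypsin",
                       tolerance_ppm = 10, fdr_threshold = 0.01,
                       noise_level = 0.2, decoy_fraction = 0.5,
                       stages = c("simulate", "build_db", "digest",
                                  "classify", "coverage", "qc"),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$synthetic$seed <- cfg$seed
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order — synthetic generation,
#' target+decoy database assembly, digestion, peptide classification and
#' substitution discoverability, residue coverage, PSM simulation and
#' quality control — writing each stage's output as a plain file (FASTA,
#' TSV, MGF, JSON) into the run directory so stages can be inspected and
#' re-run independently. A run manifest records the configuration, seeds,
#' file checksums and row counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  counts <- list()
  stages <- config$stages

  if ("simulate" %in% stages) {
    res$proteome <- generate_proteome(config$synthetic)
    res$contaminants <- generate_contaminants(config$n_contaminants,
                                              seed = config$seed + 1L)
    write_tsv(res$proteome$haplotypes, file.path(config$out_dir, "haplotypes.tsv"))
    write_tsv(res$proteome$substitutions,
              file.path(config$out_dir, "substitutions.tsv"))
    counts$haplotypes <- nrow(res$proteome$haplotypes)
  }

  if ("build_db" %in% stages) {
    if (is.null(res$proteome)) stop("stage build_db requires stage simulate")
    res$targets <- build_target_database(res$proteome$records,
                                         res$proteome$haplotypes,
                                         res$contaminants)
    res$decoys <- generate_decoys(res$targets, rule = config$rule,
                                  max_missed = config$max_missed,
                                  length_range = config$length_range,
                                  seed = config$seed + 2L)
    write_database_fasta(res$targets, file.path(config$out_dir, "targets.fasta"))
    write_database_fasta(res$decoys, file.path(config$out_dir, "decoys.fasta"))
    counts$targets <- nrow(res$targets)
    counts$decoys <- nrow(res$decoys)
  }

  if ("digest" %in% stages) {
    if (is.null(res$targets)) stop("stage digest requires stage build_db")
    res$peptides <- digest_records(res$targets, config$max_missed,
                                   config$length_range, config$rule)
    write_tsv(res$peptides, file.path(config$out_dir, "peptides.tsv"))
    counts$peptides <- nrow(res$peptides)
  }

  if ("classify" %in% stages) {
    if (is.null(res$peptides)) stop("stage classify requires stage digest")
    res$index <- build_peptide_index(res$peptides, res$targets)
    res$classes <- classify_peptides(res$index)
    res$discoverability <- substitution_discoverability(
      res$index, res$classes, res$proteome$substitutions)
    strat <- frequency_stratify(res$discoverability, res$proteome$haplotypes)
    res$discoverability <- strat$substitutions
    res$frequency_aggregate <- strat$aggregate
    cls_out <- res$classes
    write_tsv(cls_out, file.path(config$out_dir, "classification.tsv"))
    write_tsv(res$discoverability,
              file.path(config$out_dir, "discoverability.tsv"))
    counts$unique_peptides <- nrow(res$classes)
  }

  if ("coverage" %in% stages) {
    if (is.null(res$classes)) stop("stage coverage requires stage classify")
    res$coverage <- residue_coverage(res$proteome$records, res$index,
                                     res$classes)
    write_tsv(res$coverage$per_protein, file.path(config$out_dir, "coverage.tsv"))
    counts$proteins_covered <- nrow(res$coverage$per_protein)
  }

  if ("qc" %in% stages) {
    if (is.null(res$index)) {
      stop("stage qc requires PSM input or simulation (stage classify missing)")
    }
    predictor <- toy_predictor()
    variant_occ <- res$index[res$index$n_subs > 0L, , drop = FALSE]
    pool <- unique(rbind(
      variant_occ[, c("peptide", "accession")],
      res$index[res$index$missed_cleavages == 0L & res$index$kind == "reference",
                c("peptide", "accession")]
    ))
    names(pool) <- c("peptide", "accession")
    sim <- simulate_psms(pool, predictor,
                         noise_level = config$noise_level,
                         decoy_fraction = config$decoy_fraction,
                         seed = config$seed + 3L)
    cont_peps <- unique(res$index$peptide[res$index$kind == "contaminant"])
    sim$psms$is_contaminant <- sim$psms$peptide %in% cont_peps
    res$psms <- qc_psms(sim$psms, sim$spectra, predictor,
                        tolerance_ppm = config$tolerance_ppm,
                        fdr_threshold = config$fdr_threshold)
    res$psm_manifest <- sim$manifest
    write_mgf(sim$spectra, file.path(config$out_dir, "spectra.mgf"))
    write_tsv(res$psms, file.path(config$out_dir, "qc_psms.tsv"))
    counts$psms <- nrow(res$psms)
    counts$confident_psms <- sum(res$psms$confident)
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    stages = stages,
    parameters = list(max_missed = config$max_missed,
                      length_range = config$length_range,
                      tolerance_ppm = config$tolerance_ppm,
                      fdr_threshold = config$fdr_threshold),
    checksums = as.list(tools::md5sum(files)),
    row_counts = counts
  )
  cfg_for_hash <- config; cfg_for_hash$out_dir <- NULL
  manifest$config_hash <- digest_config(cfg_for_hash)
  jsonlite::write_json(manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# stable hash of a configuration via its deparsed, serialized form
digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}
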