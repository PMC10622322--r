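test_that("peak matching honors the 10 ppm tolerance and tie-breaks", {
  obs <- spectrum(c(500.0000, 600.0000), c(10, 20))
  pred <- spectrum(c(500.0025, 600.0150), c(5, 5))
  m <- match_peaks(obs, pred, tolerance_ppm = 10)
  # 500.0025 is 5 ppm away -> matched; 600.0150 is 25 ppm away -> not
  expect_equal(m$matches$obs_idx, 1L)
  expect_equal(m$matches$pred_idx, 1L)
  expect_equal(m$matches$ppm, 5, tolerance = 1e-5)  # denominator is predicted m/z
  # 20 ppm observed offset is rejected
  m2 <- match_peaks(spectrum(500.0100, 1), spectrum(500.0000, 1), 10)
  expect_equal(m2$n, 0L)
  # two observed peaks competing for one prediction: smaller ppm wins
  obs3 <- spectrum(c(500.0005, 500.0008), c(1, 1))
  m3 <- match_peaks(obs3, spectrum(500.0000, 1), 10)
  expect_equal(m3$matches$obs_idx, 1L)
  pred3 <- spectrum(c(499.999, 500.001), c(1, 1))
  # one-to-one: a second observed peak takes the remaining prediction
  obs4 <- spectrum(c(499.9995, 500.0005), c(1, 1))
  m4 <- match_peaks(obs4, pred3, 10)
  expect_equal(sort(m4$matches$pred_idx), c(1L, 2L))
  expect_equal(anyDuplicated(m4$matches$obs_idx), 0L)
  # empty observed spectrum is a 0-match result, not an error
  expect_equal(match_peaks(spectrum(numeric(0), numeric(0)), pred3, 10)$n, 0L)
})

test_that("missing intensity predictions are excluded from M and P", {
  obs <- spectrum(c(100, 200, 300), c(1, 2, 3))
  pred <- spectrum(c(100, 200, 300), c(NA, 5, 6))
  m <- match_peaks(obs, pred, 10)
  expect_equal(nrow(m$matches), 3L)
  expect_equal(m$n, 2L)
  expect_equal(m$M, c(2, 3))
  expect_equal(m$P, c(5, 6))
})

test_that("median scaling maps observed onto predicted intensities", {
  obs <- spectrum(c(100, 200, 300), c(2, 4, 6))
  pred <- spectrum(c(100, 200, 300), c(8, 8, 8))
  expect_equal(scale_observed(obs, pred)$intensity, c(4, 8, 12))
  same <- spectrum(c(100, 200), c(8, 8))
  expect_equal(scale_observed(same, pred)$intensity, c(8, 8))
  zeros <- spectrum(c(100, 200, 300), c(0, 0, 0))
  expect_error(scale_observed(zeros, pred), "zero median and mean")
})

test_that("angular similarity reproduces its closed forms", {
  expect_equal(angular_similarity(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(angular_similarity(c(1, 0), c(0, 1)), 0.5)
  expect_equal(angular_similarity(c(1, 1), c(1, 0)), 0.75)
  expect_true(is.na(angular_similarity(numeric(0), numeric(0))))
})

test_that("angular similarity is symmetric, scale-invariant and in [0.5, 1]", {
  set.seed(17)
  for (i in 1:500) {
    n <- sample(2:30, 1)
    M <- runif(n); P <- runif(n)
    a <- angular_similarity(M, P)
    expect_gte(a, 0.5); expect_lte(a, 1)
    expect_equal(angular_similarity(P, M), a)
    expect_equal(angular_similarity(M * runif(1, 1e-3, 1e3), P), a,
                 tolerance = 1e-12)
  }
  # equal to 1 iff proportional
  expect_equal(angular_similarity(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_lt(angular_similarity(c(1, 2, 3), c(2, 4, 7)), 1)
})

test_that("retention-time deviation uses calibration z-scores", {
  expect_equal(rt_deviation(c(10, 20, 30), c(10, 20, 30)), c(0, 0, 0))
  # calibration mean 40, sd 10 in both series; observed 50 vs predicted 45
  cal <- c(40 - sqrt(150), 40 + sqrt(150), 40, 40)   # mean 40, sd 10
  dev <- rt_deviation(50, 45, cal, cal)
  expect_equal(dev, 0.5, tolerance = 1e-9)
  expect_error(rt_deviation(1, 1, 5, 5), "at least 2")
  expect_error(rt_deviation(c(1, 2), c(1, 2), c(5, 5), c(1, 2)),
               "zero variance in observed")
})

test_that("target-decoy q-values match the worked example and edge cases", {
  psms <- data.frame(score = c(10, 9, 8, 8.5),
                     label = c("target", "target", "target", "decoy"),
                     stringsAsFactors = FALSE)
  out <- target_decoy_qvalues(psms, threshold = 0.01)
  expect_equal(out$q_value, c(0, 0, 1 / 3, 1 / 3))
  expect_equal(out$confident, c(TRUE, TRUE, FALSE, FALSE))
  # no decoys: all q-values 0
  t_only <- data.frame(score = c(3, 2, 1), label = rep("target", 3))
  expect_equal(target_decoy_qvalues(t_only)$q_value, c(0, 0, 0))
  # all decoys outscore all targets: q-values 1 for the targets
  swamp <- data.frame(score = c(5, 6, 1, 2),
                      label = c("decoy", "decoy", "target", "target"))
  expect_equal(target_decoy_qvalues(swamp)$q_value[3:4], c(1, 1))
  expect_error(target_decoy_qvalues(data.frame(score = 1, label = "decoy")),
               "no target")
  # contaminant-matching peptides fall out of the confident subset
  cont <- data.frame(score = c(10, 9), label = c("target", "target"),
                     is_contaminant = c(TRUE, FALSE))
  expect_equal(target_decoy_qvalues(cont)$confident, c(FALSE, TRUE))
})

test_that("q-values agree with the brute-force oracle on random score sets", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    psms <- data.frame(
      score = round(runif(n, 0, 10), sample(0:2, 1)),  # force ties sometimes
      label = sample(c("target", "decoy"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    if (!any(psms$label == "target")) psms$label[1] <- "target"
    got <- target_decoy_qvalues(psms)$q_value
    expect_equal(got, oracle_qvalues(psms$score, psms$label))
  }
})

test_that("q-values never increase with score and thresholds nest", {
  set.seed(23)
  psms <- data.frame(score = runif(300), label = sample(c("target", "decoy"),
                                                        300, replace = TRUE))
  out <- target_decoy_qvalues(psms)
  o <- order(out$score)
  expect_true(all(diff(out$q_value[o]) <= 1e-12))
  n01 <- sum(target_decoy_qvalues(psms, threshold = 0.01)$confident)
  n05 <- sum(target_decoy_qvalues(psms, threshold = 0.05)$confident)
  expect_lte(n01, n05)
})

test_that("mirror annotation assigns the conventional peak categories", {
  obs <- spectrum(c(100, 200, 300, 400), c(5, 6, 7, 8))
  pred <- spectrum(c(100, 200, 300, 500), c(3, NA, 0, 4))
  m <- match_peaks(obs, pred, 10)
  ann <- annotate_mirror(obs, pred, m)
  expect_equal(ann$observed,
               c("matched", "missing_prediction", "unannotated", "unmatched"))
  expect_equal(ann$predicted, c("matched", "missing", "matched", "unmatched"))
  # fully matching spectra: everything matched, no red predicted peaks
  full <- match_peaks(obs, spectrum(obs$mz, obs$intensity), 10)
  ann2 <- annotate_mirror(obs, spectrum(obs$mz, obs$intensity), full)
  expect_true(all(ann2$observed == "matched"))
  expect_true(all(ann2$predicted == "matched"))
})

test_that("qc_psms separates true from planted-false matches", {
  prot <- generate_proteome(synthetic_config(n_proteins = 6, seed = 29,
                                             n_planted_pairs = 2))
  db <- suppressMessages(build_target_database(prot$records, prot$haplotypes,
                                               NULL))
  occ <- build_peptide_index(digest_records(db), db)
  pool <- unique(occ[occ$missed_cleavages == 0L, c("peptide", "accession")])
  pool <- pool[nchar(pool$peptide) <= 25, ][1:60, ]
  predictor <- toy_predictor()
  sim <- simulate_psms(pool, predictor, noise_level = 0.25,
                       decoy_fraction = 0.5, seed = 31)
  out <- qc_psms(sim$psms, sim$spectra, predictor)
  true_a <- out$angular_similarity[out$ground_truth == "true"]
  false_a <- out$angular_similarity[out$ground_truth == "planted_false"]
  expect_gt(mean(true_a, na.rm = TRUE), mean(false_a, na.rm = TRUE))
  expect_true(all(out$rt_deviation[out$confident] >= 0))
  # noise-free true match has angular similarity exactly 1
  clean <- simulate_psms(pool[1:5, ], predictor, noise_level = 0,
                         decoy_fraction = 0, seed = 7)
  clean_out <- qc_psms(clean$psms, clean$spectra, predictor)
  expect_equal(clean_out$angular_similarity, rep(1, 5))
  expect_length(clean$manifest$planted_false_psm_ids, 0L)
})

test_that("MGF files round-trip spectra", {
  sp <- list(
    spectrum(c(100.1, 200.2), c(10, 20), retention_time = 312.5, id = "s1"),
    spectrum(c(150.123456, 250.5), c(1.5, 2.5), retention_time = 10, id = "s2")
  )
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_named(back, c("s1", "s2"))
  expect_equal(back$s1$mz, sp[[1]]$mz, tolerance = 1e-6)
  expect_equal(back$s2$intensity, sp[[2]]$intensity, tolerance = 1e-6)
  expect_equal(back$s1$retention_time, 312.5)
})
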