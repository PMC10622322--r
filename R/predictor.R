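# monoisotopic residue masses (Da)
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565

# Kyte-Doolittle hydropathy, used by the toy retention-time model
AA_KD <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Toy deterministic fragment and retention-time predictor
#'
#' A pluggable stand-in for learned fragmentation / retention-time
#' predictors. Given a peptide it produces the singly charged b- and y-ion
#' m/z ladder from monoisotopic residue masses, with a deterministic
#' intensity profile (bell-shaped along the series, modulated by the
#' flanking residue so different peptides get different profiles; y ions
#' stronger than b ions, as typical for HCD). The intensity of the b1 and
#' y1 ions is reported as missing (`NA`), mimicking predictors that do not
#' model terminal ions and exercising the missing-prediction peak
#' category. Retention time is a linear function of mean residue
#' hydropathy, in seconds.
#'
#' Any object with the same interface (`predict_spectrum(peptide)`
#' returning a [spectrum()], `predict_rt(peptide)` returning seconds, both
#' deterministic) can be used wherever a predictor is accepted.
#'
#' @param gradient_seconds Length of the simulated chromatographic
#'   gradient; default 5400 s.
#' @return A list with functions `predict_spectrum` and `predict_rt`.
#' @export
toy_predictor <- function(gradient_seconds = 5400) {
  predict_spectrum <- function(peptide) {
    chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
    stopifnot(all(chars %in% names(AA_MONO_MASS)))
    n <- length(chars)
    masses <- AA_MONO_MASS[chars]
    prefix <- cumsum(masses)
    b_mz <- prefix[-n] + PROTON_MASS
    y_mz <- rev(cumsum(rev(masses)))[-1L] + WATER_MASS + PROTON_MASS
    i <- seq_len(n - 1L)
    bell <- exp(-((i - n / 2)^2) / (2 * (n / 3)^2))
    mod_b <- 0.5 + (utf8ToInt(peptide) %% 53)[i] / 53
    mod_y <- 0.5 + (utf8ToInt(peptide) %% 47)[n - i] / 47
    b_int <- 60 * bell * mod_b
    y_int <- 100 * bell * mod_y
    b_int[1L] <- NA_real_                 # b1 not predicted
    y_int[n - 1L] <- NA_real_             # y1 not predicted
    mz <- c(b_mz, y_mz)
    int <- c(b_int, y_int)
    ion <- c(paste0("b", i), paste0("y", n - i))
    o <- order(mz)
    mz <- mz[o]; int <- int[o]; ion <- ion[o]
    # isobaric b/y coincidences: nudge by 1 uDa so peaks stay distinct
    while (any(diff(mz) <= 0)) {
      j <- which(diff(mz) <= 0) + 1L
      mz[j] <- mz[j] + 1e-6
    }
    spectrum(mz = mz, intensity = int, id = paste0("pred_", peptide), ion = ion)
  }
  predict_rt <- function(peptide) {
    chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
    kd <- mean(AA_KD[chars])
    # map hydropathy in roughly [-4.5, 4.5] onto 10%..90% of the gradient
    gradient_seconds * (0.5 + 0.4 * kd / 4.5)
  }
  list(predict_spectrum = predict_spectrum, predict_rt = predict_rt)
}
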