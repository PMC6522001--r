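#' Co-occurrence analysis of one promoter set
#'
#' The core site-pair workflow on an in-memory promoter set: fits a
#' Markov background to the sequences, calibrates a min(FPR + FNR)
#' cutoff per motif, scans both strands for binding sites, enumerates
#' site pairs under the distance constraint, and converts per-pair PMI
#' values to z-scores.
#'
#' @param seqs named character vector of promoter sequences.
#' @param library a probability `MotifLibrary`.
#' @param pairing a [pairing_config()].
#' @param z_cutoff significance threshold on the z-score (default 3).
#' @param markov_order order of the calibration background model fitted
#'   to `seqs` (default 2).
#' @param n_calibration positive/negative sample size per motif.
#' @param seed root seed for the calibration sampling.
#' @param both_strands scan the reverse strand too.
#' @param background base composition for log-odds scores.
#' @return list with `markov`, `thresholds`, `sites`, `counts` and
#'   `pmi` (a [zscore_transform()] result).
#' @export
cooccurrence_analysis <- function(seqs, library, pairing = pairing_config(),
                                  z_cutoff = 3, markov_order = 2L,
                                  n_calibration = 3000L, seed = 1L,
                                  both_strands = TRUE,
                                  background = rep(0.25, 4)) {
  seqs <- check_sequences(seqs)
  mm <- fit_markov(seqs, order = markov_order)
  thresholds <- calibrate_thresholds(library, mm,
                                     n_positive = n_calibration,
                                     n_negative = n_calibration,
                                     seed = seed, background = background)
  sites <- scan_sites(library, seqs, thresholds, both_strands = both_strands,
                      background = background)
  counts <- enumerate_pairs(sites, pairing)
  pmi <- zscore_transform(compute_pmi(counts), z_cutoff = z_cutoff)
  list(markov = mm, thresholds = thresholds, sites = sites, counts = counts,
       pmi = pmi)
}
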