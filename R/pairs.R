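#' Pairing configuration for TFBS dimer construction
#'
#' Two binding sites on the same sequence can form a dimer when the gap
#' between them (start of the downstream site minus end of the upstream
#' site, in bp) lies within `[d_min, d_max]`; the defaults 5 and 20 bp
#' are the recommended distance preferences for cooperative TF pairs.
#' Overlapping site pairs (gap < 0) are excluded unless `allow_overlap`.
#'
#' @param d_min,d_max gap bounds in bp, `0 <= d_min <= d_max`.
#' @param allow_homodimer count pairs of the same motif (default TRUE).
#' @param allow_overlap also count overlapping site pairs (default FALSE).
#' @return a `PairingConfig` list.
#' @export
pairing_config <- function(d_min = 5L, d_max = 20L, allow_homodimer = TRUE,
                           allow_overlap = FALSE) {
  if (d_min < 0 || d_max < d_min) stopf("need 0 <= d_min <= d_max")
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 allow_homodimer = isTRUE(allow_homodimer),
                 allow_overlap = isTRUE(allow_overlap)),
            class = "PairingConfig")
}

#' Enumerate binding-site pairs under the distance constraint
#'
#' Counts, over all sequences, every unordered pair of sites whose gap
#' satisfies the pairing configuration. A physical site never pairs with
#' itself; two sites of the same motif count as one homodimer pair and
#' contribute 2 to that motif's slot count. The result is invariant to
#' the input order of sites.
#'
#' @param sites binding-site data frame from [scan_sites()] (columns
#'   `sequence_id`, `motif_id`, `start`, `end`).
#' @param config a [pairing_config()].
#' @return a `PairCounts`: list with `n_pairs_total` (N), `pair_counts`
#'   (data frame `motif_a`, `motif_b`, `count`, with `motif_a <=
#'   motif_b`) and `slot_counts` (named vector of motif participations;
#'   sums to 2N).
#' @export
enumerate_pairs <- function(sites, config = pairing_config()) {
  lev <- sort(unique(sites$motif_id))
  empty <- structure(list(n_pairs_total = 0L,
                          pair_counts = data.frame(motif_a = character(),
                                                   motif_b = character(),
                                                   count = integer()),
                          slot_counts = structure(numeric(0), names = character())),
                     class = "PairCounts")
  if (!nrow(sites)) return(empty)
  o <- order(sites$sequence_id, sites$start, sites$end, sites$motif_id)
  s <- sites[o, ]
  C <- pair_count_core(as.integer(factor(s$sequence_id)),
                       as.integer(s$start), as.integer(s$end),
                       as.integer(factor(s$motif_id, levels = lev)),
                       length(lev), config$d_min, config$d_max,
                       config$allow_overlap, config$allow_homodimer)
  nz <- which(C > 0, arr.ind = TRUE)
  if (!nrow(nz)) return(empty)
  pair_counts <- data.frame(motif_a = lev[nz[, 1]], motif_b = lev[nz[, 2]],
                            count = C[nz], stringsAsFactors = FALSE)
  pair_counts <- pair_counts[order(pair_counts$motif_a, pair_counts$motif_b), ]
  rownames(pair_counts) <- NULL
  M <- C + t(C)  # diagonal doubles: homodimer pairs occupy two slots
  slot <- rowSums(M)
  names(slot) <- lev
  structure(list(n_pairs_total = sum(C), pair_counts = pair_counts,
                 slot_counts = slot[slot > 0]),
            class = "PairCounts")
}

#' Pointwise mutual information of every observed TF pair
#'
#' With N total qualifying pairs, `f_ab = N_ab / N` and slot frequencies
#' `f_a = slot_a / 2N`, each observed pair scores
#' `pmi(a, b) = ln(f_ab / (c * f_a * f_b))` with `c = 2` for heterodimers
#' and `c = 1` for homodimers, so that PMI is exactly 0 when the two
#' slots of a pair are filled independently. Pairs never observed
#' (`N_ab = 0`) are not scored.
#'
#' @param counts a `PairCounts` from [enumerate_pairs()].
#' @return data frame `motif_a`, `motif_b`, `count`, `pmi` (natural log).
#' @export
compute_pmi <- function(counts) {
  N <- counts$n_pairs_total
  if (N < 1) stopf("no site pairs under the distance constraints")
  pc <- counts$pair_counts
  f_ab <- pc$count / N
  f_a <- counts$slot_counts[pc$motif_a] / (2 * N)
  f_b <- counts$slot_counts[pc$motif_b] / (2 * N)
  cc <- ifelse(pc$motif_a == pc$motif_b, 1, 2)
  data.frame(motif_a = pc$motif_a, motif_b = pc$motif_b, count = pc$count,
             pmi = log(f_ab / (cc * f_a * f_b)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Transform PMI values to z-scores and flag significant pairs
#'
#' Centers and scales the PMI values of all scored pairs with the
#' population standard deviation; a cooperation is statistically
#' significant when its z-score is at least `z_cutoff` (default 3,
#' boundary inclusive).
#'
#' @param pmi data frame from [compute_pmi()] (columns `motif_a`,
#'   `motif_b`, `pmi`; `count` carried through when present).
#' @param z_cutoff significance threshold on the z-score.
#' @return a `pmi_result` data frame with added columns `z` and
#'   `significant`; the cutoff is stored in attribute `z_cutoff`.
#' @export
zscore_transform <- function(pmi, z_cutoff = 3) {
  if (nrow(pmi) < 2) stopf("need at least 2 scored pairs for z-scores")
  m <- mean(pmi$pmi)
  s <- sqrt(mean((pmi$pmi - m)^2))
  if (s == 0) stopf("degenerate PMI distribution (SD = 0); no pair can be significant")
  out <- pmi
  out$z <- (pmi$pmi - m) / s
  out$significant <- out$z >= z_cutoff
  attr(out, "z_cutoff") <- z_cutoff
  class(out) <- c("pmi_result", "data.frame")
  out
}
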