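#' Configuration of the background-subtraction step
#'
#' @param alpha scaling factor in `[-1, +1]` controlling how much of the
#'   estimated background cooperation level is subtracted; 0.5 by
#'   default. At -1 no background is subtracted and no differentiation
#'   between specific and common pairs occurs.
#' @param n_background_sets number of simulated (shuffled) sequence sets.
#' @param seed root seed; background set k uses `seed + k`.
#' @param shuffle `"dinucleotide"` (composition- and dinucleotide-
#'   preserving Euler-path shuffle, the default) or `"mononucleotide"`.
#' @return a `SpecificityConfig` list.
#' @export
specificity_config <- function(alpha = 0.5, n_background_sets = 100L,
                               seed = 1L,
                               shuffle = c("dinucleotide", "mononucleotide")) {
  if (alpha < -1 || alpha > 1) stopf("alpha must lie in [-1, 1]")
  if (n_background_sets < 1) stopf("need at least one background set")
  structure(list(alpha = alpha,
                 n_background_sets = as.integer(n_background_sets),
                 seed = as.integer(seed), shuffle = match.arg(shuffle)),
            class = "SpecificityConfig")
}

#' Shuffle a nucleotide sequence
#'
#' Dinucleotide mode performs an Euler-path shuffle: the output has
#' exactly the input's dinucleotide multiset and the same first and last
#' base, so base composition and adjacent-pair statistics are preserved
#' while positional structure (and hence any planted motif coupling) is
#' destroyed. Mononucleotide mode is a uniform permutation of the
#' letters. Runs of N are kept in place; the segments between them are
#' shuffled independently. Sequences shorter than 2 in dinucleotide mode
#' are returned unchanged.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @param mode `"dinucleotide"` or `"mononucleotide"`.
#' @param seed optional seed for a deterministic result.
#' @return the shuffled string.
#' @export
shuffle_sequence <- function(seq, mode = c("dinucleotide", "mononucleotide"),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  codes <- encode_seq(seq)
  n <- length(codes)
  if (n == 0) return(seq)
  runs <- rle(is.na(codes))
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  out <- codes
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r]) next  # N run stays put
    idx <- starts[r]:stops[r]
    seg <- codes[idx]
    if (mode == "mononucleotide") {
      out[idx] <- seg[sample.int(length(seg))]
    } else if (length(seg) >= 2) {
      out[idx] <- dinuc_shuffle_core(seg)
    }
  }
  decode_seq(out)
}

#' Mean background PMI per pair over shuffled sequence sets
#'
#' Estimates the level of background cooperation of every TF pair:
#' generates `n_background_sets` shuffled copies of the sequence set
#' (set k seeded with `seed + k`), runs the scan / pair-enumeration /
#' PMI pipeline on each with the same library, thresholds and pairing
#' configuration as the observed analysis, and averages each pair's PMI
#' over the sets in which it was scored. Background sets yielding no
#' pairs are skipped with a warning.
#'
#' @param seqs named character vector (the observed promoter set).
#' @param library,thresholds,pairing exactly as used for the observed
#'   PMI computation.
#' @param config a [specificity_config()].
#' @param both_strands,background forwarded to [scan_sites()].
#' @return data frame `motif_a`, `motif_b`, `avg_background_pmi`,
#'   `n_sets_scored`.
#' @export
background_avg_pmi <- function(seqs, library, thresholds,
                               pairing = pairing_config(),
                               config = specificity_config(),
                               both_strands = TRUE,
                               background = rep(0.25, 4)) {
  seqs <- check_sequences(seqs)
  sums <- numeric(0)
  nobs <- integer(0)
  any_ok <- FALSE
  for (k in seq_len(config$n_background_sets)) {
    set.seed(child_seed(config$seed, k))
    shuffled <- vapply(seqs, shuffle_sequence, character(1),
                       mode = config$shuffle)
    names(shuffled) <- names(seqs)
    sites <- scan_sites(library, shuffled, thresholds,
                        both_strands = both_strands, background = background)
    counts <- enumerate_pairs(sites, pairing)
    if (counts$n_pairs_total == 0) {
      warnf("background set %d produced no site pairs; skipped", k)
      next
    }
    any_ok <- TRUE
    pm <- compute_pmi(counts)
    key <- pair_key(pm$motif_a, pm$motif_b)
    new <- setdiff(key, names(sums))
    sums[new] <- 0; nobs[new] <- 0L
    sums[key] <- sums[key] + pm$pmi
    nobs[key] <- nobs[key] + 1L
  }
  if (!any_ok) stopf("all background sets were empty")
  parts <- do.call(rbind, strsplit(names(sums), "\t", fixed = TRUE))
  data.frame(motif_a = parts[, 1], motif_b = parts[, 2],
             avg_background_pmi = unname(sums / nobs),
             n_sets_scored = unname(nobs),
             stringsAsFactors = FALSE)
}

#' Subtract the scaled background cooperation level from observed PMI
#'
#' `pmi_specific = pmi - (1 + alpha) * avg_background_pmi` per pair;
#' pairs missing from the background map use 0. With `alpha = -1` the
#' subtraction vanishes and `pmi_specific` equals the observed PMI.
#'
#' @param pmi data frame with columns `motif_a`, `motif_b`, `pmi` (e.g.
#'   a [zscore_transform()] result).
#' @param avg data frame from [background_avg_pmi()].
#' @param alpha scaling factor in `[-1, 1]`.
#' @return the `pmi` data frame with columns `avg_background_pmi` and
#'   `pmi_specific` appended.
#' @export
subtract_background <- function(pmi, avg, alpha = 0.5) {
  if (alpha < -1 || alpha > 1) stopf("alpha must lie in [-1, 1]")
  key <- pair_key(pmi$motif_a, pmi$motif_b)
  akey <- pair_key(avg$motif_a, avg$motif_b)
  av <- avg$avg_background_pmi[match(key, akey)]
  av[is.na(av)] <- 0
  out <- pmi
  out$avg_background_pmi <- av
  out$pmi_specific <- pmi$pmi - (1 + alpha) * av
  out
}

#' Split significant pairs into specific and common cooperations
#'
#' Significance (z-score) gates first; among significant pairs, those
#' with strictly positive `pmi_specific` are specific, the rest common.
#' Non-significant pairs are never classified.
#'
#' @param pmi_result a [zscore_transform()] result (columns `z`,
#'   `significant`).
#' @param pmi_specific data frame from [subtract_background()] covering all
#'   significant pairs.
#' @param alpha the alpha used, recorded on the result.
#' @return a `specificity_result` data frame: all scored pairs with
#'   columns `pmi`, `z`, `significant`, `avg_background_pmi`,
#'   `pmi_specific` and `class` (`"specific"`/`"common"`, NA when not
#'   significant).
#' @export
classify_pairs <- function(pmi_result, pmi_specific, alpha = 0.5) {
  key <- pair_key(pmi_result$motif_a, pmi_result$motif_b)
  skey <- pair_key(pmi_specific$motif_a, pmi_specific$motif_b)
  idx <- match(key, skey)
  if (anyNA(idx[pmi_result$significant]))
    stopf("pmi_specific does not cover every significant pair")
  out <- pmi_result
  out$avg_background_pmi <- pmi_specific$avg_background_pmi[idx]
  out$pmi_specific <- pmi_specific$pmi_specific[idx]
  out$class <- ifelse(out$significant,
                      ifelse(out$pmi_specific > 0, "specific", "common"),
                      NA_character_)
  attr(out, "alpha") <- alpha
  class(out) <- c("specificity_result", "data.frame")
  out
}

#' Count specific pairs over a grid of alpha values
#'
#' For each alpha the background subtraction and classification are
#' re-applied; with nonnegative background averages the count of
#' specific pairs is non-increasing in alpha, and at `alpha = -1` it
#' collapses to the number of significant pairs with positive PMI.
#'
#' @param pmi_result a [zscore_transform()] result.
#' @param avg data frame from [background_avg_pmi()].
#' @param alphas numeric vector within `[-1, 1]`.
#' @return data frame `alpha`, `n_specific`.
#' @export
alpha_sweep <- function(pmi_result, avg, alphas) {
  n <- vapply(alphas, function(a) {
    cl <- classify_pairs(pmi_result, subtract_background(pmi_result, avg, a), a)
    sum(cl$class == "specific", na.rm = TRUE)
  }, numeric(1))
  data.frame(alpha = alphas, n_specific = as.integer(n))
}

#' One-call specificity analysis of an observed promoter set
#'
#' Convenience wrapper running the observed PMI result through
#' background estimation, background subtraction and classification.
#'
#' @inheritParams background_avg_pmi
#' @param pmi_result the observed [zscore_transform()] result.
#' @return list with elements `result` (a [classify_pairs()] data
#'   frame) and `avg` (the background table).
#' @export
specificity_analysis <- function(seqs, library, thresholds, pmi_result,
                                 pairing = pairing_config(),
                                 config = specificity_config(),
                                 both_strands = TRUE,
                                 background = rep(0.25, 4)) {
  avg <- background_avg_pmi(seqs, library, thresholds, pairing, config,
                            both_strands, background)
  spec <- subtract_background(pmi_result, avg, config$alpha)
  list(result = classify_pairs(pmi_result, spec, config$alpha), avg = avg)
}
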