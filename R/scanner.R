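#' Log-odds matrix of a probability PWM
#' @param pwm a probability `PWM` (normalize first; a positive pseudocount
#'   guarantees finite scores).
#' @param background 4-vector of base probabilities.
#' @return 4 x L matrix of `log2(p / q)` scores.
#' @keywords internal
log_odds_matrix <- function(pwm, background = rep(0.25, 4)) {
  if (!pwm$is_probability) stopf("PWM '%s' must be normalized first", pwm$motif_id)
  log2(sweep(pwm$matrix, 1, background, "/"))
}

#' Log-odds score of one subsequence under a PWM
#'
#' `sum_i log2(p_i(base_i) / q(base_i))`; windows containing N score
#' `-Inf` (and are skipped by the scanner).
#'
#' @param pwm a probability `PWM` of length L.
#' @param background 4-vector of base probabilities.
#' @param subsequence string of length exactly L.
#' @return the log-odds score in bits.
#' @export
log_odds <- function(pwm, background = rep(0.25, 4), subsequence) {
  lom <- log_odds_matrix(pwm, background)
  codes <- encode_seq(subsequence)
  if (length(codes) != ncol(lom))
    stopf("subsequence length %d != motif length %d", length(codes), ncol(lom))
  if (anyNA(codes)) return(-Inf)
  sum(lom[cbind(codes, seq_along(codes))])
}

#' Calibrate a per-motif score cutoff by minimizing FPR + FNR
#'
#' Samples `n_positive` length-L words from the PWM's column
#' distributions (positives) and `n_negative` words from the background
#' model (negatives), scores all of them, and returns the cutoff --- a
#' midpoint between adjacent distinct observed scores --- that minimizes
#' the sum of false-negative and false-positive rates. Among tied
#' candidates the largest cutoff is chosen (fewest false positives). The
#' sampled score vectors are attached as the `scores` element so the
#' optimality of the cutoff can be audited.
#'
#' @param pwm a probability `PWM`.
#' @param background_model a `MarkovModel` for negatives.
#' @param n_positive,n_negative sample sizes (>= 100).
#' @param seed optional RNG seed for a deterministic result.
#' @param background base composition used for the log-odds scores.
#' @return a `ScanThreshold`: list with `motif_id`, `cutoff`,
#'   `fpr_at_cutoff`, `fnr_at_cutoff` and `scores`.
#' @export
calibrate_threshold <- function(pwm, background_model = uniform_markov(),
                                n_positive = 1000L, n_negative = 1000L,
                                seed = NULL, background = rep(0.25, 4)) {
  if (n_positive < 100 || n_negative < 100)
    stopf("need at least 100 positive and negative samples")
  if (!is.null(seed)) set.seed(seed)
  lom <- log_odds_matrix(pwm, background)
  L <- ncol(lom)
  # positives: one draw per column from the PWM's own distribution
  pos_words <- vapply(seq_len(L), function(j)
    sample.int(4L, n_positive, replace = TRUE, prob = pwm$matrix[, j]),
    integer(n_positive))
  if (is.null(dim(pos_words))) pos_words <- matrix(pos_words, nrow = n_positive)
  neg_words <- sample_markov_words(background_model, n_negative, L)
  score_words <- function(w) {
    s <- numeric(nrow(w))
    for (j in seq_len(ncol(w))) s <- s + lom[w[, j], j]
    s
  }
  pos <- score_words(pos_words)
  neg <- score_words(neg_words)
  so <- sort(unique(c(pos, neg)))
  cands <- c(so[1] - 1, if (length(so) > 1) (so[-1] + so[-length(so)]) / 2,
             so[length(so)] + 1)
  pos_sorted <- sort(pos)
  neg_sorted <- sort(neg)
  fnr <- findInterval(cands, pos_sorted, left.open = TRUE) / length(pos)  # pos < c
  fpr <- 1 - findInterval(cands, neg_sorted, left.open = TRUE) / length(neg)  # neg >= c
  tot <- fnr + fpr
  best <- which(tot == min(tot))
  pick <- best[length(best)]
  structure(list(motif_id = pwm$motif_id, cutoff = cands[pick],
                 fpr_at_cutoff = fpr[pick], fnr_at_cutoff = fnr[pick],
                 scores = list(positive = pos, negative = neg)),
            class = "ScanThreshold")
}

#' Calibrate cutoffs for every motif in a library
#'
#' @inheritParams calibrate_threshold
#' @param library a probability `MotifLibrary`.
#' @param seed root seed; motif k uses `seed + k`.
#' @return named list of `ScanThreshold`s keyed by motif id.
#' @export
calibrate_thresholds <- function(library, background_model = uniform_markov(),
                                 n_positive = 1000L, n_negative = 1000L,
                                 seed = 1L, background = rep(0.25, 4)) {
  ths <- lapply(seq_along(library$pwms), function(k)
    calibrate_threshold(library$pwms[[k]], background_model,
                        n_positive, n_negative,
                        seed = child_seed(seed, k), background = background))
  names(ths) <- names(library$pwms)
  ths
}

#' Predict binding sites by log-odds scanning
#'
#' Every window on every sequence (and, by default, its reverse
#' complement) scoring at least the motif's calibrated cutoff yields a
#' binding site. Minus-strand hits are reported in plus-strand
#' coordinates; coordinates are 0-based half-open with
#' `end - start = L`. Windows containing N are skipped; sequences
#' shorter than a motif yield nothing for that motif.
#'
#' @param library a probability `MotifLibrary`.
#' @param seqs named character vector of promoter sequences.
#' @param thresholds named list of `ScanThreshold`s covering every motif.
#' @param both_strands scan the reverse complement too (default TRUE).
#' @param background base composition for the log-odds scores.
#' @return data frame of binding sites with columns `sequence_id`,
#'   `motif_id`, `start`, `end`, `strand`, `score`, sorted by
#'   (sequence_id, start).
#' @export
scan_sites <- function(library, seqs, thresholds, both_strands = TRUE,
                       background = rep(0.25, 4)) {
  empty <- data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(library$pwms)) return(empty)
  seqs <- check_sequences(seqs)
  ids <- names(library$pwms)
  missing <- setdiff(ids, names(thresholds))
  if (length(missing)) stopf("no threshold for motif '%s'", missing[1])
  loms <- lapply(library$pwms, log_odds_matrix, background = background)
  loms_rev <- lapply(loms, rc_pwm_matrix)
  cutoffs <- vapply(ids, function(i) thresholds[[i]]$cutoff, numeric(1))
  enc <- lapply(seqs, encode_seq)
  hits <- scan_core(enc, unname(loms), unname(loms_rev), unname(cutoffs),
                    both_strands)
  if (!nrow(hits)) return(empty)
  lens <- vapply(library$pwms, function(p) ncol(p$matrix), integer(1))
  out <- data.frame(
    sequence_id = names(seqs)[hits$seq_idx],
    motif_id = ids[hits$motif_idx],
    start = hits$start,
    end = hits$start + lens[hits$motif_idx],
    strand = c("+", "-")[hits$strand_idx],
    score = hits$score,
    stringsAsFactors = FALSE)
  out <- out[order(out$sequence_id, out$start, out$motif_id, out$strand), ]
  rownames(out) <- NULL
  out
}
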