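#' Fit a Markov background model to a sequence set
#'
#' Counts (order+1)-mers over all sequences (positions containing N are
#' skipped) and converts them to transition probabilities with an add-one
#' pseudocount, plus a marginal initial base distribution. Used as the
#' negative model for cutoff calibration and as the sampling model for
#' synthetic backgrounds.
#'
#' @param seqs named character vector of sequences.
#' @param order Markov order (0 = i.i.d. composition).
#' @return a `MarkovModel`: list with `order`, `trans` (4^order x 4 row-
#'   stochastic matrix) and `initial` (length-4 base distribution).
#' @export
fit_markov <- function(seqs, order = 2L) {
  order <- as.integer(order)
  if (order < 0) stopf("order must be >= 0")
  n_ctx <- 4L^order
  counts <- matrix(0, n_ctx, 4)
  base_counts <- rep(0, 4)
  for (s in seqs) {
    codes <- encode_seq(s)
    ok <- !is.na(codes)
    base_counts <- base_counts + tabulate(codes[ok], 4)
    if (length(codes) <= order) next
    # context index for positions order+1 .. len (1-based, base-4)
    ctx <- rep(0L, length(codes))
    valid <- ok
    if (order > 0) {
      ctxv <- rep(0L, length(codes) - order)
      validv <- rep(TRUE, length(codes) - order)
      for (k in seq_len(order)) {
        prev <- codes[seq_len(length(codes) - order) + (k - 1L)]
        validv <- validv & !is.na(prev)
        ctxv <- ctxv * 4L + (ifelse(is.na(prev), 1L, prev) - 1L)
      }
      nxt <- codes[(order + 1L):length(codes)]
      use <- validv & !is.na(nxt)
      if (any(use)) {
        idx <- ctxv[use] * 4L + (nxt[use] - 1L) + 1L
        tab <- tabulate(idx, n_ctx * 4L)
        counts <- counts + matrix(tab, n_ctx, 4, byrow = TRUE)
      }
    } else {
      counts[1, ] <- counts[1, ] + tabulate(codes[ok], 4)
    }
  }
  trans <- (counts + 1) / rowSums(counts + 1)
  initial <- (base_counts + 1) / sum(base_counts + 1)
  structure(list(order = order, trans = trans, initial = initial),
            class = "MarkovModel")
}

#' A uniform background model
#' @param order Markov order.
#' @return a `MarkovModel` with all transitions equal to 1/4.
#' @export
uniform_markov <- function(order = 0L) {
  structure(list(order = as.integer(order),
                 trans = matrix(0.25, 4L^order, 4),
                 initial = rep(0.25, 4)),
            class = "MarkovModel")
}

#' Construct a Markov model from explicit probabilities
#' @param trans 4^order x 4 row-stochastic matrix (or a 4-vector for
#'   order 0).
#' @param order Markov order.
#' @param initial initial base distribution (defaults to uniform).
#' @return a `MarkovModel`.
#' @export
markov_model <- function(trans, order, initial = rep(0.25, 4)) {
  if (is.vector(trans)) trans <- matrix(trans, nrow = 4L^order, ncol = 4,
                                        byrow = TRUE)
  if (nrow(trans) != 4L^order || ncol(trans) != 4)
    stopf("trans must be 4^order x 4")
  if (any(abs(rowSums(trans) - 1) > 1e-8)) stopf("trans rows must sum to 1")
  structure(list(order = as.integer(order), trans = trans, initial = initial),
            class = "MarkovModel")
}

#' Sample fixed-length words from a Markov model
#'
#' Vectorized across words: one multinomial draw per position given each
#' word's current context. Uses the session RNG.
#'
#' @param model a `MarkovModel`.
#' @param n number of words.
#' @param len word length.
#' @return n x len integer matrix of base codes 1..4.
#' @export
sample_markov_words <- function(model, n, len) {
  k <- model$order
  out <- matrix(0L, n, len)
  cum <- t(apply(model$trans, 1, cumsum))
  if (is.vector(cum)) cum <- matrix(cum, nrow = nrow(model$trans), byrow = FALSE)
  cum_init <- cumsum(model$initial)
  ctx <- rep(0L, n)
  for (p in seq_len(len)) {
    if (p <= k) {
      u <- runif(n)
      b <- findInterval(u, cum_init) + 1L
    } else {
      u <- runif(n)
      pc <- cum[ctx + 1L, , drop = FALSE]
      b <- rowSums(u > pc) + 1L
    }
    b[b > 4L] <- 4L
    out[, p] <- b
    if (k > 0) ctx <- (ctx * 4L + (b - 1L)) %% 4L^k
  }
  out
}
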