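# Independent brute-force oracles. These deliberately share no code with
# the package implementation paths they check.

# O(n^2) all-pairs enumeration over unsorted sites; returns the counted
# unordered motif pairs as a two-column character matrix.
oracle_pairs <- function(sites, d_min = 5, d_max = 20,
                         allow_overlap = FALSE, allow_homodimer = TRUE) {
  out <- list()
  n <- nrow(sites)
  if (n < 2) return(matrix(character(), ncol = 2))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sites$sequence_id[i] != sites$sequence_id[j]) next
      gap <- max(sites$start[i] - sites$end[j], sites$start[j] - sites$end[i])
      ok <- (gap >= d_min && gap <= d_max) || (allow_overlap && gap < 0)
      if (!ok) next
      a <- sites$motif_id[i]; b <- sites$motif_id[j]
      if (a == b && !allow_homodimer) next
      out[[length(out) + 1]] <- c(min(a, b), max(a, b))
    }
  }
  if (!length(out)) return(matrix(character(), ncol = 2))
  do.call(rbind, out)
}

# direct evaluation of the slot-frequency PMI formula from a raw list of
# counted pairs
oracle_pmi <- function(pairs_mat) {
  N <- nrow(pairs_mat)
  key <- paste(pairs_mat[, 1], pairs_mat[, 2], sep = "\t")
  n_ab <- table(key)
  slots <- table(c(pairs_mat[, 1], pairs_mat[, 2]))  # homodimers count twice
  res <- lapply(names(n_ab), function(k) {
    ab <- strsplit(k, "\t", fixed = TRUE)[[1]]
    f_ab <- as.numeric(n_ab[[k]]) / N
    f_a <- as.numeric(slots[[ab[1]]]) / (2 * N)
    f_b <- as.numeric(slots[[ab[2]]]) / (2 * N)
    cc <- if (ab[1] == ab[2]) 1 else 2
    data.frame(motif_a = ab[1], motif_b = ab[2],
               count = as.integer(n_ab[[k]]),
               pmi = log(f_ab / (cc * f_a * f_b)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, res)
  df[order(df$motif_a, df$motif_b), ]
}

# naive per-position / per-strand rescanning with string reverse
# complement and explicit probability lookups
oracle_scan <- function(library, seqs, thresholds, both_strands = TRUE,
                        background = rep(0.25, 4)) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_word <- function(pwm, word) {
    ch <- strsplit(word, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(-Inf)
    idx <- match(ch, c("A", "C", "G", "T"))
    sum(log2(pwm$matrix[cbind(idx, seq_along(idx))] / background[idx]))
  }
  rows <- list()
  for (sid in names(seqs)) {
    s <- seqs[[sid]]
    for (mid in names(library$pwms)) {
      pwm <- library$pwms[[mid]]
      L <- ncol(pwm$matrix)
      if (nchar(s) < L) next
      cut <- thresholds[[mid]]$cutoff
      for (p in 1:(nchar(s) - L + 1)) {
        w <- substr(s, p, p + L - 1)
        sc <- score_word(pwm, w)
        if (sc >= cut)
          rows[[length(rows) + 1]] <- data.frame(
            sequence_id = sid, motif_id = mid, start = p - 1L,
            end = p - 1L + L, strand = "+", score = sc,
            stringsAsFactors = FALSE)
        if (both_strands) {
          sc2 <- score_word(pwm, revcomp(w))
          if (sc2 >= cut)
            rows[[length(rows) + 1]] <- data.frame(
              sequence_id = sid, motif_id = mid, start = p - 1L,
              end = p - 1L + L, strand = "-", score = sc2,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(), motif_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  df <- do.call(rbind, rows)
  df <- df[order(df$sequence_id, df$start, df$motif_id, df$strand), ]
  rownames(df) <- NULL
  df
}

# 16-entry dinucleotide count vector via substring extraction
dinuc_counts <- function(s) {
  n <- nchar(s)
  if (n < 2) return(table(factor(character(), levels = dinuc_levels())))
  d <- substring(s, 1:(n - 1), 2:n)
  table(factor(d, levels = dinuc_levels()))
}
dinuc_levels <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(b, b, paste0))
}

# exhaustive check of the two-thirds rule on a gene x tissue matrix
brute_tsg <- function(values, fraction = 2 / 3) {
  hits <- list()
  for (t in colnames(values)) hits[[t]] <- character()
  for (g in rownames(values)) {
    tot <- sum(values[g, ])
    if (tot <= 0) next
    for (t in colnames(values)) {
      if (values[g, t] >= fraction * tot)
        hits[[t]] <- c(hits[[t]], g)
    }
  }
  hits
}

# random probability PWM (independent of the package generator)
random_prob_pwm <- function(id, L = sample(3:8, 1), conc = 0.5) {
  g <- matrix(rgamma(4 * L, shape = conc) + 1e-9, 4, L)
  new_pwm(sweep(g, 2, colSums(g), "/"), id, is_probability = TRUE)
}

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# random binding-site configuration on a handful of sequences
random_sites <- function(n_sites, n_seqs = 5, n_motifs = 6, seq_len = 400) {
  motifs <- sprintf("M%02d", seq_len(n_motifs))
  start <- sample(0:(seq_len - 15), n_sites, replace = TRUE)
  data.frame(
    sequence_id = sample(sprintf("S%02d", seq_len(n_seqs)), n_sites,
                         replace = TRUE),
    motif_id = sample(motifs, n_sites, replace = TRUE),
    start = start,
    end = start + sample(4:12, n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    score = runif(n_sites, 0, 10),
    stringsAsFactors = FALSE)
}

pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b))
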