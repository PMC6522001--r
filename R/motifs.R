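#' Normalize a PWM to column probabilities
#'
#' Each column c becomes `(n_b + pseudocount) / (N_c + 4 * pseudocount)`.
#' Works for count and probability matrices alike; a small pseudocount
#' (default 0.01 per cell) avoids zero probabilities and hence infinite
#' log-odds without distorting well-populated matrices.
#'
#' @param pwm a `PWM`.
#' @param pseudocount nonnegative value added per cell.
#' @return a probability `PWM`.
#' @export
normalize_pwm <- function(pwm, pseudocount = 0.01) {
  if (pseudocount < 0) stopf("pseudocount must be nonnegative")
  m <- pwm$matrix
  cs <- colSums(m) + 4 * pseudocount
  if (any(cs == 0))
    stopf("PWM '%s': all-zero column with pseudocount 0", pwm$motif_id)
  m <- sweep(m + pseudocount, 2, cs, "/")
  new_pwm(m, pwm$motif_id, pwm$tf_gene_ids, is_probability = TRUE)
}

#' Normalize every PWM in a library
#' @inheritParams normalize_pwm
#' @param library a `MotifLibrary`.
#' @return the library with all PWMs normalized.
#' @export
normalize_library <- function(library, pseudocount = 0.01) {
  library$pwms <- lapply(library$pwms, normalize_pwm, pseudocount = pseudocount)
  library
}

#' Information content of a probability PWM
#'
#' Kullback-Leibler divergence from the background, summed over columns:
#' `sum_cols sum_b p * log2(p / q_b)` with `0 * log 0 = 0`. In bits;
#' bounded by `[0, 2L]` for a uniform background.
#'
#' @param pwm a probability `PWM`.
#' @param background 4-vector of base probabilities summing to 1.
#' @return information content in bits.
#' @export
information_content <- function(pwm, background = rep(0.25, 4)) {
  if (!pwm$is_probability) stopf("PWM '%s' must be normalized first", pwm$motif_id)
  if (abs(sum(background) - 1) > 1e-6) stopf("background must sum to 1")
  m <- pwm$matrix
  zero_bg <- background == 0
  if (any(zero_bg) && any(m[zero_bg, ] > 0))
    stopf("background has zero probability where the PWM has mass")
  term <- m * log2(sweep(m, 1, background, "/"))
  term[m == 0] <- 0
  sum(term)
}

rc_pwm_matrix <- function(m) {
  r <- m[c(4, 3, 2, 1), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(r) <- DNA_BASES
  r
}

#' Reverse complement of a PWM
#' @param pwm a `PWM`.
#' @return the reverse-complemented `PWM`.
#' @export
reverse_complement_pwm <- function(pwm) {
  new_pwm(rc_pwm_matrix(pwm$matrix), pwm$motif_id, pwm$tf_gene_ids,
          pwm$is_probability)
}

#' Best-overlap Pearson correlation of two PWMs
#'
#' For every ungapped offset with at least `min(3, min(L_a, L_b))`
#' overlapping columns, the overlapping columns of both matrices are
#' flattened into vectors and their Pearson correlation computed; the
#' maximum over all offsets and over the reverse complement of `b` is
#' returned. Offsets whose overlap window has zero variance in either
#' matrix are skipped; if every offset is skipped, 0 is returned with a
#' warning. Symmetric in its arguments.
#'
#' @param a,b probability `PWM`s.
#' @param min_overlap minimum number of overlapping columns.
#' @return correlation in `[-1, 1]`.
#' @export
pwm_correlation <- function(a, b, min_overlap = 3L) {
  if (!a$is_probability || !b$is_probability)
    stopf("pwm_correlation requires probability PWMs")
  ma <- a$matrix
  best <- -Inf
  for (mb in list(b$matrix, rc_pwm_matrix(b$matrix))) {
    la <- ncol(ma); lb <- ncol(mb)
    mo <- min(min_overlap, la, lb)
    for (s in seq(mo - lb, la - mo)) {
      jj <- max(1L, 1L - s):min(lb, la - s)
      va <- as.vector(ma[, jj + s, drop = FALSE])
      vb <- as.vector(mb[, jj, drop = FALSE])
      if (sd(va) == 0 || sd(vb) == 0) next
      best <- max(best, cor(va, vb))
    }
  }
  if (!is.finite(best)) {
    warnf("all overlap windows degenerate for '%s' vs '%s'; correlation 0",
          a$motif_id, b$motif_id)
    return(0)
  }
  best
}

#' Pairwise PWM correlation matrix of a library
#' @param library a probability `MotifLibrary`.
#' @param min_overlap minimum overlapping columns per offset.
#' @return symmetric matrix of best-overlap correlations (unit diagonal).
#' @export
pwm_correlation_matrix <- function(library, min_overlap = 3L) {
  n <- length(library$pwms)
  ids <- names(library$pwms)
  C <- diag(1, n)
  dimnames(C) <- list(ids, ids)
  if (n < 2) return(C)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      C[i, j] <- C[j, i] <- pwm_correlation(library$pwms[[i]],
                                            library$pwms[[j]], min_overlap)
    }
  }
  C
}

#' Remove motif redundancy by correlation clustering
#'
#' Average-linkage hierarchical clustering on distance `1 - correlation`,
#' with the tree cut at height `1 - correlation_cutoff`; from each cluster
#' the PWM with the highest information content is kept as representative
#' (ties broken by lexicographic motif id).
#'
#' @param library a probability `MotifLibrary`.
#' @param correlation_cutoff correlation above which motifs are considered
#'   redundant, in (0, 1); default 0.8.
#' @param background background for the information-content ranking.
#' @param min_overlap minimum overlapping columns per correlation offset;
#'   raise it for libraries of short, sharp motifs, where 3-column
#'   overlaps correlate highly by chance.
#' @return a `MotifLibrary` of cluster representatives.
#' @export
cluster_and_select <- function(library, correlation_cutoff = 0.8,
                               background = rep(0.25, 4), min_overlap = 3L) {
  if (!length(library$pwms)) stopf("empty motif library")
  if (length(library$pwms) == 1) return(library)
  C <- pwm_correlation_matrix(library, min_overlap = min_overlap)
  D <- as.dist(pmax(1 - C, 0))
  cl <- cutree(hclust(D, method = "average"), h = 1 - correlation_cutoff)
  reps <- vapply(split(names(cl), cl), function(ids) {
    ic <- vapply(ids, function(i)
      information_content(library$pwms[[i]], background), numeric(1))
    ids[order(-ic, ids)][1]
  }, character(1))
  motif_library(library$pwms[sort(unname(reps))], tissue = library$tissue,
                provenance = library$provenance)
}

#' Keep motifs whose TF gene is expressed in a tissue
#'
#' A PWM is retained when at least one of its associated TF genes has
#' expression `>= tau` in the given tissue (the boundary value itself is
#' kept: only values smaller than tau are discarded). Genes that cannot
#' be resolved against the expression matrix are dropped with a warning;
#' PWMs with no mapped gene are dropped with a warning.
#'
#' @param library a `MotifLibrary` with `tf_gene_ids` attached.
#' @param expr a `TissueExpression`.
#' @param tissue tissue column to use.
#' @param tau expression threshold.
#' @return the filtered `MotifLibrary` with the tissue label set.
#' @export
filter_by_tf_expression <- function(library, expr, tissue, tau = 1.46) {
  if (!tissue %in% colnames(expr$values))
    stopf("tissue '%s' absent from the expression data", tissue)
  keep <- vapply(library$pwms, function(p) {
    genes <- p$tf_gene_ids
    if (!length(genes)) {
      warnf("motif '%s' has no mapped TF gene; dropped", p$motif_id)
      return(FALSE)
    }
    mapped <- intersect(genes, rownames(expr$values))
    if (length(mapped) < length(genes))
      warnf("motif '%s': %d unresolvable TF gene id(s) ignored",
            p$motif_id, length(genes) - length(mapped))
    if (!length(mapped)) return(FALSE)
    any(expr$values[mapped, tissue] >= tau)
  }, logical(1))
  motif_library(library$pwms[keep], tissue = tissue,
                provenance = library$provenance)
}
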