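#' Generate an expression matrix with planted tissue-specific genes
#'
#' Background genes draw a log-normal mean expression (a mixture of an
#' unexpressed and an expressed mode, producing the bimodal density that
#' threshold estimation assumes) that is exchangeable across tissues;
#' each planted TSG has its tissue's mean multiplied by
#' `specific_fold`. Every sample value carries multiplicative log-normal
#' noise with coefficient of variation `noise_cv` (mean 1), and each
#' tissue gets `n_replicates` samples. With `noise_cv = 0` and
#' `specific_fold = 2 * (n_tissues - 1)` a planted gene holds exactly
#' two thirds of its row mass in its tissue, so the feasibility bound
#' `specific_fold >= 2 * (n_tissues - 1)` is enforced.
#'
#' The default three tissues mirror a small multi-organ expression study
#' (liver, lung, kidney) with duplicate samples.
#'
#' @param n_genes total number of genes.
#' @param tissues character vector of tissue labels (>= 2).
#' @param n_tsg_per_tissue planted TSGs per tissue.
#' @param specific_fold fold elevation of a planted gene in its tissue.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed; the generator is a pure function of it.
#' @param n_replicates samples per tissue.
#' @param p_expressed probability a background gene is in the expressed
#'   mode.
#' @param mode_low,mode_high geometric centers of the unexpressed and
#'   expressed modes (expression units).
#' @param sdlog10 log10-scale spread of each mode.
#' @param unit expression unit label.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (list with `planted_tsg`: tissue -> gene ids, and `seed`).
#' @export
gen_expression <- function(n_genes = 2000L,
                           tissues = c("liver", "lung", "kidney"),
                           n_tsg_per_tissue = 50L, specific_fold = 8,
                           noise_cv = 0.2, seed = 1L, n_replicates = 2L,
                           p_expressed = 0.6, mode_low = 0.1,
                           mode_high = 10, sdlog10 = 0.5,
                           unit = "TPM") {
  n_t <- length(tissues)
  if (n_t < 2) stopf("need at least 2 tissues")
  if (n_tsg_per_tissue * n_t > n_genes)
    stopf("cannot plant %d TSGs in %d genes", n_tsg_per_tissue * n_t, n_genes)
  if (specific_fold < 2 * (n_t - 1))
    stopf(paste0("specific_fold %g < 2 * (n_tissues - 1) = %g: a planted ",
                 "tissue would carry less than 2/3 of the expected row mass"),
          specific_fold, 2 * (n_t - 1))
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  expressed <- runif(n_genes) < p_expressed
  center <- ifelse(expressed, log10(mode_high), log10(mode_low))
  gene_mean <- 10^rnorm(n_genes, center, sdlog10)

  planted <- lapply(seq_len(n_t), function(i)
    genes[((i - 1) * n_tsg_per_tissue + 1):(i * n_tsg_per_tissue)])
  names(planted) <- tissues
  if (n_tsg_per_tissue == 0) planted <- lapply(planted, function(x) character())
  planted_idx <- rep(NA_integer_, n_genes)
  for (i in seq_len(n_t))
    planted_idx[match(planted[[i]], genes)] <- i
  # planted genes are always drawn from the expressed mode
  is_planted <- !is.na(planted_idx)
  gene_mean[is_planted] <- 10^rnorm(sum(is_planted), log10(mode_high), sdlog10)

  samples <- as.vector(t(outer(tissues, seq_len(n_replicates),
                               function(t, r) paste0(t, "_r", r))))
  sample_tissue <- rep(tissues, each = n_replicates)
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  vals <- matrix(0, n_genes, length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- gene_mean
    boost <- !is.na(planted_idx) & tissues[planted_idx] == sample_tissue[j]
    mu[boost] <- mu[boost] * specific_fold
    noise <- if (sdlog > 0)
      exp(rnorm(n_genes, -sdlog^2 / 2, sdlog)) else rep(1, n_genes)
    vals[, j] <- mu * noise
  }
  em <- expression_matrix(vals, structure(sample_tissue, names = samples),
                          unit = unit)
  list(matrix = em,
       truth = list(planted_tsg = planted, specific_fold = specific_fold,
                    noise_cv = noise_cv, seed = seed))
}

sample_pwm_word <- function(pwm) {
  vapply(seq_len(ncol(pwm$matrix)), function(j)
    sample.int(4L, 1L, prob = pwm$matrix[, j]), integer(1))
}

#' Generate promoter sequences with planted motif pairs
#'
#' Background sequence is sampled from a Markov chain of the given
#' order whose transition probabilities are drawn once (per seed) from a
#' Dirichlet around `base_probs` (order 0 with default concentration
#' uses `base_probs` exactly). In `ceiling(fraction * n_seqs)` sequences
#' one sampled word from `pair_spec$pwm_a` and one from `pair_spec$pwm_b`
#' are written with a gap drawn uniformly from `pair_spec$gap_range`
#' (upstream/downstream order randomized); decoy motif words are written
#' at independent uniform positions (`rpois(sites_per_seq)` words per
#' sequence). Planted words never overlap each other; all planted
#' coordinates are recorded in the truth manifest.
#'
#' @param n_seqs number of promoters.
#' @param length promoter length in bp; the default 600 mirrors a
#'   -500..+100 window around the transcription start site.
#' @param markov_order background Markov order.
#' @param pair_spec `list(pwm_a, pwm_b, fraction, gap_range)` or NULL
#'   for no coupled pair.
#' @param decoys list of `list(pwm, sites_per_seq)` entries.
#' @param seed RNG seed; the generator is a pure function of it.
#' @param base_probs target base composition of the background.
#' @param dirichlet_conc concentration of the per-context Dirichlet for
#'   `markov_order >= 1` (`Inf` pins every context to `base_probs`).
#' @return list with `seqs` (named character vector, ids `P0001`...)
#'   and `truth` (list with `placements` data frame of 0-based
#'   half-open planted coordinates, `planted_pairs`, `decoy_motifs`,
#'   `gaps`, `seed`).
#' @export
gen_promoters <- function(n_seqs = 300L, length = 600L, markov_order = 2L,
                          pair_spec = NULL, decoys = list(), seed = 1L,
                          base_probs = rep(0.25, 4), dirichlet_conc = 5) {
  set.seed(seed)
  n_ctx <- 4L^markov_order
  if (markov_order == 0L || is.infinite(dirichlet_conc)) {
    trans <- matrix(base_probs, n_ctx, 4, byrow = TRUE)
  } else {
    a <- matrix(rgamma(n_ctx * 4, shape = dirichlet_conc * 4 * base_probs[col(matrix(0, n_ctx, 4))]),
                n_ctx, 4)
    trans <- a / rowSums(a)
  }
  model <- markov_model(trans, markov_order, initial = base_probs)
  mat <- sample_markov_words(model, n_seqs, length)

  ids <- sprintf("P%04d", seq_len(n_seqs))
  placements <- list()
  gaps <- integer(0)
  planted_in <- character(0)
  if (!is.null(pair_spec)) {
    if (pair_spec$fraction < 0 || pair_spec$fraction > 1)
      stopf("pair fraction must lie in [0, 1]")
  }
  n_planted <- if (is.null(pair_spec)) 0L else ceiling(pair_spec$fraction * n_seqs)
  which_planted <- if (n_planted > 0) sort(sample.int(n_seqs, n_planted)) else integer(0)

  place_word <- function(occupied, L_w, lo, hi) {
    # returns a free 0-based start in [lo, hi], or NA after 1000 tries
    for (try in seq_len(1000L)) {
      st <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      iv <- c(st, st + L_w)
      clash <- any(vapply(occupied, function(o) iv[1] < o[2] && o[1] < iv[2],
                          logical(1)))
      if (!clash) return(st)
    }
    NA_integer_
  }

  for (s in seq_len(n_seqs)) {
    occupied <- list()
    if (s %in% which_planted) {
      first_is_a <- runif(1) < 0.5
      p1 <- if (first_is_a) pair_spec$pwm_a else pair_spec$pwm_b
      p2 <- if (first_is_a) pair_spec$pwm_b else pair_spec$pwm_a
      gr <- pair_spec$gap_range
      gap <- gr[1] + sample.int(gr[2] - gr[1] + 1L, 1L) - 1L
      l1 <- ncol(p1$matrix); l2 <- ncol(p2$matrix)
      block <- l1 + gap + l2
      if (block > length)
        stopf("planted pair block (%d bp) exceeds sequence length %d",
              block, length)
      st <- sample.int(length - block + 1L, 1L) - 1L
      w1 <- sample_pwm_word(p1); w2 <- sample_pwm_word(p2)
      mat[s, (st + 1):(st + l1)] <- w1
      st2 <- st + l1 + gap
      mat[s, (st2 + 1):(st2 + l2)] <- w2
      occupied <- list(c(st, st + l1), c(st2, st2 + l2))
      placements[[base::length(placements) + 1]] <- data.frame(
        sequence_id = ids[s], motif_id = c(p1$motif_id, p2$motif_id),
        start = c(st, st2), end = c(st + l1, st2 + l2),
        role = "planted_pair", stringsAsFactors = FALSE)
      gaps <- c(gaps, gap)
      planted_in <- c(planted_in, ids[s])
    }
    for (d in decoys) {
      L_w <- ncol(d$pwm$matrix)
      n_w <- rpois(1, d$sites_per_seq)
      for (w in seq_len(n_w)) {
        st <- place_word(occupied, L_w, 0L, length - L_w)
        if (is.na(st))
          stopf("could not place a decoy word after 1000 attempts; use longer sequences")
        mat[s, (st + 1):(st + L_w)] <- sample_pwm_word(d$pwm)
        occupied <- c(occupied, list(c(st, st + L_w)))
        placements[[base::length(placements) + 1]] <- data.frame(
          sequence_id = ids[s], motif_id = d$pwm$motif_id,
          start = st, end = st + L_w, role = "decoy",
          stringsAsFactors = FALSE)
      }
    }
  }
  seqs <- apply(mat, 1, decode_seq)
  names(seqs) <- ids
  placements <- if (base::length(placements))
    do.call(rbind, placements)
  else
    data.frame(sequence_id = character(), motif_id = character(),
               start = integer(), end = integer(), role = character())
  truth <- list(
    planted_pairs = if (is.null(pair_spec)) list() else
      list(list(motif_a = pair_spec$pwm_a$motif_id,
                motif_b = pair_spec$pwm_b$motif_id,
                fraction_of_sequences = pair_spec$fraction,
                gap_range = pair_spec$gap_range,
                sequences = planted_in)),
    decoy_motifs = vapply(decoys, function(d) d$pwm$motif_id, character(1)),
    placements = placements, gaps = gaps, seed = seed)
  list(seqs = seqs, truth = truth)
}

#' Generate a random motif library with controlled information content
#'
#' Columns are sampled from symmetric Dirichlet distributions with a
#' concentration re-drawn per attempt; a candidate PWM is accepted when
#' its total information content (uniform background) falls inside
#' `ic_range`.
#'
#' @param n_motifs number of motifs.
#' @param length_range inclusive range of motif lengths.
#' @param ic_range inclusive information-content window in bits; must be
#'   attainable, i.e. inside `(0, 2 * max(length_range)]`.
#' @param seed RNG seed; the generator is a pure function of it.
#' @param max_attempts sampling attempts per motif before giving up.
#' @param prefix motif id prefix (ids are `M001`, `M002`, ...).
#' @return a probability `MotifLibrary`.
#' @export
gen_motif_library <- function(n_motifs = 10L, length_range = c(8L, 10L),
                              ic_range = c(9, 13), seed = 1L,
                              max_attempts = 5000L, prefix = "M") {
  if (ic_range[1] <= 0 || ic_range[1] > ic_range[2])
    stopf("ic_range must be an increasing window above 0")
  if (ic_range[1] > 2 * max(length_range))
    stopf("ic_range exceeds the maximum of 2 bits per column")
  set.seed(seed)
  pwms <- vector("list", n_motifs)
  for (i in seq_len(n_motifs)) {
    accepted <- FALSE
    for (att in seq_len(max_attempts)) {
      L <- sample(seq(length_range[1], length_range[2]), 1)
      conc <- 10^runif(1, -1.5, 0.5)
      g <- matrix(rgamma(4 * L, shape = conc), 4, L)
      # guard against all-zero columns at tiny concentrations
      g <- g + 1e-12
      m <- sweep(g, 2, colSums(g), "/")
      pwm <- new_pwm(m, sprintf("%s%03d", prefix, i), is_probability = TRUE)
      ic <- information_content(pwm)
      if (ic >= ic_range[1] && ic <= ic_range[2]) {
        pwms[[i]] <- pwm
        accepted <- TRUE
        break
      }
    }
    if (!accepted)
      stopf("could not reach ic_range [%g, %g] in %d attempts",
            ic_range[1], ic_range[2], max_attempts)
  }
  motif_library(pwms, provenance = sprintf("synthetic (seed %d)", seed))
}

#' Coupled-pair study preset
#'
#' The standard synthetic condition for planted-pair recovery: a motif
#' library of two planted motifs plus decoys, and a promoter set with
#' the pair planted at coupled gaps over a Markov background. With
#' `with_uncoupled_pair` two additional high-abundance motifs are
#' planted independently of each other (a positionally uncoupled
#' "abundance pair" that background subtraction should classify as
#' common or leave non-significant).
#'
#' @param seed root seed (library uses `seed`, promoters `seed + 1`).
#' @param n_seqs,length promoter set dimensions.
#' @param fraction fraction of sequences carrying the coupled pair.
#' @param gap_range inclusive gap range of the coupled pair, bp.
#' @param n_decoys number of decoy motifs (1 expected site each per
#'   sequence).
#' @param markov_order background Markov order.
#' @param with_uncoupled_pair add the independent high-abundance pair.
#' @param uncoupled_rate expected planted sites per sequence for each
#'   uncoupled motif.
#' @return list with `seqs`, `library`, `truth` and identifiers
#'   `pair` (coupled) and `uncoupled` (or NULL).
#' @export
preset_coupled_pair <- function(seed = 1L, n_seqs = 300L, length = 600L,
                                fraction = 0.5, gap_range = c(5L, 20L),
                                n_decoys = 8L, markov_order = 2L,
                                with_uncoupled_pair = FALSE,
                                uncoupled_rate = 2) {
  n_extra <- if (with_uncoupled_pair) 2L else 0L
  lib <- gen_motif_library(n_motifs = 2L + n_decoys + n_extra,
                           length_range = c(8L, 10L), ic_range = c(14, 16),
                           seed = seed)
  ids <- names(lib$pwms)
  pair_ids <- ids[1:2]
  decoy_ids <- ids[3:(2 + n_decoys)]
  uncoupled_ids <- if (n_extra) ids[(3 + n_decoys):(2 + n_decoys + n_extra)] else NULL
  decoys <- lapply(decoy_ids, function(i) list(pwm = lib$pwms[[i]], sites_per_seq = 1))
  if (n_extra)
    decoys <- c(decoys, lapply(uncoupled_ids, function(i)
      list(pwm = lib$pwms[[i]], sites_per_seq = uncoupled_rate)))
  gp <- gen_promoters(n_seqs = n_seqs, length = length,
                      markov_order = markov_order,
                      pair_spec = list(pwm_a = lib$pwms[[pair_ids[1]]],
                                       pwm_b = lib$pwms[[pair_ids[2]]],
                                       fraction = fraction,
                                       gap_range = gap_range),
                      decoys = decoys, seed = child_seed(seed, 1L))
  list(seqs = gp$seqs, library = lib, truth = gp$truth,
       pair = pair_ids, uncoupled = uncoupled_ids)
}

#' Write a complete synthetic study to disk
#'
#' Emits everything [run_pipeline()] needs: an expression table with
#' planted TSGs, a tissue map, promoters for the first tissue's planted
#' TSGs (carrying the coupled motif pair) plus unrelated promoters, a
#' TRANSFAC matrix file, a TF-gene map linking each motif to an
#' expressed gene, a YAML run configuration and a JSON truth manifest.
#'
#' @param dir output directory (created if needed).
#' @param seed root seed.
#' @param n_seqs promoters per planted TSG set (capped by the number of
#'   planted TSGs).
#' @param n_background_sets background sets recorded in the config.
#' @param n_decoys decoy motif count.
#' @return the configuration path, invisibly; all file paths are
#'   returned in attribute `files`.
#' @export
write_preset <- function(dir, seed = 1L, n_seqs = 60L,
                         n_background_sets = 20L, n_decoys = 6L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ge <- gen_expression(n_genes = max(600L, 4L * n_seqs), n_tsg_per_tissue = n_seqs,
                       seed = seed)
  tissue <- names(ge$truth$planted_tsg)[1]
  tsg_genes <- ge$truth$planted_tsg[[tissue]]

  cp <- preset_coupled_pair(seed = child_seed(seed, 7L), n_seqs = length(tsg_genes),
                            n_decoys = n_decoys)
  seqs <- cp$seqs
  names(seqs) <- tsg_genes[seq_along(seqs)]

  # TF genes: reuse strongly expressed background genes so every motif
  # survives the expression filter in every tissue
  agg <- aggregate_by_tissue(ge$matrix)
  planted_all <- unlist(ge$truth$planted_tsg, use.names = FALSE)
  cand <- setdiff(rownames(agg$values), planted_all)
  cand <- cand[apply(agg$values[cand, , drop = FALSE] >= 1.46, 1, all)]
  motif_ids <- names(cp$library$pwms)
  if (length(cand) < length(motif_ids))
    stopf("not enough uniformly expressed genes for the TF map")
  tf_map <- data.frame(motif_id = motif_ids,
                       gene_id = cand[seq_along(motif_ids)],
                       stringsAsFactors = FALSE)

  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    tissue_map = file.path(dir, "tissue_map.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    matrices = file.path(dir, "matrices.transfac"),
    tf_map = file.path(dir, "tf_map.tsv"),
    config = file.path(dir, "config.yaml"),
    truth = file.path(dir, "truth.json"))

  expr_df <- data.frame(gene_id = rownames(ge$matrix$values),
                        ge$matrix$values, check.names = FALSE)
  write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = names(ge$matrix$sample_tissues),
                         tissue = unname(ge$matrix$sample_tissues)),
              paths$tissue_map, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_promoters(seqs, paths$promoters)
  # emit count matrices (1000 pseudo-observations per column), the form
  # TRANSFAC-style flat files store; the pipeline re-normalizes them
  counts_lib <- cp$library
  counts_lib$pwms <- lapply(counts_lib$pwms, function(p)
    new_pwm(round(p$matrix * 1000), p$motif_id, p$tf_gene_ids,
            is_probability = FALSE))
  write_transfac(counts_lib, paths$matrices)
  write.table(tf_map, paths$tf_map, sep = "\t", quote = FALSE,
              row.names = FALSE)

  config <- list(
    datasets = list(main = list(expression = paths$expression,
                                tissue_map = paths$tissue_map,
                                unit = "TPM", tau = 1.46)),
    promoters = paths$promoters,
    matrices = list(path = paths$matrices, dialect = "transfac"),
    tf_map = paths$tf_map,
    out_dir = file.path(dir, "results"),
    policy = structure(list("main"), names = tissue),
    parameters = list(seed = seed,
                      n_background_sets = n_background_sets,
                      min_overlap = 8L))
  yaml::write_yaml(config, paths$config)
  jsonlite::write_json(
    list(planted_tsg = ge$truth$planted_tsg,
         planted_pair = list(motif_a = cp$pair[1], motif_b = cp$pair[2],
                             promoter_tissue = tissue),
         decoy_motifs = cp$truth$decoy_motifs,
         seed = seed),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  structure(invisible(paths$config), files = paths)
}
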