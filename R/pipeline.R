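default_parameters <- function() {
  list(tau = 1.46, fraction = 2 / 3, pseudocount = 0.01,
       correlation_cutoff = 0.8, min_overlap = 3L,
       d_min = 5L, d_max = 20L, alpha = 0.5,
       n_background_sets = 100L, z_cutoff = 3, seed = 1L,
       markov_order = 2L, n_calibration = 3000L, shuffle = "dinucleotide")
}

#' Validate a run configuration file
#'
#' Reads a YAML configuration, applies the documented defaults to every
#' omitted parameter (echoing each substitution), checks parameter
#' ranges and the existence of every referenced file, and reports all
#' problems at once.
#'
#' Expected structure: `datasets` (name -> `expression`, `tissue_map`,
#' optional `unit` and `tau`, the latter a number or `"auto"`),
#' `promoters` (FASTA path), `matrices` (`path`, `dialect`), `tf_map`,
#' `out_dir`, `policy` (tissue -> dataset names) and `parameters`.
#'
#' @param path YAML configuration file.
#' @return a validated `RunConfig` list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))

  defaults <- default_parameters()
  params <- cfg$parameters %||% list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) note("unknown parameter key(s): %s",
                            paste(unknown, collapse = ", "))
  for (k in names(defaults)) {
    if (is.null(params[[k]])) {
      params[[k]] <- defaults[[k]]
      message(sprintf("config: parameter '%s' defaulted to %s", k,
                      format(defaults[[k]])))
    }
  }
  if (params$alpha < -1 || params$alpha > 1)
    note("alpha = %g outside [-1, 1]", params$alpha)
  if (params$fraction <= 0 || params$fraction > 1)
    note("fraction = %g outside (0, 1]", params$fraction)
  if (params$d_min < 0 || params$d_max < params$d_min)
    note("need 0 <= d_min <= d_max (got %s, %s)", params$d_min, params$d_max)
  if (params$n_background_sets < 1) note("n_background_sets must be >= 1")
  if (!params$shuffle %in% c("dinucleotide", "mononucleotide"))
    note("shuffle must be 'dinucleotide' or 'mononucleotide'")

  if (is.null(cfg$datasets) || !length(cfg$datasets))
    note("no datasets defined")
  for (dn in names(cfg$datasets)) {
    d <- cfg$datasets[[dn]]
    for (key in c("expression", "tissue_map")) {
      if (is.null(d[[key]])) note("dataset '%s': missing key '%s'", dn, key)
      else if (!file.exists(d[[key]]))
        note("dataset '%s': file not found: %s", dn, d[[key]])
    }
    if (!is.null(d$tau) && !identical(d$tau, "auto") && !is.numeric(d$tau))
      note("dataset '%s': tau must be a number or 'auto'", dn)
  }
  for (key in c("promoters", "tf_map")) {
    if (is.null(cfg[[key]])) note("missing key '%s'", key)
    else if (!file.exists(cfg[[key]])) note("%s file not found: %s", key, cfg[[key]])
  }
  if (is.null(cfg$matrices$path)) note("missing key 'matrices/path'")
  else if (!file.exists(cfg$matrices$path))
    note("matrices file not found: %s", cfg$matrices$path)
  if (!is.null(cfg$matrices$dialect) &&
      !cfg$matrices$dialect %in% c("transfac", "jaspar"))
    note("matrices/dialect must be 'transfac' or 'jaspar'")
  if (is.null(cfg$policy) || !length(cfg$policy)) {
    note("policy must name at least one tissue")
  } else {
    for (t in names(cfg$policy)) {
      absent <- setdiff(unlist(cfg$policy[[t]]), names(cfg$datasets))
      if (length(absent))
        note("policy for '%s' names unknown dataset '%s'", t, absent[1])
    }
  }
  if (length(problems))
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  cfg$parameters <- params
  cfg$matrices$dialect <- cfg$matrices$dialect %||% "transfac"
  cfg$out_dir <- cfg$out_dir %||% "tfcoop_results"
  structure(cfg, class = "RunConfig")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full tissue-specific cooperation workflow
#'
#' Executes, per tissue of the policy: tissue-specific gene selection
#' (threshold, low-expression filtering, replicate aggregation,
#' two-thirds rule, multi-dataset intersection), promoter subsetting,
#' TF-expression filtering and redundancy clustering of the motif
#' library, cutoff calibration and binding-site scanning, PMI/z-score
#' pair scoring, background subtraction and classification, and network
#' construction. All intermediates are written under `out_dir` with
#' stable filenames; every count in the report equals the row count of
#' the corresponding emitted table.
#'
#' @param config a validated `RunConfig` from [validate_config()].
#' @return a `RunReport`: list with `tissues` (per-tissue count table),
#'   `seed`, `out_dir` and `elapsed_sec`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) stopf("run_pipeline needs a RunConfig")
  t0 <- Sys.time()
  p <- config$parameters
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  datasets <- run_stage("load_expression", lapply(config$datasets, function(d) {
    em <- load_expression(d$expression, d$tissue_map, unit = d$unit %||% "TPM")
    tau <- d$tau %||% p$tau
    th <- if (identical(tau, "auto"))
      estimate_threshold(em) else
      estimate_threshold(em, method = "fixed", tau = tau)
    em <- drop_unexpressed(em, th)
    list(matrix = em, agg = aggregate_by_tissue(em), tau = th$tau)
  }))
  tsg_sets <- run_stage("select_tsg", lapply(datasets, function(d)
    select_tsg(d$agg, fraction = p$fraction)))
  combined <- run_stage("combine_tsg", combine_tsg(tsg_sets, config$policy))
  write_tsg(combined, file.path(config$out_dir, "tsg.tsv"))

  promoters <- run_stage("read_promoters", read_promoters(config$promoters))
  library_all <- run_stage("parse_matrices", {
    lib <- parse_matrices(config$matrices$path, config$matrices$dialect)
    lib <- attach_tf_map(lib, config$tf_map)
    normalize_library(lib, pseudocount = p$pseudocount)
  })

  if (!length(config$policy)) stopf("configuration has 0 tissues")
  rows <- list()
  for (tissue in names(config$policy)) {
    genes <- combined$genes[[tissue]]
    seqs <- promoters[intersect(names(promoters), genes)]
    if (!length(seqs)) {
      warnf("tissue '%s': no promoters for its TSGs; skipped", tissue)
      rows[[tissue]] <- data.frame(tissue = tissue, n_tsg = length(genes),
                                   n_pwms = NA_integer_, n_sites = NA_integer_,
                                   n_significant = NA_integer_,
                                   n_specific = NA_integer_)
      next
    }
    ref_dataset <- config$policy[[tissue]][[1]]
    lib <- run_stage("filter_motifs", {
      l <- filter_by_tf_expression(library_all, datasets[[ref_dataset]]$agg,
                                   tissue, tau = datasets[[ref_dataset]]$tau)
      if (!length(l$pwms)) stopf("no motif expressed in tissue '%s'", tissue)
      cluster_and_select(l, correlation_cutoff = p$correlation_cutoff,
                         min_overlap = p$min_overlap)
    })
    ana <- run_stage("cooccurrence", cooccurrence_analysis(
      seqs, lib, pairing = pairing_config(p$d_min, p$d_max),
      z_cutoff = p$z_cutoff, markov_order = p$markov_order,
      n_calibration = p$n_calibration, seed = child_seed(p$seed, 100L)))
    spec <- run_stage("specificity", specificity_analysis(
      seqs, lib, ana$thresholds, ana$pmi,
      pairing = pairing_config(p$d_min, p$d_max),
      config = specificity_config(alpha = p$alpha,
                                  n_background_sets = p$n_background_sets,
                                  seed = child_seed(p$seed, 1000L),
                                  shuffle = p$shuffle)))
    net <- build_network(spec$result, tissue)

    pre <- function(f) file.path(config$out_dir, sprintf("%s_%s", tissue, f))
    write_sites(ana$sites, pre("sites.tsv"))
    write_sites_bed(ana$sites, pre("sites.bed"))
    write_pairs(spec$result, pre("pairs.tsv"))
    write_network_edges(net, pre("network.tsv"))

    rows[[tissue]] <- data.frame(
      tissue = tissue, n_tsg = length(genes), n_pwms = length(lib$pwms),
      n_sites = nrow(ana$sites),
      n_significant = sum(spec$result$significant),
      n_specific = sum(spec$result$class == "specific", na.rm = TRUE))
  }
  report <- structure(
    list(tissues = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         seed = p$seed, out_dir = config$out_dir,
         elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "RunReport")
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (seed %d, %.1f s):\n", x$seed, x$elapsed_sec))
  print(x$tissues, row.names = FALSE)
  invisible(x)
}
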