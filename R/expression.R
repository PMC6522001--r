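#' Construct a validated expression matrix
#'
#' Container for gene x sample nonnegative expression values (TPM or RPKM)
#' with a sample-to-tissue map. All downstream tissue-specific gene (TSG)
#' selection starts from this object.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_tissues named character vector mapping sample id to
#'   tissue label; must cover every column of `values`.
#' @param unit expression unit, `"TPM"` or `"RPKM"`.
#' @return an object of class `ExpressionMatrix` with elements `values`,
#'   `sample_tissues` and `unit`.
#' @export
expression_matrix <- function(values, sample_tissues, unit = c("TPM", "RPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (is.null(rownames(values))) stopf("'values' must have gene ids as rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) stopf("duplicate gene ID '%s'", dup[1])
  if (any(!is.finite(values)))
    stopf("non-finite expression value at row %d",
          which(!is.finite(values), arr.ind = TRUE)[1, 1])
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stopf("negative expression value at gene '%s', sample '%s'",
          rownames(values)[idx[1]], colnames(values)[idx[2]])
  }
  missing <- setdiff(colnames(values), names(sample_tissues))
  if (length(missing))
    stopf("sample '%s' missing from the tissue map", missing[1])
  structure(
    list(values = values,
         sample_tissues = sample_tissues[colnames(values)],
         unit = unit),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s), %d tissues\n",
              nrow(x$values), ncol(x$values), x$unit,
              length(unique(x$sample_tissues))))
  invisible(x)
}

#' Read a sample-to-tissue map from a two-column TSV
#'
#' @param path file with columns sample id, tissue label (no header
#'   required; a `sample<TAB>tissue` header row is tolerated).
#' @return named character vector sample -> tissue.
#' @export
read_tissue_map <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("tissue map must have two columns")
  if (identical(tolower(df[1, 1]), "sample")) df <- df[-1, , drop = FALSE]
  structure(as.character(df[[2]]), names = as.character(df[[1]]))
}

#' Load a delimited expression table
#'
#' First column holds gene identifiers, remaining columns are numeric
#' expression values; the header row gives sample ids, each of which must
#' be present in `tissue_map`.
#'
#' @param path tab-delimited text table.
#' @param tissue_map named character vector sample -> tissue, or the path
#'   of a two-column TSV (see [read_tissue_map()]).
#' @param unit expression unit label.
#' @return an [expression_matrix()] with row order preserved.
#' @export
load_expression <- function(path, tissue_map, unit = c("TPM", "RPKM")) {
  unit <- match.arg(unit)
  if (is.character(tissue_map) && length(tissue_map) == 1 && file.exists(tissue_map))
    tissue_map <- read_tissue_map(tissue_map)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression table needs a gene column plus samples")
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn))
        stopf("non-numeric value at row %d, column '%s'",
              which(is.na(vn))[1], colnames(vals)[j])
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  expression_matrix(m, tissue_map, unit)
}

#' Estimate the expression threshold tau
#'
#' Pools all expression values, estimates their density on a
#' log-compressed axis (`log10(x + 1e-3)`, Gaussian KDE, Scott's
#' bandwidth) and returns the value at the first local minimum between the
#' two largest modes, mapped back to the original scale. This locates the
#' valley between the unexpressed and expressed populations of a bimodal
#' TPM/RPKM distribution; the resulting tau is used to discard genes never
#' expressed above it.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param method `"kde_local_minimum"` (default) or `"fixed"`.
#' @param tau required when `method = "fixed"`; 1.46 is the conventional
#'   default on the TPM scale.
#' @param grid_size number of KDE grid points.
#' @param eps offset of the log transform.
#' @return an `ExpressionThreshold` list with elements `tau`, `method`,
#'   `transform`.
#' @export
estimate_threshold <- function(matrix, method = c("kde_local_minimum", "fixed"),
                               tau = NULL, grid_size = 512L, eps = 1e-3) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(tau) || !is.finite(tau))
      stopf("method 'fixed' requires a finite tau")
    return(structure(list(tau = tau, method = "fixed", transform = "identity"),
                     class = "ExpressionThreshold"))
  }
  x <- as.vector(matrix$values)
  if (!length(x)) stopf("empty expression matrix")
  lx <- log10(x + eps)
  if (length(unique(lx)) < 3L || sd(lx) == 0)
    stopf("degenerate expression density (no interior local minimum); use method = 'fixed'")
  d <- density(lx, bw = "nrd", n = grid_size)
  y <- d$y
  dy <- diff(sign(diff(y)))
  maxima <- which(dy == -2) + 1L
  minima <- which(dy == 2) + 1L
  if (length(maxima) < 2L)
    stopf("expression density is unimodal (no interior local minimum); use method = 'fixed'")
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  between <- minima[minima > top2[1] & minima < top2[2]]
  if (!length(between))
    stopf("no local minimum between the two main density modes; use method = 'fixed'")
  tau <- 10^d$x[between[1]] - eps
  if (!is.finite(tau) || tau <= 0)
    stopf("estimated threshold is not positive; use method = 'fixed'")
  structure(list(tau = tau, method = "kde_local_minimum",
                 transform = sprintf("log10(x + %g)", eps)),
            class = "ExpressionThreshold")
}

#' Remove genes never expressed above the threshold
#'
#' Retains exactly the genes with at least one sample value strictly
#' greater than `tau`; row order is preserved. Idempotent.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param threshold an `ExpressionThreshold` or a bare number.
#' @return filtered `ExpressionMatrix`.
#' @export
drop_unexpressed <- function(matrix, threshold) {
  tau <- if (inherits(threshold, "ExpressionThreshold")) threshold$tau else threshold
  keep <- apply(matrix$values > tau, 1, any)
  if (!any(keep)) stopf("no gene expressed above tau = %g", tau)
  expression_matrix(matrix$values[keep, , drop = FALSE],
                    matrix$sample_tissues, matrix$unit)
}

#' Aggregate replicate samples into per-tissue means
#'
#' Each (gene, tissue) cell becomes the arithmetic mean over that tissue's
#' samples.
#'
#' @param matrix an `ExpressionMatrix`.
#' @return a `TissueExpression` list with elements `values` (gene x tissue
#'   matrix) and `aggregation`.
#' @export
aggregate_by_tissue <- function(matrix) {
  st <- matrix$sample_tissues
  tissues <- unique(unname(st))
  vals <- vapply(tissues, function(t)
    rowMeans(matrix$values[, st == t, drop = FALSE]),
    numeric(nrow(matrix$values)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(rownames(matrix$values), tissues))
  colnames(vals) <- tissues
  structure(list(values = vals, aggregation = "mean"),
            class = "TissueExpression")
}

#' Select tissue-specific genes by the two-thirds rule
#'
#' A gene is specific for a tissue when its expression there is at least
#' `fraction` (default 2/3) of its accumulated expression over all
#' tissues; the boundary is inclusive. All-zero genes are assigned
#' nowhere. For any `fraction > 1/2` at most one tissue can qualify per
#' gene.
#'
#' @param expr a `TissueExpression`.
#' @param fraction specificity fraction in (0, 1].
#' @return a `TSGSet`: list with `genes` (tissue -> character vector) and
#'   `fraction`.
#' @export
select_tsg <- function(expr, fraction = 2 / 3) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stopf("fraction must lie in (0, 1]")
  v <- expr$values
  if (ncol(v) < 2) stopf("need at least 2 tissues for TSG selection")
  totals <- rowSums(v)
  hit <- v >= fraction * totals & totals > 0
  genes <- lapply(colnames(v), function(t) rownames(v)[hit[, t]])
  names(genes) <- colnames(v)
  structure(list(genes = genes, fraction = fraction), class = "TSGSet")
}

#' @export
print.TSGSet <- function(x, ...) {
  cat(sprintf("TSGSet (fraction %.3f):\n", x$fraction))
  for (t in names(x$genes))
    cat(sprintf("  %s: %d genes\n", t, length(x$genes[[t]])))
  invisible(x)
}

#' Intersect per-dataset TSG sets according to a tissue policy
#'
#' For each tissue the policy names the datasets whose TSG lists must
#' agree; the tissue's combined list is their intersection. A
#' single-dataset policy passes that list through.
#'
#' @param per_dataset named list: dataset -> `TSGSet`.
#' @param policy named list: tissue -> character vector of dataset names.
#' @return a combined `TSGSet`.
#' @export
combine_tsg <- function(per_dataset, policy) {
  genes <- list()
  for (tissue in names(policy)) {
    ds <- policy[[tissue]]
    absent <- setdiff(ds, names(per_dataset))
    if (length(absent)) stopf("dataset '%s' named in policy is absent", absent[1])
    lists <- lapply(ds, function(d) {
      g <- per_dataset[[d]]$genes
      if (!tissue %in% names(g))
        stopf("tissue '%s' absent from dataset '%s'", tissue, d)
      g[[tissue]]
    })
    common <- Reduce(intersect, lists)
    if (!length(common))
      warnf("no common TSGs for tissue '%s' across datasets %s",
            tissue, paste(ds, collapse = ", "))
    genes[[tissue]] <- common
  }
  fr <- per_dataset[[1]]$fraction
  structure(list(genes = genes, fraction = if (is.null(fr)) NA_real_ else fr),
            class = "TSGSet")
}

#' Write / read a TSG set as TSV (tissue, gene_id)
#' @param tsg a `TSGSet`.
#' @param path output file.
#' @return `write_tsg` returns `path` invisibly; `read_tsg` a `TSGSet`.
#' @export
write_tsg <- function(tsg, path) {
  rows <- do.call(rbind, lapply(names(tsg$genes), function(t) {
    if (!length(tsg$genes[[t]])) return(NULL)
    data.frame(tissue = t, gene_id = tsg$genes[[t]], stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(tissue = character(), gene_id = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsg
#' @param fraction specificity fraction recorded on the imported set.
#' @export
read_tsg <- function(path, fraction = 2 / 3) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  genes <- split(as.character(df$gene_id), df$tissue)
  structure(list(genes = genes, fraction = fraction), class = "TSGSet")
}
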