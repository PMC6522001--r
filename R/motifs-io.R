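#' Construct a PWM object
#'
#' @param matrix 4 x L nonnegative numeric matrix, rows in A,C,G,T order.
#' @param motif_id unique motif identifier.
#' @param tf_gene_ids gene identifiers of the TF(s) the motif belongs to.
#' @param is_probability whether columns are probabilities (sum to 1).
#' @return an object of class `PWM`.
#' @export
new_pwm <- function(matrix, motif_id, tf_gene_ids = character(),
                    is_probability = FALSE) {
  if (!is.matrix(matrix) || nrow(matrix) != 4 || ncol(matrix) < 1)
    stopf("PWM '%s': matrix must be 4 x L with L >= 1", motif_id)
  if (any(matrix < 0)) stopf("PWM '%s': negative entries", motif_id)
  if (is_probability) {
    cs <- colSums(matrix)
    if (any(abs(cs - 1) > 1e-6))
      stopf("PWM '%s': probability columns must sum to 1", motif_id)
  }
  rownames(matrix) <- DNA_BASES
  structure(list(matrix = matrix, motif_id = motif_id,
                 tf_gene_ids = tf_gene_ids, is_probability = is_probability),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s (L = %d, %s)\n", x$motif_id, ncol(x$matrix),
              if (x$is_probability) "probabilities" else "counts"))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Construct a motif library
#'
#' @param pwms list of [new_pwm()] objects with unique `motif_id`s.
#' @param tissue optional tissue label.
#' @param provenance free-text origin note.
#' @return an object of class `MotifLibrary`; `pwms` is named by motif id.
#' @export
motif_library <- function(pwms, tissue = NULL, provenance = "") {
  ids <- vapply(pwms, function(p) p$motif_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate motif id '%s'", ids[duplicated(ids)][1])
  names(pwms) <- ids
  structure(list(pwms = pwms, tissue = tissue, provenance = provenance),
            class = "MotifLibrary")
}

#' @export
print.MotifLibrary <- function(x, ...) {
  cat(sprintf("MotifLibrary: %d PWMs%s\n", length(x$pwms),
              if (!is.null(x$tissue)) paste0(" [", x$tissue, "]") else ""))
  invisible(x)
}

#' @export
length.MotifLibrary <- function(x) length(x$pwms)

#' Parse a PWM flat file
#'
#' Supports the TRANSFAC flat-file dialect (AC/ID records, `P0` header,
#' numbered count rows, `//` terminators) and JASPAR PFM records
#' (`>` header followed by four base rows, with or without brackets).
#' Counts are preserved as given; matrices are not normalized.
#'
#' @param path matrix flat file.
#' @param dialect `"transfac"` or `"jaspar"`.
#' @return a [motif_library()].
#' @export
parse_matrices <- function(path, dialect = c("transfac", "jaspar")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    stopf("empty matrix file: %s", path)
  pwms <- switch(dialect,
                 transfac = parse_transfac_lines(lines),
                 jaspar = parse_jaspar_lines(lines))
  if (!length(pwms)) stopf("no matrix records found in %s", path)
  motif_library(pwms, provenance = sprintf("%s (%s)", path, dialect))
}

parse_transfac_lines <- function(lines) {
  pwms <- list()
  ac <- id <- NULL
  counts <- NULL
  in_matrix <- FALSE
  flush <- function() {
    if (is.null(counts)) return(NULL)
    mid <- if (!is.null(id)) id else ac
    if (is.null(mid)) stopf("TRANSFAC record without AC or ID")
    m <- t(do.call(rbind, counts))
    new_pwm(m, mid)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    tag <- substr(ln, 1, 2)
    if (tag == "//") {
      p <- flush()
      if (!is.null(p)) pwms[[length(pwms) + 1]] <- p
      ac <- id <- NULL; counts <- NULL; in_matrix <- FALSE
    } else if (tag == "AC") {
      ac <- trimws(substr(ln, 3, nchar(ln)))
    } else if (tag == "ID") {
      id <- trimws(substr(ln, 3, nchar(ln)))
    } else if (tag == "P0" || tag == "PO") {
      hdr <- strsplit(trimws(substr(ln, 3, nchar(ln))), "\\s+")[[1]]
      if (!identical(toupper(hdr[1:4]), DNA_BASES))
        stopf("line %d: unknown base order '%s'", i, paste(hdr, collapse = " "))
      in_matrix <- TRUE
      counts <- list()
    } else if (in_matrix && grepl("^[0-9]+\\s", ln)) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(tok[2:5]))
      if (length(tok) < 5 || anyNA(num))
        stopf("line %d: expected 4 numeric values in matrix row", i)
      counts[[length(counts) + 1]] <- num
    }
  }
  p <- flush()  # tolerate a missing trailing //
  if (!is.null(p)) pwms[[length(pwms) + 1]] <- p
  pwms
}

parse_jaspar_lines <- function(lines) {
  pwms <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, ">")) { i <- i + 1; next }
    mid <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1]][1]
    rows <- list()
    j <- i + 1
    while (j <= length(lines) && length(rows) < 4) {
      rl <- trimws(lines[j])
      if (rl == "") { j <- j + 1; next }
      if (startsWith(rl, ">")) break
      base <- NA_character_
      if (grepl("^[ACGTacgt]\\b", rl) || grepl("^[ACGTacgt]\\s*\\[", rl)) {
        base <- toupper(substr(rl, 1, 1))
        rl <- sub("^[ACGTacgt]", "", rl)
      }
      rl <- gsub("[][]", " ", rl)
      tok <- strsplit(trimws(rl), "\\s+")[[1]]
      num <- suppressWarnings(as.numeric(tok))
      if (!length(num) || anyNA(num))
        stopf("line %d: malformed JASPAR matrix row", j)
      rows[[length(rows) + 1]] <- list(base = base, num = num)
      j <- j + 1
    }
    if (length(rows) != 4) stopf("line %d: JASPAR record '%s' needs 4 base rows", i, mid)
    lens <- vapply(rows, function(r) length(r$num), integer(1))
    if (length(unique(lens)) != 1)
      stopf("line %d: unequal row lengths in JASPAR record '%s'", i, mid)
    bases <- vapply(rows, function(r) r$base, character(1))
    m <- do.call(rbind, lapply(rows, function(r) r$num))
    if (!anyNA(bases)) {
      if (!setequal(bases, DNA_BASES))
        stopf("line %d: unknown base order in JASPAR record '%s'", i, mid)
      m <- m[match(DNA_BASES, bases), , drop = FALSE]
    }
    pwms[[length(pwms) + 1]] <- new_pwm(m, mid)
    i <- j
  }
  pwms
}

#' Write a motif library in TRANSFAC flat-file dialect
#'
#' @param library a `MotifLibrary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transfac <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in library$pwms) {
    writeLines(c(sprintf("AC  %s", p$motif_id), "XX",
                 sprintf("ID  %s", p$motif_id), "XX",
                 sprintf("P0  %10s %10s %10s %10s", "A", "C", "G", "T")), con)
    m <- p$matrix
    for (j in seq_len(ncol(m))) {
      cons <- DNA_BASES[which.max(m[, j])]
      writeLines(sprintf("%02d  %10s %10s %10s %10s  %s", j,
                         sprintf("%.10g", m[1, j]), sprintf("%.10g", m[2, j]),
                         sprintf("%.10g", m[3, j]), sprintf("%.10g", m[4, j]),
                         cons), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Write a motif library as JASPAR PFM records
#'
#' @inheritParams write_transfac
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in library$pwms) {
    writeLines(sprintf(">%s", p$motif_id), con)
    for (b in 1:4) {
      writeLines(sprintf("%s  [ %s ]", DNA_BASES[b],
                         paste(sprintf("%.10g", p$matrix[b, ]), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Attach TF gene identifiers to motifs from a two-column map
#'
#' @param library a `MotifLibrary`.
#' @param map data frame (or TSV path) with columns motif_id, gene_id.
#' @return the library with `tf_gene_ids` filled in.
#' @export
attach_tf_map <- function(library, map) {
  if (is.character(map)) map <- read.delim(map, stringsAsFactors = FALSE)
  colnames(map)[1:2] <- c("motif_id", "gene_id")
  by_motif <- split(as.character(map$gene_id), as.character(map$motif_id))
  library$pwms <- lapply(library$pwms, function(p) {
    p$tf_gene_ids <- by_motif[[p$motif_id]] %||% character()
    p
  })
  names(library$pwms) <- vapply(library$pwms, `[[`, character(1), "motif_id")
  library
}

`%||%` <- function(a, b) if (is.null(a)) b else a
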