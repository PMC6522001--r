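#' Read promoter sequences from FASTA
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and validated against the A,C,G,T,N alphabet.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  for (s in seqs) encode_seq(s)  # alphabet validation
  check_sequences(seqs)
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read binding sites as TSV with raw log-odds scores
#'
#' Scores are serialized with 17 significant digits so a write-read
#' round trip reproduces them exactly.
#'
#' @param sites data frame from [scan_sites()].
#' @param path output file.
#' @return `write_sites` returns `path` invisibly; `read_sites` the
#'   site data frame.
#' @export
write_sites <- function(sites, path) {
  out <- sites
  out$score <- sprintf("%.17g", sites$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "integer",
                                  "integer", "character", "numeric"))
  df
}

#' Write / read binding sites as BED6
#'
#' chrom = sequence id, name = motif id; the BED score column carries
#' the log-odds score scaled by 10 and clipped to 0..1000, per the BED
#' convention. Coordinates, names and strands round-trip exactly; the
#' raw score does not (use [write_sites()] for that).
#'
#' @inheritParams write_sites
#' @return `write_sites_bed` returns `path` invisibly; `read_sites_bed`
#'   a data frame with BED6 columns.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$sequence_id, start = sites$start,
                    end = sites$end, name = sites$motif_id,
                    score = pmax(0L, pmin(1000L, as.integer(round(10 * sites$score)))),
                    strand = sites$strand, stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"))
  df
}

#' Write a pair statistics table as TSV
#'
#' Serializes a `pmi_result` or `specificity_result` with full-precision
#' numeric columns.
#'
#' @param result data frame of pair statistics.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(result, path) {
  out <- as.data.frame(result)
  for (cn in intersect(c("pmi", "z", "avg_background_pmi", "pmi_specific"),
                       colnames(out)))
    out[[cn]] <- sprintf("%.17g", out[[cn]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
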