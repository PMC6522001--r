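DNA_BASES <- c("A", "C", "G", "T")

.base_code <- local({
  m <- rep(NA_integer_, 256)
  m[utf8ToInt("A")] <- 1L
  m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L
  m[utf8ToInt("T")] <- 4L
  m
})

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Encode a nucleotide string as integer codes
#'
#' A,C,G,T map to 1..4; N maps to `NA`. Input is uppercased first.
#'
#' @param s a single nucleotide string over A,C,G,T,N.
#' @return integer vector of codes.
#' @keywords internal
encode_seq <- function(s) {
  v <- utf8ToInt(toupper(s))
  code <- .base_code[v]
  bad <- is.na(code) & v != utf8ToInt("N")
  if (any(bad)) {
    stopf("invalid nucleotide '%s' at position %d",
          intToUtf8(v[which(bad)[1]]), which(bad)[1])
  }
  code
}

decode_seq <- function(codes) {
  out <- rep("N", length(codes))
  ok <- !is.na(codes)
  out[ok] <- DNA_BASES[codes[ok]]
  paste(out, collapse = "")
}

check_sequences <- function(seqs) {
  if (length(seqs) == 0) stopf("empty sequence set")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stopf("sequences must be named")
  if (anyDuplicated(names(seqs)))
    stopf("duplicate sequence id '%s'", names(seqs)[duplicated(names(seqs))][1])
  toupper(seqs)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Derive a bounded child seed from a root seed
#' @keywords internal
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483647L
}
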