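# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n_chars) {
  paste(sample(DNA_BASES, n_chars, replace = TRUE), collapse = "")
}

random_dna_vec <- function(lengths) {
  n <- length(lengths)
  if (n == 0) return(character(0))
  total <- sum(lengths)
  pool <- paste(sample(DNA_BASES, total, replace = TRUE), collapse = "")
  ends <- cumsum(lengths)
  substring(pool, ends - lengths + 1, ends)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual character vector of FASTQ quality strings.
#' @return list of integer vectors, one per input string.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#'
#' @param scores integer vector of per-base qualities in \[0, 60\].
#' @return single character string.
#' @export
phred_encode <- function(scores) {
  stopifnot(all(scores >= 0 & scores <= 60))
  intToUtf8(as.integer(scores) + 33L)
}

# minimum per-base Phred of each quality string; Inf for empty strings
qual_min_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

qual_mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(Inf)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

assert_tbl_cols <- function(x, cols, what = deparse(substitute(x))) {
  if (!is.data.frame(x)) abort(paste0("`", what, "` must be a data frame"))
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(paste0("`", what, "` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(x)
}
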