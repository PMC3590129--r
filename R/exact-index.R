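#' Build an exact-match index over a sequence collection
#'
#' A thin, strand-aware wrapper around Biostrings matching: queries return
#' every `(sequence id, offset, strand)` whose substring equals the query
#' exactly, on either strand, with no mismatches -- the zero-mismatch mapping
#' used throughout annotation.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @return object of class `mirkd_index`.
#' @export
build_exact_index <- function(sequences) {
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("seq%d", seq_along(sequences))
    }
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (length(sequences) == 0) abort("cannot index an empty collection")
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  }
  rc <- Biostrings::reverseComplement(sequences)
  # concatenated subjects with N spacers: one multi-pattern scan per strand
  # covers the whole collection (N never matches an ACGT pattern base)
  spacer <- paste(rep("N", 60), collapse = "")
  widths <- Biostrings::width(sequences)
  offsets <- cumsum(c(0L, head(widths + 60L, -1)))  # 0-based starts in concat
  structure(list(subject = sequences,
                 rc_subject = rc,
                 cat_plus = Biostrings::DNAString(
                   paste(as.character(sequences), collapse = spacer)),
                 cat_minus = Biostrings::DNAString(
                   paste(as.character(rc), collapse = spacer)),
                 offsets = offsets, widths = widths,
                 ids = names(sequences)),
            class = "mirkd_index")
}

#' Query an exact index with a single sequence
#'
#' @param index a `mirkd_index`.
#' @param query sequence to look up; anything containing a character outside
#'   `{A,C,G,T}` returns no hits.
#' @return tibble with `seq_id`, `start` (0-based), `end` (half-open) and
#'   `strand` (`"-"` means the query matches the reverse complement of the
#'   subject at those subject coordinates).
#' @export
query_exact_index <- function(index, query) {
  stopifnot(inherits(index, "mirkd_index"))
  empty <- tibble(seq_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0))
  if (length(query) != 1 || !nzchar(query) || !grepl("^[ACGT]+$", query)) {
    return(empty)
  }
  hits_for <- function(subject, strand) {
    m <- Biostrings::vmatchPattern(query, subject)
    lens <- lengths(m)
    if (sum(lens) == 0) return(empty)
    starts <- unlist(lapply(m, BiocGenerics::start), use.names = FALSE)
    ids <- rep(names(subject), lens)
    widths <- Biostrings::width(subject)[rep(seq_along(subject), lens)]
    if (strand == "+") {
      tibble(seq_id = ids, start = starts - 1L,
             end = starts - 1L + nchar(query), strand = "+")
    } else {
      # match coords on the reverse complement -> subject coordinates
      tibble(seq_id = ids, start = widths - (starts - 1L + nchar(query)),
             end = widths - (starts - 1L), strand = "-")
    }
  }
  bind_rows(hits_for(index$subject, "+"), hits_for(index$rc_subject, "-")) %>%
    arrange(.data$seq_id, .data$start, .data$strand)
}

# bulk exact matching of many same-or-mixed-length queries against an index;
# returns tibble(seq, seq_id, start, end, strand) with 0-based half-open
# subject coordinates. Used by the classifier to avoid per-read matching.
match_seqs_bulk <- function(index, seqs) {
  stopifnot(inherits(index, "mirkd_index"))
  seqs <- unique(seqs)
  seqs <- seqs[nzchar(seqs) & grepl("^[ACGT]+$", seqs)]
  if (length(seqs) == 0) {
    return(tibble(seq = character(0), seq_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0)))
  }
  empty <- tibble(seq = character(0), seq_id = character(0),
                  start = integer(0), end = integer(0), strand = character(0))
  one_strand <- function(cat_subject, strand) {
    res <- list()
    for (L in unique(nchar(seqs))) {
      qs <- seqs[nchar(seqs) == L]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(qs))
      m <- Biostrings::matchPDict(pd, cat_subject)
      lens <- lengths(m)
      if (sum(lens) == 0) next
      starts0 <- unlist(lapply(m, BiocGenerics::start),
                        use.names = FALSE) - 1L  # 0-based in concat
      hit <- tibble(seq = rep(qs, lens), cat_start = starts0, len = L)
      si <- findInterval(hit$cat_start, index$offsets)
      hit$seq_id <- index$ids[si]
      local_start <- hit$cat_start - index$offsets[si]
      if (strand == "+") {
        hit$start <- local_start
        hit$end <- local_start + L
      } else {
        w <- index$widths[si]
        hit$start <- w - (local_start + L)
        hit$end <- w - local_start
      }
      hit$strand <- strand
      res[[length(res) + 1]] <- select(hit, "seq", "seq_id", "start",
                                       "end", "strand")
    }
    if (length(res) == 0) empty else bind_rows(res)
  }
  bind_rows(one_strand(index$cat_plus, "+"),
            one_strand(index$cat_minus, "-"))
}
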