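#' Trim the 3' adapter from reads
#'
#' Finds, for each read, the leftmost position where the adapter prefix
#' aligns to the read suffix with at most `max_mismatch` mismatches over an
#' overlap of at least `min_overlap` bases. Terminal overlaps shorter than
#' the full adapter are allowed with a proportionally scaled mismatch budget,
#' `floor(max_mismatch * overlap / adapter_len)`. The read (and its quality
#' string) is truncated before that position; reads with no acceptable
#' alignment are flagged as having no adapter (`insert = NA`).
#'
#' @param reads tibble with columns `read_id`, `seq`, `qual`.
#' @param adapter adapter sequence (length >= `min_overlap`).
#' @param max_mismatch mismatch budget over a full-length adapter overlap.
#' @param min_overlap minimum read/adapter overlap considered evidence of
#'   the adapter.
#' @return the input tibble with added columns `insert`, `insert_qual`
#'   (both `NA` when no adapter was found) and `adapter_pos` (0-based
#'   position of the adapter start within the read).
#' @export
trim_adapter <- function(reads, adapter, max_mismatch = 2, min_overlap = 6) {
  assert_tbl_cols(reads, c("read_id", "seq", "qual"), "reads")
  if (nchar(adapter) < min_overlap) {
    abort("`adapter` must be at least `min_overlap` bases long")
  }
  if (nrow(reads) == 0) {
    return(mutate(reads, insert = character(0), insert_qual = character(0),
                  adapter_pos = integer(0)))
  }
  a_chars <- strsplit(adapter, "")[[1]]
  la <- length(a_chars)

  out_pos <- rep(NA_integer_, nrow(reads))
  lens <- nchar(reads$seq)
  for (L in sort(unique(lens))) {
    rows <- which(lens == L)
    if (L < min_overlap) next  # includes empty reads: no-adapter flag
    m <- matrix(unlist(strsplit(reads$seq[rows], ""), use.names = FALSE),
                ncol = L, byrow = TRUE)
    pos <- rep(NA_integer_, length(rows))
    for (p in 0:(L - min_overlap)) {
      o <- min(la, L - p)
      budget <- if (o < la) floor(max_mismatch * o / la) else max_mismatch
      cols <- (p + 1):(p + o)
      mism <- rowSums(m[, cols, drop = FALSE] !=
                        matrix(a_chars[seq_len(o)], nrow = length(rows),
                               ncol = o, byrow = TRUE))
      hit <- is.na(pos) & mism <= budget
      pos[hit] <- p
      if (!anyNA(pos)) break
    }
    out_pos[rows] <- pos
  }
  reads %>% mutate(
    adapter_pos = out_pos,
    insert = ifelse(is.na(out_pos), NA_character_,
                    substr(.data$seq, 1, out_pos)),
    insert_qual = ifelse(is.na(out_pos), NA_character_,
                         substr(.data$qual, 1, out_pos))
  )
}

#' Apply the length and quality filters
#'
#' Classifies adapter-trimmed reads into the filter categories with fixed
#' precedence `no_adapter > too_short > too_long > low_quality > qualified`:
#' a trimmed insert is kept when `min_len <= length <= max_len` (inclusive
#' bounds) and its Phred quality passes the threshold over the insert.
#'
#' @param trimmed output of [trim_adapter()].
#' @param min_len,max_len inclusive insert length window in nt.
#' @param min_phred Phred threshold.
#' @param quality_mode `"per_base"` (default; minimum per-base Phred must be
#'   `>= min_phred`) or `"mean"` (mean insert Phred must be `>= min_phred`).
#' @return `trimmed` with an added `category` column.
#' @export
apply_filters <- function(trimmed, min_len = 17, max_len = 27,
                          min_phred = 10,
                          quality_mode = c("per_base", "mean")) {
  assert_tbl_cols(trimmed, c("insert", "insert_qual"), "trimmed")
  quality_mode <- match.arg(quality_mode)
  len <- nchar(trimmed$insert)
  q <- rep(NA_real_, nrow(trimmed))
  ok_len <- !is.na(trimmed$insert) & len >= min_len & len <= max_len
  q[ok_len] <- if (quality_mode == "per_base") {
    qual_min_phred(trimmed$insert_qual[ok_len])
  } else {
    qual_mean_phred(trimmed$insert_qual[ok_len])
  }
  category <- dplyr::case_when(
    is.na(trimmed$insert) ~ "no_adapter",
    len < min_len ~ "too_short",
    len > max_len ~ "too_long",
    q < min_phred ~ "low_quality",
    TRUE ~ "qualified"
  )
  mutate(trimmed, category = factor(category, levels = filter_categories()))
}

filter_categories <- function() {
  c("no_adapter", "too_short", "too_long", "low_quality", "qualified")
}

#' Tally filter categories
#'
#' @param classified output of [apply_filters()].
#' @return one-row tibble with one count per category plus `total`; the
#'   categories always sum to `total`.
#' @export
filter_stats <- function(classified) {
  assert_tbl_cols(classified, "category", "classified")
  tab <- table(factor(classified$category, levels = filter_categories()))
  out <- as_tibble(as.list(tab))
  out$total <- nrow(classified)
  out
}

#' Collapse qualified reads to unique sequences with counts
#'
#' @param qualified tibble of reads with an `insert` column (rows with
#'   `category` present are restricted to `"qualified"` first). A plain
#'   character vector of sequences is also accepted.
#' @return tibble (`seq`, `count`) sorted by descending count, ties broken
#'   lexicographically by sequence. The counts sum to the number of input
#'   reads.
#' @export
collapse_reads <- function(qualified) {
  seqs <- if (is.character(qualified)) {
    qualified
  } else {
    assert_tbl_cols(qualified, "insert", "qualified")
    x <- qualified
    if ("category" %in% names(x)) x <- filter(x, .data$category == "qualified")
    x$insert
  }
  if (length(seqs) == 0) {
    return(tibble(seq = character(0), count = integer(0)))
  }
  tibble(seq = seqs) %>%
    count(.data$seq, name = "count") %>%
    arrange(desc(.data$count), .data$seq)
}

#' Run the full preprocessing stage on one library
#'
#' Adapter trimming, length/quality filtering, and read collapsing in one
#' call.
#'
#' @inheritParams trim_adapter
#' @inheritParams apply_filters
#' @return list with `reads` (per-read tibble incl. `category`), `stats`
#'   (one-row [filter_stats()] tibble) and `collapsed` (unique qualified
#'   inserts with counts).
#' @export
preprocess_library <- function(reads, adapter, max_mismatch = 2,
                               min_overlap = 6, min_len = 17, max_len = 27,
                               min_phred = 10,
                               quality_mode = c("per_base", "mean")) {
  quality_mode <- match.arg(quality_mode)
  classified <- trim_adapter(reads, adapter, max_mismatch, min_overlap) %>%
    apply_filters(min_len, max_len, min_phred, quality_mode)
  list(reads = classified,
       stats = filter_stats(classified),
       collapsed = collapse_reads(classified))
}

#' Stacked bar chart of filter outcomes per library
#'
#' @param stats tibble of [filter_stats()] rows with a `library` column.
#' @return a ggplot object.
#' @export
plot_filter_stats <- function(stats) {
  assert_tbl_cols(stats, c("library", filter_categories()), "stats")
  long <- stats %>%
    select("library", all_of(filter_categories())) %>%
    tidyr::pivot_longer(-"library", names_to = "category",
                        values_to = "reads") %>%
    mutate(category = factor(.data$category, levels = filter_categories()))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$library, y = .data$reads,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "reads", fill = "filter outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of trimmed insert lengths
#'
#' Qualified small RNA libraries are expected to peak at 22 nt, the modal
#' mature miR length.
#'
#' @param classified output of [apply_filters()] (one or more libraries).
#' @return a ggplot object.
#' @export
plot_insert_lengths <- function(classified) {
  assert_tbl_cols(classified, "insert", "classified")
  d <- classified %>% filter(!is.na(.data$insert)) %>%
    mutate(len = nchar(.data$insert))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$len)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "trimmed insert length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}
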