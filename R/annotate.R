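#' Classify collapsed reads against the reference hierarchy
#'
#' Implements the hierarchical zero-mismatch decision used to annotate small
#' RNA reads, in fixed order: (1) no exact genome hit -> `unmapped`;
#' (2) exact hit in the non-coding RNA set -> `ncrna`; (3) genome hit inside
#' a precursor on the annotated strand, overlapping the mature or star arm
#' such that the arm's seed (positions 2-8) is fully contained in the read
#' and both end offsets are within +-3 nt -> `known_mir`, with offsets
#' `(read start - arm start, read end - arm end)`; (4) a precursor-contained
#' hit failing (3) -> `precursor_other`; (5) any other genome hit ->
#' `novel_candidate`. Reads eligible for `known_mir` at more than one locus
#' are assigned to the locus with the smallest `|offset5| + |offset3|`;
#' exact ties are flagged `multi_mapper` and excluded from counting.
#'
#' @param collapsed tibble (`seq`, `count`) from [collapse_reads()].
#' @param ref a `mirkd_reference`.
#' @param max_offset maximum absolute end offset for a known-miR call.
#' @return assignment tibble: `seq`, `count`, `category`, `locus_id`,
#'   `mir_id`, `arm`, `offset5`, `offset3`, `multi_mapper`.
#' @export
classify_reads <- function(collapsed, ref, max_offset = 3) {
  assert_tbl_cols(collapsed, c("seq", "count"), "collapsed")
  stopifnot(inherits(ref, "mirkd_reference"))
  ann <- classify_unique_seqs(unique(collapsed$seq), ref, max_offset)
  collapsed %>% left_join(ann, by = "seq")
}

#' Classify a single read sequence
#'
#' Single-read convenience wrapper around [classify_reads()].
#'
#' @param seq read sequence.
#' @inheritParams classify_reads
#' @return one-row assignment tibble.
#' @export
classify_read <- function(seq, ref, max_offset = 3) {
  classify_reads(tibble(seq = seq, count = 1L), ref, max_offset)
}

# seq-level classification shared by all libraries of a run
classify_unique_seqs <- function(seqs, ref, max_offset = 3) {
  genome_idx <- build_exact_index(ref$genome)
  nc_idx <- if (nrow(ref$ncrna) > 0) {
    build_exact_index(setNames(ref$ncrna$seq, ref$ncrna$id))
  } else {
    NULL
  }

  g_hits <- match_seqs_bulk(genome_idx, seqs)
  nc_hit_seqs <- if (!is.null(nc_idx)) {
    unique(match_seqs_bulk(nc_idx, seqs)$seq)
  } else {
    character(0)
  }

  base <- tibble(
    seq = seqs,
    category = NA_character_, locus_id = NA_character_,
    mir_id = NA_character_, arm = NA_character_,
    offset5 = NA_integer_, offset3 = NA_integer_, multi_mapper = FALSE
  )

  mapped <- unique(g_hits$seq)
  base$category[!(base$seq %in% mapped)] <- "unmapped"
  is_nc <- base$seq %in% nc_hit_seqs & is.na(base$category)
  base$category[is_nc] <- "ncrna"

  undecided <- base$seq[is.na(base$category)]
  if (length(undecided) == 0) return(finish_categories(base))

  hits <- g_hits %>% filter(.data$seq %in% undecided)

  # precursor containment (any strand)
  loci <- ref$loci
  arm_rows <- bind_rows(
    tibble(locus_id = loci$locus_id, mir_id = loci$mature_id, arm = "mature",
           arm_start = loci$mature_start, arm_end = loci$mature_end),
    tibble(locus_id = loci$locus_id, mir_id = loci$star_id, arm = "star",
           arm_start = loci$star_start, arm_end = loci$star_end) %>%
      filter(!is.na(.data$mir_id))
  )
  prec <- select(loci, "locus_id", "chrom", "genome_start", "genome_end",
                 locus_strand = "strand")

  in_prec <- hits %>%
    rename(chrom = "seq_id") %>%
    inner_join(prec, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$start >= .data$genome_start, .data$end <= .data$genome_end)

  contained_seqs <- unique(in_prec$seq)

  # candidate known-miR calls: annotated strand, precursor-relative coords
  cand <- in_prec %>%
    filter(.data$strand == .data$locus_strand) %>%
    mutate(
      rel_start = ifelse(.data$strand == "+",
                         .data$start - .data$genome_start,
                         .data$genome_end - .data$end),
      rel_end = ifelse(.data$strand == "+",
                       .data$end - .data$genome_start,
                       .data$genome_end - .data$start)
    ) %>%
    inner_join(arm_rows, by = "locus_id", relationship = "many-to-many") %>%
    mutate(
      offset5 = .data$rel_start - .data$arm_start,
      offset3 = .data$rel_end - .data$arm_end,
      seed_lo = .data$arm_start + 1L,   # seed: arm positions 2-8, 0-based
      seed_hi = .data$arm_start + 8L
    ) %>%
    filter(.data$rel_start <= .data$seed_lo, .data$rel_end >= .data$seed_hi,
           abs(.data$offset5) <= max_offset,
           abs(.data$offset3) <= max_offset)

  if (nrow(cand) > 0) {
    cand <- cand %>%
      distinct(.data$seq, .data$locus_id, .data$mir_id, .data$arm,
               .data$offset5, .data$offset3) %>%
      mutate(total_offset = abs(.data$offset5) + abs(.data$offset3)) %>%
      group_by(.data$seq) %>%
      arrange(.data$total_offset, .data$mir_id, .by_group = TRUE) %>%
      mutate(n_best = sum(.data$total_offset == min(.data$total_offset)),
             n_loci = dplyr::n_distinct(.data$locus_id)) %>%
      slice(1) %>%
      ungroup()
    idx <- match(cand$seq, base$seq)
    base$category[idx] <- "known_mir"
    base$locus_id[idx] <- cand$locus_id
    base$mir_id[idx] <- cand$mir_id
    base$arm[idx] <- cand$arm
    base$offset5[idx] <- cand$offset5
    base$offset3[idx] <- cand$offset3
    base$multi_mapper[idx] <- cand$n_loci > 1 & cand$n_best > 1
  }

  rest <- is.na(base$category)
  base$category[rest & base$seq %in% contained_seqs] <- "precursor_other"
  base$category[is.na(base$category)] <- "novel_candidate"
  finish_categories(base)
}

assignment_categories <- function() {
  c("known_mir", "precursor_other", "ncrna", "novel_candidate", "unmapped")
}

finish_categories <- function(base) {
  mutate(base, category = factor(.data$category,
                                 levels = assignment_categories()))
}

#' Annotate the collapsed reads of several libraries
#'
#' Classifies the union of unique sequences once and joins the per-library
#' counts back on, so the result is identical to classifying each library
#' separately.
#'
#' @param collapsed_by_library named list of [collapse_reads()] tibbles, or a
#'   long tibble with a `library` column.
#' @inheritParams classify_reads
#' @return long assignment tibble with a `library` column.
#' @export
annotate_libraries <- function(collapsed_by_library, ref, max_offset = 3) {
  long <- if (is.data.frame(collapsed_by_library)) {
    assert_tbl_cols(collapsed_by_library, c("library", "seq", "count"))
    collapsed_by_library
  } else {
    bind_rows(purrr::imap(collapsed_by_library,
                          function(x, nm) mutate(x, library = nm))) %>%
      select("library", "seq", "count")
  }
  ann <- classify_unique_seqs(unique(long$seq), ref, max_offset)
  long %>% left_join(ann, by = "seq")
}

#' Summarize isomiRs and call the dominant read per miR
#'
#' One record per distinct (miR arm, read sequence) with per-library and
#' total counts. The dominant read of each arm is the sequence with the
#' largest summed count across libraries (ties broken by the
#' lexicographically smallest sequence); `matches_canonical` marks reads
#' identical to the annotated arm sequence (offsets (0,0)).
#'
#' @param assignments long assignment tibble from [annotate_libraries()]
#'   (must contain a `library` column).
#' @return tibble: `mir_id`, `arm`, `seq`, `offset5`, `offset3`,
#'   `total_count`, `n_libraries`, `is_dominant`, `matches_canonical`.
#' @export
summarize_isomirs <- function(assignments) {
  assert_tbl_cols(assignments, c("library", "seq", "count", "category",
                                 "mir_id"), "assignments")
  known <- assignments %>%
    filter(.data$category == "known_mir", !.data$multi_mapper)
  known %>%
    group_by(.data$mir_id, .data$arm, .data$seq,
             .data$offset5, .data$offset3) %>%
    summarise(total_count = sum(.data$count),
              n_libraries = dplyr::n_distinct(.data$library),
              .groups = "drop") %>%
    group_by(.data$mir_id) %>%
    arrange(desc(.data$total_count), .data$seq, .by_group = TRUE) %>%
    mutate(is_dominant = row_number() == 1) %>%
    ungroup() %>%
    mutate(matches_canonical = .data$offset5 == 0L & .data$offset3 == 0L) %>%
    arrange(.data$mir_id, desc(.data$total_count), .data$seq)
}

#' Count unique reads per miR and library
#'
#' The number of distinct read sequences (isomiRs) observed for each miR arm
#' in each library, the per-sample unique-read statistic reported alongside
#' dominant reads.
#'
#' @inheritParams summarize_isomirs
#' @return tibble: `mir_id`, `library`, `n_unique_reads`.
#' @export
unique_read_counts <- function(assignments) {
  assignments %>%
    filter(.data$category == "known_mir", !.data$multi_mapper,
           .data$count > 0) %>%
    group_by(.data$mir_id, .data$library) %>%
    summarise(n_unique_reads = dplyr::n_distinct(.data$seq),
              .groups = "drop")
}

#' Build the miR count matrix
#'
#' Sums known-miR read counts per (arm, library); mature and star arms are
#' separate rows. Multi-mappers are excluded. Arms present in the reference
#' but never observed get zero rows, and libraries with no miR reads keep an
#' all-zero column.
#'
#' @inheritParams summarize_isomirs
#' @param ref the `mirkd_reference` (supplies the full row universe);
#'   optional -- without it only observed arms appear.
#' @param libraries library ids to retain as columns; defaults to those in
#'   `assignments`.
#' @return wide tibble: `mir_id` plus one integer column per library.
#' @export
build_count_matrix <- function(assignments, ref = NULL, libraries = NULL) {
  assert_tbl_cols(assignments, c("library", "count", "category", "mir_id"),
                  "assignments")
  if (is.null(libraries)) libraries <- unique(assignments$library)
  row_ids <- if (!is.null(ref)) {
    c(rbind(ref$loci$mature_id, ref$loci$star_id)) %>%
      (function(x) x[!is.na(x)])
  } else {
    sort(unique(assignments$mir_id[assignments$category == "known_mir"]))
  }
  counts <- assignments %>%
    filter(.data$category == "known_mir", !.data$multi_mapper) %>%
    group_by(.data$mir_id, .data$library) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  grid <- tidyr::expand_grid(mir_id = row_ids, library = libraries)
  grid %>%
    left_join(counts, by = c("mir_id", "library")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    tidyr::pivot_wider(names_from = "library", values_from = "count")
}

#' Per-library mapping summary
#'
#' Read totals per assignment category, mirroring the flowchart tallies
#' (known miR / precursor / ncRNA / novel candidate / unmapped).
#'
#' @inheritParams summarize_isomirs
#' @return tibble: `library`, `category`, `reads`; per-library totals equal
#'   the qualified read counts fed into annotation.
#' @export
mapping_summary <- function(assignments) {
  assignments %>%
    group_by(.data$library, .data$category) %>%
    summarise(reads = sum(.data$count), .groups = "drop")
}

#' Export novel-candidate reads as FASTA
#'
#' Genome-mapped reads matching neither ncRNA nor any annotated precursor
#' are the input a probabilistic novel-miR caller would consume; this writes
#' them with their counts in the headers.
#'
#' @inheritParams summarize_isomirs
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_novel_candidates <- function(assignments, path) {
  nov <- assignments %>%
    filter(.data$category == "novel_candidate") %>%
    group_by(.data$seq) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(desc(.data$count), .data$seq)
  dna <- Biostrings::DNAStringSet(nov$seq)
  names(dna) <- sprintf("novel_%04d count=%d", seq_len(nrow(nov)), nov$count)
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}
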