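test_that("exact index queries match the recorded loci and reject N", {
  sim <- get_tiny_sim()
  idx <- build_exact_index(sim$ref$genome)
  lc <- sim$ref$loci[3, ]
  hits <- query_exact_index(idx, lc$mature_seq)
  # the annotated position is among the hits, on the annotated strand
  g <- if (lc$strand == "+") {
    c(lc$genome_start + lc$mature_start, lc$genome_start + lc$mature_end)
  } else {
    c(lc$genome_end - lc$mature_end, lc$genome_end - lc$mature_start)
  }
  expect_true(any(hits$seq_id == lc$chrom & hits$start == g[1] &
                    hits$end == g[2] & hits$strand == lc$strand))

  expect_equal(nrow(query_exact_index(idx, "ACGTNACGTACGTACGT")), 0)
  expect_error(build_exact_index(character(0)), "empty")
})

test_that("exact index equals a naive substring scan on random queries", {
  withr::local_seed(77)
  subjects <- c(s1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                           collapse = ""),
                s2 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                           collapse = ""))
  idx <- build_exact_index(subjects)
  queries <- c(
    # planted substrings (forward and reverse complement)
    substr(subjects[1], 51, 72), substr(subjects[2], 11, 30),
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(subjects[1], 101, 120)))),
    # random 17-27-mers, mostly absent
    vapply(sample(17:27, 200, TRUE),
           function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                             collapse = ""), character(1))
  )
  for (q in queries) {
    got <- as.data.frame(query_exact_index(idx, q))[, c("seq_id", "start",
                                                        "strand")]
    want <- oracle_scan(q, as.list(subjects))
    got <- got[order(got$seq_id, got$start, got$strand), ]
    want <- want[order(want$seq_id, want$start, want$strand), ]
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
})

test_that("classification hierarchy handles canonical, isomiR and ncRNA reads", {
  sim <- get_tiny_sim()
  ref <- sim$ref
  lc <- ref$loci[1, ]

  a1 <- classify_read(lc$mature_seq, ref)
  expect_equal(as.character(a1$category), "known_mir")
  expect_equal(a1$mir_id, lc$mature_id)
  expect_equal(c(a1$offset5, a1$offset3), c(0L, 0L))

  # 1 nt shorter at the 3' end: the documented dominant-read situation
  a2 <- classify_read(substr(lc$mature_seq, 1, nchar(lc$mature_seq) - 1), ref)
  expect_equal(as.character(a2$category), "known_mir")
  expect_equal(c(a2$offset5, a2$offset3), c(0L, -1L))

  # an ncRNA fragment is excluded from miRs even though it maps to the genome
  frag <- substr(ref$ncrna$seq[1], 5, 26)
  idx <- build_exact_index(ref$genome)
  expect_gt(nrow(query_exact_index(idx, frag)), 0)
  a3 <- classify_read(frag, ref)
  expect_equal(as.character(a3$category), "ncrna")

  # precursor-contained read that misses the arm seed
  prec_frag <- substr(lc$precursor_seq, lc$mature_end - 2,
                      lc$mature_end + 17)
  a4 <- classify_read(prec_frag, ref)
  expect_equal(as.character(a4$category), "precursor_other")

  # random sequence: unmapped
  a5 <- classify_read("TGCATGCTAGCTAGGATCCGAT", ref)
  expect_equal(as.character(a5$category), "unmapped")
})

test_that("zero-noise libraries classify exactly as the sidecar says", {
  pl <- get_zero_noise_pipeline()
  per_read <- dplyr::inner_join(
    dplyr::filter(pl$reads, category == "qualified"),
    dplyr::select(pl$sim$reads, library, read_id, true_class,
                  true_mir = mir_id),
    by = c("library", "read_id"))
  per_read <- dplyr::left_join(
    per_read,
    dplyr::select(pl$assignments, library, insert = seq,
                  assigned = category, assigned_mir = mir_id),
    by = c("library", "insert"))
  expect_true(all(per_read$assigned == "known_mir"))
  expect_identical(per_read$assigned_mir, per_read$true_mir)
})

test_that("assignments are order-invariant and categories exhaustive", {
  pl <- get_tiny_pipeline()
  one_lib <- pl$collapsed[[1]]
  ref <- pl$sim$ref
  a <- classify_reads(one_lib, ref)
  b <- classify_reads(one_lib[sample.int(nrow(one_lib)), ], ref)
  b <- b[match(a$seq, b$seq), ]
  expect_equal(as.character(a$category), as.character(b$category))
  expect_equal(a$mir_id, b$mir_id)
  expect_false(anyNA(a$category))

  # per-library totals conserve qualified reads across categories
  totals <- mapping_summary(pl$assignments) |>
    dplyr::group_by(library) |>
    dplyr::summarise(reads = sum(reads))
  expect_equal(totals$reads,
               pl$filter_stats$qualified[match(totals$library,
                                               pl$filter_stats$library)])
})

test_that("a planted 60/30/10 isomiR mixture yields the 60% dominant read", {
  ref <- get_tiny_sim()$ref
  lc <- ref$loci[2, ]
  canonical <- lc$mature_seq
  minus1 <- substr(canonical, 1, nchar(canonical) - 1)
  plus1 <- substr(lc$precursor_seq, lc$mature_start + 1, lc$mature_end + 1)
  assignments <- classify_reads(
    tibble::tibble(seq = c(minus1, canonical, plus1),
                   count = c(60L, 30L, 10L)), ref) |>
    dplyr::mutate(library = "L1")
  iso <- summarize_isomirs(assignments)
  expect_equal(nrow(iso), 3)
  expect_equal(iso$seq[iso$is_dominant], minus1)
  expect_false(iso$matches_canonical[iso$is_dominant])
  expect_equal(sum(iso$is_dominant), 1)

  # single isomiR present: it is dominant
  solo <- summarize_isomirs(
    classify_reads(tibble::tibble(seq = canonical, count = 5L), ref) |>
      dplyr::mutate(library = "L1"))
  expect_true(solo$is_dominant)
})

test_that("canonical-only simulation gives canonical dominants and unique-read counts", {
  cfg <- zero_noise_config(
    isomir_offset_probs = tibble::tibble(offset5 = 0L, offset3 = 0L,
                                         prob = 1))
  pl <- run_small_rna_pipeline(sim = simulate_study(cfg))
  iso <- summarize_isomirs(pl$assignments)
  dom <- dplyr::filter(iso, is_dominant)
  expect_true(all(dom$matches_canonical))
  expect_true(all(dom$offset5 == 0 & dom$offset3 == 0))
  ucount <- unique_read_counts(pl$assignments)
  expect_true(all(ucount$n_unique_reads == 1))
})

test_that("count matrix equals truth on zero noise and keeps empty columns", {
  pl <- get_zero_noise_pipeline()
  cmp <- compare_to_truth(pl)
  expect_true(cmp$identical)

  # star arms appear as separate rows
  expect_true(any(grepl("\\*$", pl$counts$mir_id)))

  # a library with no miR reads keeps an all-zero column
  ass <- dplyr::filter(pl$assignments, library == pl$samples$library[1])
  ass$count[ass$category == "known_mir"] <- 0L
  ass <- dplyr::filter(ass, category != "known_mir")
  cm <- build_count_matrix(ass, ref = pl$sim$ref,
                           libraries = pl$samples$library[1])
  expect_true(pl$samples$library[1] %in% names(cm))
  expect_true(all(cm[[pl$samples$library[1]]] == 0))
})

test_that("equidistant multi-mappers are flagged and excluded from counts", {
  ref <- make_duplicate_mature_reference()
  shared <- ref$loci$mature_seq[1]
  a <- classify_read(shared, ref)
  expect_equal(as.character(a$category), "known_mir")
  expect_true(a$multi_mapper)
  cm <- build_count_matrix(
    dplyr::mutate(classify_reads(tibble::tibble(seq = shared, count = 10L),
                                 ref), library = "L1"),
    ref = ref)
  expect_true(all(cm$L1 == 0))

  # a read overlapping locus-specific context resolves to the closer locus
  lc <- ref$loci[1, ]
  shifted <- substr(lc$precursor_seq, lc$mature_start + 2,
                    lc$mature_end + 1)  # offsets (+1, +1) only valid at dup-a
  b <- classify_read(shifted, ref)
  expect_equal(as.character(b$category), "known_mir")
  expect_false(b$multi_mapper)
  expect_equal(b$locus_id, "dup-a")
})

test_that("novel candidates are exported as FASTA with counts", {
  pl <- get_tiny_pipeline()
  path <- withr::local_tempfile(fileext = ".fa")
  write_novel_candidates(pl$assignments, path)
  fa <- Biostrings::readDNAStringSet(path)
  nov <- dplyr::filter(pl$assignments, category == "novel_candidate")
  expect_equal(length(fa), length(unique(nov$seq)))
})
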