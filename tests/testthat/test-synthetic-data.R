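test_that("reference construction places arms verbatim and round-trips GFF3", {
  cfg <- sim_config(n_loci = 10, star_fraction = 1, seed = 1)
  ref <- build_reference(cfg)

  # every mature/star sequence is the precursor substring at its interval,
  # and the precursor sits verbatim in the genome at its coordinates
  for (i in seq_len(nrow(ref$loci))) {
    lc <- ref$loci[i, ]
    expect_identical(substr(lc$precursor_seq, lc$mature_start + 1,
                            lc$mature_end), lc$mature_seq)
    gseq <- as.character(Biostrings::subseq(ref$genome[[lc$chrom]],
                                            lc$genome_start + 1,
                                            lc$genome_end))
    expect_identical(gseq, if (lc$strand == "+") lc$precursor_seq else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(lc$precursor_seq))))
  }

  # extracting arm intervals back out of the written bundle reproduces the
  # arm sequences exactly
  dir <- withr::local_tempdir()
  write_reference(ref, dir)
  rr <- read_reference(dir)
  merged <- dplyr::inner_join(ref$loci, rr$loci, by = "locus_id",
                              suffix = c("", ".rt"))
  expect_equal(nrow(merged), 10)
  expect_identical(merged$mature_seq, merged$mature_seq.rt)
  expect_identical(merged$star_seq, merged$star_seq.rt)
})

test_that("reference generation is byte-deterministic given the config", {
  cfg <- sim_config(n_loci = 10, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference(build_reference(cfg), d1)
  write_reference(build_reference(cfg), d2)
  for (f in c("genome.fa", "ncrna.fa", "mirs.gff3")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("a 10-locus all-star reference annotates 20 arm features", {
  cfg <- sim_config(n_loci = 10, star_fraction = 1, seed = 7)
  dir <- withr::local_tempdir()
  write_reference(build_reference(cfg), dir)
  # independent one-line scan of the GFF3
  lines <- readLines(file.path(dir, "mirs.gff3"))
  expect_equal(sum(grepl("\tmiRNA\t", lines, fixed = TRUE)), 20)
  expect_equal(sum(grepl("\tmiRNA_primary_transcript\t", lines,
                         fixed = TRUE)), 10)
})

test_that("oversized requests fail with a sizing error", {
  cfg <- sim_config(n_loci = 300, genome_size = 10000, seed = 1)
  expect_error(build_reference(cfg), "capacity")
})

test_that("truth counts are Poisson in the alpha = 0, no-fold-change limit", {
  cfg <- sim_config(n_pairs = 150, n_loci = 12, dispersion = 0,
                    planted_log2fc = setNames(numeric(0), character(0)),
                    seed = 5)
  ref <- build_reference(cfg)
  truth <- simulate_truth_counts(ref, cfg)
  m <- as.matrix(truth$counts[-1])
  sf <- truth$samples$size_factor_true
  norm <- sweep(m, 2, sf, "/")
  # var(k_j / s_j) = q * mean(1/s) under Poisson; ratio should sit near 1
  ratio <- apply(norm, 1, var) / (rowMeans(norm) * mean(1 / sf))
  keep <- rowMeans(norm) > 5
  expect_gt(median(ratio[keep]), 0.85)
  expect_lt(median(ratio[keep]), 1.15)
})

test_that("a planted log2FC of 3 yields an 8-fold pooled mean ratio", {
  cfg <- sim_config(n_pairs = 5000, n_loci = 10, dispersion = 0.05,
                    planted_log2fc = c("sim-mir-03" = 3), seed = 9)
  ref <- build_reference(cfg)
  truth <- simulate_truth_counts(ref, cfg)
  m <- as.matrix(truth$counts[-1])
  acute <- truth$samples$condition == "acute"
  row <- which(truth$rows$mir_id == "miR-sim-03")
  ratio <- mean(m[row, acute]) / mean(m[row, !acute])
  expect_gt(ratio, 8 * 0.95)
  expect_lt(ratio, 8 * 1.05)
})

test_that("truth and read synthesis are deterministic and self-consistent", {
  cfg <- tiny_config()
  ref <- build_reference(cfg)
  t1 <- simulate_truth_counts(ref, cfg)
  t2 <- simulate_truth_counts(ref, cfg)
  expect_identical(t1, t2)

  sim <- get_tiny_sim()
  # sidecar per-(arm, library) read tallies equal the truth table exactly
  tallies <- sim$reads |>
    dplyr::filter(.data$true_class == "mir") |>
    dplyr::count(.data$mir_id, .data$library)
  truth_long <- tidyr::pivot_longer(sim$truth$counts, -mir_id,
                                    names_to = "library",
                                    values_to = "count") |>
    dplyr::filter(count > 0)
  joined <- dplyr::full_join(tallies, truth_long,
                             by = c("mir_id", "library"))
  expect_false(anyNA(joined$n))
  expect_false(anyNA(joined$count))
  expect_equal(joined$n, joined$count)

  # every pair id occurs in exactly two libraries with opposite conditions
  pairs <- sim$truth$samples |>
    dplyr::count(.data$pair_id, .data$condition)
  expect_true(all(pairs$n == 1))
  expect_equal(sum(pairs$condition == "acute"),
               sum(pairs$condition == "convalescent"))
})

test_that("concentrated offsets and zero noise produce only annotated arms", {
  cfg <- zero_noise_config(
    isomir_offset_probs = tibble::tibble(offset5 = 0L, offset3 = 0L,
                                         prob = 1))
  sim <- simulate_study(cfg)
  arms <- c(sim$ref$loci$mature_seq, stats::na.omit(sim$ref$loci$star_seq))
  expect_true(all(sim$reads$insert %in% arms))
})

test_that("the modal trimmed insert length under default conditions is 22 nt", {
  # at the study scale (50 loci) the abundance-weighted mode is stable
  cfg <- sim_config(n_pairs = 2, n_loci = 50, library_size = 1500, seed = 101)
  sim <- simulate_study(cfg)
  lens <- nchar(sim$reads$insert[sim$reads$expected_filter == "qualified"])
  expect_equal(as.integer(names(which.max(table(lens)))), 22L)
})

test_that("per-library reads are conserved across simulated classes", {
  sim <- get_tiny_sim()
  per_class <- sim$reads |>
    dplyr::count(.data$library, .data$true_class) |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(total = sum(n))
  per_lib <- sim$reads |> dplyr::count(.data$library)
  expect_equal(per_class$total, per_lib$n)
})

test_that("config validation rejects bad noise fractions and wild offsets", {
  expect_error(sim_config(ncrna_fraction = 0.6, junk_fraction = 0.5),
               "sum")
  expect_error(sim_config(n_pairs = 1), "n_pairs")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(
    sim_config(isomir_offset_probs = tibble::tibble(offset5 = 0L,
                                                    offset3 = 9L, prob = 1)),
    "offsets")
})
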