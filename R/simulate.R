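#' Simulate the ground-truth count table
#'
#' Draws the true per-arm, per-library assigned-read counts of the study
#' design. Baseline (convalescent) relative abundances are log-normal across
#' loci; star arms express at 5-15% of their mature arm. Acute means are the
#' convalescent means times `2^log2fc` for planted rows (both arms of a
#' planted locus). Counts are negative-binomial with mean `s_j * q_i(cond)`
#' and variance `mean + alpha * mean^2`; library scaling factors `s_j` are
#' log-normal around 1 (sd 0.15 on the log scale). `alpha = 0` falls back to
#' Poisson.
#'
#' @param ref a `mirkd_reference` from [build_reference()].
#' @param config the same [sim_config()] used to build `ref`.
#' @return object of class `mirkd_truth`: list with `counts` (wide tibble,
#'   `mir_id` x library), `samples` (tibble: `library`, `condition`,
#'   `pair_id`, `size_factor_true`), and `rows` (tibble: `mir_id`,
#'   `locus_id`, `arm`, `log2fc`, `planted_de`).
#' @export
simulate_truth_counts <- function(ref, config) {
  stopifnot(inherits(ref, "mirkd_reference"), inherits(config, "mirkd_config"))
  planted <- config$planted_log2fc
  if (!is.null(planted) &&
      !all(names(planted) %in% ref$loci$locus_id)) {
    abort("planted_log2fc keys must be a subset of reference locus ids")
  }
  with_seed(config$seed + 1L, simulate_truth_impl(ref, config, planted))
}

simulate_truth_impl <- function(ref, config, planted) {
  loci <- ref$loci
  if (is.null(planted)) {
    k <- ceiling(0.1 * nrow(loci))
    planted <- setNames(rep(2, k), sample(loci$locus_id, k))
  }

  base <- rlnorm(nrow(loci), meanlog = 0, sdlog = 1.3)
  star_factor <- runif(nrow(loci), 0.05, 0.15)
  rows <- bind_rows(
    tibble(mir_id = loci$mature_id, locus_id = loci$locus_id, arm = "mature",
           base_weight = base),
    tibble(mir_id = loci$star_id, locus_id = loci$locus_id, arm = "star",
           base_weight = base * star_factor) %>% filter(!is.na(.data$mir_id))
  ) %>%
    mutate(log2fc = unname(ifelse(.data$locus_id %in% names(planted),
                                  planted[.data$locus_id], 0)),
           planted_de = .data$log2fc != 0)

  mir_frac <- 1 - config$ncrna_fraction - config$junk_fraction -
    config$short_long_fraction
  budget <- config$library_size * mir_frac
  # scale so the across-condition average library sums to the miR budget
  avg <- rows$base_weight * (1 + 2^rows$log2fc) / 2
  rows$mu_conv <- rows$base_weight * budget / sum(avg)
  rows$mu_acute <- rows$mu_conv * 2^rows$log2fc

  if (config$paired) {
    samples <- tibble(
      pair_id = rep(sprintf("P%02d", seq_len(config$n_pairs)), each = 2),
      condition = rep(c("acute", "convalescent"), config$n_pairs)
    ) %>% mutate(library = paste0(.data$pair_id, "_",
                                  substr(.data$condition, 1, 4)))
  } else {
    samples <- tibble(
      pair_id = NA_character_,
      condition = rep(c("acute", "control"), each = config$n_pairs),
      library = c(sprintf("KD%02d_acut", seq_len(config$n_pairs)),
                  sprintf("CT%02d_ctrl", seq_len(config$n_pairs)))
    )
  }
  samples$size_factor_true <- exp(rnorm(nrow(samples), 0, 0.15))

  alpha <- config$dispersion
  counts <- matrix(0L, nrow(rows), nrow(samples),
                   dimnames = list(rows$mir_id, samples$library))
  for (j in seq_len(nrow(samples))) {
    mu <- samples$size_factor_true[j] *
      if (samples$condition[j] == "acute") rows$mu_acute else rows$mu_conv
    counts[, j] <- if (alpha > 0) {
      rnbinom(nrow(rows), size = 1 / alpha, mu = mu)
    } else {
      rpois(nrow(rows), mu)
    }
  }
  counts_tbl <- bind_cols(tibble(mir_id = rows$mir_id),
                          as_tibble(counts))
  structure(list(counts = counts_tbl,
                 samples = select(samples, "library", "condition", "pair_id",
                                  "size_factor_true"),
                 rows = select(rows, "mir_id", "locus_id", "arm", "log2fc",
                               "planted_de")),
            class = "mirkd_truth")
}

#' @export
print.mirkd_truth <- function(x, ...) {
  cat("<mirkd_truth>", nrow(x$counts), "miR arms x", nrow(x$samples),
      "libraries;", sum(x$rows$planted_de), "planted DE rows\n")
  invisible(x)
}

draw_offsets <- function(probs, n) {
  idx <- sample.int(nrow(probs), n, replace = TRUE, prob = probs$prob)
  list(o5 = probs$offset5[idx], o3 = probs$offset3[idx])
}

#' Synthesize per-library FASTQ-ready reads with a truth sidecar
#'
#' Turns the truth counts into instrument reads. Each counted read is its
#' arm's sequence modified by an isomiR offset drawn from the configured
#' offset distribution, with the 3' adapter appended and the result padded
#' with random bases (or truncated) to the instrument read length. Noise
#' reads are added per library: ncRNA fragments (17-27 nt substrings of
#' ncRNA records), random unmappable junk (17-27 nt), and inserts outside the
#' length window (10-16 nt and 28-33 nt; long inserts that leave less than
#' the minimum adapter overlap become no-adapter reads). A configurable
#' fraction of otherwise-qualified reads receives one sub-Q10 base. The
#' sidecar columns record each read's true class and the filter category it
#' is constructed to land in.
#'
#' @param truth a `mirkd_truth` from [simulate_truth_counts()].
#' @param ref the matching `mirkd_reference`.
#' @param config the matching [sim_config()].
#' @return object of class `mirkd_sim`: list with `reads` (long tibble:
#'   `library`, `read_id`, `seq`, `qual`, `true_class`, `mir_id`, `offset5`,
#'   `offset3`, `source_id`, `insert`, `expected_filter`), plus the `truth`,
#'   `ref` and `config` that produced it.
#' @export
synthesize_fastq <- function(truth, ref, config) {
  stopifnot(inherits(truth, "mirkd_truth"), inherits(ref, "mirkd_reference"))
  with_seed(config$seed + 2L, synthesize_fastq_impl(truth, ref, config))
}

synthesize_fastq_impl <- function(truth, ref, config) {
  probs <- config$isomir_offset_probs
  rl <- config$read_length
  adapter <- config$adapter_seq
  min_ov <- 6L

  arm_tbl <- truth$rows %>%
    left_join(ref$loci, by = "locus_id") %>%
    mutate(
      arm_start = ifelse(.data$arm == "mature", .data$mature_start,
                         .data$star_start),
      arm_end = ifelse(.data$arm == "mature", .data$mature_end,
                       .data$star_end)
    ) %>%
    select("mir_id", "precursor_seq", "arm_start", "arm_end")

  counts_long <- truth$counts %>%
    tidyr::pivot_longer(-"mir_id", names_to = "library",
                        values_to = "count") %>%
    filter(.data$count > 0)

  libs <- truth$samples$library
  per_lib <- purrr::map(libs, function(lib) {
    lc <- counts_long %>% filter(.data$library == lib) %>%
      left_join(arm_tbl, by = "mir_id")
    idx <- rep(seq_len(nrow(lc)), lc$count)
    n_mir <- length(idx)
    off <- draw_offsets(probs, n_mir)
    ins_start <- lc$arm_start[idx] + off$o5
    ins_end <- lc$arm_end[idx] + off$o3
    if (any(ins_start < 0) || any(ins_end > nchar(lc$precursor_seq[idx]))) {
      abort("isomiR offset runs outside a precursor; check config margins")
    }
    mir <- tibble(
      true_class = "mir",
      mir_id = lc$mir_id[idx],
      source_id = lc$mir_id[idx],
      offset5 = off$o5, offset3 = off$o3,
      insert = substr(lc$precursor_seq[idx], ins_start + 1, ins_end)
    )

    # noise class sizes around the configured fractions of the nominal total
    sf <- truth$samples$size_factor_true[truth$samples$library == lib]
    nominal <- config$library_size * sf
    n_nc <- rpois(1, nominal * config$ncrna_fraction)
    n_junk <- rpois(1, nominal * config$junk_fraction)
    n_sl <- rpois(1, nominal * config$short_long_fraction)
    n_short <- rbinom(1, n_sl, 0.5)
    n_long <- n_sl - n_short

    nc_idx <- sample.int(nrow(ref$ncrna), n_nc, replace = TRUE)
    nc_len <- sample(17:27, n_nc, replace = TRUE)
    nc_max <- nchar(ref$ncrna$seq[nc_idx]) - nc_len
    nc_start <- floor(runif(n_nc) * (nc_max + 1))
    nc <- tibble(
      true_class = rep("ncrna", n_nc),
      mir_id = NA_character_, source_id = ref$ncrna$id[nc_idx],
      offset5 = NA_integer_, offset3 = NA_integer_,
      insert = substr(ref$ncrna$seq[nc_idx], nc_start + 1, nc_start + nc_len)
    )
    junk <- tibble(
      true_class = rep("junk", n_junk),
      mir_id = NA_character_, source_id = NA_character_,
      offset5 = NA_integer_, offset3 = NA_integer_,
      insert = random_dna_vec(sample(17:27, n_junk, replace = TRUE))
    )
    shortr <- tibble(
      true_class = rep("short", n_short),
      mir_id = NA_character_, source_id = NA_character_,
      offset5 = NA_integer_, offset3 = NA_integer_,
      insert = random_dna_vec(sample(10:16, n_short, replace = TRUE))
    )
    longr <- tibble(
      true_class = rep("long", n_long),
      mir_id = NA_character_, source_id = NA_character_,
      offset5 = NA_integer_, offset3 = NA_integer_,
      insert = random_dna_vec(sample(28:33, n_long, replace = TRUE))
    )

    reads <- bind_rows(mir, nc, junk, shortr, longr)
    reads <- reads[sample.int(nrow(reads)), ]
    n <- nrow(reads)
    ins_len <- nchar(reads$insert)

    # assemble instrument read: insert + adapter + random fill, cut to length
    fill_len <- pmax(0L, rl - ins_len - nchar(adapter))
    full <- paste0(reads$insert, adapter,
                   random_dna_vec(fill_len))
    reads$seq <- substr(full, 1, rl)

    qmat <- matrix(pmin(40L, pmax(2L, round(rnorm(n * rl, config$quality_mean,
                                                  config$quality_sd)))),
                   nrow = n)
    # expected filter category, by construction
    adapter_ov <- pmin(nchar(adapter), rl - ins_len)
    expected <- ifelse(adapter_ov < min_ov, "no_adapter",
                ifelse(ins_len < 17, "too_short",
                ifelse(ins_len > 27, "too_long", "qualified")))
    inject <- expected == "qualified" & runif(n) < config$low_quality_fraction
    bad_pos <- sample.int(rl, n, replace = TRUE)
    bad_pos <- pmin(bad_pos, pmax(1L, ins_len))  # inside the insert
    qmat[cbind(which(inject), bad_pos[inject])] <-
      sample(2:9, sum(inject), replace = TRUE)
    expected[inject] <- "low_quality"
    # one pass Phred+33 encoding: one long string, sliced per read
    qual_cat <- intToUtf8(as.integer(t(qmat)) + 33L)
    ends <- seq_len(n) * rl
    reads$qual <- substring(qual_cat, ends - rl + 1, ends)
    reads$expected_filter <- expected
    reads$library <- lib
    reads$read_id <- sprintf("%s_r%06d", lib, seq_len(n))
    select(reads, "library", "read_id", "seq", "qual", "true_class",
           "mir_id", "offset5", "offset3", "source_id", "insert",
           "expected_filter")
  })

  structure(list(reads = bind_rows(per_lib), truth = truth, ref = ref,
                 config = config),
            class = "mirkd_sim")
}

#' @export
print.mirkd_sim <- function(x, ...) {
  cat("<mirkd_sim>", nrow(x$reads), "reads across",
      length(unique(x$reads$library)), "libraries\n")
  invisible(x)
}

#' Write simulated libraries as FASTQ plus truth sidecars
#'
#' One Phred+33 FASTQ and one `<library>_truth.tsv` sidecar per library,
#' plus `samples.tsv` (library, condition, pair id) and
#' `truth_counts.tsv` (the ground-truth count table).
#'
#' @param sim a `mirkd_sim` from [synthesize_fastq()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_fastq_libraries <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lib in unique(sim$reads$library)) {
    r <- sim$reads[sim$reads$library == lib, ]
    dna <- Biostrings::DNAStringSet(setNames(r$seq, r$read_id))
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(lib, ".fastq")),
                                format = "fastq",
                                qualities = Biostrings::BStringSet(r$qual))
    readr::write_tsv(select(r, -"library"),
                     file.path(dir, paste0(lib, "_truth.tsv")))
  }
  readr::write_tsv(sim$truth$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth$counts, file.path(dir, "truth_counts.tsv"))
  invisible(dir)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return tibble with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(read_id = names(x), seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

#' Simulate the full study in one call
#'
#' Convenience wrapper: [build_reference()], [simulate_truth_counts()],
#' [synthesize_fastq()].
#'
#' @param config a [sim_config()].
#' @return a `mirkd_sim`.
#' @export
simulate_study <- function(config = sim_config()) {
  ref <- build_reference(config)
  truth <- simulate_truth_counts(ref, config)
  synthesize_fastq(truth, ref, config)
}
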