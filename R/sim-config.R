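#' Default isomiR offset distribution
#'
#' Joint distribution over (5' offset, 3' offset) pairs used when reads are
#' synthesized from a mature or star arm. Offsets are in nucleotides relative
#' to the annotated ends: `offset5 = read start - arm start`,
#' `offset3 = read end - arm end`, so `offset3 = -1` is a read one base
#' shorter at the 3' end. Whole-blood small RNA data show mostly 3'-terminal
#' isomiR variation, so the defaults put four times more probability on a
#' non-zero 3' offset (0.4) than on a non-zero 5' offset (0.1).
#'
#' @return tibble with columns `offset5`, `offset3`, `prob` summing to 1.
#' @export
default_isomir_probs <- function() {
  p5 <- c("-1" = 0.05, "0" = 0.90, "1" = 0.05)
  p3 <- c("-2" = 0.05, "-1" = 0.15, "0" = 0.60, "1" = 0.15, "2" = 0.05)
  grid <- tidyr::expand_grid(
    offset5 = as.integer(names(p5)),
    offset3 = as.integer(names(p3))
  )
  grid$prob <- unname(p5[as.character(grid$offset5)] *
                        p3[as.character(grid$offset3)])
  grid
}

#' Simulation configuration for the synthetic small RNA study
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode the
#' emulated study design: 12 subjects sampled in matched acute/convalescent
#' pairs, a mini two-chromosome reference with 50 miR loci, ~2000 reads per
#' library (a desk-scale stand-in for multi-million-read libraries that keeps
#' brute-force oracles feasible), negative-binomial counts with dispersion
#' 0.1, and noise fractions chosen so that roughly 86% of reads survive the
#' adapter/length/quality filters and ~75% of all reads are miR-derived,
#' mirroring the percentages such libraries report.
#'
#' @param n_pairs number of subject pairs (acute + convalescent library each);
#'   with `paired = FALSE`, number of libraries per group.
#' @param n_loci number of miR loci on the mini genome (>= 10).
#' @param library_size mean total reads per library.
#' @param planted_log2fc named numeric vector mapping locus ids
#'   (`"sim-mir-<i>"`) to acute-vs-convalescent log2 fold changes, or `NULL`
#'   to plant the default design: 10% of loci up-regulated at log2FC = +2.
#' @param dispersion negative-binomial dispersion alpha (variance =
#'   mean + alpha * mean^2); 0 gives Poisson counts.
#' @param star_fraction fraction of loci with an annotated star arm.
#' @param isomir_offset_probs tibble (`offset5`, `offset3`, `prob`); see
#'   [default_isomir_probs()]. Absolute offsets must be <= 3.
#' @param adapter_seq 3' adapter ligated to every insert (synthetic 21-mer).
#' @param read_length instrument read length in cycles.
#' @param quality_mean,quality_sd per-base Phred model: scores are drawn from
#'   a discretized normal clamped to \[2, 40\].
#' @param low_quality_fraction fraction of otherwise-qualified reads given one
#'   sub-Q10 base, to exercise the quality filter.
#' @param ncrna_fraction fraction of reads drawn from non-coding RNA records.
#' @param junk_fraction fraction of random unmappable reads.
#' @param short_long_fraction fraction of reads with inserts outside the
#'   17-27 nt window (split evenly between short and long).
#' @param n_ncrna number of non-coding RNA records in the reference.
#' @param genome_size total mini-genome size in bases (two chromosomes).
#' @param paired `TRUE` for the matched acute/convalescent design; `FALSE`
#'   generates two independent groups (`acute` vs `control`), the
#'   febrile-control contrast.
#' @param seed integer seed; the generator is fully deterministic given the
#'   config.
#' @return object of class `mirkd_config`.
#' @export
sim_config <- function(n_pairs = 12,
                       n_loci = 50,
                       library_size = 2000,
                       planted_log2fc = NULL,
                       dispersion = 0.1,
                       star_fraction = 0.3,
                       isomir_offset_probs = default_isomir_probs(),
                       adapter_seq = "CAAGTCGGATCGTACGCATAC",
                       read_length = 36,
                       quality_mean = 35,
                       quality_sd = 4,
                       low_quality_fraction = 0.01,
                       ncrna_fraction = 0.10,
                       junk_fraction = 0.03,
                       short_long_fraction = 0.12,
                       n_ncrna = 15,
                       genome_size = 50000,
                       paired = TRUE,
                       seed = 1) {
  if (n_pairs < 2) abort("`n_pairs` must be >= 2")
  if (n_loci < 10) abort("at least 10 miR loci are required")
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  fracs <- c(ncrna_fraction, junk_fraction, short_long_fraction)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) >= 1) {
    abort("noise fractions must lie in [0, 1] and sum to < 1")
  }
  if (low_quality_fraction < 0 || low_quality_fraction > 1) {
    abort("`low_quality_fraction` must lie in [0, 1]")
  }
  if (star_fraction < 0 || star_fraction > 1) {
    abort("`star_fraction` must lie in [0, 1]")
  }
  assert_tbl_cols(isomir_offset_probs, c("offset5", "offset3", "prob"),
                  "isomir_offset_probs")
  if (abs(sum(isomir_offset_probs$prob) - 1) > 1e-8) {
    abort("isomiR offset probabilities must sum to 1")
  }
  if (max(abs(isomir_offset_probs$offset5),
          abs(isomir_offset_probs$offset3)) > 3) {
    abort("isomiR offsets beyond +-3 nt are not representable on the loci")
  }
  if (!grepl("^[ACGT]+$", adapter_seq)) abort("adapter must be over {A,C,G,T}")
  if (!is.null(planted_log2fc) && is.null(names(planted_log2fc))) {
    abort("`planted_log2fc` must be a named vector keyed by locus id")
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs), n_loci = as.integer(n_loci),
      library_size = library_size, planted_log2fc = planted_log2fc,
      dispersion = dispersion, star_fraction = star_fraction,
      isomir_offset_probs = isomir_offset_probs,
      adapter_seq = adapter_seq, read_length = as.integer(read_length),
      quality_mean = quality_mean, quality_sd = quality_sd,
      low_quality_fraction = low_quality_fraction,
      ncrna_fraction = ncrna_fraction, junk_fraction = junk_fraction,
      short_long_fraction = short_long_fraction,
      n_ncrna = as.integer(n_ncrna), genome_size = as.integer(genome_size),
      paired = isTRUE(paired), seed = as.integer(seed)
    ),
    class = "mirkd_config"
  )
}

#' @export
print.mirkd_config <- function(x, ...) {
  cat("<mirkd_config>\n")
  cat("  design     :", if (x$paired) "paired acute/convalescent" else
    "unpaired acute vs control", "-", x$n_pairs, "per group\n")
  cat("  reference  :", x$n_loci, "miR loci,", x$n_ncrna, "ncRNA records,",
      x$genome_size, "bp genome\n")
  cat("  library    :", x$library_size, "reads, dispersion",
      x$dispersion, "\n")
  cat("  noise      : ncRNA", x$ncrna_fraction, "junk", x$junk_fraction,
      "short/long", x$short_long_fraction, "\n")
  cat("  seed       :", x$seed, "\n")
  invisible(x)
}
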