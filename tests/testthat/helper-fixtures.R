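# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_config <- function(...) {
  sim_config(n_pairs = 3, n_loci = 12, library_size = 500, seed = 101, ...)
}

zero_noise_config <- function(...) {
  tiny_config(ncrna_fraction = 0, junk_fraction = 0, short_long_fraction = 0,
              low_quality_fraction = 0, ...)
}

get_tiny_sim <- function() fixture("tiny_sim", function() {
  simulate_study(tiny_config())
})

get_tiny_pipeline <- function() fixture("tiny_pipeline", function() {
  run_small_rna_pipeline(sim = get_tiny_sim())
})

get_zero_noise_pipeline <- function() fixture("zero_noise_pipeline", function() {
  run_small_rna_pipeline(sim = simulate_study(zero_noise_config()))
})

# hand-built two-locus reference whose precursors share one mature sequence,
# to exercise multi-mapper handling; plus one ncRNA record
make_duplicate_mature_reference <- function() {
  mature <- "ACGTACGGTTCAGATACCGTAG"              # 22 nt, shared by both loci
  prec1 <- paste0("GGCCA", "TTGAC", mature, "CCGGATTACCAGGTACCAGTAGGA")
  prec2 <- paste0("AATTG", "CCAGT", mature, "GGATCCAGGACCTTAGACCATGGA")
  ncrna_seq <- paste0("GGGG", strrep("ATCGGCTA", 12), "CCCC")
  flank <- function(n, base = "A") strrep(base, n)
  chr1 <- paste0(flank(50, "T"), prec1, flank(40, "G"), ncrna_seq,
                 flank(50, "T"))
  chr2 <- paste0(flank(60, "C"), prec2, flank(60, "A"))
  genome <- Biostrings::DNAStringSet(c(chrT1 = chr1, chrT2 = chr2))
  loci <- tibble::tibble(
    locus_id = c("dup-a", "dup-b"),
    mature_id = c("miR-dup-a", "miR-dup-b"),
    star_id = NA_character_,
    chrom = c("chrT1", "chrT2"),
    genome_start = c(50L, 60L),
    genome_end = c(50L + nchar(prec1), 60L + nchar(prec2)),
    strand = "+",
    precursor_seq = c(prec1, prec2),
    precursor_len = nchar(c(prec1, prec2)),
    mature_start = 10L, mature_end = 10L + nchar(mature),
    star_start = NA_integer_, star_end = NA_integer_,
    mature_seq = mature, star_seq = NA_character_
  )
  ncrna <- tibble::tibble(id = "nc-test", rna_class = "tRNA", seq = ncrna_seq)
  structure(list(genome = genome, loci = loci, ncrna = ncrna, config = NULL),
            class = "mirkd_reference")
}

# quality string helper: constant Phred
qual_const <- function(len, phred = 35) {
  strrep(intToUtf8(phred + 33), len)
}

# reads tibble shortcut
make_reads <- function(seqs, quals = NULL, phred = 35) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), qual_const, character(1),
                                      phred = phred)
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                 seq = seqs, qual = quals)
}
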