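#' Build the synthetic reference bundle
#'
#' Generates a mini two-chromosome genome that contains every miR precursor
#' and every non-coding RNA record verbatim at recorded, non-overlapping
#' coordinates separated by random flanking sequence. Each locus carries a
#' mature arm (21-23 nt, modal 22) and, for a configurable fraction of loci,
#' a star arm on the same hairpin; arms are placed with >= 3 nt of precursor
#' margin on each side so that isomiR offsets up to +-3 nt stay inside the
#' precursor. Loci are randomly assigned to a genome strand; the genome holds
#' the reverse complement of minus-strand precursors.
#'
#' Coordinates are 0-based half-open internally; [write_reference()] emits
#' 1-based inclusive GFF3.
#'
#' @param config a [sim_config()] object.
#' @return object of class `mirkd_reference`: list with `genome`
#'   (named [Biostrings::DNAStringSet] of 2 chromosomes), `loci` (tibble, one
#'   row per locus), `ncrna` (tibble: `id`, `rna_class`, `seq`) and `config`.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "mirkd_config"))
  with_seed(config$seed, build_reference_impl(config))
}

build_reference_impl <- function(config) {
  n <- config$n_loci
  has_star <- runif(n) < config$star_fraction

  loci <- purrr::map(seq_len(n), function(i) {
    mature_len <- sample(c(21L, 22L, 23L), 1, prob = c(0.1, 0.8, 0.1))
    mature_start <- sample(5:9, 1)            # >= 3 nt 5' margin for isomiRs
    mature_end <- mature_start + mature_len
    if (has_star[i]) {
      star_len <- sample(c(21L, 22L, 23L), 1, prob = c(0.1, 0.8, 0.1))
      star_start <- mature_end + sample(6:10, 1)
      star_end <- star_start + star_len
      prec_len <- star_end + sample(5:9, 1)
    } else {
      star_start <- NA_integer_
      star_end <- NA_integer_
      prec_len <- mature_end + sample(20:30, 1)
    }
    prec_seq <- random_dna(prec_len)
    tibble(
      locus_id = sprintf("sim-mir-%02d", i),
      mature_id = sprintf("miR-sim-%02d", i),
      star_id = if (has_star[i]) sprintf("miR-sim-%02d*", i) else NA_character_,
      precursor_seq = prec_seq,
      precursor_len = prec_len,
      mature_start = mature_start, mature_end = mature_end,
      star_start = star_start, star_end = star_end,
      mature_seq = substr(prec_seq, mature_start + 1, mature_end),
      star_seq = if (has_star[i]) {
        substr(prec_seq, star_start + 1, star_end)
      } else NA_character_,
      strand = sample(c("+", "-"), 1)
    )
  }) %>% bind_rows()

  classes <- c("lincRNA", "rRNA", "snRNA", "snoRNA", "tRNA")
  ncrna <- tibble(
    id = sprintf("ncrna-%02d", seq_len(config$n_ncrna)),
    rna_class = rep_len(classes, config$n_ncrna),
    seq = random_dna_vec(sample(80:300, config$n_ncrna, replace = TRUE))
  )

  # interleave loci and ncRNAs across the two chromosomes with random flanks
  features <- bind_rows(
    tibble(feature_id = loci$locus_id, kind = "locus",
           seq = ifelse(loci$strand == "-",
                        revcomp(loci$precursor_seq), loci$precursor_seq)),
    tibble(feature_id = ncrna$id, kind = "ncrna", seq = ncrna$seq)
  )
  features <- features[sample(nrow(features)), ]
  features$chrom <- rep_len(c("chrS1", "chrS2"), nrow(features))

  chrom_len <- config$genome_size %/% 2L
  placed <- purrr::map(c("chrS1", "chrS2"), function(chr) {
    feats <- features[features$chrom == chr, ]
    gaps <- sample(40:120, nrow(feats) + 1, replace = TRUE)
    need <- sum(nchar(feats$seq)) + sum(gaps)
    if (need > chrom_len) {
      abort(paste0("requested loci/ncRNAs exceed genome capacity on ", chr,
                   " (need ", need, " bp, have ", chrom_len, ")"))
    }
    pieces <- character(2 * nrow(feats) + 1)
    starts <- integer(nrow(feats))
    pos <- 0L
    for (k in seq_len(nrow(feats))) {
      pieces[2 * k - 1] <- random_dna(gaps[k])
      pos <- pos + gaps[k]
      starts[k] <- pos
      pieces[2 * k] <- feats$seq[k]
      pos <- pos + nchar(feats$seq[k])
    }
    pieces[2 * nrow(feats) + 1] <- random_dna(chrom_len - pos)
    list(seq = paste(pieces, collapse = ""),
         placement = tibble(feature_id = feats$feature_id, chrom = chr,
                            genome_start = starts,
                            genome_end = starts + nchar(feats$seq)))
  })
  genome <- Biostrings::DNAStringSet(
    setNames(vapply(placed, `[[`, character(1), "seq"), c("chrS1", "chrS2"))
  )
  placement <- bind_rows(purrr::map(placed, "placement"))

  loci <- loci %>%
    left_join(placement, by = c(locus_id = "feature_id")) %>%
    select("locus_id", "mature_id", "star_id", "chrom", "genome_start",
           "genome_end", "strand", dplyr::everything())

  structure(list(genome = genome, loci = loci, ncrna = ncrna,
                 config = config),
            class = "mirkd_reference")
}

#' @export
print.mirkd_reference <- function(x, ...) {
  cat("<mirkd_reference>\n")
  cat("  genome:", paste(names(x$genome), collapse = ", "), "-",
      sum(Biostrings::width(x$genome)), "bp\n")
  cat("  loci  :", nrow(x$loci), "precursors (",
      sum(!is.na(x$loci$star_id)), "with star arms )\n")
  cat("  ncRNA :", nrow(x$ncrna), "records\n")
  invisible(x)
}

# genomic 0-based half-open interval of an arm given precursor-relative coords
arm_genomic <- function(loci, rel_start, rel_end) {
  plus <- loci$strand == "+"
  start <- ifelse(plus, loci$genome_start + rel_start,
                  loci$genome_end - rel_end)
  end <- ifelse(plus, loci$genome_start + rel_end,
                loci$genome_end - rel_start)
  list(start = start, end = end)
}

#' Convert the reference annotation to a GRanges in miRBase GFF3 dialect
#'
#' One `miRNA_primary_transcript` feature per precursor plus one `miRNA`
#' feature per mature/star arm (with `Derives_from` pointing at the
#' precursor), 1-based inclusive coordinates.
#'
#' @param ref a `mirkd_reference`.
#' @return [GenomicRanges::GRanges] with `type`, `ID`, `Name`, `Derives_from`.
#' @export
reference_granges <- function(ref) {
  loci <- ref$loci
  prim <- tibble(
    chrom = loci$chrom, start = loci$genome_start, end = loci$genome_end,
    strand = loci$strand, type = "miRNA_primary_transcript",
    ID = loci$locus_id, Name = loci$locus_id, Derives_from = NA_character_
  )
  mat_g <- arm_genomic(loci, loci$mature_start, loci$mature_end)
  mat <- tibble(
    chrom = loci$chrom, start = mat_g$start, end = mat_g$end,
    strand = loci$strand, type = "miRNA",
    ID = paste0(loci$locus_id, "_mature"), Name = loci$mature_id,
    Derives_from = loci$locus_id
  )
  st_loci <- loci[!is.na(loci$star_id), ]
  st_g <- arm_genomic(st_loci, st_loci$star_start, st_loci$star_end)
  st <- tibble(
    chrom = st_loci$chrom, start = st_g$start, end = st_g$end,
    strand = st_loci$strand, type = "miRNA",
    ID = paste0(st_loci$locus_id, "_star"), Name = st_loci$star_id,
    Derives_from = st_loci$locus_id
  )
  feats <- bind_rows(prim, mat, st)
  gr <- GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand
  )
  S4Vectors::mcols(gr)$type <- feats$type
  S4Vectors::mcols(gr)$ID <- feats$ID
  S4Vectors::mcols(gr)$Name <- feats$Name
  S4Vectors::mcols(gr)$Derives_from <- feats$Derives_from
  gr
}

#' Write the reference bundle to disk
#'
#' Emits `genome.fa`, `ncrna.fa` (FASTA) and `mirs.gff3` (miRBase-dialect
#' GFF3, 1-based inclusive). Regeneration from the same config is
#' byte-identical.
#'
#' @param ref a `mirkd_reference`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  nc <- Biostrings::DNAStringSet(setNames(ref$ncrna$seq, ref$ncrna$id))
  Biostrings::writeXStringSet(nc, file.path(dir, "ncrna.fa"))
  gff <- file.path(dir, "mirs.gff3")
  rtracklayer::export(reference_granges(ref), gff, format = "gff3")
  # drop the run-date header line so regeneration is byte-identical
  lines <- readLines(gff)
  writeLines(lines[!startsWith(lines, "##date")], gff)
  invisible(dir)
}

#' Read a reference bundle written by [write_reference()]
#'
#' Reconstructs the locus table (precursor, mature and star sequences and
#' precursor-relative arm coordinates) from the genome FASTA and the GFF3
#' annotation, so the on-disk bundle is self-contained.
#'
#' @param dir directory holding `genome.fa`, `ncrna.fa`, `mirs.gff3`.
#' @return a `mirkd_reference` (with `config = NULL`).
#' @export
read_reference <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  nc_set <- Biostrings::readDNAStringSet(file.path(dir, "ncrna.fa"))
  names(nc_set) <- sub("\\s.*$", "", names(nc_set))
  ncrna <- tibble(id = names(nc_set), rna_class = NA_character_,
                  seq = as.character(nc_set))
  gr <- rtracklayer::import(file.path(dir, "mirs.gff3"), format = "gff3")
  md <- S4Vectors::mcols(gr)
  prim <- gr[md$type == "miRNA_primary_transcript"]
  arms <- gr[md$type == "miRNA"]

  genome_sub <- function(chrom, start0, end0, strand) {
    s <- as.character(Biostrings::subseq(genome[[chrom]], start0 + 1, end0))
    if (strand == "-") revcomp(s) else s
  }
  loci <- purrr::map(seq_along(prim), function(i) {
    p <- prim[i]
    pid <- S4Vectors::mcols(p)$ID
    gs <- BiocGenerics::start(p) - 1L
    ge <- BiocGenerics::end(p)
    strand <- as.character(BiocGenerics::strand(p))
    chrom <- as.character(GenomicRanges::seqnames(p))
    children <- arms[S4Vectors::mcols(arms)$Derives_from == pid]
    rel <- function(a) {
      as0 <- BiocGenerics::start(a) - 1L
      ae0 <- BiocGenerics::end(a)
      if (strand == "+") c(as0 - gs, ae0 - gs) else c(ge - ae0, ge - as0)
    }
    is_star <- grepl("\\*$", S4Vectors::mcols(children)$Name)
    mat <- children[!is_star][1]
    st <- if (any(is_star)) children[is_star][1] else NULL
    mrel <- rel(mat)
    srel <- if (!is.null(st)) rel(st) else c(NA_integer_, NA_integer_)
    prec_seq <- genome_sub(chrom, gs, ge, strand)
    tibble(
      locus_id = pid,
      mature_id = S4Vectors::mcols(mat)$Name,
      star_id = if (!is.null(st)) S4Vectors::mcols(st)$Name else NA_character_,
      chrom = chrom, genome_start = gs, genome_end = ge, strand = strand,
      precursor_seq = prec_seq, precursor_len = nchar(prec_seq),
      mature_start = mrel[1], mature_end = mrel[2],
      star_start = srel[1], star_end = srel[2],
      mature_seq = substr(prec_seq, mrel[1] + 1, mrel[2]),
      star_seq = if (!is.null(st)) substr(prec_seq, srel[1] + 1, srel[2])
      else NA_character_
    )
  }) %>% bind_rows()
  structure(list(genome = genome, loci = loci, ncrna = ncrna, config = NULL),
            class = "mirkd_reference")
}
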