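#' Run the full synthetic pipeline end to end
#'
#' Simulates the study (or consumes an existing `mirkd_sim`), preprocesses
#' every library (adapter trimming, length/quality filters, collapsing),
#' annotates reads against the reference and assembles the miR count matrix
#' with per-library filter and mapping summaries.
#'
#' @param config a [sim_config()]; ignored when `sim` is supplied.
#' @param sim optionally, a `mirkd_sim` from [synthesize_fastq()].
#' @return object of class `mirkd_pipeline`: list with `sim`, `reads`
#'   (per-read filter outcomes), `filter_stats`, `collapsed`, `assignments`,
#'   `counts` (wide tibble), `mapping`, `samples`.
#' @export
run_small_rna_pipeline <- function(config = sim_config(), sim = NULL) {
  if (is.null(sim)) sim <- simulate_study(config)
  cfg <- sim$config
  libs <- sim$truth$samples$library
  pre <- purrr::map(libs, function(lib) {
    r <- sim$reads[sim$reads$library == lib, c("read_id", "seq", "qual")]
    preprocess_library(r, cfg$adapter_seq)
  })
  names(pre) <- libs
  reads <- bind_rows(purrr::imap(pre, function(p, nm) {
    mutate(p$reads, library = nm)
  }))
  stats <- bind_rows(purrr::imap(pre, function(p, nm) {
    mutate(p$stats, library = nm, .before = 1)
  }))
  collapsed <- purrr::map(pre, "collapsed")
  assignments <- annotate_libraries(collapsed, sim$ref)
  counts <- build_count_matrix(assignments, ref = sim$ref, libraries = libs)
  structure(list(sim = sim, reads = reads, filter_stats = stats,
                 collapsed = collapsed, assignments = assignments,
                 counts = counts, mapping = mapping_summary(assignments),
                 samples = sim$truth$samples),
            class = "mirkd_pipeline")
}

#' @export
print.mirkd_pipeline <- function(x, ...) {
  cat("<mirkd_pipeline>", length(unique(x$samples$library)), "libraries,",
      nrow(x$counts), "miR arms counted\n")
  invisible(x)
}

#' Compare recovered counts against the planted truth
#'
#' @param pipeline a `mirkd_pipeline`.
#' @return list: `identical` (logical; recovered count matrix equals the
#'   truth table exactly), `truth`, `recovered` (both aligned wide tibbles).
#' @export
compare_to_truth <- function(pipeline) {
  truth <- pipeline$sim$truth$counts %>% arrange(.data$mir_id)
  rec <- pipeline$counts %>%
    select(all_of(names(truth))) %>%
    arrange(.data$mir_id)
  list(identical = isTRUE(all.equal(as.data.frame(truth),
                                    as.data.frame(rec),
                                    check.attributes = FALSE)),
       truth = truth, recovered = rec)
}

#' Read-level assignment accuracy against the simulation sidecar
#'
#' Among miR-derived reads that survive the adapter/length/quality filters,
#' the fraction whose trimmed insert is assigned to the true locus and arm
#' by the classifier. Reads removed by the filters never reach annotation
#' and are excluded from the denominator.
#'
#' @param pipeline a `mirkd_pipeline`.
#' @return one-row tibble: `n_qualified_mir_reads`, `n_correct`, `accuracy`.
#' @export
assignment_accuracy <- function(pipeline) {
  truth_reads <- pipeline$sim$reads %>%
    filter(.data$true_class == "mir") %>%
    select("library", "read_id", true_mir = "mir_id")
  trimmed <- pipeline$reads %>%
    filter(.data$category == "qualified") %>%
    select("library", "read_id", "insert", "category")
  assign_map <- pipeline$assignments %>%
    select("library", seq_assigned = "seq", assigned_category = "category",
           assigned_mir = "mir_id", "multi_mapper")
  joined <- truth_reads %>%
    inner_join(trimmed, by = c("library", "read_id")) %>%
    left_join(assign_map,
              by = c("library", insert = "seq_assigned"))
  correct <- joined$assigned_category == "known_mir" &
    !joined$multi_mapper & joined$assigned_mir == joined$true_mir
  correct[is.na(correct)] <- FALSE
  tibble(n_qualified_mir_reads = nrow(joined),
         n_correct = sum(correct),
         accuracy = sum(correct) / nrow(joined))
}
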