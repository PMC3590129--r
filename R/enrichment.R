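#' Union predicted-target set at a miTG score threshold
#'
#' Genes predicted as a target of at least one of the listed miRs with a
#' miTG score at or above the threshold (inclusive, per the conventional
#' 0.7 cutoff). Scores are consumed as an opaque, precomputed table.
#'
#' @param mir_ids character vector of miR identifiers.
#' @param targets tibble: `mir_id`, `gene_id`, `mitg_score`.
#' @param threshold minimum miTG score (inclusive).
#' @return sorted character vector of unique gene ids. miRs absent from the
#'   table raise a warning and contribute nothing.
#' @export
union_target_set <- function(mir_ids, targets, threshold = 0.7) {
  assert_tbl_cols(targets, c("mir_id", "gene_id", "mitg_score"), "targets")
  if (threshold < 0) abort("`threshold` must be >= 0")
  missing <- setdiff(mir_ids, unique(targets$mir_id))
  if (length(missing) > 0) {
    warn(paste("miR id(s) absent from target table:",
               paste(missing, collapse = ", ")))
  }
  targets %>%
    filter(.data$mir_id %in% mir_ids, .data$mitg_score >= threshold) %>%
    pull("gene_id") %>%
    unique() %>%
    sort()
}

#' One-sided Fisher's exact test for one pathway
#'
#' Upper hypergeometric tail `P(X >= overlap)` for drawing
#' `n_targets_in_universe` genes from a universe of `n_universe` of which
#' `n_pathway` belong to the pathway. Targets are intersected with the
#' universe before testing.
#'
#' @param target_genes character vector of target gene ids.
#' @param pathway_genes character vector; must be a subset of `universe`.
#' @param universe character vector of all genes considered.
#' @return one-row tibble: `n_universe`, `n_pathway`, `n_targets_in_universe`,
#'   `n_overlap`, `p`.
#' @export
fisher_pathway_test <- function(target_genes, pathway_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("the gene universe is empty")
  pathway_genes <- unique(pathway_genes)
  if (!all(pathway_genes %in% universe)) {
    abort("pathway genes must be contained in the universe")
  }
  targets <- intersect(unique(target_genes), universe)
  n_overlap <- length(intersect(targets, pathway_genes))
  p <- phyper(n_overlap - 1, length(pathway_genes),
              length(universe) - length(pathway_genes),
              length(targets), lower.tail = FALSE)
  tibble(n_universe = length(universe), n_pathway = length(pathway_genes),
         n_targets_in_universe = length(targets), n_overlap = n_overlap,
         p = p)
}

#' Pathway over-representation of predicted miR targets
#'
#' Builds the union target set of the given miRs at the miTG threshold,
#' restricts it to the pathway-database universe (the union of all pathway
#' genes), drops pathways smaller than `min_pathway_genes`, scores each
#' remaining pathway with the one-sided Fisher test and returns results
#' sorted by ascending p, with the overlapping genes attached. Raw p-values
#' are reported; set `bh = TRUE` to add a BH-adjusted column.
#'
#' @inheritParams union_target_set
#' @param pathways tibble: `pathway_id`, `gene_id` (one row per pathway
#'   member).
#' @param min_pathway_genes pathways with fewer genes are excluded before
#'   testing.
#' @param bh also report BH-adjusted p-values.
#' @return object of class `mirkd_enrichment` (a tibble: `pathway_id`,
#'   `n_pathway`, `n_overlap`, `p`, optional `p_adj`, `overlap_genes`
#'   list-column) with attributes `n_universe` and `n_targets_in_universe`.
#' @export
run_enrichment <- function(mir_ids, targets, pathways,
                           min_pathway_genes = 10, threshold = 0.7,
                           bh = FALSE) {
  assert_tbl_cols(pathways, c("pathway_id", "gene_id"), "pathways")
  target_set <- union_target_set(mir_ids, targets, threshold)
  universe <- unique(pathways$gene_id)
  sets <- split(pathways$gene_id, pathways$pathway_id)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) >= min_pathway_genes]
  if (length(sets) == 0) {
    warn("no pathway passes the minimum-size filter")
    out <- tibble(pathway_id = character(0), n_pathway = integer(0),
                  n_overlap = integer(0), p = numeric(0),
                  overlap_genes = list())
  } else {
    out <- purrr::imap(sets, function(genes, id) {
      res <- fisher_pathway_test(target_set, genes, universe)
      tibble(pathway_id = id, n_pathway = res$n_pathway,
             n_overlap = res$n_overlap, p = res$p,
             overlap_genes = list(sort(intersect(target_set, genes))))
    }) %>%
      bind_rows() %>%
      arrange(.data$p, .data$pathway_id)
  }
  if (bh) out <- mutate(out, p_adj = bh_adjust(.data$p), .after = "p")
  structure(out, class = c("mirkd_enrichment", class(out)),
            n_universe = length(universe),
            n_targets_in_universe = length(intersect(target_set, universe)),
            threshold = threshold, min_pathway_genes = min_pathway_genes)
}

#' @export
print.mirkd_enrichment <- function(x, ...) {
  cat("<mirkd_enrichment>", nrow(x), "pathways tested;",
      attr(x, "n_targets_in_universe"), "targets in a universe of",
      attr(x, "n_universe"), "genes\n")
  NextMethod()
}
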