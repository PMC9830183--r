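#' Intersect the three detection routes into a putative toolkit set
#'
#' The toolkit is defined as the intersection of the SVM predictor set
#' (common to all focal species) with the network trait-associated set; the
#' differential expression overlap is reported but, being much sparser
#' across species, does not gate the toolkit. All percentages are
#' recomputed from the stored sets with their denominators named.
#'
#' @param svm_set character vector: cross-species common SVM predictors.
#' @param wgcna_set character vector: trait-associated network genes.
#' @param de_set character vector: differential expression overlap genes.
#' @param truth optional `synthetic_truth` for recovery scoring.
#' @return a `toolkit_report`: sets, pairwise/three-way intersections with
#'   sizes and percentages, `toolkit`, and `recovery` when truth is given.
#' @export
build_toolkit <- function(svm_set, wgcna_set, de_set = character(0),
                          truth = NULL) {
  svm_set <- unique(as.character(svm_set))
  wgcna_set <- unique(as.character(wgcna_set))
  de_set <- unique(as.character(de_set))
  if (length(svm_set) == 0 || length(wgcna_set) == 0)
    warning("empty SVM or WGCNA set; toolkit is empty")
  toolkit <- intersect(svm_set, wgcna_set)
  three_way <- intersect(toolkit, de_set)
  pct <- function(part, whole) {
    if (length(whole) == 0) return(NA_real_)
    100 * length(part) / length(whole)
  }
  report <- list(
    svm_predictors = svm_set, wgcna_trait_genes = wgcna_set,
    de_genes = de_set, toolkit = toolkit, three_way = three_way,
    intersections = list(
      svm_wgcna = toolkit,
      svm_de = intersect(svm_set, de_set),
      wgcna_de = intersect(wgcna_set, de_set)),
    percentages = list(
      toolkit_of_svm = pct(toolkit, svm_set),
      toolkit_of_wgcna = pct(toolkit, wgcna_set),
      de_of_svm = pct(intersect(svm_set, de_set), svm_set),
      de_of_wgcna = pct(intersect(wgcna_set, de_set), wgcna_set)))
  if (!is.null(truth))
    report$recovery <- score_recovery(toolkit, truth, role = "toolkit")
  structure(report, class = "toolkit_report")
}

#' @export
print.toolkit_report <- function(x, ...) {
  cat(sprintf("toolkit_report: %d SVM, %d WGCNA, %d DE genes\n",
              length(x$svm_predictors), length(x$wgcna_trait_genes),
              length(x$de_genes)))
  cat(sprintf("  toolkit (SVM ∩ WGCNA): %d genes (%.1f%% of SVM set)\n",
              length(x$toolkit), x$percentages$toolkit_of_svm))
  cat(sprintf("  three-way overlap with DE: %d genes\n", length(x$three_way)))
  if (!is.null(x$recovery))
    cat(sprintf("  recovery vs planted toolkit: precision %.2f recall %.2f\n",
                x$recovery$precision, x$recovery$recall))
  invisible(x)
}

#' Fisher exact term enrichment
#'
#' Per-term one-sided Fisher exact test of the 2x2 table (in term /
#' foreground vs not), the "classic" per-term algorithm without graph
#' decorrelation. Terms with fewer than `min_annotated` background genes
#' are excluded; BH correction across the tested terms.
#'
#' @param foreground character gene ids (must be a subset of background).
#' @param background character gene ids: the analyzed universe.
#' @param term_map data.frame with columns `gene_id`, `term_id` (and
#'   optionally `term_name`).
#' @param min_annotated minimum annotated background genes per term
#'   (default 5).
#' @return data.frame with per-term counts, expected overlap, one-sided
#'   Fisher `p` and `p_adj`.
#' @export
fisher_enrichment <- function(foreground, background, term_map,
                              min_annotated = 5) {
  if (length(foreground) == 0) stop("empty foreground")
  stopifnot(all(foreground %in% background))
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- split(unique(term_map[, c("gene_id", "term_id")])$gene_id,
                 unique(term_map[, c("gene_id", "term_id")])$term_id)
  terms <- terms[vapply(terms, length, 1L) >= min_annotated]
  N <- length(unique(background)); n_fg <- length(unique(foreground))
  rows <- lapply(names(terms), function(t) {
    annot <- terms[[t]]
    k <- length(intersect(annot, foreground))
    tab <- matrix(c(k, length(annot) - k,
                    n_fg - k, N - length(annot) - n_fg + k), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = t, annotated = length(annot), significant = k,
               expected = n_fg * length(annot) / N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term_id = character(0), annotated = integer(0),
               significant = integer(0), expected = numeric(0),
               p = numeric(0))
  out$p_adj <- bh_adjust(out$p)
  if ("term_name" %in% names(term_map)) {
    nm <- unique(term_map[, c("term_id", "term_name")])
    out$term_name <- nm$term_name[match(out$term_id, nm$term_id)]
  }
  out[order(out$p), ]
}
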