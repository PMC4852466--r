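#' Known-interaction lookup table
#'
#' Unordered, case-normalized factor-name pairs (e.g. a BioGRID low-throughput
#' physical-interaction export reduced to two columns).  Self-pairs are
#' dropped; duplicates collapsed.
#'
#' @param pairs data frame whose first two columns are factor names, or a
#'   path to a two-column TSV (comment lines start with `#`).
#' @return an `interaction_table` (environment-free list with a `pairs`
#'   data frame and a `has` lookup function is avoided; plain data frame with
#'   class attribute).
#' @export
interaction_table <- function(pairs) {
  if (is.character(pairs) && length(pairs) == 1L)
    pairs <- utils::read.delim(pairs, header = TRUE, comment.char = "#",
                               stringsAsFactors = FALSE)
  a <- tolower(trimws(as.character(pairs[[1]])))
  b <- tolower(trimws(as.character(pairs[[2]])))
  keep <- a != b & nzchar(a) & nzchar(b)
  key <- unique(paste(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]),
                      sep = "\r"))
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(factor_a = vapply(parts, `[`, "", 1),
                    factor_b = vapply(parts, `[`, "", 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_table", "data.frame")
  out
}

interaction_keys <- function(interactions) {
  a <- tolower(interactions$factor_a); b <- tolower(interactions$factor_b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Label ranked edges against known interactions
#'
#' Applies the evaluation exclusions: edges connecting two data sets of the
#' same factor (even across labs/cell types/treatments) are removed, as are
#' edges with a histone-mark endpoint (histone marks do not appear in
#' protein-protein interaction databases).  The remaining edges are filtered
#' by cell-type scope and labeled 1 when the factor pair is a known
#' interaction.  The result is sorted by weight, descending (the ranking
#' statistic is whatever `weight` already encodes).
#'
#' @param edges data frame with columns `a`, `b` (dataset ids) and `weight`.
#' @param metadata an [experiment_metadata()].
#' @param interactions an [interaction_table()] (or data frame / path
#'   coercible to one).
#' @param scope `"all"`, `"within_cell_type"` (drop edges whose endpoints are
#'   in different cell types), or `"cross_cell_type"` (keep only those).
#' @return the filtered edges with extra columns `factor_a`, `factor_b`,
#'   `label`, sorted by decreasing weight.
#' @export
label_edges <- function(edges, metadata, interactions,
                        scope = c("all", "within_cell_type",
                                  "cross_cell_type")) {
  scope <- match.arg(scope)
  if (!inherits(interactions, "interaction_table"))
    interactions <- interaction_table(interactions)
  ia <- match(edges$a, metadata$id)
  ib <- match(edges$b, metadata$id)
  if (anyNA(ia) || anyNA(ib))
    stop("unknown dataset id(s): ",
         paste(unique(c(edges$a[is.na(ia)], edges$b[is.na(ib)])),
               collapse = ", "))
  fa <- tolower(metadata$factor[ia]); fb <- tolower(metadata$factor[ib])
  keep <- fa != fb
  histone <- metadata$target_class == "histone_mark"
  keep <- keep & !histone[ia] & !histone[ib]
  if (scope == "within_cell_type")
    keep <- keep & metadata$cell_type[ia] == metadata$cell_type[ib]
  else if (scope == "cross_cell_type")
    keep <- keep & metadata$cell_type[ia] != metadata$cell_type[ib]
  out <- edges[keep, , drop = FALSE]
  fa <- fa[keep]; fb <- fb[keep]
  key <- paste(pmin(fa, fb), pmax(fa, fb), sep = "\r")
  out$factor_a <- fa
  out$factor_b <- fb
  out$label <- as.integer(key %in% interaction_keys(interactions))
  out[order(-out$weight), , drop = FALSE]
}

#' Fold enrichment of true edges among top predictions
#'
#' `TP * N_total / (n_predictions * n_interactions)`, i.e. the number of
#' correct edges in the prediction set divided by the expected number in a
#' random set of the same size.  Equivalently
#' `TP * N / ((TP + FP) (TP + FN))`, which is inversely proportional to both
#' the type I and type II error counts.
#'
#' @param tp number of true positives among the predictions.
#' @param n_predictions size of the prediction set (TP + FP).
#' @param n_interactions total number of known interactions in the edge
#'   universe (TP + FN).
#' @param n_total total number of candidate edges.
#' @return fold enrichment (>= 0).
#' @export
fold_enrichment <- function(tp, n_predictions, n_interactions, n_total) {
  stopifnot(n_predictions <= n_total, n_interactions <= n_total,
            tp <= n_predictions, tp <= n_interactions)
  if (n_predictions == 0 || n_interactions == 0)
    stop("fold enrichment undefined: zero predictions or zero interactions")
  tp * n_total / (n_predictions * n_interactions)
}

#' Enrichment-versus-N curve for a labeled ranked edge list
#'
#' For each N in the grid, the fold enrichment of the top-N edges by the
#' ranking statistic.  The random-background expectation is computed
#' analytically (the hypergeometric mean `N * n_interactions / N_total`),
#' which matches sampling random edge sets in expectation while keeping the
#' curve deterministic.
#'
#' @param labeled output of [label_edges()] (needs a 0/1 `label` column,
#'   rows already ranked) -- rows are re-sorted by `weight` if present.
#' @param n_grid evaluation grid (default: every N from 1 to the number of
#'   edges).
#' @return an `enrichment_result`: list with `n_grid`, `fold`, `tp`,
#'   `n_interactions`, `n_total`, and `auc` (mean fold over the grid).
#' @export
enrichment_curve <- function(labeled, n_grid = NULL) {
  if (nrow(labeled) == 0) stop("empty edge list")
  lab <- if (!is.null(labeled$weight))
    labeled$label[order(-labeled$weight)] else labeled$label
  n_total <- length(lab)
  n_int <- sum(lab)
  if (is.null(n_grid)) n_grid <- seq_len(n_total)
  if (n_int == 0) stop("no true interactions among the labeled edges")
  tp <- cumsum(lab)[n_grid]
  fold <- tp * n_total / (n_grid * n_int)
  structure(list(n_grid = n_grid, fold = fold, tp = tp,
                 n_interactions = n_int, n_total = n_total,
                 auc = mean(fold)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d edges, %d true, AUC (mean fold) %.3f\n",
              x$n_total, x$n_interactions, x$auc))
  invisible(x)
}

#' Factor-level bootstrap comparison of ranked edge lists
#'
#' Resamples regulatory factors with replacement; every time a factor is
#' drawn, *all* of its data sets enter the replicate (multiplicity
#' preserved), so an edge between factors with multiplicities m_a and m_b is
#' replicated m_a * m_b times.  Resampling factors rather than edges keeps
#' the replicates honest: edges sharing a data set do not vary
#' independently.  Per replicate, the area under the enrichment-versus-N
#' curve is computed for each method; the reported p-value for each
#' incumbent is the fraction of replicates in which the challenger fails to
#' outperform it (ties count against the challenger -- conservative).
#'
#' @param rankings named list (>= 2) of labeled edge lists from
#'   [label_edges()], all over the same edge universe.
#' @param metadata an [experiment_metadata()] (defines the factor of each
#'   dataset).
#' @param challenger name of the method being tested (default: first).
#' @param n_reps number of bootstrap replicates.
#' @param seed integer seed.
#' @return a `bootstrap_comparison`: list with `auc` (n_reps x methods
#'   matrix), `p_values` (named, one per incumbent), `challenger`, `n_reps`,
#'   `seed`.
#' @export
bootstrap_compare <- function(rankings, metadata,
                              challenger = names(rankings)[1],
                              n_reps = 100L, seed = 1L) {
  stopifnot(length(rankings) >= 2, challenger %in% names(rankings))
  facs <- unique(tolower(metadata$factor))
  if (length(facs) < 2) stop("need at least 2 distinct factors to bootstrap")
  set.seed(seed)
  auc <- matrix(NA_real_, n_reps, length(rankings),
                dimnames = list(NULL, names(rankings)))
  for (r in seq_len(n_reps)) {
    draw <- sample(facs, replace = TRUE)
    mult <- table(draw)
    for (m in names(rankings)) {
      el <- rankings[[m]]
      ma <- as.integer(mult[el$factor_a]); ma[is.na(ma)] <- 0L
      mb <- as.integer(mult[el$factor_b]); mb[is.na(mb)] <- 0L
      reps <- ma * mb
      if (sum(reps) == 0 || sum(el$label * reps) == 0) {
        auc[r, m] <- 0
        next
      }
      idx <- rep.int(seq_len(nrow(el)), reps)
      boot <- el[idx, c("weight", "label")]
      auc[r, m] <- enrichment_curve(boot)$auc
    }
  }
  others <- setdiff(names(rankings), challenger)
  p <- vapply(others, function(m)
    mean(auc[, challenger] <= auc[, m]), numeric(1))
  structure(list(auc = auc, p_values = p, challenger = challenger,
                 n_reps = n_reps, seed = seed),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("bootstrap_comparison: challenger '%s', %d replicates\n",
              x$challenger, x$n_reps))
  for (m in names(x$p_values))
    cat(sprintf("  vs %s: P = %.4f\n", m, x$p_values[m]))
  invisible(x)
}

#' Label a ranked edge list against simulation ground truth
#'
#' The simulated-data analogue of [label_edges()]: the evaluation universe is
#' all cross-complex data-set pairs, and an edge is true when the two data
#' sets are joined by a nonzero generative precision entry.  Complex labels
#' are attached as the factor columns so [bootstrap_compare()] resamples
#' complexes as units.
#'
#' @param edges data frame with columns `a`, `b` (dataset ids), `weight`.
#' @param sim a [simulate_counts()] result.
#' @return edges with `factor_a`, `factor_b` (complex labels) and `label`,
#'   sorted by decreasing weight.
#' @export
label_simulated_edges <- function(edges, sim) {
  md <- sim$metadata
  ia <- match(edges$a, md$id); ib <- match(edges$b, md$id)
  if (anyNA(ia) || anyNA(ib)) stop("unknown dataset id(s) in edges")
  keep <- md$factor[ia] != md$factor[ib]   # drop within-complex pairs
  out <- edges[keep, , drop = FALSE]
  out$factor_a <- tolower(md$factor[ia[keep]])
  out$factor_b <- tolower(md$factor[ib[keep]])
  tkey <- paste(pmin(sim$true_edges$a, sim$true_edges$b),
                pmax(sim$true_edges$a, sim$true_edges$b))
  out$label <- as.integer(paste(pmin(out$a, out$b),
                                pmax(out$a, out$b)) %in% tkey)
  out[order(-out$weight), , drop = FALSE]
}

#' Rank factors by association with enhancer marks
#'
#' For each non-histone factor in a cell type, sums the pair edge weights
#' between its data sets and the data sets of the enhancer-flanking histone
#' marks (H3K27ac and H3K4me1 by default) in that cell type.  Factors are
#' ranked descending; EP300-like enhancer binders should rank near the top.
#'
#' @param pair_edges output of [pair_edge_weights()].
#' @param metadata an [experiment_metadata()].
#' @param marks histone-mark factor names (case-insensitive).
#' @param cell_type cell type to restrict to.
#' @return data frame with columns `factor` and `score`, sorted descending.
#' @export
enhancer_association <- function(pair_edges, metadata,
                                 marks = c("H3K27ac", "H3K4me1"),
                                 cell_type) {
  md <- metadata
  md$fac <- tolower(md$factor)
  marks <- tolower(marks)
  in_ct <- md$cell_type == cell_type
  for (m in marks)
    if (!any(in_ct & md$fac == m))
      stop("mark '", m, "' not measured in cell type '", cell_type, "'")
  mark_ids <- md$id[in_ct & md$fac %in% marks]
  cand <- md[in_ct & !md$fac %in% marks &
               md$target_class != "histone_mark", ]
  scores <- vapply(unique(cand$fac), function(f) {
    f_ids <- cand$id[cand$fac == f]
    sel <- (pair_edges$a %in% f_ids & pair_edges$b %in% mark_ids) |
      (pair_edges$b %in% f_ids & pair_edges$a %in% mark_ids)
    sum(pair_edges$weight[sel])
  }, numeric(1))
  out <- data.frame(factor = unique(cand$fac), score = scores,
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}
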