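#' Rank-one leave-one-out update of an inverse correlation matrix
#'
#' Given the inverse correlation matrix `theta` of population-standardized
#' data and the scaled sample vector `u = standardized sample / sqrt(n)`,
#' returns the inverse of the correlation matrix recomputed *without* that
#' sample, under the assumption that removing one sample does not change the
#' column means or standard deviations.  Uses the Woodbury identity for the
#' rank-one downdate plus a diagonal renormalization:
#' `theta_bar = D (theta - v v' / (u'v - 1)) D` with `v = theta u` and
#' `D_ii = sqrt(1 - u_i^2)`.
#'
#' @param theta inverse correlation matrix.
#' @param u length-p scaled sample vector; all `|u_i| < 1` required.
#' @param tol degeneracy tolerance for `u'v - 1`.
#' @return the leave-one-out inverse correlation matrix.
#' @export
loo_inverse <- function(theta, u, tol = 1e-12) {
  u <- as.numeric(u)
  if (length(u) != nrow(theta)) stop("u has wrong length")
  if (any(!is.finite(u))) stop("u must be finite")
  if (any(abs(u) >= 1))
    stop("|u_i| >= 1: sample carries all of a column's variance; ",
         "cannot remove it (only possible at tiny n)")
  v <- as.numeric(theta %*% u)
  utv <- sum(u * v)
  if (abs(utv - 1) < tol)
    stop("degenerate leave-one-out update: u'v = 1")
  d <- sqrt(1 - u^2)
  tb <- theta - tcrossprod(v) / (utv - 1)
  tb <- tb * tcrossprod(d)
  (tb + t(tb)) / 2
}

#' Per-bin influence of the genome on a group edge
#'
#' For every genomic bin s, computes the difference between the group-edge
#' weight with the bin included and with the bin removed (via
#' [loo_inverse()], restricted to the entries the group-edge sum needs).
#' Positive influence means the bin strengthens the signed edge weight.  The
#' computation is O(p^2) per bin and never materializes a per-bin p x p
#' matrix for all bins at once.
#'
#' Bins whose scaled sample vector is degenerate (`|u_i| >= 1` or
#' `u'v = 1`, possible only at tiny n) get `NA` influence and are counted in
#' a warning.
#'
#' @param model a [network_model()] fit on `counts`.
#' @param counts the [binned_counts()] (or matrix) the model was fit on.
#' @param edge list of two disjoint member index vectors (into the model's
#'   retained columns), or two dataset id vectors.
#' @return a `context_scores`: list with `influence` (length-n vector),
#'   `edge`, `edge_weight` (full-data group-edge weight), `bins` (if
#'   available).
#' @export
edge_context <- function(model, counts, edge) {
  x <- if (inherits(counts, "binned_counts")) counts$counts else as.matrix(counts)
  x <- x[, model$kept, drop = FALSE]
  edge <- lapply(edge, function(g) {
    if (is.character(g)) match(g, model$dataset_ids) else as.integer(g)
  })
  if (any(is.na(unlist(edge)))) stop("edge references unknown data sets")
  g <- edge[[1]]; h <- edge[[2]]
  if (length(intersect(g, h)) > 0) stop("edge groups must be disjoint")
  theta <- model$theta
  n <- model$n_samples
  if (nrow(x) != n) stop("counts do not match the model's sample count")
  xt <- apply_transform(x, model$transform)
  U <- sweep(sweep(xt, 2, model$means, "-"), 2, model$sds, "/") / sqrt(n)
  V <- U %*% theta
  den <- rowSums(U * V) - 1
  D <- sqrt(pmax(1 - U^2, 0))
  bad <- (rowSums(abs(U) >= 1) > 0) | (abs(den) < 1e-12)
  M <- theta[g, h, drop = FALSE]
  t1 <- rowSums((D[, g, drop = FALSE] %*% M) * D[, h, drop = FALSE])
  sg <- rowSums(D[, g, drop = FALSE] * V[, g, drop = FALSE])
  sh <- rowSums(D[, h, drop = FALSE] * V[, h, drop = FALSE])
  g_full <- sum(M)
  infl <- g_full - (t1 - sg * sh / den)
  if (any(bad)) {
    warning(sum(bad), " degenerate bin(s) received NA influence")
    infl[bad] <- NA_real_
  }
  structure(list(influence = infl, edge = edge, edge_weight = g_full,
                 bins = if (inherits(counts, "binned_counts")) counts$bins),
            class = "context_scores")
}

#' @export
print.context_scores <- function(x, ...) {
  cat(sprintf("context_scores: %d bins, edge weight %.4g\n",
              length(x$influence), x$edge_weight))
  invisible(x)
}

#' Overlap of top influence bins with each data set's top count bins
#'
#' Takes the k bins with the largest influence on the edge (by default in
#' the direction of the edge's own sign, so for a negative edge the most
#' edge-strengthening bins are the most negative influences) and intersects
#' them with each data set's top-k bins by raw count.  Ties are broken by bin
#' index.  Data sets whose counts are constant have a degenerate ranking and
#' trigger a warning.
#'
#' @param scores an [edge_context()] result.
#' @param counts [binned_counts()] or matrix of candidate data sets (need not
#'   be the model's own columns; held-out experiments are the typical use).
#' @param k number of top bins (default 1000).
#' @param direction `"edge_sign"` (default), `"positive"`, `"negative"`, or
#'   `"abs"`.
#' @return named integer vector of overlap sizes, sorted descending.
#' @export
top_context_overlap <- function(scores, counts, k = 1000L,
                                direction = c("edge_sign", "positive",
                                              "negative", "abs")) {
  direction <- match.arg(direction)
  x <- if (inherits(counts, "binned_counts")) counts$counts else as.matrix(counts)
  s <- scores$influence
  if (k > length(s)) stop("k exceeds the number of bins")
  sc <- switch(direction,
               edge_sign = s * if (scores$edge_weight < 0) -1 else 1,
               positive = s,
               negative = -s,
               abs = abs(s))
  sc[is.na(sc)] <- -Inf
  top_edge <- order(-sc, seq_along(sc))[seq_len(k)]
  const <- apply(x, 2, function(col) length(unique(col)) == 1)
  if (any(const))
    warning("constant count column(s) have degenerate rankings: ",
            paste(colnames(x)[const], collapse = ", "))
  ov <- vapply(seq_len(ncol(x)), function(j) {
    top_j <- order(-x[, j], seq_len(nrow(x)))[seq_len(k)]
    length(intersect(top_edge, top_j))
  }, integer(1))
  names(ov) <- colnames(x)
  ov[order(-ov)]
}
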