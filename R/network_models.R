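#' Standardize a count matrix
#'
#' Applies an optional element-wise variance-stabilizing transform and then
#' standardizes every column to mean 0 and *population* variance 1 (divide by
#' n, not n - 1).  Population normalization is deliberate: it makes the
#' rank-one leave-one-out update of [loo_inverse()] exact with
#' `u = standardized sample / sqrt(n)`.  Zero-variance columns cannot be
#' standardized; they are dropped with a warning and recorded in the result.
#'
#' @param counts a [binned_counts()] or a numeric matrix (bins x data sets).
#' @param transform `"raw"` (default, recommended for binned ChIP-seq
#'   counts), `"sqrt"` or `"asinh"`.
#' @return list with `x` (standardized matrix), `means`, `sds` (population),
#'   `kept` (original column indices retained), `dropped`, `transform`,
#'   `n_samples`, `dataset_ids`.
#' @export
standardize <- function(counts, transform = c("raw", "sqrt", "asinh")) {
  transform <- match.arg(transform)
  x <- if (inherits(counts, "binned_counts")) counts$counts else as.matrix(counts)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(ncol(x)))
  xt <- apply_transform(x, transform)
  n <- nrow(xt)
  means <- colMeans(xt)
  xc <- sweep(xt, 2, means, "-")
  sds <- sqrt(colSums(xc^2) / n)
  dropped <- which(sds == 0 | !is.finite(sds))
  if (length(dropped) == ncol(xt))
    stop("all columns are constant; nothing to standardize")
  if (length(dropped) > 0) {
    warning("dropping zero-variance column(s): ",
            paste(ids[dropped], collapse = ", "))
    xc <- xc[, -dropped, drop = FALSE]
    means_k <- means[-dropped]; sds_k <- sds[-dropped]
    kept <- setdiff(seq_along(ids), dropped)
  } else {
    means_k <- means; sds_k <- sds
    kept <- seq_along(ids)
  }
  xs <- sweep(xc, 2, sds_k, "/")
  list(x = xs, means = means_k, sds = sds_k, kept = kept, dropped = dropped,
       transform = transform, n_samples = n, dataset_ids = ids[kept])
}

apply_transform <- function(x, transform) {
  switch(transform, raw = x, sqrt = sqrt(x), asinh = asinh(x))
}

#' Sample correlation matrix of standardized columns
#'
#' With population-standardized columns this is `crossprod(x) / n`, a true
#' correlation matrix (unit diagonal, entries in \[-1, 1\]).
#'
#' @param std output of [standardize()], or a standardized matrix.
#' @return p x p correlation matrix.
#' @export
correlation_network <- function(std) {
  x <- if (is.list(std)) std$x else std
  n <- nrow(x)
  if (n < 2) stop("need at least 2 samples")
  sigma <- crossprod(x) / n
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- 1
  sigma[sigma > 1] <- 1
  sigma[sigma < -1] <- -1
  sigma
}

#' Inverse sample correlation matrix
#'
#' Edge weight between data sets i != j is `theta[i, j]`; a zero entry means
#' conditional independence given all other data sets (in the Gaussian
#' approximation).  No silent regularization is applied: an ill-conditioned
#' input with `ridge = 0` is an error, because any ridge changes the
#' group-edge weights downstream.
#'
#' @param sigma correlation matrix.
#' @param ridge non-negative value added to the diagonal before inversion
#'   (default 0).
#' @param max_condition maximum allowed (reciprocal-condition-based)
#'   condition number.
#' @return symmetric p x p inverse correlation matrix.
#' @export
inverse_correlation_network <- function(sigma, ridge = 0, max_condition = 1e12) {
  stopifnot(ridge >= 0)
  s <- as.matrix(sigma)
  if (ridge > 0) diag(s) <- diag(s) + ridge
  rc <- rcond(s)
  if (!is.finite(rc) || rc < 1 / max_condition)
    stop("correlation matrix is singular or ill-conditioned (rcond = ",
         format(rc), "); consider a ridge > 0 or removing duplicate columns")
  theta <- tryCatch(chol2inv(chol(s)), error = function(e) solve(s))
  theta <- (theta + t(theta)) / 2
  dimnames(theta) <- dimnames(sigma)
  theta
}

#' Partial correlation matrix from an inverse correlation matrix
#'
#' `P = -D^{-1/2} theta D^{-1/2}` where `D` is the diagonal of `theta`.
#' The diagonal of `P` is -1 by convention.
#'
#' @param theta inverse correlation matrix with strictly positive diagonal.
#' @return partial correlation matrix.
#' @export
partial_correlation_network <- function(theta) {
  d <- diag(theta)
  if (any(d <= 0)) stop("inverse correlation diagonal must be positive")
  p <- -theta / sqrt(outer(d, d))
  p <- (p + t(p)) / 2
  diag(p) <- -1
  dimnames(p) <- dimnames(theta)
  p
}

#' Hierarchical groups of correlated data sets
#'
#' Complete-linkage agglomerative clustering on distance `1 - correlation`.
#' All `p` leaves and all `p - 1` internal merge nodes form the group
#' candidates; a multi-member group is retained only when the minimum
#' pairwise correlation among its members is strictly greater than `rho`
#' (default 0.8).  Groups with lower internal correlation are unlikely to
#' cause collinearity problems and would only blur edges.
#'
#' @param sigma correlation matrix.
#' @param rho retention threshold on the minimum within-group correlation.
#' @return a `group_tree`: list with `nodes` (each with `members`, `children`,
#'   `min_corr`), `p`, `rho`, `retained` (node indices), `dataset_ids`.
#' @export
build_groups <- function(sigma, rho = 0.8) {
  p <- nrow(sigma)
  ids <- colnames(sigma)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  nodes <- vector("list", 2 * p - 1)
  for (i in seq_len(p))
    nodes[[i]] <- list(members = i, children = NULL, min_corr = 1)
  if (p > 1) {
    d <- stats::as.dist(pmax(1 - sigma, 0))
    hc <- stats::hclust(d, method = "complete")
    for (k in seq_len(p - 1)) {
      ch <- ifelse(hc$merge[k, ] < 0, -hc$merge[k, ], p + hc$merge[k, ])
      members <- sort(c(nodes[[ch[1]]]$members, nodes[[ch[2]]]$members))
      sub <- sigma[members, members, drop = FALSE]
      nodes[[p + k]] <- list(members = members, children = ch,
                             min_corr = min(sub[upper.tri(sub)]))
    }
  }
  min_corr <- vapply(nodes, `[[`, numeric(1), "min_corr")
  retained <- which(seq_along(nodes) <= p | min_corr > rho)
  structure(list(nodes = nodes, p = p, rho = rho, retained = retained,
                 dataset_ids = ids),
            class = "group_tree")
}

#' @export
print.group_tree <- function(x, ...) {
  nm <- sum(x$retained > x$p)
  cat(sprintf("group_tree: %d data sets, %d nodes, %d retained (%d multi-member at rho > %g)\n",
              x$p, length(x$nodes), length(x$retained), nm, x$rho))
  invisible(x)
}

#' Group graphical model network
#'
#' The weight of an edge between two disjoint groups is the sum of
#' inverse-correlation entries between their members:
#' `G[i, j] = sum(theta[g_i, g_j])`.  For singleton groups this reduces to the
#' plain inverse-correlation edge.  Pairs of overlapping groups (shared
#' members, including ancestor/descendant pairs in the tree) have no defined
#' conditional-dependence weight and are set to `NA`.
#'
#' @param theta inverse correlation matrix.
#' @param tree a [build_groups()] result (its retained groups are used).
#' @return a `group_network`: list with `G` (q' x q' weight matrix, `NA` for
#'   overlapping pairs and the diagonal), `members` (list of member indices
#'   per retained group), `group_ids`, `min_corr`, `tree`.
#' @export
group_network <- function(theta, tree) {
  ret <- tree$retained
  q <- length(ret)
  members <- lapply(tree$nodes[ret], `[[`, "members")
  gid <- vapply(seq_len(q), function(i) {
    m <- members[[i]]
    if (length(m) == 1) tree$dataset_ids[m]
    else paste0("[", paste(tree$dataset_ids[m], collapse = "+"), "]")
  }, character(1))
  G <- matrix(NA_real_, q, q, dimnames = list(gid, gid))
  for (i in seq_len(q - 1)) {
    for (j in seq(i + 1, q)) {
      gi <- members[[i]]; gj <- members[[j]]
      if (length(intersect(gi, gj)) == 0) {
        w <- sum(theta[gi, gj])
        G[i, j] <- w
        G[j, i] <- w
      }
    }
  }
  structure(list(G = G, members = members, group_ids = gid,
                 min_corr = vapply(tree$nodes[ret], `[[`, numeric(1), "min_corr"),
                 tree = tree),
            class = "group_network")
}

#' @export
print.group_network <- function(x, ...) {
  cat(sprintf("group_network: %d groups, %d defined edges\n",
              length(x$members), sum(!is.na(x$G[upper.tri(x$G)]))))
  invisible(x)
}

#' Per-dataset-pair edge weights from a group network
#'
#' For every unordered pair of data sets (a, b), takes the maximum of the
#' ranking statistic over all disjoint retained group pairs (g containing a,
#' h containing b) in which both groups are *factor-pure* (all members share
#' one ChIP target, case-insensitive).  This scores exactly one edge per
#' data-set pair, comparable across methods, while letting group edges rescue
#' pairs whose single-variable edges are destroyed by redundancy.  Pairs with
#' no eligible group pair are omitted.
#'
#' @param gnet a [group_network()].
#' @param metadata an [experiment_metadata()] covering all data sets.
#' @param statistic `"signed"` (default; ranks positive co-localization
#'   first) or `"abs"` (magnitude).
#' @return data frame with columns `a`, `b` (dataset ids), `weight` (the
#'   signed group-edge weight attaining the maximum statistic).
#' @export
pair_edge_weights <- function(gnet, metadata, statistic = c("signed", "abs")) {
  statistic <- match.arg(statistic)
  ids <- gnet$tree$dataset_ids
  if (!all(ids %in% metadata$id))
    stop("metadata does not cover all data sets")
  fac <- tolower(metadata$factor[match(ids, metadata$id)])
  members <- gnet$members
  q <- length(members)
  pure <- vapply(members, function(m) length(unique(fac[m])) == 1, logical(1))
  p <- length(ids)
  best <- matrix(-Inf, p, p)
  wmat <- matrix(NA_real_, p, p)
  for (i in seq_len(q - 1)) {
    if (!pure[i]) next
    for (j in seq(i + 1, q)) {
      if (!pure[j]) next
      w <- gnet$G[i, j]
      if (is.na(w)) next
      s <- if (statistic == "abs") abs(w) else w
      for (a in members[[i]]) {
        for (b in members[[j]]) {
          if (s > best[a, b]) {
            best[a, b] <- s; best[b, a] <- s
            wmat[a, b] <- w; wmat[b, a] <- w
          }
        }
      }
    }
  }
  up <- which(upper.tri(best) & is.finite(best), arr.ind = TRUE)
  data.frame(a = ids[up[, 1]], b = ids[up[, 2]],
             weight = wmat[up], stringsAsFactors = FALSE)
}

#' Fit correlation / inverse-correlation model from counts
#'
#' Convenience wrapper: [standardize()] then [correlation_network()] then
#' [inverse_correlation_network()].
#'
#' @inheritParams standardize
#' @inheritParams inverse_correlation_network
#' @return a `network_model`: list with `sigma`, `theta`, `means`, `sds`,
#'   `n_samples`, `transform`, `dataset_ids`, `kept`, `dropped`.
#' @export
network_model <- function(counts, transform = "raw", ridge = 0) {
  std <- standardize(counts, transform)
  sigma <- correlation_network(std)
  theta <- inverse_correlation_network(sigma, ridge = ridge)
  structure(list(sigma = sigma, theta = theta, means = std$means,
                 sds = std$sds, n_samples = std$n_samples,
                 transform = std$transform, dataset_ids = std$dataset_ids,
                 kept = std$kept, dropped = std$dropped),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("network_model: %d data sets, %d samples, transform = %s\n",
              length(x$dataset_ids), x$n_samples, x$transform))
  invisible(x)
}

#' Export a network (nodes, groups, edges) as JSON
#'
#' @param gnet a [group_network()].
#' @param metadata an [experiment_metadata()].
#' @param path output path; if `NULL` the JSON string is returned.
#' @param min_weight drop edges with `|weight|` below this (default 0: keep
#'   all defined edges).
#' @return path (invisibly) or JSON string.
#' @export
export_network_json <- function(gnet, metadata, path = NULL, min_weight = 0) {
  ids <- gnet$tree$dataset_ids
  md <- metadata[match(ids, metadata$id), ]
  nodes <- data.frame(id = ids, factor = md$factor, cell_type = md$cell_type,
                      target_class = md$target_class, stringsAsFactors = FALSE)
  groups <- lapply(seq_along(gnet$members), function(i)
    list(id = gnet$group_ids[i], members = ids[gnet$members[[i]]],
         min_corr = gnet$min_corr[i]))
  up <- which(upper.tri(gnet$G) & !is.na(gnet$G) &
                abs(gnet$G) >= min_weight, arr.ind = TRUE)
  edges <- data.frame(a = gnet$group_ids[up[, 1]], b = gnet$group_ids[up[, 2]],
                      weight = gnet$G[up], stringsAsFactors = FALSE)
  doc <- list(nodes = nodes, groups = groups, edges = edges)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
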