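#' Resistance-distance matrix of a conditional-dependence network
#'
#' Interprets the inverse correlation matrix as a (signed) graph Laplacian.
#' Entries with `|theta_ij| < threshold` (off-diagonal) are zeroed --- tiny
#' edges mostly encode noise --- and the result is inverted to `gamma`, which
#' is renormalized to unit diagonal (after thresholding the inverse is no
#' longer exactly correlation-shaped).  The resistance distance then
#' simplifies to `omega_ij = 1 - gamma_ij`, an affine rescaling of the full
#' four-term form `gamma_ii + gamma_jj - 2 gamma_ij`; the two are
#' rank-order identical and classical MDS is scale-invariant.
#'
#' @param theta inverse correlation (edge-weight) matrix.
#' @param threshold zero out edges below this magnitude (default 0.01).
#' @return an `embedding_model`: list with `theta_thresholded`, `gamma`
#'   (renormalized), `omega` (symmetric, zero diagonal).
#' @export
resistance_distance <- function(theta, threshold = 0.01) {
  tm <- as.matrix(theta)
  off <- abs(tm) < threshold
  diag(off) <- FALSE
  tm[off] <- 0
  rc <- rcond(tm)
  if (!is.finite(rc) || rc < 1e-12)
    stop("thresholded network is singular (rcond = ", format(rc),
         "); lower the threshold")
  gamma <- solve(tm)
  d <- diag(gamma)
  if (any(d <= 0))
    stop("inverse of thresholded network has non-positive diagonal; ",
         "lower the threshold")
  gamma <- gamma / sqrt(outer(d, d))
  gamma <- (gamma + t(gamma)) / 2
  omega <- 1 - gamma
  diag(omega) <- 0
  dimnames(omega) <- dimnames(theta)
  structure(list(theta_thresholded = tm, gamma = gamma, omega = omega,
                 threshold = threshold),
            class = "embedding_model")
}

#' Deterministic 2D embedding by classical multidimensional scaling
#'
#' Double-centers the squared distances and takes the top-2 eigenvectors.
#' Deterministic given the input; reflections are fixed by requiring the
#' first node's coordinate in each axis to be non-negative (falling back to
#' the first node with a nonzero coordinate).
#'
#' @param omega symmetric distance-like matrix (zero diagonal), or an
#'   `embedding_model`.
#' @return n x 2 coordinate matrix.
#' @export
embed_2d <- function(omega) {
  if (inherits(omega, "embedding_model")) omega <- omega$omega
  n <- nrow(omega)
  if (n < 3) stop("need at least 3 nodes to embed")
  coords <- suppressWarnings(stats::cmdscale(omega, k = 2))
  if (ncol(coords) < 2)
    coords <- cbind(coords, matrix(0, n, 2 - ncol(coords)))
  for (k in 1:2) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) > 0 && coords[nz[1], k] < 0)
      coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(omega)
  coords
}

#' Correlate each data set with a genomic annotation track
#'
#' Converts BED intervals to a per-bin 0/1 indicator (1 when a bin overlaps
#' any interval) and computes the Pearson correlation of every data set with
#' it.  Node sizes are the absolute correlations normalized so the largest
#' is 1.0.
#'
#' @param counts a [binned_counts()].
#' @param annotation a `GRanges`, or a BED file path (0-based half-open
#'   intervals, imported with rtracklayer).
#' @return data frame with columns `id`, `correlation`, `size`.
#' @export
annotation_overlay <- function(counts, annotation) {
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "BED")
  bins_gr <- GenomicRanges::GRanges(
    counts$bins$contig,
    IRanges::IRanges(start = counts$bins$start + 1, end = counts$bins$end))
  hit <- GenomicRanges::countOverlaps(bins_gr, annotation) > 0
  if (!any(hit)) stop("annotation overlaps no bins")
  ind <- as.numeric(hit)
  cors <- vapply(seq_len(ncol(counts$counts)), function(j) {
    x <- counts$counts[, j]
    if (stats::sd(x) == 0) {
      warning("data set '", counts$dataset_ids[j],
              "' has constant counts; correlation reported as 0")
      return(0)
    }
    stats::cor(x, ind)
  }, numeric(1))
  size <- if (max(abs(cors)) > 0) abs(cors) / max(abs(cors)) else cors
  data.frame(id = counts$dataset_ids, correlation = cors, size = size,
             stringsAsFactors = FALSE)
}

#' Export a visualization-ready network JSON
#'
#' Nodes carry metadata and 2D coordinates; edges are group edges with
#' `|weight| >= display_threshold` (0.2 by default, below which edges are no
#' longer enriched for known interactions).  When two connected groups have
#' children that are themselves connected above the threshold, the parental
#' edge is redundant and is hidden.
#'
#' @param gnet a [group_network()].
#' @param coords p x 2 matrix from [embed_2d()] (rows = data sets).
#' @param metadata an [experiment_metadata()].
#' @param display_threshold minimum displayed edge magnitude.
#' @param path output path; if `NULL` the JSON string is returned.
#' @param overlay optional [annotation_overlay()] result merged into nodes.
#' @return path (invisibly) or JSON string.
#' @export
export_viz_json <- function(gnet, coords, metadata, display_threshold = 0.2,
                            path = NULL, overlay = NULL) {
  ids <- gnet$tree$dataset_ids
  if (nrow(coords) != length(ids))
    stop("coords must cover all data sets")
  md <- metadata[match(ids, metadata$id), ]
  nodes <- data.frame(id = ids, factor = md$factor, cell_type = md$cell_type,
                      target_class = md$target_class,
                      x = coords[, 1], y = coords[, 2],
                      stringsAsFactors = FALSE)
  if (!is.null(overlay)) {
    nodes$annotation_correlation <- overlay$correlation[match(ids, overlay$id)]
    nodes$size <- overlay$size[match(ids, overlay$id)]
  }
  groups <- lapply(seq_along(gnet$members), function(i)
    list(id = gnet$group_ids[i], members = ids[gnet$members[[i]]],
         min_corr = gnet$min_corr[i]))
  G <- gnet$G
  q <- nrow(G)
  ret <- gnet$tree$retained
  # children (in the retained-group index space) of each retained group
  child_idx <- lapply(gnet$tree$nodes[ret], function(nd) {
    ch <- match(nd$children, ret)
    ch[!is.na(ch)]
  })
  visible <- !is.na(G) & abs(G) >= display_threshold
  edges <- list()
  for (i in seq_len(q - 1)) {
    for (j in seq(i + 1, q)) {
      if (!visible[i, j]) next
      redundant <- FALSE
      for (ci in child_idx[[i]]) {
        for (cj in child_idx[[j]]) {
          if (visible[ci, cj]) { redundant <- TRUE; break }
        }
        if (redundant) break
      }
      if (redundant) next
      edges[[length(edges) + 1]] <- list(
        a = gnet$group_ids[i], b = gnet$group_ids[j],
        weight = G[i, j], negative = G[i, j] < 0)
    }
  }
  doc <- list(nodes = nodes, groups = groups, edges = edges,
              display_threshold = display_threshold)
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a visualization JSON's edge set
#'
#' @param path JSON written by [export_viz_json()].
#' @return list with `nodes`, `groups`, `edges` data frames.
#' @export
import_viz_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  doc
}
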