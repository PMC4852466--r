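#' Generate a ground-truth dependence structure for simulated ChIP-seq data
#'
#' Data sets are grouped into "complexes" of size 1 (60%), 2 (20%) or 3
#' (20%), mimicking the tight coupling seen among some factors in real data.
#' The latent multivariate-Gaussian signal has within-complex correlations
#' drawn uniformly in `within_corr_range`, and sparse cross-complex
#' conditional dependencies: each cross-complex precision entry is nonzero
#' with probability `sparsity`, with magnitude uniform in `off_block_range`
#' and random sign.  Data sets joined by a nonzero generative precision
#' entry are the true network connections to be recovered.
#'
#' The precision matrix is made positive-definite by shrinking the
#' cross-complex part toward zero until the minimum eigenvalue is at least
#' 1e-3 (this leaves the within-complex blocks untouched), then rescaled so
#' the latent signal has unit variance per data set (the simulator scales it
#' by `signal_sd`).  If the couplings still push within-complex marginal
#' correlations out of the target range (tolerance 0.02), the construction
#' retries with a new seed offset.
#'
#' @param n_complexes number of complexes (the real-data analogue used 80).
#' @param size_probs probabilities of complex sizes 1, 2, 3.
#' @param sparsity probability that a cross-complex precision entry is
#'   nonzero (default 0.1).
#' @param within_corr_range target within-complex latent correlations.
#' @param off_block_range magnitude range of cross-complex precision entries
#'   (on the unit-variance scale, before loading).
#' @param signal_sd latent signal standard deviation in *reads per bin*
#'   (default 10): enriched 1000-bp bins carry tens of reads, so the
#'   Poisson and negative-binomial noise perturb but do not drown the
#'   signal.
#' @param nb_r,nb_p negative-binomial background-noise parameters (number of
#'   successes / success probability; mean `nb_r (1 - nb_p) / nb_p`, about
#'   2.78 reads per bin at the defaults r = 25, p = 0.9).
#' @param n_batches number of distinct genome-wide batch-effect tracks.
#' @param batch_amplitude amplitude of the batch-effect rate tracks (reads
#'   per bin).
#' @param mu latent mean in reads per bin (recycled; default 0, which with
#'   thresholding at zero yields zero-inflated right-skewed counts).
#' @param seed integer seed.
#' @param max_tries retries of the positive-definite construction.
#' @return a `simulation_truth`: list with `precision` (unit-variance
#'   scale), `covariance` (latent correlation), `signal_sd`, `mu`,
#'   `complexes` (integer assignment), `members` (list per complex),
#'   `connected_complexes` (2-column matrix of complex pairs with nonzero
#'   cross precision), and all parameters.
#' @export
generate_truth <- function(n_complexes = 80, size_probs = c(0.6, 0.2, 0.2),
                           sparsity = 0.1, within_corr_range = c(0.8, 0.9),
                           off_block_range = c(0.1, 0.3), signal_sd = 10,
                           nb_r = 25, nb_p = 0.9, n_batches = 8,
                           batch_amplitude = 0.5, mu = 0,
                           seed = 1L, max_tries = 50L) {
  stopifnot(n_complexes >= 1, abs(sum(size_probs) - 1) < 1e-8)
  for (try in seq_len(max_tries)) {
    set.seed(seed + (try - 1L) * 1000L)
    sizes <- sample(1:3, n_complexes, replace = TRUE, prob = size_probs)
    p <- sum(sizes)
    cx <- rep(seq_len(n_complexes), sizes)
    members <- split(seq_len(p), cx)
    omega <- matrix(0, p, p)
    for (m in members) {
      if (length(m) == 1) { omega[m, m] <- 1; next }
      R <- diag(length(m))
      off <- which(upper.tri(R), arr.ind = TRUE)
      r <- stats::runif(nrow(off), within_corr_range[1], within_corr_range[2])
      R[off] <- r
      R[cbind(off[, 2], off[, 1])] <- r
      omega[m, m] <- solve(R)
    }
    # sparse cross-complex conditional dependencies (element-level density)
    block <- omega
    off <- matrix(0, p, p)
    cross <- which(upper.tri(omega) & outer(cx, cx, "!="), arr.ind = TRUE)
    on <- stats::runif(nrow(cross)) < sparsity
    val <- sign(stats::runif(sum(on)) - 0.5) *
      stats::runif(sum(on), off_block_range[1], off_block_range[2])
    off[cross[on, , drop = FALSE]] <- val
    off[cross[on, c(2, 1), drop = FALSE]] <- val
    ca <- cx[cross[on, 1]]; cb <- cx[cross[on, 2]]
    support <- unique(cbind(pmin(ca, cb), pmax(ca, cb)))
    # Enforce positive-definiteness and the within-complex correlation
    # targets by shrinking the cross-complex part: unlike diagonal loading
    # this leaves the within-complex precision blocks untouched, and in the
    # block-diagonal limit the marginal correlations match the targets
    # exactly, so the loop terminates at any p.
    in_range <- function(covm) {
      for (m in members) {
        if (length(m) > 1) {
          sub <- covm[m, m][upper.tri(covm[m, m])]
          if (any(sub < within_corr_range[1] - 0.02) ||
              any(sub > within_corr_range[2] + 0.02)) return(FALSE)
        }
      }
      TRUE
    }
    shrink <- 1
    ok <- FALSE
    while (shrink > 1e-3) {
      omega <- block + shrink * off
      ev <- min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values)
      if (ev >= 1e-3) {
        covm <- stats::cov2cor(solve(omega))
        if (in_range(covm)) { ok <- TRUE; break }
      }
      shrink <- shrink * 0.8
    }
    if (ok) {
      precision <- solve(covm)
      precision <- (precision + t(precision)) / 2
      return(structure(
        list(precision = precision, covariance = covm, signal_sd = signal_sd,
             mu = rep_len(mu, p), complexes = cx, members = members,
             connected_complexes = support, sizes = sizes,
             within_corr_range = within_corr_range,
             off_block_range = off_block_range, sparsity = sparsity,
             nb_r = nb_r, nb_p = nb_p, n_batches = n_batches,
             batch_amplitude = batch_amplitude,
             smoothing_weights = c(1 / 20, 9 / 10, 1 / 20),
             shrink = shrink, seed = seed, tries = try),
        class = "simulation_truth"))
    }
  }
  stop("could not build a positive-definite precision meeting the ",
       "within-complex correlation targets after ", max_tries,
       " tries (base seed ", seed, ")")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("simulation_truth: %d data sets in %d complexes, %d connected complex pairs\n",
              length(x$complexes), length(x$members),
              nrow(x$connected_complexes)))
  invisible(x)
}

#' Neighbor-smooth rate tracks
#'
#' Replaces each rate with the mix `w1 * rate[t-1] + w2 * rate[t] +
#' w3 * rate[t+1]` (defaults 1/20, 9/10, 1/20), making nearby bins more
#' similar so positional samples are not i.i.d.  At the boundaries the
#' missing neighbor contributes zero under `boundary = "zero"` (default; the
#' interior weights are applied to an implicit zero-rate flank), or the
#' weights are renormalized over the available neighbors under
#' `boundary = "renormalize"`.
#'
#' @param rates numeric vector or matrix (positions x data sets).
#' @param weights length-3 smoothing weights.
#' @param boundary `"zero"` or `"renormalize"`.
#' @return smoothed rates, same shape.
#' @export
smooth_rates <- function(rates, weights = c(1 / 20, 9 / 10, 1 / 20),
                         boundary = c("zero", "renormalize")) {
  boundary <- match.arg(boundary)
  f <- function(r) {
    n <- length(r)
    if (n < 3) stop("smoothing needs at least 3 positions")
    prev <- c(0, r[-n]); nxt <- c(r[-1], 0)
    out <- weights[1] * prev + weights[2] * r + weights[3] * nxt
    if (boundary == "renormalize") {
      out[1] <- out[1] / (weights[2] + weights[3])
      out[n] <- out[n] / (weights[1] + weights[2])
    }
    out
  }
  if (is.matrix(rates)) apply(rates, 2, f) else f(rates)
}

#' Simulate binned ChIP-seq counts from a known dependence structure
#'
#' Per position t and data set j the count is `c = v + eps` where
#' `v ~ Poisson(rate)`, `eps ~ NegBinomial(nb_r, nb_p)` background noise,
#' and the rate is built as: draw `s ~ N(mu, Sigma)` jointly across data
#' sets, threshold at zero, add the data set's genome-wide batch-effect
#' track (one of `n_batches` independent smoothed thresholded-Gaussian
#' tracks, assigned uniformly at random), then smooth across neighboring
#' positions with weights (1/20, 9/10, 1/20).  Identical seeds give
#' bit-identical output.
#'
#' @param truth a [generate_truth()] result.
#' @param n_samples number of positional samples (>= 3).
#' @param seed integer seed.
#' @param bin_size nominal bin width for the synthetic contig.
#' @return a `simulated_dataset`: list with `counts` ([binned_counts()] on
#'   contig "sim_chr1"), `truth`, `metadata` (factor = complex label, so
#'   complexes are resampled as units by [bootstrap_compare()] and
#'   within-complex edges fall under the same-factor exclusion),
#'   `true_edges` (cross-complex data-set pairs joined by a nonzero
#'   generative precision entry), and `true_factor_edges` (complex pairs
#'   with any cross connection, usable as an [interaction_table()]).
#' @export
simulate_counts <- function(truth, n_samples, seed = 1L, bin_size = 1000L) {
  stopifnot(n_samples >= 3)
  p <- length(truth$complexes)
  signal_sd <- if (is.null(truth$signal_sd)) 1 else truth$signal_sd
  set.seed(seed)
  L <- chol(truth$covariance)
  s <- matrix(stats::rnorm(n_samples * p), n_samples, p) %*% L * signal_sd
  s <- sweep(s, 2, truth$mu, "+")
  rates <- pmax(s, 0)
  # genome-wide additive batch effects (confounders shared across data sets)
  B <- matrix(stats::rnorm(n_samples * truth$n_batches), n_samples)
  B <- smooth_rates(pmax(B, 0) * truth$batch_amplitude)
  assignment <- sample.int(truth$n_batches, p, replace = TRUE)
  rates <- rates + B[, assignment, drop = FALSE]
  rates <- smooth_rates(rates, truth$smoothing_weights)
  v <- matrix(stats::rpois(n_samples * p, lambda = rates), n_samples, p)
  eps <- matrix(stats::rnbinom(n_samples * p, size = truth$nb_r,
                               prob = truth$nb_p), n_samples, p)
  cnt <- v + eps
  ids <- sprintf("D%03d", seq_len(p))
  bins <- data.frame(contig = "sim_chr1",
                     start = (seq_len(n_samples) - 1) * bin_size,
                     end = seq_len(n_samples) * bin_size)
  bc <- binned_counts(cnt, bins, ids, bin_size)
  fac <- sprintf("C%02d", truth$complexes)
  md <- experiment_metadata(data.frame(
    id = ids, factor = fac, cell_type = "sim", lab = "sim",
    treatment = "none", target_class = "transcription_factor",
    stringsAsFactors = FALSE))
  cc <- truth$connected_complexes
  tf <- if (nrow(cc) > 0)
    data.frame(factor_a = sprintf("C%02d", cc[, 1]),
               factor_b = sprintf("C%02d", cc[, 2]),
               stringsAsFactors = FALSE)
  else data.frame(factor_a = character(0), factor_b = character(0))
  # true connections: cross-complex data-set pairs joined by a nonzero
  # generative precision entry (the zero pattern survives loading/rescaling)
  cxm <- truth$complexes
  nz <- which(abs(truth$precision) > 1e-8 & upper.tri(truth$precision) &
                outer(cxm, cxm, "!="), arr.ind = TRUE)
  te <- data.frame(a = ids[nz[, 1]], b = ids[nz[, 2]],
                   stringsAsFactors = FALSE)
  structure(list(counts = bc, truth = truth, metadata = md,
                 true_edges = te, true_factor_edges = tf,
                 batch_assignment = assignment, seed = seed),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset: %d bins x %d data sets, %d true complex pairs\n",
              nrow(x$counts$counts), ncol(x$counts$counts),
              nrow(x$true_factor_edges)))
  invisible(x)
}

#' Save simulation ground truth as JSON
#'
#' The precision matrix is stored as sparse triplets.
#'
#' @param truth a [generate_truth()] result.
#' @param path output JSON path.
#' @export
save_truth_json <- function(truth, path) {
  nz <- which(truth$precision != 0 & upper.tri(truth$precision, diag = TRUE),
              arr.ind = TRUE)
  doc <- list(
    precision = data.frame(i = nz[, 1], j = nz[, 2],
                           value = truth$precision[nz]),
    complexes = truth$complexes,
    connected_complexes = as.data.frame(truth$connected_complexes),
    parameters = truth[c("sparsity", "within_corr_range", "off_block_range",
                         "nb_r", "nb_p", "n_batches", "batch_amplitude",
                         "smoothing_weights", "seed")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
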