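# Fixtures are built in code at test time; nothing binary ships with the
# package.

# a tiny two-contig genome
toy_contigs <- function() contig_table(c("chr1", "chr2"), c(2000, 1500))

# write a minimal SAM file and convert it to BAM (Rsamtools ships with the
# package dependencies); returns the BAM path
write_toy_bam <- function(dir, positions, contig = "chr1") {
  sam <- file.path(dir, "toy.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              "@SQ\tSN:chr1\tLN:2000",
              "@SQ\tSN:chr2\tLN:1500")
  # SAM POS is 1-based
  recs <- sprintf("r%03d\t0\t%s\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t**********",
                  seq_along(positions), contig, sort(positions) + 1L)
  writeLines(c(header, recs), sam)
  Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = FALSE)
}

toy_metadata <- function(ids, factors = ids,
                         cell_type = "K562",
                         target_class = "transcription_factor") {
  experiment_metadata(data.frame(
    id = ids, factor = factors,
    cell_type = rep_len(cell_type, length(ids)),
    lab = "lab1", treatment = "none",
    target_class = rep_len(target_class, length(ids)),
    stringsAsFactors = FALSE))
}

# random correlation matrix of Gaussian data (well-conditioned for n >> p)
random_std_data <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# small simulated world shared by several tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_truth(n_complexes = 20, seed = 1)
      cache <<- simulate_counts(truth, n_samples = 20000, seed = 1)
    }
    cache
  }
})

# labeled ranked edge list for a weight matrix under the simulated truth
sim_labeled <- function(sim, wmat, rho = 1) {
  m <- network_model(sim$counts)
  tree <- build_groups(m$sigma, rho = rho)
  w <- if (is.character(wmat)) switch(wmat, corr = m$sigma, invcorr = m$theta)
       else wmat
  pe <- pair_edge_weights(group_network(w, tree), sim$metadata,
                          statistic = "abs")
  pe$weight <- abs(pe$weight)
  label_simulated_edges(pe, sim)
}
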