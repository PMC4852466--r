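test_that("standardize gives population mean-0/var-1 columns and applies transforms", {
  s <- standardize(matrix(c(0, 2, 4), ncol = 1))
  expect_equal(s$x[, 1], c(-1, 0, 1) * sqrt(3 / 2))  # population sd
  expect_equal(colMeans(s$x), 0, ignore_attr = TRUE)
  expect_equal(colSums(s$x^2) / nrow(s$x), 1, ignore_attr = TRUE)

  sq <- standardize(matrix(c(0, 1, 4, 9), ncol = 1), transform = "sqrt")
  expect_equal(sq$x, standardize(matrix(0:3, ncol = 1))$x)

  x <- cbind(a = c(1, 2, 3), b = c(0, 0, 0))
  expect_warning(s2 <- standardize(x), "zero-variance.*b")
  expect_equal(s2$kept, 1L)
  expect_error(standardize(matrix(5, 4, 2)), "all columns are constant")
})

test_that("correlation_network matches the Pearson formula", {
  expect_equal(correlation_network(standardize(cbind(c(1, 2, 3), c(1, 2, 3) * 2)))[1, 2], 1)
  expect_equal(correlation_network(standardize(cbind(c(1, 2, 3), -c(1, 2, 3))))[1, 2], -1)
  x <- random_std_data(1e5, 2, seed = 2)
  sig <- correlation_network(standardize(x))
  expect_lt(abs(sig[1, 2]), 0.02)
  expect_equal(sig[1, 2], cor(x[, 1], x[, 2]), tolerance = 1e-10)
})

test_that("inverse correlation: closed forms, explaining away, and inverse identity", {
  th <- inverse_correlation_network(matrix(c(1, .5, .5, 1), 2))
  expect_equal(th, matrix(c(4, -2, -2, 4) / 3, 2), ignore_attr = TRUE)

  # chain A-C-B: r_AB = r_AC * r_CB forces conditional independence
  sig <- diag(3)
  sig[1, 3] <- sig[3, 1] <- 0.6
  sig[2, 3] <- sig[3, 2] <- 0.6
  sig[1, 2] <- sig[2, 1] <- 0.36
  expect_equal(inverse_correlation_network(sig)[1, 2], 0, tolerance = 1e-12)

  x <- random_std_data(400, 20, seed = 3)
  sig20 <- correlation_network(standardize(x))
  th20 <- inverse_correlation_network(sig20)
  expect_lt(max(abs(th20 %*% sig20 - diag(20))), 1e-8)
  expect_equal(th20, solve(sig20), tolerance = 1e-8, ignore_attr = TRUE)

  dup <- cbind(x[, 1], x[, 1])
  sigd <- correlation_network(standardize(dup))
  expect_error(inverse_correlation_network(sigd), "ridge")
  expect_silent(inverse_correlation_network(sigd, ridge = 0.01))
})

test_that("partial correlation matches the residual-correlation definition", {
  th <- matrix(c(4, -2, -2, 4) / 3, 2)
  expect_equal(partial_correlation_network(th)[1, 2], 0.5)
  expect_equal(partial_correlation_network(diag(3)), -diag(3),
               ignore_attr = TRUE)
  expect_error(partial_correlation_network(matrix(c(-1, 0, 0, 1), 2)),
               "positive")

  # oracle: correlation of regression residuals on the other variables
  x <- random_std_data(500, 10, seed = 8)
  th10 <- inverse_correlation_network(correlation_network(standardize(x)))
  P <- partial_correlation_network(th10)
  for (pair in list(c(1, 2), c(3, 7))) {
    i <- pair[1]; j <- pair[2]
    ri <- lm.fit(cbind(1, x[, -pair]), x[, i])$residuals
    rj <- lm.fit(cbind(1, x[, -pair]), x[, j])$residuals
    expect_equal(P[i, j], cor(ri, rj), tolerance = 1e-8)
  }
})

test_that("build_groups retains leaves plus tight complete-linkage clusters", {
  sig <- diag(3)
  sig[1, 2] <- sig[2, 1] <- 0.95
  sig[1, 3] <- sig[3, 1] <- 0.1
  sig[2, 3] <- sig[3, 2] <- 0.1
  tree <- build_groups(sig, rho = 0.8)
  mem <- lapply(tree$nodes[tree$retained], `[[`, "members")
  expect_setequal(vapply(mem, paste, "", collapse = ","),
                  c("1", "2", "3", "1,2"))

  # all pairwise 0.9: complete linkage merges two, then the triple at 0.9
  sig9 <- matrix(0.9, 3, 3); diag(sig9) <- 1
  tree9 <- build_groups(sig9, rho = 0.8)
  mem9 <- lapply(tree9$nodes[tree9$retained], `[[`, "members")
  expect_setequal(vapply(mem9, paste, "", collapse = ","),
                  c("1", "2", "3", "1,2", "1,2,3"))

  # orthogonal variables: only leaves
  tree0 <- build_groups(diag(4), rho = 0.8)
  expect_equal(tree0$retained, 1:4)

  # retention is strictly greater-than rho
  sig8 <- matrix(0.8, 2, 2); diag(sig8) <- 1
  expect_equal(build_groups(sig8, rho = 0.8)$retained, 1:2)
})

test_that("group tree structure is a valid dendrogram", {
  x <- random_std_data(300, 12, seed = 5)
  sig <- correlation_network(standardize(x))
  tree <- build_groups(sig, rho = 0.8)
  expect_length(tree$nodes, 2 * 12 - 1)
  for (k in seq_along(tree$nodes)) {
    nd <- tree$nodes[[k]]
    if (!is.null(nd$children)) {
      expect_setequal(nd$members,
                      c(tree$nodes[[nd$children[1]]]$members,
                        tree$nodes[[nd$children[2]]]$members))
      # complete linkage: min correlation never increases toward the root
      for (ch in nd$children)
        expect_lte(nd$min_corr, tree$nodes[[ch]]$min_corr + 1e-12)
    }
  }
})

test_that("group_network implements the group-edge sum with additivity", {
  x <- random_std_data(200, 6, seed = 6)
  m <- network_model(x)
  tree <- build_groups(m$sigma, rho = 0.8)
  gnet <- group_network(m$theta, tree)
  # singleton-singleton edges equal theta entries
  singles <- which(lengths(gnet$members) == 1)
  for (i in singles[1:3]) for (j in singles[4:6]) {
    expect_equal(gnet$G[i, j],
                 m$theta[gnet$members[[i]], gnet$members[[j]]])
  }
  # additivity: weight(g1 union g2, h) = weight(g1,h) + weight(g2,h)
  w <- function(g, h) sum(m$theta[g, h])
  for (h in list(5L, 6L, c(5L, 6L))) {
    expect_equal(w(c(1L, 2L), h), w(1L, h) + w(2L, h))
    expect_equal(w(c(1L, 2L, 3L), h), w(c(1L, 2L), h) + w(3L, h))
  }
  # overlapping group pairs are undefined
  gi <- which(vapply(gnet$members, function(mm) 1L %in% mm, TRUE))
  if (length(gi) > 1) expect_true(is.na(gnet$G[gi[1], gi[2]]))
})

test_that("with rho >= 1 GroupGM reduces exactly to inverse correlation", {
  x <- random_std_data(300, 8, seed = 9)
  m <- network_model(x)
  gnet <- group_network(m$theta, build_groups(m$sigma, rho = 1))
  expect_equal(length(gnet$members), 8)
  md <- toy_metadata(m$dataset_ids)
  pe <- pair_edge_weights(gnet, md)
  expect_equal(nrow(pe), choose(8, 2))
  for (k in seq_len(nrow(pe))) {
    i <- match(pe$a[k], m$dataset_ids); j <- match(pe$b[k], m$dataset_ids)
    expect_equal(pe$weight[k], m$theta[i, j])
  }
})

test_that("pair_edge_weights applies the max rule and factor purity", {
  # 3 variables: 1 and 2 tightly correlated (same factor), 3 separate
  sig <- diag(3)
  sig[1, 2] <- sig[2, 1] <- 0.95
  sig[1, 3] <- sig[3, 1] <- 0.3
  sig[2, 3] <- sig[3, 2] <- 0.25
  theta <- solve(sig)
  colnames(sig) <- colnames(theta) <- rownames(theta) <- c("a1", "a2", "b")
  tree <- build_groups(sig, rho = 0.8)
  gnet <- group_network(theta, tree)
  md <- toy_metadata(c("a1", "a2", "b"), factors = c("A", "A", "B"))
  pe <- pair_edge_weights(gnet, md, statistic = "abs")
  grp_w <- sum(theta[1:2, 3])
  best <- max(abs(c(theta[1, 3], grp_w)))
  got <- pe$weight[pe$a == "a1" & pe$b == "b"]
  expect_equal(abs(got), best)

  # impure group is ineligible: only singleton edges remain
  md2 <- toy_metadata(c("a1", "a2", "b"), factors = c("A", "C", "B"))
  pe2 <- pair_edge_weights(gnet, md2, statistic = "abs")
  expect_equal(pe2$weight[pe2$a == "a1" & pe2$b == "b"], theta[1, 3])
})

test_that("duplicated variable: group edge preserved, single edge degrades", {
  set.seed(20)
  n <- 50000
  sig5 <- matrix(0.3, 5, 5); diag(sig5) <- 1
  x5 <- matrix(rnorm(n * 5), n, 5) %*% chol(sig5)
  ref <- network_model(x5)$theta[1, 2]
  x6 <- cbind(x5, x5[, 1] + rnorm(n, sd = 0.02))
  m6 <- network_model(x6)
  expect_gte(m6$sigma[1, 6], 0.999)
  gnet <- group_network(m6$theta, build_groups(m6$sigma, rho = 0.8))
  gi <- which(vapply(gnet$members, setequal, TRUE, c(1L, 6L)))
  bi <- which(vapply(gnet$members, identical, TRUE, 2L))
  expect_lt(abs(gnet$G[gi, bi] - ref) / abs(ref), 0.05)
  expect_gt(abs(m6$theta[1, 2] - ref) / abs(ref), 0.25)
})

test_that("network JSON export round-trips nodes, groups, edges", {
  x <- random_std_data(200, 5, seed = 11)
  m <- network_model(x)
  gnet <- group_network(m$theta, build_groups(m$sigma, rho = 0.8))
  md <- toy_metadata(m$dataset_ids)
  path <- withr::local_tempfile(fileext = ".json")
  export_network_json(gnet, md, path)
  doc <- jsonlite::fromJSON(path)
  expect_equal(doc$nodes$id, m$dataset_ids)
  up <- which(upper.tri(gnet$G) & !is.na(gnet$G), arr.ind = TRUE)
  expect_equal(sort(doc$edges$weight), sort(gnet$G[up]))
})
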