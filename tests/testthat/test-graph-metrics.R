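test_that("mean strength is the plain average of |w| over pairs", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- -0.4
  w[2, 3] <- w[3, 2] <- 0.6
  expect_equal(mean_strength(connectivity_matrix(w)), 0.4)
  expect_equal(mean_strength(connectivity_matrix(matrix(0, 4, 4))), 0)
  w10 <- random_signed_matrix(10, seed = 21)
  expect_equal(mean_strength(connectivity_matrix(w10)),
               oracle_mean_strength(w10))
})

test_that("path length matches hand-worked cases", {
  tri <- matrix(0.5, 3, 3); diag(tri) <- 0
  pl <- char_path_length(connectivity_matrix(tri), 0.4)
  expect_equal(as.numeric(pl), 2)          # direct edge 1/0.5 beats two hops
  expect_true(attr(pl, "connected"))
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(as.numeric(char_path_length(connectivity_matrix(star), 0.5)),
               1.5)                        # (3*1 + 3*2) / 6
})

test_that("path length and clustering agree with brute-force oracles", {
  for (s in 1:20) {
    n <- sample(8:12, 1)
    w <- random_signed_matrix(n, seed = 100 + s)
    cm <- connectivity_matrix(w)
    tau <- runif(1, 0.2, 0.6)
    expect_equal(as.numeric(char_path_length(cm, tau)),
                 oracle_path_length(w, tau), tolerance = 1e-9)
    expect_equal(avg_clustering(cm, tau), oracle_clustering(w, tau),
                 tolerance = 1e-9)
  }
})

test_that("shortest paths agree with an independent igraph computation", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    w <- random_signed_matrix(9, seed = 300 + s)
    tau <- 0.35
    len <- ifelse(abs(w) >= tau, 1 / abs(w), 0)
    g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d <- igraph::distances(g)
    off <- d[upper.tri(d)]
    expect_equal(as.numeric(char_path_length(connectivity_matrix(w), tau)),
                 mean(off[is.finite(off)]), tolerance = 1e-9)
  }
})

test_that("disconnected graphs exclude unreachable pairs and say so", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[3, 4] <- w[4, 3] <- 0.5
  pl <- char_path_length(connectivity_matrix(w), 0.4)
  expect_false(attr(pl, "connected"))
  expect_equal(as.numeric(pl), mean(c(1 / 0.8, 1 / 0.5)))
  none <- char_path_length(connectivity_matrix(matrix(0, 3, 3)), 0.4)
  expect_equal(as.numeric(none), Inf)
})

test_that("clustering matches hand cases and the unweighted special case", {
  tri <- matrix(0.7, 3, 3); diag(tri) <- 0
  expect_equal(avg_clustering(connectivity_matrix(tri), 0.4), 1)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(avg_clustering(connectivity_matrix(star), 0.5), 0)
  for (s in 1:5) {
    set.seed(400 + s)
    n <- 9
    adj <- matrix(runif(n * n) < 0.4, n, n)
    adj <- adj & t(adj); diag(adj) <- FALSE
    w <- adj * 1
    expect_equal(avg_clustering(connectivity_matrix(w), 0.5),
                 oracle_unweighted_clustering(adj), tolerance = 1e-12)
  }
})

test_that("the complete graph with |w| = c hits its closed-form limits", {
  for (c0 in c(0.6, 0.8, 1.0)) {
    w <- matrix(c0, 5, 5); diag(w) <- 0
    cm <- connectivity_matrix(w)
    expect_equal(mean_strength(cm), c0)
    expect_equal(as.numeric(char_path_length(cm, 0.5)), 1 / c0)
    expect_equal(avg_clustering(cm, 0.5), 1)
  }
})

test_that("metrics ignore the sign pattern of the weights", {
  w <- random_signed_matrix(8, seed = 55)
  cm1 <- connectivity_matrix(w)
  set.seed(56)
  flip <- matrix(1, 8, 8)
  flip[upper.tri(flip)] <- sample(c(-1, 1), 28, replace = TRUE)
  flip[lower.tri(flip)] <- t(flip)[lower.tri(flip)]
  cm2 <- connectivity_matrix(w * flip)
  expect_equal(mean_strength(cm2), mean_strength(cm1))
  expect_equal(as.numeric(char_path_length(cm2, 0.3)),
               as.numeric(char_path_length(cm1, 0.3)))
  expect_equal(avg_clustering(cm2, 0.3), avg_clustering(cm1, 0.3))
})

test_that("on a connected graph, strengthening a connection never lengthens paths", {
  # (on a disconnected graph a strengthened edge can newly connect a
  # distant pair and so raise the mean over reachable pairs)
  w <- random_signed_matrix(8, seed = 60)
  tau <- 0.15
  base <- char_path_length(connectivity_matrix(w), tau)
  expect_true(attr(base, "connected"))
  for (k in 1:10) {
    set.seed(500 + k)
    i <- sample(7, 1)
    j <- if (i == 7) 8L else sample((i + 1):8, 1)
    w2 <- w
    bump <- min(1, abs(w2[i, j]) + runif(1, 0, 0.5))
    w2[i, j] <- w2[j, i] <- sign(w2[i, j] + 0.5) * bump
    pert <- as.numeric(char_path_length(connectivity_matrix(w2), tau))
    expect_lte(pert, as.numeric(base) + 1e-12)
  }
})

test_that("network_metrics assembles the three parameters consistently", {
  w <- random_signed_matrix(10, seed = 70)
  cm <- connectivity_matrix(w, subject_id = "s1", band = "theta")
  row <- network_metrics(cm, 0.4)
  expect_equal(row$strength, mean_strength(cm))
  expect_equal(row$path_length, as.numeric(char_path_length(cm, 0.4)))
  expect_equal(row$clustering, avg_clustering(cm, 0.4))
  expect_equal(row$band, "theta")
  expect_equal(row$n_nodes, 10)
})
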