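test_that("clustering coefficient on canonical graphs", {
  # complete graph, unit weights: perfect clustering
  K4 <- matrix(1, 4, 4)
  expect_equal(unname(local_clustering(as_plv(K4))), rep(1, 4))
  expect_equal(global_clustering(as_plv(K4)), 1)

  # star: no triangles
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1; diag(S) <- 1
  expect_equal(unname(local_clustering(as_plv(S))), rep(0, 5))
  expect_equal(global_clustering(as_plv(S)), 0)

  # weighted triangle 0.8 / 0.5 / 0.2: geometric-mean formula
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.2
  diag(W) <- 1
  expected <- (1 * 0.625 * 0.25)^(1 / 3)
  expect_equal(unname(local_clustering(as_plv(W))), rep(expected, 3),
               tolerance = 1e-12)
  expect_equal(global_clustering(as_plv(W)), expected, tolerance = 1e-12)
})

test_that("all-zero weights warn and return zeros", {
  Z <- matrix(0, 4, 4)
  expect_warning(cc <- local_clustering(as_plv(Z)), "all-zero")
  expect_equal(unname(cc), rep(0, 4))
})

test_that("characteristic path length on canonical graphs", {
  K4 <- matrix(1, 4, 4)
  expect_equal(char_path_length(as_plv(K4)), 1)

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- 1
  chain[2, 3] <- chain[3, 2] <- 1
  diag(chain) <- 1
  expect_equal(char_path_length(as_plv(chain)), 4 / 3)
  expect_equal(char_path_length(as_plv(chain), mode = "sum"), 4)

  half <- chain; half[half > 0] <- 0.5; diag(half) <- 1
  expect_equal(char_path_length(as_plv(half)), 8 / 3)
})

test_that("disconnected graphs warn and use reachable pairs", {
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 1
  D[3, 4] <- D[4, 3] <- 1
  diag(D) <- 1
  expect_warning(v <- char_path_length(as_plv(D)), "disconnected")
  expect_equal(v, 1)  # two reachable pairs, each at distance 1
})

test_that("metrics are permutation-equivariant and weight-scale aware", {
  set.seed(20)
  for (trial in 1:10) {
    g <- random_plv_graph(7, seed = 300 + trial)
    W <- g$values
    perm <- sample(7)
    Wp <- W[perm, perm]
    expect_equal(unname(local_clustering(as_plv(Wp))),
                 unname(local_clustering(g))[perm], tolerance = 1e-12)
    expect_equal(char_path_length(as_plv(Wp)), char_path_length(g),
                 tolerance = 1e-12)
    # scaling all weights: CC invariant (max-normalised), CPL scales as 1/a
    a <- 0.37
    expect_equal(local_clustering(as_plv(a * W)), local_clustering(g),
                 tolerance = 1e-12)
    expect_equal(char_path_length(as_plv(a * W)),
                 char_path_length(g) / a, tolerance = 1e-12)
  }
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  for (trial in 1:20) {
    g <- random_plv_graph(8, seed = 400 + trial)
    expect_equal(unname(local_clustering(g)), oracle_local_cc(g$values),
                 tolerance = 1e-10)
    expect_equal(char_path_length(g), oracle_cpl(g$values),
                 tolerance = 1e-10)
    expect_equal(char_path_length(g, mode = "sum"),
                 oracle_cpl(g$values, mode = "sum"), tolerance = 1e-10)
  }
})

test_that("feature assembly has documented length, order and names", {
  mats <- lapply(c("alpha", "beta"), function(b) {
    g <- random_plv_graph(10, seed = match(b, c("alpha", "beta")))
    g$band <- b
    g
  })
  v <- assemble_features(mats)
  expect_length(v, 10 * 2 + 2 * 2)
  idx <- attr(v, "index")
  expect_equal(idx$kind[1:12],
               c(rep("local_cc", 10), "global_cc", "path_length"))
  expect_equal(idx$band[1:12], rep("alpha", 12))
  expect_equal(names(v)[11], "alpha__global_cc")
  expect_equal(names(v)[12], "alpha__path_length")
  # values consistent with the metric functions
  expect_equal(unname(v[1:10]), unname(local_clustering(mats[[1]])))
  expect_equal(unname(v[11]), global_clustering(mats[[1]]))
  expect_equal(unname(v[24]), char_path_length(mats[[2]]))
})

test_that("feature assembly rejects degenerate or inconsistent inputs", {
  one <- as_plv(matrix(1, 1, 1))
  expect_error(assemble_features(list(one)), "single node")
  g5 <- random_plv_graph(5, seed = 1)
  g6 <- random_plv_graph(6, seed = 2)
  expect_error(assemble_features(list(g5, g6)), "share one node set")
})
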