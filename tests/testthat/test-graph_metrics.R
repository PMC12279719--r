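test_that("the length transform is the reciprocal with Inf for absent edges", {
  w <- matrix(c(0, 2, 0, 2, 0, 0.5, 0, 0.5, 0), 3)
  len <- length_matrix(w)
  expect_equal(len[1, 2], 0.5)
  expect_equal(len[2, 3], 2)
  expect_identical(len[1, 3], Inf)
  expect_identical(diag(unclass(len)), c(0, 0, 0))
  # homogeneity: weights x10 => finite lengths x0.1
  len10 <- length_matrix(w * 10)
  expect_equal(len10[1, 2], len[1, 2] / 10)
})

test_that("shortest paths match hand values and handle disconnection", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  d <- shortest_paths(length_matrix(path3))
  expect_equal(d[1, 3], 2)
  disc <- matrix(0, 4, 4)
  disc[1, 2] <- disc[2, 1] <- 1
  d2 <- shortest_paths(length_matrix(disc))
  expect_identical(d2[1, 3], Inf)
})

test_that("global efficiency: complete graph 1, empty graph 0, path graph 5/6", {
  for (n in c(3, 5, 8)) {
    k <- matrix(1, n, n); diag(k) <- 0
    expect_equal(global_efficiency(k), 1)
  }
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_error(global_efficiency(matrix(0, 1, 1)), "at least 2")
})

test_that("regional efficiency: triangle 1, star centre 0, mean identity", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  expect_equal(unname(regional_efficiency(k3)), rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  er <- regional_efficiency(star)
  expect_equal(unname(er[1]), 0)   # neighbours disconnected without centre
  expect_equal(unname(er[2:5]), rep(0, 4))  # leaves have a single neighbour
  for (s in 1:20) {
    w <- random_weighted_graph(9, 0.5, seed = 100 + s)
    expect_equal(local_efficiency(w), mean(regional_efficiency(w)),
                 tolerance = 1e-12)
  }
  expect_equal(local_efficiency(matrix(0, 4, 4)), 0)
})

test_that("weighted metrics reduce exactly to binary formulas on 0/1 graphs", {
  for (s in 1:40) {
    n <- sample(4:12, 1)
    a <- random_binary_graph(n, runif(1, 0.2, 0.8), seed = 2000 + s)
    expect_equal(global_efficiency(a), binary_global_efficiency_oracle(a),
                 tolerance = 1e-12)
    expect_equal(unname(regional_efficiency(a)),
                 binary_regional_efficiency_oracle(a), tolerance = 1e-12)
  }
})

test_that("efficiencies are invariant under node relabelling and scale linearly", {
  w <- random_weighted_graph(10, 0.5, seed = 77)
  set.seed(78)
  perm <- sample(10)
  wp <- w[perm, perm]
  expect_equal(global_efficiency(wp), global_efficiency(w), tolerance = 1e-12)
  expect_equal(unname(regional_efficiency(wp)),
               unname(regional_efficiency(w))[perm], tolerance = 1e-12)
  # degree-1 homogeneity
  expect_equal(global_efficiency(3 * w), 3 * global_efficiency(w),
               tolerance = 1e-12)
  expect_equal(local_efficiency(3 * w), 3 * local_efficiency(w),
               tolerance = 1e-12)
})

test_that("supplementary metrics: density, clustering, strength, modularity", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  supp <- supplementary_global_metrics(k5)
  expect_equal(supp$density, 1)
  expect_equal(supp$clustering, 1)
  expect_equal(supplementary_global_metrics(matrix(c(0, 2, 2, 0), 2))$strength,
               2)
  # two disconnected K4 cliques: Louvain must reach the exhaustive optimum
  two_k4 <- matrix(0, 8, 8)
  two_k4[1:4, 1:4] <- 1
  two_k4[5:8, 5:8] <- 1
  diag(two_k4) <- 0
  supp2 <- supplementary_global_metrics(two_k4, seed = 5)
  expect_equal(supp2$modularity, best_two_partition_modularity(two_k4),
               tolerance = 1e-12)
  # determinism under a fixed seed
  supp3 <- supplementary_global_metrics(two_k4, seed = 5)
  expect_identical(supp2$modularity, supp3$modularity)
})

test_that("cohort profiles are one row per subject, deterministic, age-sensitive", {
  sim <- fixture_sim()
  prof <- fixture_profiles()
  expect_equal(nrow(prof), 90)
  expect_true(all(c("e_glob", "e_loc", "density", "clustering",
                    "modularity", "strength") %in% names(prof)))
  expect_equal(prof$e_loc,
               rowMeans(prof[, node_names(sim$cohort$atlas)]),
               tolerance = 1e-12)
  # generator plants an age-related decline in efficiency
  expect_lt(cor(sim$cohort$subjects$age, prof$e_glob), 0)
  expect_lt(cor(sim$cohort$subjects$age, prof$e_loc), 0)
  # determinism: recompute one subject
  p1 <- efficiency_profile(sim$cohort$connectomes[[1]], seed = 7)
  expect_equal(p1$e_glob, prof$e_glob[1])
  expect_equal(p1$modularity, prof$modularity[1])
})
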