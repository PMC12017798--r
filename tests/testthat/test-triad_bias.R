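test_that("centroids are on the simplex and pairwise distinct", {
  C <- bias_centroids()
  expect_equal(unname(rowSums(C)), rep(1, 7))
  expect_equal(nrow(unique(C)), 7)
})

test_that("relative contributions normalize exactly and guard zero sums", {
  expect_equal(relative_contribution(c(2, 2, 2)), c(1, 1, 1) / 3)
  expect_equal(relative_contribution(c(4, 1, 0)), c(0.8, 0.2, 0))
  expect_error(relative_contribution(c(0, 0, 0)), "zero total")
  expect_error(relative_contribution(c(-1, 1, 1)), "negative")
  set.seed(2)
  e <- matrix(rexp(300), 100, 3)
  r <- relative_contribution(e)
  expect_equal(rowSums(r), rep(1, 100))
})

test_that("centroid identities and worked examples classify correctly", {
  b <- classify_triad(c(1, 1, 1) / 3)
  expect_equal(b$category, "Balanced")
  expect_equal(unname(b$distances["Balanced"]), 0)
  expect_equal(classify_triad(c(1, 0, 0))$category, "LF_dominant")
  # (0.05, 0.45, 0.50): nearest centroid is (0, 0.5, 0.5) at ~0.0707
  b2 <- classify_triad(c(0.05, 0.45, 0.50))
  expect_equal(b2$category, "LF_suppressed")
  expect_equal(unname(b2$distances["LF_suppressed"]), 0.070711,
               tolerance = 1e-5)
  # (0.80, 0.15, 0.05): (1,0,0) at ~0.2550 beats Balanced at ~0.5759
  b3 <- classify_triad(c(0.80, 0.15, 0.05))
  expect_equal(b3$category, "LF_dominant")
  expect_equal(unname(b3$distances["LF_dominant"]), 0.254951,
               tolerance = 1e-5)
  expect_equal(unname(b3$distances["Balanced"]), 0.575905, tolerance = 1e-5)
  expect_error(classify_triad(c(0.5, 0.5, 0.5)), "simplex")
})

test_that("classification agrees with the exhaustive nearest-centroid oracle
          and is equivariant under subgenome permutation", {
  set.seed(31)
  r <- random_simplex(2000)
  for (i in seq_len(nrow(r))) {
    expect_identical(classify_triad(r[i, ])$category, oracle_classify(r[i, ]))
  }
  # label equivariance: swapping LF and MF1 swaps the matching categories
  swap <- c(2, 1, 3)
  map <- c(Balanced = "Balanced", LF_dominant = "MF1_dominant",
           MF1_dominant = "LF_dominant", MF2_dominant = "MF2_dominant",
           LF_suppressed = "MF1_suppressed",
           MF1_suppressed = "LF_suppressed",
           MF2_suppressed = "MF2_suppressed")
  for (i in seq_len(200)) {
    a <- classify_triad(r[i, ])$category
    b <- classify_triad(r[i, swap])$category
    expect_identical(unname(map[a]), b)
  }
})

test_that("scale invariance: classification depends only on the ray", {
  set.seed(8)
  for (i in 1:50) {
    e <- rexp(3)
    k <- runif(1, 0.01, 100)
    expect_identical(classify_triad(relative_contribution(e))$category,
                     classify_triad(relative_contribution(k * e))$category)
  }
})

test_that("constructed equidistant points break ties toward the earlier
          category (Balanced first)", {
  # midpoint of Balanced and LF_suppressed on the simplex is equidistant
  mid <- (c(1, 1, 1) / 3 + c(0, 0.5, 0.5)) / 2
  b <- classify_triad(mid)
  expect_equal(unname(b$distances["Balanced"]),
               unname(b$distances["LF_suppressed"]))
  expect_identical(b$category, "Balanced")
  # midpoint of two adjacent non-balanced centroids: earlier enum order wins
  mid2 <- (c(1, 0, 0) + c(0.5, 0, 0.5)) / 2
  b2 <- classify_triad(mid2)
  expect_equal(unname(b2$distances["LF_dominant"]),
               unname(b2$distances["MF1_suppressed"]))
  expect_true(all(b2$distances[!names(b2$distances) %in%
                                 c("LF_dominant", "MF1_suppressed")] >
                    b2$distances["LF_dominant"]))
  expect_identical(b2$category, "LF_dominant")
})

test_that("classify_all assigns filtered triads per cluster with proportions
          summing to one", {
  # profile in which every triad is exactly balanced and above threshold
  tab <- toy_homology()
  genes <- tab$gene_id
  me <- matrix(1, 2, length(genes), dimnames = list(c("A", "B"), genes))
  prof <- structure(list(clusters = c("A", "B"), mean_expr = me,
                         expressed = NULL, n_cells = c(A = 1L, B = 1L)),
                    class = "cluster_profile")
  res <- classify_all(prof, tab, bias_config(min_total_expr = 0.5))
  expect_true(all(res$assignments$category == "Balanced"))
  expect_true(all(res$assignments$passed_filter))
  agg <- tapply(res$proportions$proportion, res$proportions$cluster, sum)
  expect_equal(as.numeric(agg), c(1, 1))
  expect_equal(res$unbalanced$unbalanced_fraction, c(0, 0))
  # a filter nothing can pass is an error, not an empty table
  expect_error(classify_all(prof, tab, bias_config(min_total_expr = 4)),
               "no triad passes")
  # raising the filter never increases the number of assigned triads
  half <- prof
  half$mean_expr["B", ] <- 0.1             # cluster B triads total 0.3
  res3 <- classify_all(half, tab, bias_config(min_total_expr = 0.5))
  expect_lte(sum(res3$assignments$passed_filter),
             sum(res$assignments$passed_filter))
  expect_true(all(is.na(
    res3$assignments$category[!res3$assignments$passed_filter])))
})

test_that("missing homoeologs contribute zero expression and everything
          below the filter stays uncategorized", {
  tab <- toy_homology()
  genes <- setdiff(tab$gene_id, "a_LF")    # drop one homoeolog of triad t1
  me <- matrix(2, 1, length(genes), dimnames = list("A", genes))
  prof <- structure(list(clusters = "A", mean_expr = me, expressed = NULL,
                         n_cells = c(A = 1L)), class = "cluster_profile")
  res <- classify_all(prof, tab)
  t1 <- res$assignments[res$assignments$triad_id == "t1", ]
  expect_equal(t1$e_LF, 0)
  expect_identical(t1$category, "LF_suppressed")
})

test_that("ground-truth categories are recovered from simulated counts at
          tight concentration", {
  cfg <- sim_config(n_clusters = 4, cells_per_cluster = 150,
                    genome = list(subgenome_sizes = c(LF = 200, MF1 = 170,
                                                      MF2 = 150, UG = 20),
                                  n_triads = 80, n_duplets = 40),
                    dominance_strength = 5000,
                    nb_mean_log_range = c(log(1), log(8)), seed = 19)
  sim <- simulate_dataset(cfg)
  prof <- pseudobulk(normalize_counts(sim$counts), sim$counts$clusters)
  res <- classify_all(prof, sim$homology)
  m <- merge(res$assignments, sim$truth$categories,
             by = c("triad_id", "cluster"))
  f <- m[m$passed_filter, ]
  expect_gt(nrow(f), 0.9 * nrow(m))
  expect_gte(mean(f$category.x == f$category.y), 0.99)
})

test_that("recovery degrades as the Dirichlet concentration loosens", {
  rec_at <- function(strength) {
    cfg <- sim_config(n_clusters = 2, cells_per_cluster = 120,
                      genome = list(subgenome_sizes = c(LF = 120, MF1 = 100,
                                                        MF2 = 90, UG = 10),
                                    n_triads = 60, n_duplets = 20),
                      dominance_strength = strength,
                      nb_mean_log_range = c(log(1), log(8)), seed = 4)
    sim <- simulate_dataset(cfg)
    prof <- pseudobulk(normalize_counts(sim$counts), sim$counts$clusters)
    res <- classify_all(prof, sim$homology)
    m <- merge(res$assignments, sim$truth$categories,
               by = c("triad_id", "cluster"))
    f <- m[m$passed_filter, ]
    mean(f$category.x == f$category.y)
  }
  r <- vapply(c(200, 20, 5, 1), rec_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_lt(r[4], r[1])
})

test_that("ternary coordinates map corners and center to the documented
          triangle", {
  expect_equal(unlist(ternary_coordinates(c(1, 0, 0))), c(x = 0, y = 0))
  expect_equal(unlist(ternary_coordinates(c(0, 1, 0))), c(x = 1, y = 0))
  expect_equal(unlist(ternary_coordinates(c(0, 0, 1))),
               c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(unlist(ternary_coordinates(c(1, 1, 1) / 3)),
               c(x = 0.5, y = sqrt(3) / 6))
  expect_error(ternary_coordinates(c(0.7, 0.7, -0.4)), "simplex")
})
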