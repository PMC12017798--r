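test_that("group classification covers triads, duplets, monads and UG", {
  cls <- classify_groups(toy_homology())
  expect_equal(unname(cls$counts),
               c(2L, 1L, 2L, 2L))            # triads, duplets, monads, ug
  expect_equal(unname(cls$group_class[c("t1", "dp1", "mo1")]),
               c("triad", "duplet", "monad"))
  expect_equal(unname(cls$gene_class[c("a_LF", "d_M2", "m1", "u1")]),
               c("triad", "duplet", "monad", "ungrouped"))
  # empty table -> all zero counts
  empty <- homology_table(data.frame(gene_id = character(),
                                     subgenome = character(),
                                     group_id = character()))
  expect_true(all(classify_groups(empty)$counts == 0))
})

test_that("random membership patterns are tallied like a brute-force count", {
  set.seed(14)
  for (rep in 1:5) {
    n_tri <- sample(0:20, 1); n_dup <- sample(0:20, 1)
    n_mon <- sample(0:20, 1); n_ug <- sample(0:20, 1)
    rows <- list()
    if (n_tri) for (i in seq_len(n_tri))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = paste0("t", i, c("L", "M", "N")),
        subgenome = c("LF", "MF1", "MF2"), group_id = paste0("T", i))
    if (n_dup) for (i in seq_len(n_dup))
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = paste0("d", i, c("A", "B")),
        subgenome = sample(c("LF", "MF1", "MF2"), 2),
        group_id = paste0("D", i))
    if (n_mon) rows[[length(rows) + 1]] <- data.frame(
      gene_id = paste0("m", seq_len(n_mon)),
      subgenome = sample(c("LF", "MF1", "MF2"), n_mon, TRUE),
      group_id = paste0("M", seq_len(n_mon)))
    if (n_ug) rows[[length(rows) + 1]] <- data.frame(
      gene_id = paste0("u", seq_len(n_ug)), subgenome = "UG", group_id = "")
    tab <- homology_table(do.call(rbind, rows))
    cls <- classify_groups(tab)
    expect_equal(unname(cls$counts),
                 c(n_tri, n_dup, n_mon, n_ug))
    expect_equal(unname(3 * cls$counts[1] + 2 * cls$counts[2] +
                          cls$counts[3] + cls$counts[4]), nrow(tab))
  }
})

test_that("genome composition reproduces the published percentages from the
          published counts", {
  rows <- data.frame(
    gene_id = sprintf("g%05d", 1:41020),
    subgenome = rep(c("LF", "MF1", "MF2", "UG"),
                    times = c(16270, 11633, 9653, 3464)),
    group_id = "")
  rows$group_id[rows$subgenome != "UG"] <-
    paste0("m", seq_len(sum(rows$subgenome != "UG")))
  comp <- genome_composition(homology_table(rows))
  expect_equal(comp$count, c(16270, 11633, 9653, 3464))
  expect_equal(comp$percent[comp$subgenome == "LF"], 39.7)
  expect_equal(comp$percent[comp$subgenome == "MF2"], 23.5)
  expect_equal(comp$percent[comp$subgenome == "UG"], 8.4)
  # recomputed MF1 share: 100 * 11633 / 41020
  expect_equal(comp$percent[comp$subgenome == "MF1"], 28.4)
  expect_equal(sum(comp$fraction), 1)
})

test_that("genome composition is symmetric and scale invariant", {
  mk <- function(n) homology_table(data.frame(
    gene_id = sprintf("g%04d", seq_len(4 * n)),
    subgenome = rep(c("LF", "MF1", "MF2", "UG"), each = n),
    group_id = c(paste0("m", seq_len(3 * n)), rep("", n))))
  c1 <- genome_composition(mk(1))
  expect_equal(c1$percent, rep(25.0, 4))
  c9 <- genome_composition(mk(9))
  expect_equal(c1$fraction, c9$fraction)
  expect_error(genome_composition(mk(1)[0, ]), "empty")
})

test_that("expressed composition equals brute-force tallies and sums to 1", {
  sim <- simulate_dataset(tiny_config())
  norm <- normalize_counts(sim$counts)
  expr <- detect_expressed(sim$counts)
  prof <- pseudobulk(norm, sim$counts$clusters, expr)
  comp <- expressed_composition(prof, sim$homology)
  sg <- setNames(sim$homology$subgenome, sim$homology$gene_id)
  for (cl in prof$clusters) {
    genes_on <- colnames(expr)[expr[cl, ]]
    want <- table(factor(sg[genes_on], c("LF", "MF1", "MF2", "UG")))
    sub <- comp[comp$cluster == cl, ]
    expect_equal(sub$n_expressed, as.integer(want))
    expect_equal(sum(sub$proportion), 1, tolerance = 1e-12)
  }
})

test_that("per-class expressed fractions match brute force and tolerate an
          absent class", {
  sim <- simulate_dataset(tiny_config())
  expr <- detect_expressed(sim$counts)
  prof <- pseudobulk(normalize_counts(sim$counts), sim$counts$clusters, expr)
  frac <- expressed_fraction_by_class(prof, sim$homology)
  cls <- classify_groups(sim$homology)
  for (cl in prof$clusters) {
    on <- colnames(expr)[expr[cl, ]]
    for (k in c("triad", "duplet", "monad", "ungrouped")) {
      members <- names(cls$gene_class)[cls$gene_class == k]
      want <- mean(members %in% on)
      got <- frac$fraction[frac$cluster == cl & frac$class == k]
      expect_equal(got, want)
    }
  }
  # class absent from the genome: NA fraction, no crash
  no_ug <- homology_table(
    as.data.frame(sim$homology)[sim$homology$subgenome != "UG", ])
  f2 <- expressed_fraction_by_class(prof, no_ug)
  expect_true(all(is.na(f2$fraction[f2$class == "ungrouped"])))
})

test_that("one-way ANOVA matches the textbook sum-of-squares closed form", {
  mk_profile <- function(values, groups) {
    # one cluster, one gene per observation
    genes <- sprintf("g%03d", seq_along(values))
    me <- matrix(values, 1, dimnames = list("C", genes))
    ex <- matrix(TRUE, 1, length(values), dimnames = list("C", genes))
    prof <- structure(list(clusters = "C", mean_expr = me, expressed = ex,
                           n_cells = c(C = 1L)), class = "cluster_profile")
    tab <- homology_table(data.frame(gene_id = genes, subgenome = groups,
                                     group_id = ifelse(groups == "UG", "",
                                                       genes)))
    list(prof = prof, tab = tab)
  }
  # groups (1,2), (5,6), (9,10): F = 64, p = pf(64, 2, 3, lower = FALSE)
  f <- mk_profile(c(1, 2, 5, 6, 9, 10), rep(c("LF", "MF1", "MF2"), each = 2))
  a <- subgenome_anova(f$prof, f$tab, "C")
  expect_equal(a$F, 64)
  expect_equal(a$p, 0.00346557209980753, tolerance = 1e-12)
  expect_equal(unname(a$group_means), c(1.5, 5.5, 9.5))
  # identical group value-vectors: F = 0
  g0 <- mk_profile(c(1, 2, 3, 1, 2, 3), rep(c("LF", "MF1"), each = 3))
  expect_equal(subgenome_anova(g0$prof, g0$tab, "C")$F, 0)
  # all observations identical: F = 0, p = 1 by convention
  gc <- mk_profile(rep(2, 6), rep(c("LF", "MF1", "MF2"), each = 2))
  ac <- subgenome_anova(gc$prof, gc$tab, "C")
  expect_equal(ac$F, 0); expect_equal(ac$p, 1)
  # insufficient groups
  g1 <- mk_profile(c(1, 2, 3), c("LF", "LF", "LF"))
  expect_error(subgenome_anova(g1$prof, g1$tab, "C"), "insufficient")
})

test_that("ANOVA agrees with a hand-computed between/within decomposition on
          random fixtures", {
  set.seed(77)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    n <- sample(3:10, k, replace = TRUE)
    groups <- rep(c("LF", "MF1", "MF2", "UG")[seq_len(k)], times = n)
    y <- round(rnorm(sum(n), mean = rep(runif(k, 0, 4), times = n)), 3)
    genes <- sprintf("g%03d", seq_along(y))
    me <- matrix(y, 1, dimnames = list("C", genes))
    ex <- matrix(TRUE, 1, length(y), dimnames = list("C", genes))
    prof <- structure(list(clusters = "C", mean_expr = me, expressed = ex,
                           n_cells = c(C = 1L)), class = "cluster_profile")
    tab <- homology_table(data.frame(
      gene_id = genes, subgenome = groups,
      group_id = ifelse(groups == "UG", "", genes)))
    a <- subgenome_anova(prof, tab, "C")
    # independent oracle: explicit SS arithmetic
    gm <- tapply(y, groups, mean)
    ssb <- sum(tapply(y, groups, length) * (gm - mean(y))^2)
    ssw <- sum((y - gm[groups])^2)
    F_oracle <- (ssb / (k - 1)) / (ssw / (length(y) - k))
    expect_lt(abs(a$F - F_oracle), 1e-8)
    expect_equal(a$p, pf(F_oracle, k - 1, length(y) - k, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("UG contrasts report each subgenome against UG", {
  set.seed(3)
  y <- c(rnorm(5, 3), rnorm(5, 3.2), rnorm(5, 2.9), rnorm(5, 1))
  groups <- rep(c("LF", "MF1", "MF2", "UG"), each = 5)
  genes <- sprintf("g%03d", seq_along(y))
  me <- matrix(y, 1, dimnames = list("C", genes))
  ex <- matrix(TRUE, 1, length(y), dimnames = list("C", genes))
  prof <- structure(list(clusters = "C", mean_expr = me, expressed = ex,
                         n_cells = c(C = 1L)), class = "cluster_profile")
  tab <- homology_table(data.frame(gene_id = genes, subgenome = groups,
                                   group_id = ifelse(groups == "UG", "",
                                                     genes)))
  a <- subgenome_anova(prof, tab, "C")
  expect_equal(a$contrasts$contrast, c("LF-UG", "MF1-UG", "MF2-UG"))
  gm <- tapply(y, groups, mean)
  expect_equal(a$contrasts$estimate,
               as.numeric(gm[c("LF", "MF1", "MF2")] - gm[["UG"]]))
  expect_true(all(a$contrasts$p < 0.05))
})
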