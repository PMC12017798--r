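# Small simulation configs and in-code fixtures shared across tests.

# a 1/50-scale genome with a 3-cluster population; fast enough for most tests
tiny_config <- function(seed = 101, ...) {
  sim_config(n_clusters = 3, cells_per_cluster = 40,
             genome = brapa_genome(0.02), seed = seed, ...)
}

# hand-built homology table: 2 triads, 1 duplet (LF:MF2), 2 monads, 2 UG
toy_homology <- function() {
  homology_table(data.frame(
    gene_id = c("a_LF", "a_M1", "a_M2", "b_LF", "b_M1", "b_M2",
                "d_LF", "d_M2", "m1", "m2", "u1", "u2"),
    subgenome = c("LF", "MF1", "MF2", "LF", "MF1", "MF2",
                  "LF", "MF2", "MF1", "MF2", "UG", "UG"),
    group_id = c("t1", "t1", "t1", "t2", "t2", "t2",
                 "dp1", "dp1", "mo1", "mo2", "", "")))
}

# dense matrix -> count_matrix with auto-generated names
as_cm <- function(m, clusters = NULL) {
  count_matrix(Matrix::Matrix(m, sparse = TRUE),
               barcodes = sprintf("c%03d", seq_len(nrow(m))),
               gene_ids = sprintf("g%03d", seq_len(ncol(m))),
               clusters = clusters)
}

# uniform random simplex points (flat Dirichlet), n x 3
random_simplex <- function(n) {
  g <- matrix(stats::rexp(n * 3), n, 3)
  g / rowSums(g)
}

# independent nearest-centroid oracle: explicit centroid list, loop + which.min
oracle_classify <- function(r) {
  cents <- list(Balanced = c(1, 1, 1) / 3, LF_dominant = c(1, 0, 0),
                MF1_dominant = c(0, 1, 0), MF2_dominant = c(0, 0, 1),
                LF_suppressed = c(0, 0.5, 0.5),
                MF1_suppressed = c(0.5, 0, 0.5),
                MF2_suppressed = c(0.5, 0.5, 0))
  d <- vapply(cents, function(mu) sqrt(sum((r - mu)^2)), numeric(1))
  names(cents)[which.min(d)]
}
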