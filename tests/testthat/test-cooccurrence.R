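test_that("right-sided Fisher matches exact enumeration on worked tables", {
  # both-present diagonal: single most extreme table
  expect_equal(fisher_right(matrix(c(4, 0, 0, 4), 2, byrow = TRUE)), 1 / 70,
               tolerance = 1e-12)
  # balanced table: tail over x in {2, 3, 4}
  expect_equal(fisher_right(matrix(c(2, 2, 2, 2), 2, byrow = TRUE)), 53 / 70,
               tolerance = 1e-12)
  # zero margins -> degenerate support -> p = 1
  expect_equal(fisher_right(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)), 1)
  expect_equal(fisher_right(matrix(c(0, 4, 0, 5), 2, byrow = TRUE)), 1)
  expect_error(fisher_right(matrix(c(-1, 0, 0, 4), 2)), class = "domain_error")
  expect_error(fisher_right(matrix(c(0.5, 0, 0, 4), 2)), class = "domain_error")
})

test_that("fisher_right equals the hypergeometric tail oracle over all margins", {
  # exhaustive over all margin combinations up to N = 25 in the unit suite
  # (the acceptance suite extends this to N = 60)
  for (N in c(0, 1, 5, 12, 25)) {
    for (m in 0:N) {
      n <- N - m
      for (k in 0:N) {
        lo <- max(0, k - n); hi <- min(k, m)
        for (a in unique(c(lo, pmin(hi, lo + 1), hi))) {
          tb <- matrix(c(a, m - a, k - a, n - (k - a)), 2, byrow = TRUE)
          expect_equal(fisher_right(tb), oracle_hyper_tail(a, m, n, k),
                       tolerance = 1e-12)
        }
      }
    }
  }
  # monotone non-increasing in the both-present count at fixed margins
  ps <- vapply(0:4, function(a) {
    fisher_right(matrix(c(a, 4 - a, 4 - a, 2 + a), 2, byrow = TRUE))
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
  # cross-check against the established exact test implementation
  set.seed(5)
  for (i in 1:20) {
    tb <- matrix(sample(0:8, 4, replace = TRUE), 2)
    expect_equal(fisher_right(tb),
                 stats::fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("pairwise co-occurrence restricts to the anchor universe", {
  m <- matrix(FALSE, 10, 3, dimnames = list(sprintf("g%02d", 1:10),
                                            c("anchor", "A", "B")))
  m[, "anchor"] <- TRUE
  m[1:5, "A"] <- TRUE
  m[1:5, "B"] <- TRUE
  pw <- pairwise_cooccurrence(m, "anchor")
  # A-B: both in the same 5 of 10 genomes
  ab <- pw[pw$protein_a == "A" & pw$protein_b == "B", ]
  expect_equal(ab$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(ab$both, 5)
  # anchor self-pair absent; anchor pairs are margin-degenerate with p = 1
  expect_false(any(pw$protein_a == "anchor" & pw$protein_b == "anchor"))
  expect_true(all(pw$p[pw$protein_a == "anchor"] == 1))
  # a protein present in every universe genome is degenerate against any other
  m2 <- m; m2[, "A"] <- TRUE
  pw2 <- pairwise_cooccurrence(m2, "anchor")
  expect_equal(pw2$p[pw2$protein_a == "A" & pw2$protein_b == "B"], 1)
  expect_error(pairwise_cooccurrence(m, "missing"), class = "key_error")

  # permuting genome rows leaves all p-values unchanged
  set.seed(9)
  sim <- simulate_presence_matrix(n_genomes = 40, flip_prob = 0.1, seed = 2)
  p1 <- pairwise_cooccurrence(sim, "anchor")
  perm <- sim[sample(nrow(sim)), ]
  p2 <- pairwise_cooccurrence(perm, "anchor")
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
})

test_that("BH adjustment applies the step-up rule with monotone discoveries", {
  # worked example: only 0.001 <= (1/3) * 0.01 survives at q = 0.01
  adj <- bh_adjust(c(0.001, 0.02, 0.5), q = 0.01)
  expect_equal(sum(adj$discovery), 1)
  expect_equal(adj$p_adj, c(0.003, 0.03, 0.5), tolerance = 1e-12)

  expect_equal(sum(bh_adjust(rep(1, 10), 0.01)$discovery), 0)
  expect_true(bh_adjust(0.009, 0.01)$discovery)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "domain_error")

  # discovery count is monotone non-decreasing in q
  set.seed(13)
  for (i in 1:10) {
    p <- stats::runif(30)^2
    counts <- vapply(c(0.001, 0.01, 0.05, 0.1, 0.5),
                     function(q) sum(bh_adjust(p, q)$discovery), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("network construction thresholds edges and counts degrees", {
  pairs <- data.frame(
    protein_a = c("A", "B", "A"), protein_b = c("B", "C", "C"),
    p = c(1e-6, 2e-6, 0.8)
  )
  net <- build_network(pairs, q = 0.01)
  expect_equal(net$nodes$degree[net$nodes$protein == "B"], 2)
  expect_equal(net$nodes$degree[net$nodes$protein == "A"], 1)
  expect_equal(net$nodes$degree[net$nodes$protein == "C"], 1)
  expect_true(all(net$edges$p_adj >= net$edges$p_raw))

  # no significant pairs -> empty edge set, all degrees zero
  net0 <- build_network(data.frame(protein_a = "A", protein_b = "B", p = 0.9))
  expect_equal(sum(net0$edges$significant), 0)
  expect_equal(net0$nodes$degree, c(0L, 0L))

  # threshold 1 keeps the complete graph
  net1 <- build_network(pairs, q = 1)
  expect_equal(sum(net1$edges$significant), 3)
})

test_that("a perfectly co-occurring module is recovered as a clique", {
  sim <- simulate_presence_matrix(
    n_genomes = 30, anchor_prob = 1,
    modules = list(clock = list(proteins = c("kaiA3", "kaiB3", "kaiC3"),
                                prevalence = 0.5)),
    n_background = 3, background_prob = 0.5, seed = 7
  )
  out <- withr::local_tempdir()
  net <- run_cooccurrence(sim, "anchor", q = 0.01, out_dir = out)
  expect_true(all(file.exists(file.path(out, c("edges.csv", "nodes.csv",
                                               "manifest.json")))))
  expect_equal(nrow(utils::read.csv(file.path(out, "edges.csv"))),
               nrow(net$edges))
  sig <- net$edges[net$edges$significant, ]
  trio <- c("kaiA3", "kaiB3", "kaiC3")
  in_trio <- sig$protein_a %in% trio & sig$protein_b %in% trio
  expect_equal(sum(in_trio), 3) # the 3-clique
  deg <- net$nodes$degree[net$nodes$protein %in% trio]
  expect_true(all(deg >= 2))
  expect_error(run_cooccurrence(matrix(TRUE, 3, 1,
                                       dimnames = list(letters[1:3], "x")),
                                "x"),
               class = "config_error")
})

test_that("presence matrices round-trip through delimited text", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- simulate_presence_matrix(n_genomes = 15, seed = 3)
  utils::write.csv(data.frame(genome = rownames(sim), sim * 1L,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  back <- read_presence_matrix(path)
  expect_equal(unname(back), unname(sim == TRUE))
  expect_equal(colnames(back), colnames(sim))
})
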