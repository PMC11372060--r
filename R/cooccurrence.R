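#' Read a genome x protein presence/absence matrix
#'
#' Delimited text, genomes as rows (first column = genome id), proteins as
#' columns (header row); cell values are interpreted as logical (0/1,
#' TRUE/FALSE).
#'
#' @param path file path.
#' @param sep delimiter (default comma).
#' @return logical matrix with genome rownames and protein colnames.
#' @export
read_presence_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  if (is.character(m)) {
    m <- matrix(trimws(m) %in% c("1", "TRUE", "true", "T"),
                nrow(df), ncol(df), dimnames = dimnames(df))
  }
  mode(m) <- "logical"
  if (anyNA(m)) cr_abort("presence matrix contains unparseable cells", "parse_error")
  validate_presence_matrix(m)
}

#' Validate a presence/absence matrix
#' @param m logical matrix, genomes x proteins, unique dimnames.
#' @return the matrix, invisibly usable.
#' @export
validate_presence_matrix <- function(m) {
  if (!is.matrix(m) || !is.logical(m)) {
    cr_abort("presence matrix must be a logical matrix", "parse_error")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    cr_abort("presence matrix needs genome rownames and protein colnames",
             "parse_error")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    cr_abort("duplicate genome or protein ids", "parse_error")
  }
  m
}

#' Right-sided Fisher's exact test on a 2x2 table
#'
#' Exact right-tail hypergeometric probability `P(X >= a)` given fixed
#' margins, where `a` is the both-present count (top-left cell): the
#' enrichment test for joint presence. Computed in log space via the
#' hypergeometric distribution function for numerical stability. A table
#' with a zero row or column margin has degenerate support and returns 1.
#'
#' @param table 2x2 matrix of nonnegative integer counts,
#'   rows = protein 1 present/absent, columns = protein 2 present/absent.
#' @return p-value in (0, 1].
#' @examples
#' fisher_right(matrix(c(4, 0, 0, 4), 2, byrow = TRUE)) # 1/70
#' @export
fisher_right <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) cr_abort("need a 2x2 table", "shape_error")
  if (any(tb < 0) || any(tb != round(tb)) || anyNA(tb)) {
    cr_abort("counts must be nonnegative integers", "domain_error")
  }
  a <- tb[1, 1]
  m <- tb[1, 1] + tb[1, 2] # protein-1 present
  n <- tb[2, 1] + tb[2, 2] # protein-1 absent
  k <- tb[1, 1] + tb[2, 1] # protein-2 present
  # P(X >= a), X ~ Hypergeometric(m, n, k)
  exp(stats::phyper(a - 1, m, n, k, lower.tail = FALSE, log.p = TRUE))
}

#' Pairwise co-occurrence p-values within an anchor-restricted universe
#'
#' Restricts the genome universe to genomes carrying the anchor protein
#' (e.g. the canonical clock kinase, so only genomes with a functional core
#' clock are compared), then computes a right-sided Fisher's exact test for
#' joint presence of every unordered protein pair within that universe. The
#' anchor's self-pair is excluded; pairs involving the anchor are degenerate
#' (the anchor is present throughout the universe) and return p = 1.
#'
#' @param m logical presence matrix (genomes x proteins).
#' @param anchor protein id defining the universe.
#' @return data.frame with columns `protein_a`, `protein_b`, `n_universe`,
#'   `both`, `only_a`, `only_b`, `neither`, `p`.
#' @export
pairwise_cooccurrence <- function(m, anchor) {
  m <- validate_presence_matrix(m)
  if (!anchor %in% colnames(m)) {
    cr_abort(sprintf("anchor protein '%s' not in matrix", anchor), "key_error")
  }
  u <- m[m[, anchor], , drop = FALSE]
  proteins <- colnames(m)
  pairs <- utils::combn(proteins, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pa <- u[, pairs[1, j]]
    pb <- u[, pairs[2, j]]
    tb <- matrix(c(sum(pa & pb), sum(pa & !pb),
                   sum(!pa & pb), sum(!pa & !pb)), 2, 2, byrow = TRUE)
    data.frame(protein_a = pairs[1, j], protein_b = pairs[2, j],
               n_universe = nrow(u), both = tb[1, 1], only_a = tb[1, 2],
               only_b = tb[2, 1], neither = tb[2, 2], p = fisher_right(tb))
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjustment with discovery flags
#'
#' Step-up FDR adjustment (monotone, capped at 1); a pair is a discovery when
#' its adjusted p-value is at most `q` (the published analysis used an
#' expected false discovery rate of 0.01).
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.01).
#' @return list with `p_adj` and logical `discovery`.
#' @export
bh_adjust <- function(pvals, q = 0.01) {
  pvals <- as.numeric(pvals)
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    cr_abort("p-values must lie in [0, 1]", "domain_error")
  }
  p_adj <- stats::p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, discovery = p_adj <= q)
}

#' Build the co-occurrence network
#'
#' Edges are protein pairs whose (by default adjusted) p-value is at or below
#' the threshold; node degree counts incident edges. In the published network
#' figure, missing links were those with p-values above 0.01.
#'
#' @param pairs data.frame from [pairwise_cooccurrence()].
#' @param q FDR level / edge threshold (default 0.01).
#' @param use_raw threshold the raw instead of the BH-adjusted p-values
#'   (default `FALSE`).
#' @return object of class `cooccur_network`: `edges` (data.frame
#'   `protein_a`, `protein_b`, `p_raw`, `p_adj`, `significant`), `nodes`
#'   (data.frame `protein`, `degree`), `q`.
#' @export
build_network <- function(pairs, q = 0.01, use_raw = FALSE) {
  adj <- bh_adjust(pairs$p, q)
  crit <- if (use_raw) pairs$p else adj$p_adj
  edges <- data.frame(
    protein_a = pairs$protein_a, protein_b = pairs$protein_b,
    p_raw = pairs$p, p_adj = adj$p_adj, significant = crit <= q
  )
  proteins <- sort(unique(c(pairs$protein_a, pairs$protein_b)))
  sig <- edges[edges$significant, , drop = FALSE]
  deg <- table(factor(c(sig$protein_a, sig$protein_b), levels = proteins))
  structure(
    list(edges = edges,
         nodes = data.frame(protein = proteins, degree = as.integer(deg)),
         q = q),
    class = "cooccur_network"
  )
}

#' @export
print.cooccur_network <- function(x, ...) {
  cat(sprintf("<cooccur_network> %d proteins, %d/%d significant pairs (q = %g)\n",
              nrow(x$nodes), sum(x$edges$significant), nrow(x$edges), x$q))
  invisible(x)
}

#' Simulate a synthetic presence/absence matrix
#'
#' Test-bed generator for the co-occurrence analysis: an anchor protein
#' present in a subset of genomes, one or more co-occurring modules (protein
#' sets present together in a random subset of the anchor universe), plus
#' background proteins present independently at random. Presence calls can be
#' flipped with a small noise probability.
#'
#' @param n_genomes number of genomes.
#' @param anchor_prob probability a genome carries the anchor.
#' @param modules named list: each element a list with `proteins` (ids) and
#'   `prevalence` (probability the module is present in an anchor genome).
#' @param n_background number of independent background proteins.
#' @param background_prob presence probability of background proteins.
#' @param flip_prob probability of flipping any presence call (noise).
#' @param seed RNG seed.
#' @return logical matrix (genomes x proteins) with an `"anchor"` attribute.
#' @export
simulate_presence_matrix <- function(n_genomes = 60, anchor_prob = 0.8,
                                     modules = list(
                                       clockA = list(
                                         proteins = c("kaiA3", "kaiB3", "kaiC3"),
                                         prevalence = 0.5
                                       )
                                     ),
                                     n_background = 4, background_prob = 0.5,
                                     flip_prob = 0, seed = 1L) {
  set.seed(as.integer(seed))
  anchor <- stats::runif(n_genomes) < anchor_prob
  cols <- list(anchor = anchor)
  for (mod in modules) {
    on <- anchor & (stats::runif(n_genomes) < mod$prevalence)
    for (p in mod$proteins) cols[[p]] <- on
  }
  for (b in seq_len(n_background)) {
    cols[[sprintf("bg%02d", b)]] <- stats::runif(n_genomes) < background_prob
  }
  m <- do.call(cbind, cols)
  if (flip_prob > 0) {
    flips <- matrix(stats::runif(length(m)) < flip_prob, nrow(m))
    m <- xor(m, flips)
  }
  rownames(m) <- sprintf("genome%03d", seq_len(n_genomes))
  attr(m, "anchor") <- "anchor"
  m
}

#' Write network tables to CSV
#' @param network a [build_network()] result.
#' @param edge_path,node_path output paths.
#' @return invisibly, the edge path.
#' @export
write_network <- function(network, edge_path, node_path) {
  utils::write.csv(network$edges, edge_path, row.names = FALSE)
  utils::write.csv(network$nodes, node_path, row.names = FALSE)
  invisible(edge_path)
}
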