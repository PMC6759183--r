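# Trait-seeded mutual-rank (MR) co-expression networks.
#
# For every pair of nodes (genes plus seed traits) the MR is the geometric
# mean of the two directed correlation ranks: if gene j is the 2nd most
# correlated node of gene i and i is the 8th of j, MR(i,j) = sqrt(2*8) = 4.
# Small MR = strong, mutual co-expression. Networks are grown from trait
# seeds: genes whose MR to any seed is below a threshold join, and
# gene-gene edges below the threshold among joined genes are kept.

#' Mutual-rank matrix over genes and seed traits
#'
#' @param expr Genes x samples numeric matrix (log-scale expression).
#' @param seed_traits Named list or data frame of per-sample trait vectors
#'   (e.g. line-matched BLUPs), aligned to the columns of `expr`.
#' @return Object of class `mr_matrix`: `mr` (nodes x nodes, diagonal NA),
#'   `cor` (Pearson correlations), `seeds` (seed node names). Rank ties get
#'   average ranks.
#' @export
mutual_ranks <- function(expr, seed_traits = NULL) {
  m <- as.matrix(expr)
  if (!is.null(seed_traits)) {
    st <- as.matrix(as.data.frame(seed_traits))
    if (nrow(st) != ncol(m)) abort("seed traits must align with samples")
    m <- rbind(m, t(st))
  }
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(paste("excluding zero-variance nodes:",
               paste(rownames(m)[sds == 0], collapse = ", ")))
    m <- m[sds > 0, , drop = FALSE]
  }
  cc <- cor(t(m))
  diag(cc) <- NA
  # rank 1 = most correlated, per row, self excluded
  R <- t(apply(-cc, 1, rank, na.last = "keep"))
  mr <- sqrt(R * t(R))
  seeds <- if (is.null(seed_traits)) character(0) else
    intersect(colnames(as.data.frame(seed_traits)), rownames(m))
  structure(list(mr = mr, cor = cc, seeds = seeds), class = "mr_matrix")
}

#' Seed-expanded MR network
#'
#' Includes every gene whose MR to at least one seed is `<= threshold`,
#' then every gene-gene edge `<= threshold` among included genes. Seeds
#' sharing a correlated gene contribute it once (the node set is a union).
#' Edges carry the correlation value, whose sign distinguishes positive
#' from negative co-expression.
#'
#' @param mr An `mr_matrix`.
#' @param seeds Seed node names (default: the traits stored in `mr`).
#' @param threshold MR cutoff; the reference series used 10, 20, 30, 50.
#' @return Object of class `mr_network`: `nodes` tibble (`node`, `type`),
#'   `edges` tibble (`from`, `to`, `mr`, `cor`), `threshold`.
#' @export
seed_mr_network <- function(mr, seeds = mr$seeds, threshold = 30) {
  if (!all(seeds %in% rownames(mr$mr))) {
    abort(paste("unknown seeds:",
                paste(setdiff(seeds, rownames(mr$mr)), collapse = ", ")))
  }
  genes <- setdiff(rownames(mr$mr), seeds)
  sg <- mr$mr[seeds, genes, drop = FALSE]
  joined <- genes[apply(sg <= threshold, 2, any)]
  nodes <- tibble(node = c(seeds, joined),
                  type = c(rep("seed", length(seeds)),
                           rep("gene", length(joined))))
  edge_rows <- function(a, b) {
    mr_val <- mr$mr[cbind(a, b)]
    cor_val <- mr$cor[cbind(a, b)]
    tibble(from = a, to = b, mr = mr_val, cor = cor_val)
  }
  # seed-gene edges
  se <- which(sg <= threshold, arr.ind = TRUE)
  edges <- if (nrow(se) > 0) {
    edge_rows(seeds[se[, 1]], genes[se[, 2]])
  } else {
    tibble(from = character(), to = character(), mr = numeric(),
           cor = numeric())
  }
  # gene-gene edges among joined genes
  if (length(joined) > 1) {
    gg <- mr$mr[joined, joined, drop = FALSE]
    gg[lower.tri(gg, diag = TRUE)] <- NA
    ge <- which(gg <= threshold, arr.ind = TRUE)
    if (nrow(ge) > 0) {
      edges <- bind_rows(edges, edge_rows(joined[ge[, 1]], joined[ge[, 2]]))
    }
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "mr_network")
}

#' @exportS3Method
tidy.mr_network <- function(x, ...) x$edges

#' Permutation test of seeded-network size
#'
#' Shuffles the seed-trait values across samples (one permutation of the
#' sample labels applied jointly to all seeds, preserving trait-trait
#' correlation), rebuilds the seeded network, and records the number of
#' seed-gene edges. The empirical p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (n_perm + 1), so it is never zero.
#'
#' @param expr Genes x samples matrix.
#' @param seed_traits As in [mutual_ranks()].
#' @param threshold MR cutoff.
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @return List: `observed` (seed-gene edge count), `null` (length
#'   `n_perm`), `p.value`, `zero_edge_fraction` (share of permutations with
#'   an empty seeded network).
#' @export
mr_permutation_test <- function(expr, seed_traits, threshold = 30,
                                n_perm = 100, seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  set.seed(as.integer(seed))
  count_edges <- function(st) {
    mr <- mutual_ranks(expr, st)
    genes <- setdiff(rownames(mr$mr), mr$seeds)
    sum(mr$mr[mr$seeds, genes, drop = FALSE] <= threshold)
  }
  st <- as.data.frame(seed_traits)
  observed <- count_edges(st)
  null <- vapply(seq_len(n_perm), function(i) {
    count_edges(st[sample(nrow(st)), , drop = FALSE])
  }, numeric(1))
  list(observed = observed, null = null,
       p.value = (1 + sum(null >= observed)) / (n_perm + 1),
       zero_edge_fraction = mean(null == 0))
}
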