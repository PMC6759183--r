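# Expression preprocessing, mutual-rank networks, and signed-hybrid
# modules/eigengenes.

sim_counts <- function(n_genes, n_samples, seed = 1, lib = 1e5) {
  set.seed(seed)
  mu <- 2^stats::rnorm(n_genes, 6, 1.5)
  m <- matrix(stats::rpois(n_genes * n_samples, rep(mu, n_samples)),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  m
}

# samples x modules latent factors -> genes x samples log expression
sim_modular_expr <- function(n_per_module = 40, n_modules = 5, n_samples = 60,
                             noise = 0.3, seed = 1) {
  set.seed(seed)
  fac <- matrix(stats::rnorm(n_modules * n_samples), n_modules)
  m <- do.call(rbind, lapply(seq_len(n_modules), function(k) {
    load <- stats::runif(n_per_module, 0.8, 1.2)
    outer(load, fac[k, ]) + matrix(stats::rnorm(n_per_module * n_samples, 0, noise),
                                   n_per_module)
  }))
  rownames(m) <- sprintf("mod%d_g%02d", rep(seq_len(n_modules), each = n_per_module),
                         rep(seq_len(n_per_module), n_modules))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  list(expr = m, truth = rep(seq_len(n_modules), each = n_per_module),
       factors = fac)
}

test_that("count preprocessing filters, normalises, and flags bad libraries", {
  m <- sim_counts(200, 10, seed = 1)
  m[1, ] <- 0                        # all-zero gene must go
  em <- preprocess_counts(m, cpm_min = 2, min_samples = 5)
  expect_false("g001" %in% rownames(em$log2cpm))

  # identical libraries have unit TMM factors
  same <- matrix(rep(m[, 1], 4), ncol = 4,
                 dimnames = list(rownames(m), paste0("s", 1:4)))
  em2 <- preprocess_counts(same, cpm_min = 0, min_samples = 1)
  expect_equal(unname(em2$norm_factors), rep(1, 4), tolerance = 1e-9)

  # doubling a library without composition change is undone by the factors:
  # exactly proportional libraries so the trimmed M-values are all zero
  base <- m[, 2] + 1L
  prop <- cbind(orig = base, other = 3L * base, doubled = 2L * base)
  em3 <- preprocess_counts(prop, cpm_min = 0, min_samples = 1)
  expect_equal(em3$log2cpm[, "orig"], em3$log2cpm[, "doubled"],
               tolerance = 1e-6)

  zz <- m; zz[, 2] <- 0
  expect_error(preprocess_counts(zz, cpm_min = 0, min_samples = 1),
               "zero total counts")
})

test_that("top_variable ranks by between-line variance with deterministic ties", {
  m <- sim_counts(50, 8, seed = 2)
  lm2 <- log2(m + 0.5)
  expect_identical(nrow(top_variable(lm2, k = 500)), 50L)
  kept <- top_variable(lm2, k = 10)
  v <- apply(lm2, 1, var)
  expect_setequal(rownames(kept), names(sort(v, decreasing = TRUE))[1:10])
  expect_true(all(diff(apply(kept, 1, var)) <= 1e-12))

  # replicate collapsing by line mean
  line <- rep(c("A", "B", "C", "D"), each = 2)
  collapsed <- top_variable(lm2, k = 5, line = line)
  expect_equal(ncol(collapsed), 4)
})

test_that("mutual ranks agree with a brute-force oracle and are symmetric", {
  set.seed(3)
  m <- matrix(stats::rnorm(10 * 30), 10,
              dimnames = list(paste0("n", 1:10), NULL))
  mr <- mutual_ranks(m)
  expect_true(all(abs(mr$mr - t(mr$mr)) < 1e-12, na.rm = TRUE))
  expect_true(all(mr$mr >= 1, na.rm = TRUE))
  oracle <- mr_bruteforce(mr$cor)
  expect_equal(mr$mr, oracle, tolerance = 1e-12)
})

test_that("mutual top correlates get MR 1 and rank products average over ties", {
  set.seed(4)
  base <- stats::rnorm(40)
  m <- rbind(a = base + stats::rnorm(40, 0, 0.01),
             b = base + stats::rnorm(40, 0, 0.01),
             c = stats::rnorm(40), d = stats::rnorm(40), e = stats::rnorm(40))
  mr <- mutual_ranks(m)
  expect_equal(mr$mr["a", "b"], 1)
})

test_that("seeded networks grow monotonically with the MR threshold", {
  sm <- sim_modular_expr(n_per_module = 15, n_modules = 3, n_samples = 40,
                         seed = 5)
  trait <- sm$factors[1, ] + stats::rnorm(40, 0, 0.2)
  mr <- mutual_ranks(sm$expr, data.frame(trait = trait))
  nets <- lapply(c(10, 20, 30, 50), function(th)
    seed_mr_network(mr, threshold = th))
  for (i in 1:3) {
    expect_true(all(nets[[i]]$nodes$node %in% nets[[i + 1]]$nodes$node))
  }
  # an impossible threshold keeps only the seeds
  n0 <- seed_mr_network(mr, threshold = 0.5)
  expect_equal(n0$nodes$node, "trait")
  expect_equal(nrow(n0$edges), 0)
  expect_error(seed_mr_network(mr, seeds = "nope", threshold = 10),
               "unknown seeds")
})

test_that("trait-seeded networks recover a planted co-expression cluster", {
  sm <- sim_modular_expr(n_per_module = 20, n_modules = 4, n_samples = 60,
                         noise = 0.4, seed = 6)
  trait <- sm$factors[2, ] + stats::rnorm(60, 0, 0.3)
  mr <- mutual_ranks(sm$expr, data.frame(trait = trait))
  net <- seed_mr_network(mr, threshold = 30)
  cluster <- rownames(sm$expr)[sm$truth == 2]
  recovered <- mean(cluster %in% net$nodes$node)
  expect_gte(recovered, 0.9)
})

test_that("MR permutation p-values behave at the extremes", {
  sm <- sim_modular_expr(n_per_module = 10, n_modules = 3, n_samples = 40,
                         seed = 7)
  # trait built from a planted gene set is maximally extreme
  trait <- colMeans(sm$expr[sm$truth == 1, ])
  res <- mr_permutation_test(sm$expr, data.frame(t = trait), threshold = 10,
                             n_perm = 50, seed = 8)
  expect_equal(res$p.value, 1 / 51)
  expect_gte(min(res$null), 0)

  # independent trait: p bounded and not extreme
  res0 <- mr_permutation_test(sm$expr, data.frame(t = stats::rnorm(40)),
                              threshold = 10, n_perm = 50, seed = 9)
  expect_gte(res0$p.value, 1 / 51)
  expect_lte(res0$p.value, 1)
  expect_gt(res0$p.value, 0.05)
})

test_that("soft-threshold selection returns the lowest qualifying power", {
  sm <- sim_modular_expr(n_per_module = 30, n_modules = 5, n_samples = 50,
                         noise = 0.6, seed = 10)
  ps <- pick_soft_threshold(sm$expr, powers = c(1, 2, 3, 4, 6, 8, 10))
  qual <- ps$fits$power[ps$fits$fit > 0.9]
  if (length(qual) > 0) {
    expect_false(ps$flagged)
    expect_equal(ps$power, min(qual))
  } else {
    expect_true(ps$flagged)
  }
  expect_error(pick_soft_threshold(sm$expr, powers = -1), "positive")
})

test_that("signed-hybrid adjacency zeroes negative correlations and TOM matches brute force", {
  set.seed(11)
  m <- matrix(stats::rnorm(20 * 30), 20,
              dimnames = list(paste0("g", 1:20), NULL))
  m[2, ] <- -m[1, ] + stats::rnorm(30, 0, 0.1)  # strongly negative pair
  a <- signed_hybrid_adjacency(m, power = 3)
  expect_equal(a[1, 2], 0)
  expect_true(all(a >= 0 & a <= 1))
  tom <- topological_overlap(a)
  expect_true(all(abs(tom - t(tom)) < 1e-12))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  expect_equal(tom, tom_bruteforce(a), tolerance = 1e-10)
})

test_that("module detection recovers planted orthogonal modules", {
  sm <- sim_modular_expr(n_per_module = 40, n_modules = 5, n_samples = 60,
                         noise = 0.3, seed = 12)
  mods <- build_modules(sm$expr, power = 6, min_module_size = 10,
                        cut_height = 0.6)
  found <- mods$module
  ari <- adjusted_rand(found, sm$truth)
  expect_gt(ari, 0.9)
})

test_that("eigengenes summarise modules as oriented unit-variance first PCs", {
  sm <- sim_modular_expr(n_per_module = 10, n_modules = 2, n_samples = 20,
                         noise = 0.2, seed = 13)
  mods <- tibble::tibble(gene = rownames(sm$expr),
                         module = sprintf("M%02d", sm$truth))
  eg <- eigengenes(sm$expr, mods)
  expect_equal(dim(eg), c(2, 20))
  expect_equal(apply(eg, 1, stats::sd), c(M01 = 1, M02 = 1), tolerance = 1e-9)
  # orientation: positively correlated with the module mean profile
  for (k in 1:2) {
    mm <- colMeans(sm$expr[sm$truth == k, ])
    expect_gt(stats::cor(eg[k, ], mm), 0.9)
  }
  # a module of identical profiles returns that standardised profile
  prof <- stats::rnorm(20)
  same <- matrix(rep(prof, 5), 5, byrow = TRUE,
                 dimnames = list(paste0("h", 1:5), NULL))
  egs <- eigengenes(same, tibble::tibble(gene = paste0("h", 1:5),
                                         module = "M01"))
  expect_equal(unname(egs[1, ]), as.numeric(scale(prof)), tolerance = 1e-9)

  # variance explained matches a power-iteration oracle
  z <- t(scale(t(sm$expr[sm$truth == 1, ])))
  ev <- eigen(crossprod(z))$values
  expect_equal(unname(attr(eg, "var_explained")["M01"]), ev[1] / sum(ev),
               tolerance = 1e-8)

  # flipping all genes in a module leaves the oriented eigengene stable
  flipped <- sm$expr
  flipped[sm$truth == 1, ] <- -flipped[sm$truth == 1, ]
  egf <- eigengenes(flipped, mods)
  expect_gt(abs(stats::cor(egf[1, ], eg[1, ])), 0.99)
})

test_that("module-trait tests apply the Holm step-down correctly", {
  sm <- sim_modular_expr(n_per_module = 15, n_modules = 4, n_samples = 50,
                         noise = 0.3, seed = 14)
  mods <- tibble::tibble(gene = rownames(sm$expr),
                         module = sprintf("M%02d", sm$truth))
  eg <- eigengenes(sm$expr, mods)
  traits <- data.frame(coupled = sm$factors[3, ] + stats::rnorm(50, 0, 0.2),
                       noise = stats::rnorm(50))
  mt <- module_trait_tests(eg, traits)
  expect_equal(mt$p.adj, holm_bruteforce(mt$p.value), tolerance = 1e-12)
  expect_true(all(mt$p.adj >= mt$p.value))
  driven <- mt %>% dplyr::filter(module == "M03", trait == "coupled")
  expect_true(driven$significant)

  single <- module_trait_tests(eg[1, , drop = FALSE],
                               traits["coupled"])
  expect_equal(single$p.adj, single$p.value)
})
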