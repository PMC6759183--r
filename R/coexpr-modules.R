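# Signed-hybrid weighted co-expression modules and eigengenes.
#
# Adjacency a_ij = cor(i,j)^power for positive correlations and 0
# otherwise ("signed hybrid": only positively co-expressed genes connect).
# Modules come from average-linkage clustering of 1 - TOM (topological
# overlap) with a static cut; each module is summarised by its eigengene,
# the first principal component of its standardised expression.

#' Soft-threshold power selection by scale-free fit
#'
#' For each candidate power, computes the signed-hybrid connectivity
#' k_i = sum_j a_ij, bins log10(k), and regresses log10 of the bin
#' frequency on log10 of the bin's mean connectivity. The scale-free fit
#' index is the squared correlation of that regression (taken as 0 when the
#' slope is positive). Returns the lowest power whose fit exceeds
#' `fit_min`; if none qualifies, the best-fitting power is returned with
#' `flagged = TRUE`.
#'
#' @param expr Genes x samples matrix.
#' @param powers Candidate powers (positive).
#' @param fit_min Minimum acceptable fit (default 0.9).
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List: `power`, `flagged`, `fits` (tibble `power`, `fit`,
#'   `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                fit_min = 0.9, n_bins = 10) {
  if (any(powers <= 0)) abort("powers must be positive")
  cc <- cor(t(as.matrix(expr)))
  diag(cc) <- 0
  cc[cc < 0] <- 0
  fits <- purrr::map_dfr(powers, function(p) {
    k <- rowSums(cc^p)
    sf <- scale_free_fit(k, n_bins)
    tibble(power = p, fit = sf$fit, slope = sf$slope, mean_k = mean(k))
  })
  ok <- fits$power[fits$fit > fit_min]
  if (length(ok) > 0) {
    list(power = min(ok), flagged = FALSE, fits = fits)
  } else {
    list(power = fits$power[which.max(fits$fit)], flagged = TRUE, fits = fits)
  }
}

# histogram regression of log10 p(k) on log10 k
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  br <- unique(quantile(k, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  kt <- tapply(k, bin, mean)
  pk <- tapply(k, bin, length) / length(k)
  keep <- !is.na(kt) & pk > 0
  if (sum(keep) < 3) abort("fewer than 3 occupied connectivity bins")
  x <- log10(kt[keep]); y <- log10(pk[keep])
  if (sd(x) == 0 || sd(y) == 0) return(list(fit = 0, slope = 0))
  fit <- lm(y ~ x)
  sl <- unname(coef(fit)[2])
  r2 <- cor(x, y)^2
  list(fit = if (sl < 0) r2 else 0, slope = sl)
}

#' Signed-hybrid adjacency
#'
#' @param expr Genes x samples matrix.
#' @param power Soft-threshold power (>= 1).
#' @return Genes x genes adjacency with zero diagonal; negative
#'   correlations map to exactly 0.
#' @export
signed_hybrid_adjacency <- function(expr, power) {
  if (power < 1) abort("power must be >= 1")
  cc <- cor(t(as.matrix(expr)))
  if (any(!is.finite(cc))) abort("non-finite correlations (constant gene?)")
  cc[cc < 0] <- 0
  a <- cc^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' l_ij = sum_u a_iu a_uj, unit diagonal; entries lie in \[0, 1\] for
#' adjacency values in \[0, 1\].
#'
#' @param a Adjacency matrix (symmetric, zero diagonal, entries in
#'   \[0, 1\]).
#' @return TOM of the same shape.
#' @export
topological_overlap <- function(a) {
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

#' Build co-expression modules
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static cut at
#' `cut_height`; clusters smaller than `min_module_size` become background.
#' Modules are labelled `M01`, `M02`, ... by decreasing size and also get a
#' colour-style label for plotting.
#'
#' @param expr Genes x samples matrix.
#' @param power Soft-threshold power.
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_height Static cut height on the 1 - TOM dendrogram scale
#'   (default 0.25... see Details). Heights near 1 merge everything;
#'   heights near 0 shatter the tree.
#' @return Object of class `module_set`: tibble `gene`, `module`, `color`;
#'   attributes `power`, `cut_height`, plus the `tom` matrix.
#' @export
build_modules <- function(expr, power, min_module_size = 30,
                          cut_height = 0.25) {
  a <- signed_hybrid_adjacency(expr, power)
  tom <- topological_overlap(a)
  tree <- hclust(as.dist(1 - tom), method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("background", length(cl))
  ord <- keep[order(-sizes[keep])]
  for (i in seq_along(ord)) lab[cl == ord[i]] <- sprintf("M%02d", i)
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan")
  color <- ifelse(lab == "background", "grey",
                  palette[pmin(as.integer(sub("M", "", ifelse(lab == "background", "0", lab))),
                               length(palette))])
  out <- tibble(gene = rownames(as.matrix(expr)), module = lab, color = color)
  attr(out, "power") <- power
  attr(out, "cut_height") <- cut_height
  attr(out, "tom") <- tom
  class(out) <- c("module_set", class(out))
  out
}

#' Module eigengenes
#'
#' For each module, genes are standardised across samples and the first
#' right singular vector (the sample-space first principal component) is
#' taken as the eigengene, sign-oriented to correlate positively with the
#' module's mean expression profile and scaled to unit variance.
#'
#' @param expr Genes x samples matrix.
#' @param modules A `module_set` (or tibble `gene`, `module`); background
#'   genes are skipped.
#' @return Object of class `eigengene_matrix`: modules x samples matrix
#'   with an attribute `var_explained` (share of module variance carried by
#'   the eigengene).
#' @export
eigengenes <- function(expr, modules) {
  m <- as.matrix(expr)
  mods <- setdiff(sort(unique(modules$module)), "background")
  if (length(mods) == 0) abort("no modules to summarise")
  ve <- numeric(length(mods))
  eg <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(mods, colnames(m)))
  for (i in seq_along(mods)) {
    genes <- modules$gene[modules$module == mods[i]]
    if (length(genes) < 2) abort(sprintf("module %s has fewer than 2 genes", mods[i]))
    sub <- m[genes, , drop = FALSE]
    if (any(apply(sub, 1, sd) == 0)) abort(sprintf("constant gene in module %s", mods[i]))
    z <- t(scale(t(sub)))
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (cor(e, colMeans(z)) < 0) e <- -e
    eg[i, ] <- e / sd(e)
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(eg, var_explained = setNames(ve, mods),
            class = c("eigengene_matrix", "matrix"))
}

#' Module-trait association tests
#'
#' Pearson correlation test of every eigengene against every trait, with
#' Holm step-down adjustment across the whole module x trait family;
#' associations are significant at adjusted p < 0.05.
#'
#' @param eig An `eigengene_matrix` (modules x samples).
#' @param traits Data frame / named list of per-sample trait vectors
#'   aligned to the columns of `eig`.
#' @param alpha Significance level on the adjusted scale.
#' @return Tibble: `module`, `trait`, `r`, `p.value`, `p.adj`,
#'   `significant`.
#' @export
module_trait_tests <- function(eig, traits, alpha = 0.05) {
  tr <- as.data.frame(traits)
  if (nrow(tr) != ncol(eig)) abort("traits must align with eigengene samples")
  res <- purrr::map_dfr(rownames(eig), function(mo) {
    purrr::map_dfr(names(tr), function(tn) {
      ct <- cor.test(eig[mo, ], tr[[tn]])
      tibble(module = mo, trait = tn, r = unname(ct$estimate),
             p.value = ct$p.value)
    })
  })
  res %>%
    mutate(p.adj = p.adjust(.data$p.value, method = "holm"),
           significant = .data$p.adj < alpha)
}
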