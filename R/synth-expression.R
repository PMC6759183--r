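# Synthetic bulk RNA-seq with planted co-expression modules, cis-eQTL,
# trans hotspots, and trait-coupled genes.
#
# Counts follow a negative-binomial model around genotype-dependent means,
# the standard bulk RNA-seq assumption. Each gene gets physical coordinates
# between two named markers so cis/trans classification and QTL overlap can
# be tested against known truth.

#' Specify an expression architecture
#'
#' @param n_modules Number of planted co-expression modules.
#' @param module_size Genes per planted module.
#' @param module_sd SD of the per-line module latent factor on the log2
#'   expression scale (loadings are 1).
#' @param n_cis Number of genes with a cis-eQTL at their local marker.
#' @param cis_effect Additive cis effect on log2 expression (AA - BB
#'   difference is twice this).
#' @param hotspots Tibble `marker`, `n_targets`, `effect`: trans hotspots,
#'   each regulating `n_targets` background genes with the given log2
#'   additive effect. `NULL` for none.
#' @param trait_coupled Tibble `gene_index`, `coupling`, `noise_sd`
#'   describing genes whose (log2) expression is `coupling * scale(trait) +
#'   noise`; the trait vector is supplied to [simulate_expression_study()].
#'   `NULL` for none.
#' @param base_log2_mean,base_log2_sd Distribution of gene-level baseline
#'   log2 mean expression.
#' @param dispersion Negative-binomial dispersion (1/size); 0 gives Poisson.
#' @param lib_size_mean,lib_size_cv Library size distribution (log-normal).
#' @return A list of class `expression_architecture`.
#' @export
expression_architecture <- function(n_modules = 5, module_size = 40,
                                    module_sd = 1,
                                    n_cis = 50, cis_effect = 1,
                                    hotspots = NULL,
                                    trait_coupled = NULL,
                                    base_log2_mean = 5, base_log2_sd = 1.5,
                                    dispersion = 0.05,
                                    lib_size_mean = 2e6, lib_size_cv = 0.2) {
  structure(
    list(n_modules = n_modules, module_size = module_size,
         module_sd = module_sd, n_cis = n_cis, cis_effect = cis_effect,
         hotspots = hotspots, trait_coupled = trait_coupled,
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         dispersion = dispersion, lib_size_mean = lib_size_mean,
         lib_size_cv = lib_size_cv),
    class = "expression_architecture"
  )
}

#' Simulate an expression study
#'
#' Generates a gene-by-line count matrix plus gene coordinates. Planted
#' structure, in order of assignment over the gene index: module genes
#' (driven by a per-line latent factor), cis genes (shifted by the local
#' genotype), hotspot targets (shifted by a distant hotspot marker's
#' genotype), and trait-coupled genes (log2 mean tracks a supplied trait).
#' Remaining genes are background. Genes are placed uniformly along the
#' physical map, each strictly between two named flanking markers.
#'
#' @param genotypes Character genotype matrix from [simulate_rils()].
#' @param map Genetic map with `pos_bp` (from [make_genetic_map()]).
#' @param arch An [expression_architecture()].
#' @param n_genes Total genes (must exceed the planted count).
#' @param trait Optional numeric trait vector (one per line, named or in
#'   row order of `genotypes`) for trait-coupled genes.
#' @param seed Integer seed.
#' @return List with `counts` (gene x line integer matrix), `genes` (tibble:
#'   gene, chrom, start_bp, end_bp, left_marker, right_marker), and `truth`
#'   (tibble: gene, role, module, marker, effect).
#' @export
simulate_expression_study <- function(genotypes, map,
                                      arch = expression_architecture(),
                                      n_genes = 2000, trait = NULL,
                                      seed = 1L) {
  stopifnot(inherits(arch, "expression_architecture"))
  if (!is.null(arch$hotspots) && !all(arch$hotspots$marker %in% map$marker)) {
    abort("hotspot markers must exist in the genetic map")
  }
  set.seed(as.integer(seed))
  lines <- rownames(genotypes)
  n <- length(lines)
  x <- code_genotypes(genotypes)
  x[is.na(x)] <- 0

  n_module_genes <- arch$n_modules * arch$module_size
  n_hot <- if (is.null(arch$hotspots)) 0L else sum(arch$hotspots$n_targets)
  n_tc <- if (is.null(arch$trait_coupled)) 0L else nrow(arch$trait_coupled)
  n_planted <- n_module_genes + arch$n_cis + n_hot + n_tc
  if (n_genes < n_planted) {
    abort(sprintf("n_genes (%d) smaller than planted genes (%d)", n_genes, n_planted))
  }

  genes <- sprintf("gene%05d", seq_len(n_genes))
  coords <- place_genes(genes, map)

  log2_mu <- matrix(rnorm(n_genes, arch$base_log2_mean, arch$base_log2_sd),
                    n_genes, n, dimnames = list(genes, lines))
  truth <- tibble(gene = genes, role = "background",
                  module = "background", marker = NA_character_, effect = 0)
  idx <- 0L
  if (n_module_genes > 0) {
    for (m in seq_len(arch$n_modules)) {
      fac <- rnorm(n, 0, arch$module_sd)
      gi <- idx + seq_len(arch$module_size)
      log2_mu[gi, ] <- log2_mu[gi, ] + rep(fac, each = arch$module_size)
      truth$role[gi] <- "module"
      truth$module[gi] <- sprintf("planted%02d", m)
      idx <- idx + arch$module_size
    }
  }
  if (arch$n_cis > 0) {
    gi <- idx + seq_len(arch$n_cis)
    for (g in gi) {
      mk <- coords$left_marker[g]  # local marker = cis anchor
      log2_mu[g, ] <- log2_mu[g, ] + arch$cis_effect * x[, mk]
      truth$role[g] <- "cis"
      truth$marker[g] <- mk
      truth$effect[g] <- arch$cis_effect
    }
    idx <- idx + arch$n_cis
  }
  if (n_hot > 0) {
    for (hi in seq_len(nrow(arch$hotspots))) {
      hs <- arch$hotspots[hi, ]
      gi <- idx + seq_len(hs$n_targets)
      log2_mu[gi, ] <- log2_mu[gi, ] +
        hs$effect * rep(x[, hs$marker], each = hs$n_targets)
      truth$role[gi] <- "trans_target"
      truth$marker[gi] <- hs$marker
      truth$effect[gi] <- hs$effect
      idx <- idx + hs$n_targets
    }
  }
  if (n_tc > 0) {
    if (is.null(trait)) abort("trait vector required for trait-coupled genes")
    tv <- if (!is.null(names(trait))) trait[lines] else trait
    zs <- as.numeric(scale(tv))
    for (k in seq_len(n_tc)) {
      g <- idx + k
      tc <- arch$trait_coupled[k, ]
      log2_mu[g, ] <- log2_mu[g, ] + tc$coupling * zs +
        rnorm(n, 0, tc$noise_sd)
      truth$role[g] <- "trait_coupled"
      truth$effect[g] <- tc$coupling
    }
  }

  lib <- rlnorm(n, log(arch$lib_size_mean), sqrt(log(1 + arch$lib_size_cv^2)))
  mu_counts <- 2^log2_mu
  mu_counts <- sweep(mu_counts, 2, lib / colSums(mu_counts), `*`)
  counts <- if (arch$dispersion > 0) {
    matrix(rnbinom(length(mu_counts), mu = mu_counts, size = 1 / arch$dispersion),
           n_genes, n, dimnames = dimnames(log2_mu))
  } else {
    matrix(stats::rpois(length(mu_counts), mu_counts),
           n_genes, n, dimnames = dimnames(log2_mu))
  }
  list(counts = counts, genes = coords, truth = truth)
}

# uniform placement along the physical genome, each gene strictly between
# two adjacent markers of one chromosome
place_genes <- function(genes, map) {
  if (!"pos_bp" %in% names(map)) abort("map must carry pos_bp for gene placement")
  chroms <- split(map, factor(map$chrom, levels = unique(map$chrom)))
  lens <- vapply(chroms, function(cm) max(cm$pos_bp), numeric(1))
  ch_idx <- sample(seq_along(chroms), length(genes), replace = TRUE,
                   prob = lens / sum(lens))
  out <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    cm <- chroms[[ch_idx[g]]]
    i <- sample(nrow(cm) - 1L, 1L)
    lo <- cm$pos_bp[i]
    hi <- cm$pos_bp[i + 1L]
    start <- floor(runif(1, lo, hi - 1))
    out[[g]] <- tibble(
      gene = genes[g], chrom = cm$chrom[1],
      start_bp = start, end_bp = min(start + 999, hi - 1),
      left_marker = cm$marker[i], right_marker = cm$marker[i + 1L]
    )
  }
  bind_rows(out)
}
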