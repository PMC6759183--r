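# Study configuration, file I/O, and the end-to-end pipeline driver.
#
# All tabular formats are plain CSV/TSV (UTF-8, header row, "." decimal,
# NA token "NA"); gene coordinates travel as GFF3 (1-based, inclusive,
# `gene` features with `ID=` attributes). Every stochastic stage derives
# its seed deterministically from the master seed and the stage name, so a
# rerun with the same config is bit-identical.

config_defaults <- function() {
  list(
    seed = 1L,
    paths = list(genotypes = NULL, map = NULL, phenotypes = NULL,
                 counts = NULL, genes_gff3 = NULL, amax = NULL,
                 temperatures = NULL),
    simulate = list(n_lines = 120L, n_chrom = 10L, markers_per_chrom = 146L,
                    chrom_length = 100, n_genes = 2000L),
    mcmc = list(n_iterations = 20000L, n_burnin = 10000L, thin = 5L),
    scan = list(step = 1, error = 0.001, n_perm = 1000L,
                quantile_p = 0.95),
    cim = list(n_covar = 3L, window = 10),
    network = list(mr_thresholds = c(10, 20, 30, 50), n_perm = 100L,
                   cpm_min = 2, min_samples = 44L, top_k = 10000L),
    modules = list(powers = c(1:10, 12, 14, 16, 18, 20), fit_min = 0.9,
                   min_module_size = 30L, cut_height = 0.25),
    integrate = list(n_perm = 1000L, stay_p = 0.10)
  )
}

#' Load and validate a study configuration
#'
#' Reads a YAML configuration, fills defaults, and rejects unknown keys.
#' Any file paths listed under `paths` must exist.
#'
#' @param path YAML file path, or a named list for programmatic use.
#' @return Validated config list of class `study_config`.
#' @export
load_study_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  defs <- config_defaults()
  check_keys <- function(u, d, prefix = "") {
    bad <- setdiff(names(u), names(d))
    if (length(bad) > 0) {
      abort(sprintf("unknown config key%s: %s",
                    if (length(bad) > 1) "s" else "",
                    paste0(prefix, bad, collapse = ", ")))
    }
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        check_keys(as.list(u[[k]]), d[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(user, defs)
  cfg <- modifyList(defs, user)
  for (p in purrr::compact(cfg$paths)) {
    if (!file.exists(p)) abort(sprintf("configured file does not exist: %s", p))
  }
  structure(cfg, class = c("study_config", "list"))
}

#' Stage-specific seed derived from the master seed
#'
#' @param config A `study_config` (or its master seed).
#' @param stage Stage name.
#' @return Integer seed below 2^31, stable in (seed, stage).
#' @export
stage_seed <- function(config, stage) {
  master <- if (is.list(config)) config$seed else config
  digits <- utils::head(strtoi(charToRaw(stage), 16L), 8)
  as.integer((sum(digits * seq_along(digits)) * 2654435.0 + master * 97) %%
               .Machine$integer.max)
}

#' Write a synthetic study bundle to disk
#'
#' @param study List with `map`, `genotypes`, `growth` (from
#'   [simulate_growth_study()]) and optionally `expression` (from
#'   [simulate_expression_study()]).
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$map, file.path(dir, "map.csv"))
  geno <- as_tibble(study$genotypes, rownames = "line")
  readr::write_csv(geno, file.path(dir, "genotypes.csv"))
  readr::write_csv(study$growth$observations, file.path(dir, "phenotypes.csv"))
  readr::write_csv(study$growth$truth, file.path(dir, "growth_truth.csv"))
  if (!is.null(study$growth$amax)) {
    readr::write_csv(study$growth$amax, file.path(dir, "amax.csv"))
  }
  if (!is.null(study$expression)) {
    cts <- as_tibble(study$expression$counts, rownames = "gene")
    readr::write_tsv(cts, file.path(dir, "counts.tsv"))
    write_gff3(study$expression$genes, file.path(dir, "genes.gff3"))
    readr::write_csv(study$expression$truth, file.path(dir, "expression_truth.csv"))
  }
  invisible(dir)
}

#' Write gene coordinates as GFF3
#'
#' @param genes Tibble `gene`, `chrom`, `start_bp`, `end_bp`.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tgrowthnet\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, as.integer(genes$start_bp),
                     as.integer(genes$end_bp), genes$gene))
  writeLines(lines, path)
}

#' Read gene coordinates from GFF3
#'
#' Parses `gene` features of a GFF3 file (1-based inclusive coordinates);
#' every feature must carry an `ID=` attribute.
#'
#' @param path GFF3 file.
#' @return Tibble `gene`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gff3 <- function(path) {
  raw <- readLines(path)
  raw <- raw[!startsWith(raw, "#") & nzchar(raw)]
  out <- list()
  for (i in seq_along(raw)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) abort(sprintf("malformed GFF3 line %d", i))
    if (f[3] != "gene") next
    id <- regmatches(f[9], regexec("ID=([^;]+)", f[9]))[[1]][2]
    if (is.na(id)) abort(sprintf("GFF3 gene without ID attribute at line %d", i))
    out[[length(out) + 1]] <- tibble(gene = id, chrom = f[1],
                                     start_bp = as.numeric(f[4]),
                                     end_bp = as.numeric(f[5]))
  }
  bind_rows(out)
}

#' Read the study inputs named in a config
#'
#' Loads genotypes, map, phenotypes and (when configured) counts, gene
#' coordinates and Amax, with schema validation and id cross-referencing.
#'
#' @param config A `study_config` whose `paths` entries point at files.
#' @return List: `map`, `genotypes` (character matrix), `phenotypes`,
#'   and optionally `counts`, `genes`, `amax`.
#' @export
read_study_inputs <- function(config) {
  p <- config$paths
  if (is.null(p$map) || is.null(p$genotypes) || is.null(p$phenotypes)) {
    abort("config must point at map, genotypes and phenotypes files")
  }
  map <- readr::read_csv(p$map, show_col_types = FALSE)
  validate_genetic_map(map)
  gt <- readr::read_csv(p$genotypes, show_col_types = FALSE)
  geno <- as.matrix(gt[, -1])
  rownames(geno) <- gt[[1]]
  bad <- setdiff(unique(as.vector(geno)), c("AA", "BB", NA))
  if (length(bad) > 0) {
    abort(paste("invalid genotype codes:", paste(bad, collapse = ", ")))
  }
  pheno <- readr::read_csv(p$phenotypes, show_col_types = FALSE)
  need <- c("line", "replicate", "time_dd", "height_cm")
  if (!all(need %in% names(pheno))) {
    abort("phenotype file needs columns line, replicate, time_dd, height_cm")
  }
  orphan <- setdiff(unique(pheno$line), rownames(geno))
  if (length(orphan) > 0) {
    abort(paste("phenotype lines absent from genotypes:",
                paste(orphan, collapse = ", ")))
  }
  out <- list(map = map, genotypes = geno, phenotypes = pheno)
  if (!is.null(p$counts)) {
    ct <- readr::read_tsv(p$counts, show_col_types = FALSE)
    cm <- as.matrix(ct[, -1])
    rownames(cm) <- ct[[1]]
    out$counts <- cm
  }
  if (!is.null(p$genes_gff3)) out$genes <- read_gff3(p$genes_gff3)
  if (!is.null(p$amax)) {
    out$amax <- readr::read_csv(p$amax, show_col_types = FALSE)
  }
  out
}

#' Run the pipeline end-to-end
#'
#' Executes the requested stages in dependency order -- simulate,
#' fit-growth, blup, scan, mr-net, modules, integrate -- writing each
#' stage's outputs under `out_dir`. With no input paths configured, the
#' `simulate` stage generates the default synthetic study; later stages
#' then consume it. Stage seeds derive from the master seed, so identical
#' configs reproduce identical outputs.
#'
#' @param config A `study_config` (or list accepted by
#'   [load_study_config()]).
#' @param out_dir Output directory.
#' @param stages Subset of
#'   `c("simulate", "fit-growth", "blup", "scan", "mr-net", "modules",
#'   "integrate")`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("growthnet_run_"),
                         stages = c("simulate", "fit-growth", "blup", "scan",
                                    "mr-net", "modules", "integrate")) {
  cfg <- if (inherits(config, "study_config")) config else
    load_study_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("simulate" %in% stages) {
    sm <- cfg$simulate
    map <- make_genetic_map(sm$n_chrom, sm$markers_per_chrom, sm$chrom_length,
                            seed = stage_seed(cfg, "simulate-map"))
    geno <- simulate_rils(map, sm$n_lines, seed = stage_seed(cfg, "simulate-rils"))
    arch <- growth_architecture(
      qtl = tibble(marker = map$marker[round(nrow(map) * c(0.15, 0.65))],
                   param = c("log_r", "log_hmax"), effect = c(0.08, 0.08))
    )
    growth <- simulate_growth_study(geno, arch, map,
                                    seed = stage_seed(cfg, "simulate-growth"))
    # plant structure scaled to the configured gene count
    n_hot <- max(5L, sm$n_genes %/% 60)
    n_tc <- max(5L, sm$n_genes %/% 100)
    hot <- tibble(marker = map$marker[round(nrow(map) * c(0.3, 0.85))],
                  n_targets = n_hot, effect = 1)
    truth_r <- growth$truth %>% filter(.data$treatment == "UN")
    expr_arch <- expression_architecture(
      n_modules = 5, module_size = max(5L, sm$n_genes %/% 50),
      n_cis = max(5L, sm$n_genes %/% 40),
      hotspots = hot,
      trait_coupled = tibble(gene_index = seq_len(n_tc), coupling = 1,
                             noise_sd = 0.5))
    expression <- simulate_expression_study(
      geno, map, expr_arch, n_genes = sm$n_genes,
      trait = setNames(truth_r$r, truth_r$line),
      seed = stage_seed(cfg, "simulate-expression"))
    res$study <- list(map = map, genotypes = geno, growth = growth,
                      expression = expression)
    write_study(res$study, file.path(out_dir, "study"))
  } else {
    inp <- read_study_inputs(cfg)
    res$study <- list(map = inp$map, genotypes = inp$genotypes,
                      growth = list(observations = inp$phenotypes),
                      expression = if (!is.null(inp$counts))
                        list(counts = inp$counts, genes = inp$genes))
  }
  study <- res$study

  if ("fit-growth" %in% stages) {
    obs <- study$growth$observations
    if ("treatment" %in% names(obs)) obs <- obs[obs$treatment == obs$treatment[1], ]
    fit <- fit_hierarchical_growth(
      obs, mcmc_settings(cfg$mcmc$n_iterations, cfg$mcmc$n_burnin,
                         cfg$mcmc$thin, seed = stage_seed(cfg, "fit-growth")))
    res$growth_fit <- fit
    readr::write_csv(tidy(fit), file.path(out_dir, "fvt_posteriors.csv"))
  }

  if ("blup" %in% stages) {
    obs <- study$growth$observations
    stopifnot(!is.null(res$growth_fit))
    fvt <- tidy(res$growth_fit) %>%
      filter(.data$param %in% c("r", "hmax")) %>%
      select("line", "param", "estimate") %>%
      tidyr::pivot_wider(names_from = "param", values_from = "estimate")
    res$fvt <- fvt
    readr::write_csv(fvt, file.path(out_dir, "fvt_point_estimates.csv"))
  }

  if ("scan" %in% stages) {
    probs <- genotype_probabilities(study$genotypes, study$map,
                                    step = cfg$scan$step, error = cfg$scan$error)
    y <- setNames(res$fvt$r, res$fvt$line)
    thr <- permutation_threshold(probs, y, n_perm = cfg$scan$n_perm,
                                 quantile_p = cfg$scan$quantile_p,
                                 seed = stage_seed(cfg, "scan-perm"))
    model <- build_multi_qtl_model(probs, y, thr$threshold)
    res$probs <- probs; res$qtl_model <- model; res$threshold <- thr$threshold
    readr::write_csv(as_tibble(model), file.path(out_dir, "qtl_model.csv"))
    jsonlite::write_json(list(threshold = thr$threshold,
                              model = as.data.frame(model)),
                         file.path(out_dir, "qtl_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("mr-net" %in% stages && !is.null(study$expression)) {
    em <- preprocess_counts(study$expression$counts,
                            cpm_min = cfg$network$cpm_min,
                            min_samples = min(cfg$network$min_samples,
                                              ncol(study$expression$counts) %/% 2))
    keep <- top_variable(em, k = cfg$network$top_k)
    seeds_df <- data.frame(r = res$fvt$r[match(colnames(keep), res$fvt$line)])
    mr <- mutual_ranks(keep, seeds_df)
    net <- seed_mr_network(mr, threshold = max(cfg$network$mr_thresholds))
    res$expr <- keep; res$mr_network <- net
    readr::write_csv(net$edges, file.path(out_dir, "mr_edges.csv"))
    writeLines(sprintf("%s\tmr\t%s", net$edges$from, net$edges$to),
               file.path(out_dir, "mr_network.sif"))
  }

  if ("modules" %in% stages && !is.null(res$expr)) {
    pw <- pick_soft_threshold(res$expr, powers = cfg$modules$powers,
                              fit_min = cfg$modules$fit_min)
    mods <- build_modules(res$expr, pw$power,
                          min_module_size = cfg$modules$min_module_size,
                          cut_height = cfg$modules$cut_height)
    eg <- eigengenes(res$expr, mods)
    traits <- data.frame(r = res$fvt$r[match(colnames(eg), res$fvt$line)])
    mt <- module_trait_tests(eg, traits)
    res$modules <- mods; res$eigengenes <- eg; res$module_trait <- mt
    readr::write_csv(as_tibble(mods), file.path(out_dir, "modules.csv"))
    readr::write_csv(mt, file.path(out_dir, "module_trait.csv"))
  }

  if ("integrate" %in% stages && !is.null(res$qtl_model) &&
      nrow(res$qtl_model) > 0) {
    base <- scan_hk(res$probs, setNames(res$fvt$r, res$fvt$line))
    ivs <- purrr::map_dfr(seq_len(nrow(res$qtl_model)), function(i) {
      support_interval(base, res$qtl_model$chrom[i], res$qtl_model$pos_cM[i],
                       method = "lod_drop")
    }) %>%
      rename(lo = "lo_cM", hi = "hi_cM") %>%
      mutate(coord = "cM")
    under <- genes_in_intervals(study$expression$genes, ivs, study$map)
    res$genes_under_qtl <- under
    readr::write_csv(tibble(gene = under),
                     file.path(out_dir, "genes_under_qtl.csv"))
  }

  jsonlite::write_json(list(seed = cfg$seed, stages = stages),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
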