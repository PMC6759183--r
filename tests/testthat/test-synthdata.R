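# Synthetic-study generators: maps, RIL genotypes, growth and expression
# studies, temperature series.

test_that("genetic maps have forced endpoints, the right density, and are reproducible", {
  m <- make_genetic_map(1, 2, 100, seed = 1)
  expect_equal(m$pos_cM, c(0, 100))

  m <- make_genetic_map(10, 146, 100, spacing = "uniform", seed = 1)
  expect_equal(nrow(m), 1460)
  sp <- m %>% dplyr::group_by(chrom) %>%
    dplyr::summarise(s = mean(diff(pos_cM)))
  expect_equal(mean(sp$s), 100 / 145, tolerance = 1e-12)

  expect_identical(make_genetic_map(3, 10, 80, "jittered", seed = 7),
                   make_genetic_map(3, 10, 80, "jittered", seed = 7))
  expect_error(make_genetic_map(0, 5, 100), "n_chrom")
  expect_error(make_genetic_map(1, 1, 100), "n_chrom")
})

test_that("jittered maps keep positions strictly increasing", {
  for (s in 1:5) {
    m <- make_genetic_map(2, 30, 50, spacing = "jittered", seed = s)
    incr <- m %>% dplyr::group_by(chrom) %>%
      dplyr::summarise(ok = all(diff(pos_cM) > 0))
    expect_true(all(incr$ok))
  }
})

test_that("RILs are fully homozygous with balanced allele frequencies", {
  map <- make_genetic_map(2, 20, 100, seed = 1)
  g <- simulate_rils(map, 300, seed = 2)
  expect_true(all(g %in% c("AA", "BB")))
  freq <- colMeans(g == "AA")
  expect_true(all(abs(freq - 0.5) < 0.15))
  expect_identical(simulate_rils(map, 50, seed = 9),
                   simulate_rils(map, 50, seed = 9))
})

test_that("tightly linked markers never recombine and unlinked markers are independent", {
  map0 <- tibble::tibble(marker = c("a", "b"), chrom = "chr01",
                         pos_cM = c(0, 1e-6))
  g <- simulate_rils(map0, 500, seed = 3)
  expect_true(all(g[, 1] == g[, 2]))

  map2 <- tibble::tibble(marker = c("a", "b"), chrom = c("chr01", "chr02"),
                         pos_cM = c(0, 0)) %>%
    dplyr::bind_rows(tibble::tibble(marker = c("a2", "b2"),
                                    chrom = c("chr01", "chr02"),
                                    pos_cM = c(50, 50)))
  map2 <- map2 %>% dplyr::arrange(chrom, pos_cM)
  g <- simulate_rils(map2, 10000, seed = 4)
  r_obs <- mean(g[, "a"] != g[, "b"])
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(r_obs - 0.5), 3 * se)
})

test_that("RIL recombination between linked markers matches the selfed-RIL map expansion", {
  # classical closed form for repeatedly selfed lines: R = 2r/(1+2r)
  for (d in c(5, 20, 40)) {
    map <- tibble::tibble(marker = c("a", "b"), chrom = "chr01",
                          pos_cM = c(0, d))
    g <- simulate_rils(map, 10000, n_selfing_generations = 12, seed = d)
    r <- haldane_r(d)
    expected <- 2 * r / (1 + 2 * r)
    r_obs <- mean(g[, 1] != g[, 2])
    se <- sqrt(expected * (1 - expected) / 10000)
    expect_lt(abs(r_obs - expected), 3 * se)
  }
})

test_that("noise-free growth studies sit exactly on the line's logistic curve", {
  map <- make_genetic_map(1, 3, 50, seed = 1)
  geno <- simulate_rils(map, 5, seed = 2)
  arch <- growth_architecture(sd_noise = 0,
                              sd_rep = c(log_r = 0, log_hmax = 0, id = 0),
                              sd_block = 0)
  st <- simulate_growth_study(geno, arch, map, treatments = "UN",
                              reps_per_line = 2, seed = 3)
  joined <- st$observations %>%
    dplyr::left_join(st$truth, by = c("line", "treatment")) %>%
    dplyr::mutate(expected = logistic_height(time_dd, r, hmax, id))
  expect_equal(joined$height_cm, joined$expected, tolerance = 1e-12)
})

test_that("growth studies are reproducible, flag odd schedules, and express GxT variance", {
  map <- make_genetic_map(1, 3, 50, seed = 1)
  geno <- simulate_rils(map, 40, seed = 2)
  arch <- growth_architecture()
  a <- simulate_growth_study(geno, arch, map, seed = 5)
  b <- simulate_growth_study(geno, arch, map, seed = 5)
  expect_identical(a$observations, b$observations)

  expect_warning(
    simulate_growth_study(geno, arch, map, treatments = "UN",
                          schedule = seq(100, 1300, length.out = 4), seed = 1),
    "5-13")

  # genotype-by-treatment variance reorders lines across treatments
  arch_gxt <- growth_architecture(sd_gxt = c(log_r = 0.3, log_hmax = 0.3, id = 0),
                                  sd_line = c(log_r = 0.05, log_hmax = 0.05, id = 10))
  st <- simulate_growth_study(geno, arch_gxt, map, seed = 6)
  wide <- st$truth %>% dplyr::select(line, treatment, hmax) %>%
    tidyr::pivot_wider(names_from = treatment, values_from = hmax)
  expect_lt(stats::cor(rank(wide$UN), rank(wide$CR)), 0.95)
  arch_null <- growth_architecture(sd_gxt = c(log_r = 0, log_hmax = 0, id = 0))
  st0 <- simulate_growth_study(geno, arch_null, map, seed = 6)
  wide0 <- st0$truth %>% dplyr::select(line, treatment, hmax) %>%
    tidyr::pivot_wider(names_from = treatment, values_from = hmax)
  expect_equal(stats::cor(wide0$UN, wide0$CR), 1, tolerance = 1e-12)
})

test_that("expression studies plant recoverable cis effects and trait coupling", {
  st <- small_study()
  arch <- expression_architecture(n_modules = 0, n_cis = 10, cis_effect = 2,
                                  dispersion = 0.01,
                                  trait_coupled = tibble::tibble(
                                    gene_index = 1, coupling = 1, noise_sd = 0),
                                  base_log2_mean = 8)
  trait <- stats::rnorm(nrow(st$geno))
  names(trait) <- rownames(st$geno)
  ex <- simulate_expression_study(st$geno, st$map, arch, n_genes = 50,
                                  trait = trait, seed = 7)
  expect_equal(dim(ex$counts), c(50, 120))

  # planted cis gene: expression splits by local genotype
  cg <- ex$truth %>% dplyr::filter(role == "cis") %>% dplyr::slice(1)
  lg <- log2(ex$counts[cg$gene, ] + 0.5)
  cls <- st$geno[, cg$marker]
  expect_gt(mean(lg[cls == "AA"]) - mean(lg[cls == "BB"]), 2)

  # trait-coupled gene tracks the trait
  tg <- ex$truth %>% dplyr::filter(role == "trait_coupled")
  lt <- log2(ex$counts[tg$gene, ] + 0.5)
  expect_gt(stats::cor(lt, trait), 0.9)

  expect_error(simulate_expression_study(st$geno, st$map, arch, n_genes = 5,
                                         trait = trait),
               "planted")
  # gene coordinates sit between their flanking markers
  pos <- ex$genes %>%
    dplyr::left_join(st$map, by = c("left_marker" = "marker")) %>%
    dplyr::rename(left_bp = pos_bp) %>%
    dplyr::left_join(st$map, by = c("right_marker" = "marker")) %>%
    dplyr::rename(right_bp = pos_bp)
  expect_true(all(pos$start_bp >= pos$left_bp & pos$end_bp <= pos$right_bp))
})

test_that("temperature series honour the requested daily means", {
  tt <- simulate_temperatures(3, daily_mean = 20, amplitude = 0, seed = 1)
  expect_true(all(tt$temp_C == 20))
  tt <- simulate_temperatures(5, daily_mean = c(18, 19, 20, 21, 22),
                              amplitude = 6, seed = 2)
  dm <- tapply(tt$temp_C, tt$day, mean)
  expect_equal(as.numeric(dm), c(18, 19, 20, 21, 22), tolerance = 1e-9)
  expect_identical(simulate_temperatures(2, 15, 4, 0.5, seed = 3),
                   simulate_temperatures(2, 15, 4, 0.5, seed = 3))
})
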