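# Genotype-probability HMM, Haley-Knott and composite interval mapping,
# permutation thresholds, multi-QTL search, support intervals, PVE, and
# effect signs.

test_that("HMM posteriors honour typed markers and missing data", {
  st <- small_study()
  map <- st$map; geno <- st$geno
  probs <- genotype_probabilities(geno, map, step = 2, error = 1e-9)
  at_marker <- probs$grid$marker %in% map$marker[1]
  typed <- geno[, map$marker[1]]
  p <- probs$p_aa[, which(at_marker)]
  expect_true(all(abs(p[typed == "AA"] - 1) < 1e-6))
  expect_true(all(p[typed == "BB"] < 1e-6))

  # fully missing line falls back to the 1/2 prior everywhere
  geno_na <- geno
  geno_na[1, ] <- NA
  probs_na <- genotype_probabilities(geno_na, map, step = 2)
  expect_true(all(abs(probs_na$p_aa[1, ] - 0.5) < 1e-12))
})

test_that("HMM midpoint posterior matches a hand-enumerated three-point chain", {
  map <- tibble::tibble(marker = c("m1", "m2"), chrom = "chr01",
                        pos_cM = c(0, 2))
  geno <- matrix(c("AA", "AA"), 1, 2,
                 dimnames = list("L1", c("m1", "m2")))
  e <- 0.001
  probs <- genotype_probabilities(geno, map, step = 1, error = e)
  # direct enumeration over the hidden state at 1 cM
  r <- ril_r(haldane_r(1))
  tr <- matrix(c(1 - r, r, r, 1 - r), 2)
  em <- c(1 - e, e)  # both flanks typed AA
  joint <- function(s_mid) {
    sum(vapply(1:2, function(s1) {
      sum(vapply(1:2, function(s3) {
        0.5 * em[s1] * tr[s1, s_mid] * tr[s_mid, s3] * em[s3]
      }, numeric(1)))
    }, numeric(1)))
  }
  expected <- joint(1) / (joint(1) + joint(2))
  mid <- which(probs$grid$pos_cM == 1)
  expect_equal(probs$p_aa[1, mid], expected, tolerance = 1e-12)
})

test_that("marker/map mismatches are rejected", {
  st <- small_study()
  geno_bad <- st$geno
  colnames(geno_bad)[1] <- "not_in_map"
  expect_error(genotype_probabilities(geno_bad, st$map), "absent from the map")
})

test_that("HK LOD at a noise-free marker matches a direct regression oracle", {
  st <- small_study()
  x <- code_genotypes(st$geno)
  mk <- st$map$marker[10]
  y <- x[, mk]
  names(y) <- rownames(st$geno)
  sc <- scan_hk(st$probs, y)
  peak <- which.max(sc$lod)
  expect_equal(sc$marker[peak], mk)
  # independent least-squares computation at the peak
  dos <- genotype_dosage(st$probs)[, peak]
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::resid(stats::lm(y ~ dos))^2)
  n <- attr(sc, "n")
  expect_equal(sc$lod[peak], (n / 2) * log10(rss0 / max(rss1, 1e-300)),
               tolerance = 1e-8)
})

test_that("constant phenotypes give a flat zero curve with a warning", {
  st <- small_study()
  y <- rep(1, nrow(st$geno))
  names(y) <- rownames(st$geno)
  expect_warning(sc <- scan_hk(st$probs, y), "zero variance")
  expect_true(all(sc$lod == 0))
})

test_that("scans are invariant to line ordering", {
  st <- small_study()
  set.seed(5)
  y <- stats::rnorm(nrow(st$geno))
  names(y) <- rownames(st$geno)
  sc1 <- scan_hk(st$probs, y)
  perm <- sample(length(y))
  sc2 <- scan_hk(st$probs, y[perm])
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-10)
})

test_that("single-QTL PVE identity holds to numerical precision", {
  st <- small_study()
  set.seed(6)
  x <- code_genotypes(st$geno)
  y <- 0.6 * x[, st$map$marker[15]] + stats::rnorm(nrow(st$geno))
  names(y) <- rownames(st$geno)
  sc <- scan_hk(st$probs, y)
  n <- attr(sc, "n")
  for (j in c(1, 10, which.max(sc$lod))) {
    dos <- genotype_dosage(st$probs)[, j]
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(stats::resid(stats::lm(y ~ dos))^2)
    expect_equal(pve(sc$lod[j], n), 100 * (1 - rss1 / rss0),
                 tolerance = 1e-10)
  }
  expect_equal(pve(0, 100), 0)
  expect_equal(pve(1e6, 100), 100)
  expect_equal(pve(5, 100), 100 * (1 - 10^(-0.1)), tolerance = 1e-12)
})

test_that("permutation thresholds are the null max-LOD quantile and reproducible", {
  st <- small_study()
  set.seed(7)
  y <- stats::rnorm(nrow(st$geno))
  names(y) <- rownames(st$geno)
  pt <- permutation_threshold(st$probs, y, n_perm = 100, seed = 8)
  expect_equal(pt$threshold,
               unname(stats::quantile(pt$max_lods, 0.95)))
  pt2 <- permutation_threshold(st$probs, y, n_perm = 100, seed = 8)
  expect_identical(pt$max_lods, pt2$max_lods)
})

test_that("CIM reduces to single-QTL mapping without covariates and excludes windowed covariates", {
  st <- small_study()
  set.seed(9)
  x <- code_genotypes(st$geno)
  y <- 0.5 * x[, st$map$marker[5]] + 0.5 * x[, st$map$marker[40]] +
    stats::rnorm(nrow(st$geno))
  names(y) <- rownames(st$geno)
  c0 <- scan_cim(st$probs, y, n_covar = 0)
  h <- scan_hk(st$probs, y)
  expect_equal(c0$lod, h$lod, tolerance = 1e-10)

  cc <- scan_cim(st$probs, y, n_covar = 2, window = 10)
  active <- attr(cc, "covar_active")
  cov_mk <- attr(cc, "covar_markers")
  cov_idx <- which(cc$marker %in% cov_mk)
  for (j in seq_len(nrow(cc))) {
    for (q in cov_idx) {
      if (cc$chrom[q] == cc$chrom[j] &&
          abs(cc$pos_cM[q] - cc$pos_cM[j]) <= 10) {
        expect_false(q %in% active[[j]])
      }
    }
  }
  expect_error(scan_cim(st$probs, y, n_covar = 1e6), "smaller")
})

test_that("CIM beats plain interval mapping at one QTL when another segregates", {
  st <- small_study()
  x <- code_genotypes(st$geno)
  m1 <- st$map$marker[10]               # chromosome 1
  m2 <- st$map$marker[30]               # chromosome 2
  set.seed(10)
  wins <- replicate(10, {
    y <- 0.5 * x[, m1] + 0.9 * x[, m2] + stats::rnorm(nrow(x))
    names(y) <- rownames(x)
    im <- scan_hk(st$probs, y)
    cim <- scan_cim(st$probs, y, n_covar = 2, window = 10)
    j <- which(im$marker == m1)
    cim$lod[j] > im$lod[j]
  })
  expect_gte(mean(wins), 0.6)
})

test_that("multi-QTL search returns an empty model under the null and signed effects otherwise", {
  st <- small_study()
  set.seed(11)
  ynull <- stats::rnorm(nrow(st$geno))
  names(ynull) <- rownames(st$geno)
  m0 <- build_multi_qtl_model(st$probs, ynull, threshold = 10)
  expect_equal(nrow(m0), 0)
  expect_equal(glance(m0)$model_pve, 0)

  x <- code_genotypes(st$geno)
  mk1 <- st$map$marker[8]; mk2 <- st$map$marker[34]
  y1 <- 0.8 * x[, mk1] - 0.8 * x[, mk2] + stats::rnorm(nrow(x), 0, 0.5)
  y2 <- -0.8 * x[, mk1] + 0.8 * x[, mk2] + stats::rnorm(nrow(x), 0, 0.5)
  names(y1) <- names(y2) <- rownames(x)
  mm1 <- build_multi_qtl_model(st$probs, y1, threshold = 3)
  mm2 <- build_multi_qtl_model(st$probs, y2, threshold = 3)
  expect_equal(nrow(mm1), 2)
  expect_equal(nrow(mm2), 2)
  # opposite planted effects recover with opposite signs
  expect_true(all(sign(mm1$effect) == -sign(mm2$effect)))
})

test_that("QTL effects are half the class-mean difference, signed to the R500 parent", {
  st <- small_study()
  x <- code_genotypes(st$geno)
  mk <- st$map$marker[12]
  y <- ifelse(x[, mk] > 0, 1, -1)
  names(y) <- rownames(st$geno)
  ef <- qtl_effect(st$probs, y, st$map$chrom[12], st$map$pos_cM[12])
  expect_equal(ef$effect, 1, tolerance = 1e-6)
  expect_equal(ef$direction, "R500+")

  set.seed(12)
  y2 <- 0.4 * x[, mk] + stats::rnorm(nrow(x), 0, 0.3)
  names(y2) <- rownames(x)
  ef2 <- qtl_effect(st$probs, y2, st$map$chrom[12], st$map$pos_cM[12])
  oracle <- (mean(y2[x[, mk] > 0]) - mean(y2[x[, mk] < 0])) / 2
  expect_equal(ef2$effect, oracle, tolerance = 1e-6)

  yflat <- rep(0.5, nrow(x)); names(yflat) <- rownames(x)
  expect_equal(qtl_effect(st$probs, yflat, st$map$chrom[12],
                          st$map$pos_cM[12])$effect, 0, tolerance = 1e-9)
})

test_that("support intervals contain the peak, nest in probability, and fall back when degenerate", {
  st <- small_study()
  set.seed(13)
  x <- code_genotypes(st$geno)
  y <- 0.8 * x[, st$map$marker[13]] + stats::rnorm(nrow(x), 0, 0.8)
  names(y) <- rownames(x)
  sc <- scan_hk(st$probs, y)
  pk <- sc[which.max(sc$lod), ]
  si <- support_interval(sc, pk$chrom, pk$pos_cM, method = "lod_drop")
  expect_true(si$lo_cM <= si$peak_cM && si$peak_cM <= si$hi_cM)
  b99 <- support_interval(sc, pk$chrom, pk$pos_cM, method = "bayes", prob = 0.99)
  b95 <- support_interval(sc, pk$chrom, pk$pos_cM, method = "bayes", prob = 0.95)
  expect_lte(b99$lo_cM, b95$lo_cM)
  expect_gte(b99$hi_cM, b95$hi_cM)

  # a spike curve collapses the Bayes interval and triggers the fallback
  spike <- sc
  spike$lod <- rep(0, nrow(spike))
  spike$lod[10] <- 50
  class(spike) <- class(sc)
  fb <- support_interval(spike, spike$chrom[10], spike$pos_cM[10],
                         method = "bayes")
  expect_true(fb$fallback)
  expect_equal(fb$hi_cM - fb$lo_cM, 5, tolerance = 1e-9)

  expect_error(support_interval(sc, pk$chrom, 0.123 +
                                  sc$pos_cM[which.min(sc$lod)]),
               "local maximum")
})
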