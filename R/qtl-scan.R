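# Genome scans: Haley-Knott interval mapping, permutation thresholds, and
# composite interval mapping.
#
# Haley-Knott regression replaces the full mixture likelihood by an
# ordinary regression of the phenotype on the expected genotype dosage at
# each grid position; LOD = (n/2) log10(RSS0/RSS1) against the covariate-
# only null. With covariates, both y and the dosage are residualised
# against the covariate design first (Frisch-Waugh), so the whole scan
# reduces to one correlation per position and permutation scans become a
# single cross-product.

#' Haley-Knott genome scan
#'
#' @param probs A `geno_probs` from [genotype_probabilities()].
#' @param y Named numeric phenotype vector (names = line ids) or unnamed in
#'   the row order of `probs`. Lines with missing phenotype are dropped
#'   scan-wide and `n` records the lines actually used.
#' @param covariates Optional numeric matrix/data frame of additive
#'   covariates (rows aligned with the lines used).
#' @return Object of class `lod_curve`: tibble `chrom`, `pos_cM`, `marker`,
#'   `lod` with attributes `n` and `scan_type`.
#' @export
scan_hk <- function(probs, y, covariates = NULL) {
  al <- align_phenotype(probs, y, covariates)
  if (sd(al$y) == 0) {
    warn("phenotype has zero variance; returning an all-zero LOD curve")
    return(new_lod_curve(probs$grid, rep(0, nrow(probs$grid)), al$n, "IM-HK"))
  }
  lods <- hk_lods(al$X, al$y, al$Z)
  new_lod_curve(probs$grid, lods, al$n, "IM-HK")
}

align_phenotype <- function(probs, y, covariates = NULL) {
  if (!is.null(names(y))) {
    y <- y[probs$lines]
  } else if (length(y) != length(probs$lines)) {
    abort("unnamed phenotype must match the number of lines")
  }
  keep <- !is.na(y)
  X <- genotype_dosage(probs)[keep, , drop = FALSE]
  Z <- cbind(`(Intercept)` = rep(1, sum(keep)))
  if (!is.null(covariates)) {
    Z <- cbind(Z, as.matrix(covariates)[keep, , drop = FALSE])
  }
  list(X = X, y = as.numeric(y[keep]), Z = Z, n = sum(keep))
}

# LOD via residualised correlations; X may be a matrix of positions and y a
# matrix of (possibly permuted) phenotypes
hk_lods <- function(X, y, Z) {
  n <- nrow(X)
  Q <- qr.Q(qr(Z))
  Xr <- X - Q %*% crossprod(Q, X)
  yr <- as.matrix(y) - Q %*% crossprod(Q, as.matrix(y))
  xs <- sqrt(colSums(Xr^2)); ys <- sqrt(colSums(yr^2))
  r <- crossprod(Xr, yr) / outer(pmax(xs, 1e-300), pmax(ys, 1e-300))
  r[xs < 1e-12, ] <- 0
  -(n / 2) * log10(pmax(1 - r^2, 1e-300))
}

new_lod_curve <- function(grid, lod, n, scan_type) {
  out <- grid %>% mutate(lod = as.numeric(lod))
  attr(out, "n") <- n
  attr(out, "scan_type") <- scan_type
  class(out) <- c("lod_curve", class(out))
  out
}

#' Genome-wide permutation threshold
#'
#' Shuffles the phenotype across lines `n_perm` times, records the
#' genome-wide maximum LOD of each permuted scan, and returns the requested
#' empirical quantile (default 0.95). The stored maxima are returned so the
#' quantile property can be inspected.
#'
#' @inheritParams scan_hk
#' @param n_perm Number of permutations (10,000 emulates the reference
#'   schedule; scale down for exploration).
#' @param quantile_p Quantile of the null max-LOD distribution.
#' @param seed Integer seed.
#' @return List: `threshold`, `max_lods` (length `n_perm`), `quantile_p`.
#' @export
permutation_threshold <- function(probs, y, covariates = NULL,
                                  n_perm = 10000, quantile_p = 0.95,
                                  seed = 1L) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  al <- align_phenotype(probs, y, covariates)
  set.seed(as.integer(seed))
  Yp <- vapply(seq_len(n_perm), function(i) sample(al$y), numeric(al$n))
  lods <- hk_lods(al$X, Yp, al$Z)
  mx <- apply(lods, 2, max)
  list(threshold = unname(quantile(mx, quantile_p)), max_lods = mx,
       quantile_p = quantile_p)
}

#' Composite interval mapping
#'
#' Selects up to `n_covar` marker covariates by forward regression on the
#' phenotype, then scans as in [scan_hk()] but drops any selected covariate
#' lying within `window` cM of the position being tested (on its
#' chromosome). With `n_covar = 0` the scan reduces exactly to [scan_hk()].
#'
#' @inheritParams scan_hk
#' @param n_covar Number of marker covariates (default 3).
#' @param window Exclusion window in cM around the test position.
#' @return A `lod_curve` (scan type `"CIM"`) with attribute
#'   `covar_markers`.
#' @export
scan_cim <- function(probs, y, n_covar = 3, window = 10) {
  al <- align_phenotype(probs, y)
  marker_idx <- which(!is.na(probs$grid$marker))
  if (n_covar >= length(marker_idx)) {
    abort("n_covar must be smaller than the number of markers")
  }
  if (sd(al$y) == 0) {
    warn("phenotype has zero variance; returning an all-zero LOD curve")
    return(new_lod_curve(probs$grid, rep(0, nrow(probs$grid)), al$n, "CIM"))
  }
  sel <- integer(0)
  if (n_covar > 0) {
    resid <- al$y - mean(al$y)
    cand <- marker_idx
    for (k in seq_len(n_covar)) {
      sc <- abs(crossprod(al$X[, cand, drop = FALSE], resid))
      pick <- cand[which.max(sc)]
      sel <- c(sel, pick)
      cand <- setdiff(cand, pick)
      fit <- lm.fit(cbind(1, al$X[, sel, drop = FALSE]), al$y)
      resid <- fit$residuals
    }
  }
  grid <- probs$grid
  lod <- numeric(nrow(grid))
  # positions sharing an active covariate set are scanned together
  active <- lapply(seq_len(nrow(grid)), function(j) {
    drop <- sel[grid$chrom[sel] == grid$chrom[j] &
                  abs(grid$pos_cM[sel] - grid$pos_cM[j]) <= window]
    sort(setdiff(sel, drop))
  })
  key <- vapply(active, paste, character(1), collapse = ",")
  for (k in unique(key)) {
    idx <- which(key == k)
    cv <- active[[idx[1]]]
    Z <- cbind(1, al$X[, cv, drop = FALSE])
    lod[idx] <- hk_lods(al$X[, idx, drop = FALSE], al$y, Z)
  }
  out <- new_lod_curve(grid, lod, al$n, "CIM")
  attr(out, "covar_markers") <- grid$marker[sel]
  attr(out, "covar_active") <- active
  out
}

#' Percent variance explained by a QTL
#'
#' PVE = 100 (1 - 10^(-2 LOD / n)).
#'
#' @param lod LOD score (>= 0, vectorised).
#' @param n Number of lines in the scan.
#' @return Percent.
#' @export
pve <- function(lod, n) {
  if (n < 1) abort("n must be >= 1")
  100 * (1 - 10^(-2 * lod / n))
}

#' Additive QTL effect at a position
#'
#' Half the difference between the fitted phenotype means of the two
#' homozygous classes, signed relative to the AA (R500-like) parent: a
#' positive effect means the R500 allele increases the trait. Computed by
#' regressing the phenotype on the dosage at the peak, so partially
#' informative positions contribute through their expected dosage.
#'
#' @param probs A `geno_probs`.
#' @param y Phenotype (as in [scan_hk()]).
#' @param chrom,pos_cM Peak position (nearest grid point is used).
#' @return Tibble: `chrom`, `pos_cM`, `effect`, `direction`.
#' @export
qtl_effect <- function(probs, y, chrom, pos_cM) {
  al <- align_phenotype(probs, y)
  j <- grid_index(probs$grid, chrom, pos_cM)
  x <- al$X[, j]
  cls <- x >= 0  # lines called by their most probable genotype
  if (all(cls) || all(!cls)) {
    abort("only one genotype class present at this position")
  }
  b <- unname((mean(al$y[cls]) - mean(al$y[!cls])) / 2)
  tibble(chrom = chrom, pos_cM = probs$grid$pos_cM[j], effect = b,
         direction = if (b >= 0) "R500+" else "R500-")
}

grid_index <- function(grid, chrom, pos_cM) {
  on <- which(grid$chrom == chrom)
  if (length(on) == 0) abort(sprintf("chromosome %s not on grid", chrom))
  on[which.min(abs(grid$pos_cM[on] - pos_cM))]
}
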