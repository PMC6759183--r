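# Multi-QTL model search and support intervals.
#
# The search seeds a joint Haley-Knott regression with the genome-wide
# significant peaks of a single-QTL scan, then iterates: refine each QTL
# position to its conditional LOD maximum, scan for additional QTL
# conditional on the model, and drop members whose conditional LOD falls
# below the threshold, until membership and positions stabilise.

#' Iterative multi-QTL model search
#'
#' @param probs A `geno_probs`.
#' @param y Phenotype (as in [scan_hk()]).
#' @param threshold Genome-wide LOD threshold from
#'   [permutation_threshold()].
#' @param max_iter Safety cap on refine/add/drop rounds.
#' @param min_sep Minimum cM separation between model QTL on one
#'   chromosome (peaks closer than this to an existing QTL are not added).
#' @return Object of class `qtl_model`: tibble of QTL (`chrom`, `pos_cM`,
#'   `lod` conditional on the rest, `effect`, `pve`), with attributes
#'   `n`, `threshold`, `model_pve`, `converged`.
#' @export
build_multi_qtl_model <- function(probs, y, threshold, max_iter = 10,
                                  min_sep = 10) {
  al <- align_phenotype(probs, y)
  grid <- probs$grid
  X <- al$X; yv <- al$y; n <- al$n
  rss <- function(Z) sum(lm.fit(Z, yv)$residuals^2)
  rss0 <- sum((yv - mean(yv))^2)
  model_lod <- function(pos_idx) {
    # conditional LOD of each member and of candidate additions
    Zfull <- cbind(1, X[, pos_idx, drop = FALSE])
    r_full <- rss(Zfull)
    vapply(seq_along(pos_idx), function(i) {
      Zred <- cbind(1, X[, pos_idx[-i], drop = FALSE])
      (n / 2) * log10(rss(Zred) / r_full)
    }, numeric(1))
  }

  # seed: per-chromosome peaks of the single-QTL scan above threshold
  base <- scan_hk(probs, y)
  seeds <- integer(0)
  for (ch in unique(grid$chrom)) {
    on <- which(grid$chrom == ch)
    j <- on[which.max(base$lod[on])]
    if (base$lod[j] >= threshold) seeds <- c(seeds, j)
  }
  qtl <- seeds
  converged <- TRUE
  if (length(qtl) > 0 || TRUE) {
    for (iter in seq_len(max_iter)) {
      prev <- sort(qtl)
      # refine positions one at a time, conditional on the others
      if (length(qtl) > 0) {
        for (i in seq_along(qtl)) {
          ch <- grid$chrom[qtl[i]]
          on <- which(grid$chrom == ch)
          others <- qtl[-i]
          Z <- cbind(1, X[, others, drop = FALSE])
          lods <- hk_lods(X[, on, drop = FALSE], yv, Z)
          qtl[i] <- on[which.max(lods)]
        }
      }
      # drop non-significant members (weakest first)
      repeat {
        if (length(qtl) == 0) break
        cl <- model_lod(qtl)
        if (min(cl) >= threshold) break
        qtl <- qtl[-which.min(cl)]
      }
      # add: genome scan conditional on the model
      Z <- cbind(1, X[, qtl, drop = FALSE])
      lods <- hk_lods(X, yv, Z)
      near <- rep(FALSE, nrow(grid))
      for (q in qtl) {
        near <- near | (grid$chrom == grid$chrom[q] &
                          abs(grid$pos_cM - grid$pos_cM[q]) < min_sep)
      }
      lods[near] <- 0
      if (max(lods) >= threshold) {
        cand <- which(lods == max(lods))
        # tie-break: lowest chromosome, then lowest position
        qtl <- c(qtl, cand[order(grid$chrom[cand], grid$pos_cM[cand])][1])
      }
      if (identical(sort(qtl), prev)) break
      if (iter == max_iter) converged <- FALSE
    }
  }
  if (length(qtl) == 0) {
    out <- tibble(chrom = character(), pos_cM = numeric(), lod = numeric(),
                  effect = numeric(), pve = numeric())
    attr(out, "model_pve") <- 0
  } else {
    qtl <- sort(qtl)
    cl <- model_lod(qtl)
    fit <- lm.fit(cbind(1, X[, qtl, drop = FALSE]), yv)
    out <- tibble(chrom = grid$chrom[qtl], pos_cM = grid$pos_cM[qtl],
                  lod = cl, effect = unname(coef(fit)[-1]),
                  pve = pve(cl, n))
    attr(out, "model_pve") <- 100 * (1 - sum(fit$residuals^2) / rss0)
  }
  attr(out, "n") <- n
  attr(out, "threshold") <- threshold
  attr(out, "converged") <- converged
  class(out) <- c("qtl_model", class(out))
  if (!converged) warn("multi-QTL search hit max_iter without stabilising")
  out
}

#' @exportS3Method
glance.qtl_model <- function(x, ...) {
  tibble(n_qtl = nrow(x), n = attr(x, "n"),
         threshold = attr(x, "threshold"),
         model_pve = attr(x, "model_pve"),
         converged = attr(x, "converged"))
}

#' QTL support interval
#'
#' Either the 1.5-LOD drop interval (widest interval around the peak where
#' LOD stays within `drop` of the peak) or an approximate Bayesian credible
#' interval (smallest set of highest-mass grid positions whose normalised
#' 10^LOD mass reaches `prob`, spanned to a contiguous interval). A Bayes
#' interval that collapses to a single grid position is replaced by peak
#' +/- 2.5 cM with the `fallback` flag set, since a one-point interval is
#' unrealistically narrow for the recombination content of a RIL panel.
#'
#' @param curve A `lod_curve`.
#' @param chrom,pos_cM Peak position (must be a local maximum of the
#'   curve).
#' @param method `"lod_drop"` or `"bayes"`.
#' @param drop LOD drop for `"lod_drop"` (default 1.5).
#' @param prob Mass for `"bayes"` (default 0.99).
#' @param fallback_halfwidth Half-width in cM for the degenerate-interval
#'   fallback (default 2.5).
#' @return Tibble: `chrom`, `peak_cM`, `lo_cM`, `hi_cM`, `method`,
#'   `fallback`.
#' @export
support_interval <- function(curve, chrom, pos_cM,
                             method = c("lod_drop", "bayes"),
                             drop = 1.5, prob = 0.99,
                             fallback_halfwidth = 2.5) {
  method <- match.arg(method)
  on <- which(curve$chrom == chrom)
  if (length(on) == 0) abort("chromosome not on curve")
  pos <- curve$pos_cM[on]; lod <- curve$lod[on]
  j <- which.min(abs(pos - pos_cM))
  nb <- c(if (j > 1) lod[j - 1], if (j < length(on)) lod[j + 1])
  if (any(nb > lod[j] + 1e-9)) abort("peak position is not a local maximum")
  fallback <- FALSE
  if (method == "lod_drop") {
    ok <- lod >= lod[j] - drop
    lo <- j; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- j; while (hi < length(on) && ok[hi + 1]) hi <- hi + 1
  } else {
    mass <- 10^(lod - max(lod))
    mass <- mass / sum(mass)
    ord <- order(mass, decreasing = TRUE)
    take <- ord[seq_len(which(cumsum(mass[ord]) >= prob)[1])]
    lo <- min(take); hi <- max(take)
    if (lo == hi) {
      fallback <- TRUE
      return(tibble(chrom = chrom, peak_cM = pos[j],
                    lo_cM = max(min(pos), pos[j] - fallback_halfwidth),
                    hi_cM = min(max(pos), pos[j] + fallback_halfwidth),
                    method = "bayes", fallback = TRUE))
    }
  }
  tibble(chrom = chrom, peak_cM = pos[j], lo_cM = pos[lo], hi_cM = pos[hi],
         method = method, fallback = fallback)
}
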