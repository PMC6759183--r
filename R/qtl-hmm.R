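# Hidden-Markov genotype probabilities on a cM grid.
#
# Two hidden states (the homozygous parental classes AA and BB of a selfed
# RIL). Transition probability between grid positions d cM apart uses the
# Haldane per-meiosis fraction r = (1 - exp(-2d/100))/2 expanded to the RIL
# scale R = 2r/(1+2r); emissions allow a genotyping error rate. Forward-
# backward runs vectorised across lines, with pseudomarkers inserted every
# `step` cM so scans have uniform resolution.

#' RIL-scale recombination fraction
#'
#' Map expansion for a selfed RIL: the observed fraction of recombinant
#' lines between two loci with per-meiosis fraction `r` is 2r/(1+2r).
#'
#' @param r Per-meiosis recombination fraction.
#' @return RIL-scale fraction.
#' @export
ril_r <- function(r) 2 * r / (1 + 2 * r)

#' Genotype probabilities by forward-backward HMM
#'
#' @param geno Character genotype matrix (lines x markers, `"AA"`/`"BB"`/
#'   `NA`) whose markers all appear in `map`, in map order per chromosome.
#' @param map Genetic map tibble (`marker`, `chrom`, `pos_cM`).
#' @param step Pseudomarker spacing in cM (default 1).
#' @param error Genotyping error rate (default 0.001).
#' @return Object of class `geno_probs`: `grid` (tibble `chrom`, `pos_cM`,
#'   `marker` with `NA` at pseudomarkers), `p_aa` (lines x positions matrix
#'   of P(AA)), `lines`, `step`, `error`. P(BB) is `1 - p_aa`.
#' @export
genotype_probabilities <- function(geno, map, step = 1, error = 0.001) {
  validate_genetic_map(map)
  if (!all(colnames(geno) %in% map$marker)) {
    abort("genotype matrix contains markers absent from the map")
  }
  n <- nrow(geno)
  chroms <- split(map, factor(map$chrom, levels = unique(map$chrom)))
  grids <- list(); probs <- list()
  for (cm in chroms) {
    typed <- cm$marker[cm$marker %in% colnames(geno)]
    cm <- cm[cm$marker %in% typed, , drop = FALSE]
    if (nrow(cm) == 0) next
    if (!identical(match(typed, colnames(geno)), sort(match(typed, colnames(geno))))) {
      abort(sprintf("marker order on %s disagrees between genotypes and map",
                    cm$chrom[1]))
    }
    pos <- sort(unique(c(cm$pos_cM,
                         seq(min(cm$pos_cM), max(cm$pos_cM), by = step))))
    mk <- cm$marker[match(pos, cm$pos_cM)]
    P <- length(pos)
    # emission likelihoods per line x position x state
    e_aa <- matrix(1, n, P); e_bb <- matrix(1, n, P)
    for (j in which(!is.na(mk))) {
      call <- geno[, mk[j]]
      e_aa[, j] <- ifelse(is.na(call), 1, ifelse(call == "AA", 1 - error, error))
      e_bb[, j] <- ifelse(is.na(call), 1, ifelse(call == "BB", 1 - error, error))
    }
    R <- ril_r(haldane_r(diff(pos)))
    # forward
    fa <- matrix(NA_real_, n, P); fb <- matrix(NA_real_, n, P)
    a1 <- 0.5 * e_aa[, 1]; b1 <- 0.5 * e_bb[, 1]
    z <- a1 + b1; fa[, 1] <- a1 / z; fb[, 1] <- b1 / z
    for (j in seq_len(P - 1L)) {
      r <- R[j]
      a <- (fa[, j] * (1 - r) + fb[, j] * r) * e_aa[, j + 1]
      b <- (fa[, j] * r + fb[, j] * (1 - r)) * e_bb[, j + 1]
      z <- a + b
      fa[, j + 1] <- a / z; fb[, j + 1] <- b / z
    }
    # backward
    ba <- matrix(1, n, P); bb <- matrix(1, n, P)
    for (j in rev(seq_len(P - 1L))) {
      r <- R[j]
      a <- (1 - r) * e_aa[, j + 1] * ba[, j + 1] + r * e_bb[, j + 1] * bb[, j + 1]
      b <- r * e_aa[, j + 1] * ba[, j + 1] + (1 - r) * e_bb[, j + 1] * bb[, j + 1]
      z <- a + b
      ba[, j] <- a / z; bb[, j] <- b / z
    }
    post <- fa * ba / (fa * ba + fb * bb)
    grids[[cm$chrom[1]]] <- tibble(chrom = cm$chrom[1], pos_cM = pos, marker = mk)
    probs[[cm$chrom[1]]] <- post
  }
  grid <- bind_rows(grids)
  p_aa <- do.call(cbind, probs)
  colnames(p_aa) <- paste(grid$chrom, format(grid$pos_cM, trim = TRUE), sep = "@")
  rownames(p_aa) <- rownames(geno)
  structure(list(grid = grid, p_aa = p_aa,
                 lines = rownames(geno), step = step, error = error),
            class = "geno_probs")
}

#' Expected genotype dosage
#'
#' Dosage on the +1 (AA, R500-like) / -1 (BB) scale: `2 P(AA) - 1`.
#'
#' @param probs A `geno_probs`.
#' @return Lines x positions numeric matrix.
#' @export
genotype_dosage <- function(probs) 2 * probs$p_aa - 1

#' @exportS3Method
tidy.geno_probs <- function(x, ...) {
  as_tibble(x$p_aa, rownames = "line") %>%
    tidyr::pivot_longer(-"line", names_to = "position", values_to = "p_aa") %>%
    tidyr::separate("position", c("chrom", "pos_cM"), sep = "@", convert = TRUE) %>%
    mutate(p_bb = 1 - .data$p_aa)
}
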