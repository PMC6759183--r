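# Genetic map and RIL genotype simulation.
#
# The target design is a biparental recombinant inbred line (RIL) population
# of the Brassica rapa IMB211 x R500 type: ~120 lines genotyped at a dense
# SNP map (defaults emulate 10 chromosomes, ~1450 markers, ~0.7 cM mean
# spacing), essentially fully homozygous after repeated selfing.

#' Build a synthetic genetic map
#'
#' Constructs a marker map over `n_chrom` chromosomes with
#' `markers_per_chrom` markers each. The first and last marker of every
#' chromosome sit at 0 and `chrom_length` cM; interior markers are either
#' evenly spaced (`spacing = "uniform"`) or uniformly scattered
#' (`spacing = "jittered"`). Each marker also receives a physical position
#' (bp) from a monotone, mildly nonlinear cM-to-bp expansion so that map-
#' anchored coordinate conversion can be exercised downstream.
#'
#' The defaults (10 chromosomes, 146 markers each, 100 cM) emulate a map of
#' ~1460 SNPs at ~0.7 cM mean spacing, the density typical of a RIL SNP map.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param markers_per_chrom Markers per chromosome (>= 2).
#' @param chrom_length Chromosome length in cM (> 0).
#' @param spacing `"uniform"` or `"jittered"`.
#' @param bp_per_cm Average physical-to-genetic scaling used for the bp
#'   coordinate (default 250,000 bp/cM).
#' @param seed Integer seed; same seed gives an identical map.
#' @return A tibble with columns `marker`, `chrom`, `pos_cM`, `pos_bp`,
#'   ordered by chromosome then position.
#' @export
make_genetic_map <- function(n_chrom = 10, markers_per_chrom = 146,
                             chrom_length = 100, spacing = c("uniform", "jittered"),
                             bp_per_cm = 250000, seed = 1L) {
  spacing <- match.arg(spacing)
  if (n_chrom < 1 || markers_per_chrom < 2 || chrom_length <= 0) {
    abort("need n_chrom >= 1, markers_per_chrom >= 2, chrom_length > 0")
  }
  set.seed(as.integer(seed))
  purrr::map_dfr(seq_len(n_chrom), function(ch) {
    if (spacing == "uniform") {
      pos <- seq(0, chrom_length, length.out = markers_per_chrom)
    } else {
      inner <- sort(runif(markers_per_chrom - 2L, 0, chrom_length))
      pos <- c(0, inner, chrom_length)
      # nudge ties apart; positions must be strictly increasing
      while (any(diff(pos) <= 0)) {
        pos <- cumsum(c(0, pmax(diff(pos), 1e-6)))
        pos <- pos / max(pos) * chrom_length
      }
    }
    # smooth monotone cM->bp warp, distinct per chromosome
    warp <- 1 + 0.3 * sin(seq(0, pi, length.out = markers_per_chrom) + ch)
    bp <- cumsum(c(0, diff(pos) * bp_per_cm * warp[-1]))
    tibble(
      marker = sprintf("c%02d_m%04d", ch, seq_len(markers_per_chrom)),
      chrom = sprintf("chr%02d", ch),
      pos_cM = pos,
      pos_bp = round(bp) + 1L
    )
  })
}

#' Haldane map function
#'
#' Converts a map distance in cM to a per-meiosis recombination fraction,
#' assuming no interference: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM Distance in centimorgans (vectorised).
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) (1 - exp(-2 * d_cM / 100)) / 2

#' Simulate RIL genotypes by repeated selfing
#'
#' Starting from an F1 heterozygous at every marker, each line is selfed for
#' `n_selfing_generations` meioses. Gametes recombine between adjacent
#' markers with the Haldane fraction for the map distance, independently per
#' interval (no interference), so map expansion across selfing generations
#' emerges from the forward process rather than a closed form. By default
#' any residual heterozygous markers are driven to fixation by continued
#' selfing (capped, then randomly resolved), emulating RILs that are >99%
#' homozygous; set `fully_homozygous = FALSE` to keep residual
#' heterozygotes, which are then reported as missing calls (`NA`).
#'
#' @param map Genetic map tibble from [make_genetic_map()] (or with columns
#'   `marker`, `chrom`, `pos_cM`).
#' @param n_lines Number of RILs to simulate.
#' @param n_selfing_generations Selfing meioses after the F1 (default 7).
#' @param fully_homozygous Drive residual heterozygotes to fixation
#'   (default `TRUE`).
#' @param missing_rate Fraction of calls masked to `NA` at random.
#' @param seed Integer seed.
#' @return A `line x marker` character matrix with entries `"AA"` (R500-like
#'   parent), `"BB"` (IMB211-like parent) or `NA`, with line ids as row
#'   names and marker ids as column names.
#' @export
simulate_rils <- function(map, n_lines, n_selfing_generations = 7,
                          fully_homozygous = TRUE, missing_rate = 0,
                          seed = 1L) {
  validate_genetic_map(map)
  if (n_lines < 1) abort("n_lines must be >= 1")
  set.seed(as.integer(seed))
  chroms <- split(map, factor(map$chrom, levels = unique(map$chrom)))
  geno <- lapply(chroms, function(cm) {
    m <- nrow(cm)
    r <- haldane_r(diff(cm$pos_cM))
    # two chromatids per line, alleles coded 0 (A) / 1 (B); F1 is 0 | 1
    A <- matrix(0L, n_lines, m)
    B <- matrix(1L, n_lines, m)
    gamete <- function(A, B, r) {
      m <- ncol(A)
      start <- rbinom(nrow(A), 1L, 0.5)
      if (m == 1L) {
        idx <- matrix(start, ncol = 1L)
      } else {
        sw <- matrix(rbinom(nrow(A) * (m - 1L), 1L, rep(r, each = nrow(A))),
                     nrow(A), m - 1L)
        ut <- upper.tri(diag(m - 1L), diag = TRUE) * 1L
        idx <- (start + cbind(0L, sw %*% ut)) %% 2L
      }
      A * (1L - idx) + B * idx
    }
    self_once <- function(state) {
      list(A = gamete(state$A, state$B, r), B = gamete(state$A, state$B, r))
    }
    st <- list(A = A, B = B)
    for (g in seq_len(n_selfing_generations)) st <- self_once(st)
    if (fully_homozygous) {
      extra <- 0L
      while (any(st$A != st$B) && extra < 25L) {
        het <- which(rowSums(st$A != st$B) > 0L)
        sub <- self_once(list(A = st$A[het, , drop = FALSE],
                              B = st$B[het, , drop = FALSE]))
        st$A[het, ] <- sub$A
        st$B[het, ] <- sub$B
        extra <- extra + 1L
      }
      if (any(st$A != st$B)) { # force the stragglers
        pick <- matrix(rbinom(length(st$A), 1L, 0.5), nrow(st$A))
        st$A <- st$A * (1L - pick) + st$B * pick
        st$B <- st$A
      }
    }
    list(A = st$A, B = st$B)
  })
  allele_a <- do.call(cbind, lapply(geno, `[[`, "A"))
  allele_b <- do.call(cbind, lapply(geno, `[[`, "B"))
  calls <- matrix(NA_character_, n_lines, nrow(map))
  calls[allele_a == 0L & allele_b == 0L] <- "AA"
  calls[allele_a == 1L & allele_b == 1L] <- "BB"
  if (missing_rate > 0) {
    calls[runif(length(calls)) < missing_rate] <- NA_character_
  }
  dimnames(calls) <- list(sprintf("RIL%03d", seq_len(n_lines)), map$marker)
  calls
}

validate_genetic_map <- function(map) {
  need <- c("marker", "chrom", "pos_cM")
  if (!all(need %in% names(map)) || nrow(map) == 0) {
    abort("map must have columns marker, chrom, pos_cM and at least one row")
  }
  bad <- map %>%
    group_by(.data$chrom) %>%
    summarise(ok = n() >= 2 && all(diff(.data$pos_cM) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort("each chromosome needs >= 2 markers with strictly increasing positions")
  }
  invisible(map)
}

#' Numeric genotype coding
#'
#' Codes RIL calls as +1 (`AA`, R500-like), -1 (`BB`) with `NA` preserved.
#' This sign convention propagates to QTL effect directions: a positive
#' additive effect means the R500 allele raises the trait.
#'
#' @param calls Character genotype matrix from [simulate_rils()].
#' @return Numeric matrix of the same shape.
#' @export
code_genotypes <- function(calls) {
  x <- matrix(NA_real_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  x[calls == "AA"] <- 1
  x[calls == "BB"] <- -1
  x
}
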