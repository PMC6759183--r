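# Cross-layer statistics: genes under QTL, enrichment, QTL-eQTL overlap,
# colocalization permutation tests, cis/trans classification, and the
# predictive-model comparison across data types.
#
# QTL intervals live in cM, gene coordinates in bp. A monotone piecewise-
# linear map anchored at markers (which carry both coordinates) converts
# between the two systems; all interval comparisons are closed at the
# boundaries.

#' Map-anchored coordinate conversion
#'
#' Converts positions between cM and bp by piecewise-linear interpolation
#' through the markers of one chromosome (constant extrapolation at the
#' ends).
#'
#' @param map Genetic map with `chrom`, `pos_cM`, `pos_bp`.
#' @param chrom Chromosome id.
#' @param pos Positions to convert (vectorised).
#' @param from `"cM"` or `"bp"`.
#' @return Converted positions.
#' @export
convert_position <- function(map, chrom, pos, from = c("cM", "bp")) {
  from <- match.arg(from)
  cm <- map[map$chrom == chrom, ]
  if (nrow(cm) == 0) abort(sprintf("chromosome %s not in map", chrom))
  if (!"pos_bp" %in% names(map)) abort("map lacks pos_bp anchors")
  if (from == "cM") {
    approx(cm$pos_cM, cm$pos_bp, xout = pos, rule = 2)$y
  } else {
    approx(cm$pos_bp, cm$pos_cM, xout = pos, rule = 2)$y
  }
}

#' Genes under QTL intervals
#'
#' Returns the unique set of genes overlapping any interval. Intervals in
#' cM are converted to bp through the map; overlap is closed at the
#' boundary.
#'
#' @param genes Tibble `gene`, `chrom`, `start_bp`, `end_bp`.
#' @param intervals Tibble `chrom`, `lo`, `hi` plus a `coord` attribute or
#'   column (`"cM"` or `"bp"`).
#' @param map Genetic map with bp anchors (required for cM intervals).
#' @return Character vector of gene ids, deduplicated.
#' @export
genes_in_intervals <- function(genes, intervals, map = NULL) {
  if (nrow(intervals) == 0) return(character(0))
  coord <- if ("coord" %in% names(intervals)) intervals$coord else
    rep(attr(intervals, "coord") %||% "bp", nrow(intervals))
  if (any(coord == "cM") && is.null(map)) {
    abort("cM intervals need a map with bp anchors for conversion")
  }
  hits <- character(0)
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals$lo[i]; hi <- intervals$hi[i]
    if (coord[i] == "cM") {
      lo <- convert_position(map, intervals$chrom[i], lo, "cM")
      hi <- convert_position(map, intervals$chrom[i], hi, "cM")
    }
    sel <- genes$chrom == intervals$chrom[i] &
      genes$start_bp <= hi & genes$end_bp >= lo
    hits <- c(hits, genes$gene[sel])
  }
  unique(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher enrichment of one gene set in another
#'
#' Two-sided Fisher's exact test on the 2x2 classification of the universe
#' by membership in `set_a` and `set_b`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all candidate elements.
#' @return Tibble: the four table counts (`both`, `a_only`, `b_only`,
#'   `neither`), `odds_ratio`, `p.value`.
#' @export
enrichment_fisher <- function(set_a, set_b, universe) {
  if (length(universe) == 0) abort("empty universe")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  ina <- universe %in% set_a; inb <- universe %in% set_b
  tab <- matrix(c(sum(ina & inb), sum(ina & !inb),
                  sum(!ina & inb), sum(!ina & !inb)), 2)
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(both = tab[1, 1], a_only = tab[2, 1], b_only = tab[1, 2],
         neither = tab[2, 2], odds_ratio = unname(ft$estimate),
         p.value = ft$p.value)
}

#' Classify an eQTL as cis or trans
#'
#' cis iff the eQTL interval contains the physical location of the gene
#' whose expression it maps (closed interval, same chromosome); otherwise
#' trans.
#'
#' @param eqtl Tibble `gene`, `chrom`, `lo`, `hi` (cM or bp; must match
#'   `genes` through `coord`/`map` as in [genes_in_intervals()]).
#' @param genes Gene coordinate tibble (`gene`, `chrom`, `start_bp`,
#'   `end_bp`).
#' @param map Map for cM -> bp conversion when needed.
#' @return `eqtl` with an added `class` column (`"cis"`/`"trans"`).
#' @export
classify_cis_trans <- function(eqtl, genes, map = NULL) {
  coord <- if ("coord" %in% names(eqtl)) eqtl$coord else
    rep(attr(eqtl, "coord") %||% "bp", nrow(eqtl))
  cls <- character(nrow(eqtl))
  for (i in seq_len(nrow(eqtl))) {
    g <- genes[genes$gene == eqtl$gene[i], ]
    if (nrow(g) == 0) abort(sprintf("unknown gene %s", eqtl$gene[i]))
    lo <- eqtl$lo[i]; hi <- eqtl$hi[i]
    if (coord[i] == "cM") {
      if (is.null(map)) abort("cM eQTL intervals need a map for conversion")
      lo <- convert_position(map, eqtl$chrom[i], lo, "cM")
      hi <- convert_position(map, eqtl$chrom[i], hi, "cM")
    }
    cls[i] <- if (g$chrom == eqtl$chrom[i] && g$start_bp <= hi && g$end_bp >= lo)
      "cis" else "trans"
  }
  eqtl %>% mutate(class = cls)
}

#' Pairwise interval overlap table
#'
#' Two intervals overlap iff they share a chromosome and
#' a.lo <= b.hi and b.lo <= a.hi (closed intervals: touching endpoints
#' overlap).
#'
#' @param a,b Interval tibbles (`chrom`, `lo`, `hi`, same coordinate
#'   system).
#' @return Tibble with one row per (a, b) pair and an `overlap` flag.
#' @export
interval_overlap <- function(a, b) {
  out <- tidyr::crossing(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
  out %>%
    mutate(chrom_a = a$chrom[.data$ia], lo_a = a$lo[.data$ia],
           hi_a = a$hi[.data$ia],
           chrom_b = b$chrom[.data$ib], lo_b = b$lo[.data$ib],
           hi_b = b$hi[.data$ib],
           overlap = .data$chrom_a == .data$chrom_b &
             .data$lo_a <= .data$hi_b & .data$lo_b <= .data$hi_a)
}

#' Colocalization permutation test
#'
#' Tests whether B intervals overlap A intervals more often than expected
#' if B intervals were placed at random. The statistic is the number of B
#' intervals overlapping at least one A interval; the null re-places every
#' B interval uniformly (width preserved) on a chromosome drawn
#' proportional to its length. p uses the add-one estimator and is never
#' zero.
#'
#' @param a,b Interval tibbles (`chrom`, `lo`, `hi`, cM coordinates).
#' @param map Genetic map giving chromosome lengths.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `observed`, `null`, `p.value`.
#' @export
colocalization_permutation <- function(a, b, map, n_perm = 1000, seed = 1L) {
  set.seed(as.integer(seed))
  lens <- map %>% group_by(.data$chrom) %>%
    summarise(len = max(.data$pos_cM), .groups = "drop")
  widths <- b$hi - b$lo
  if (any(widths > max(lens$len))) abort("interval wider than any chromosome")
  count_overlaps <- function(bi) {
    n_hit <- 0L
    for (i in seq_len(nrow(bi))) {
      hit <- any(a$chrom == bi$chrom[i] & a$lo <= bi$hi[i] & bi$lo[i] <= a$hi)
      n_hit <- n_hit + hit
    }
    n_hit
  }
  observed <- count_overlaps(b)
  m <- nrow(b)
  null <- vapply(seq_len(n_perm), function(p) {
    ch <- sample(lens$chrom, m, replace = TRUE, prob = lens$len)
    len <- lens$len[match(ch, lens$chrom)]
    lo <- runif(m, 0, pmax(len - widths, 0))
    count_overlaps(tibble(chrom = ch, lo = lo, hi = lo + widths))
  }, numeric(1))
  list(observed = observed, null = null,
       p.value = (1 + sum(null >= observed)) / (n_perm + 1))
}

#' Compare QTL, MR-gene, and eigengene predictive models
#'
#' Builds the additive linear-model families of the data-type comparison --
#' single data type (QTL only, MR expression only, eigengene only), the
#' three pairwise combinations, and the full model -- with the trait BLUP
#' as response. Each model undergoes backward elimination: the term with
#' the largest p-value is removed (ties broken by name) until every
#' remaining term has p < `stay_p`. Final models are reported with F,
#' adjusted R-squared and AIC; nested pairs are compared by F-test.
#'
#' @param blup Named numeric response (line-matched trait BLUPs).
#' @param qtl Data frame of per-line QTL dosage/effect predictors (or
#'   NULL).
#' @param mr_expr Data frame of per-line MR-gene expression predictors.
#' @param eigen Data frame of per-line eigengene predictors.
#' @param stay_p Stay threshold for backward elimination (default 0.10).
#' @return Object of class `model_comparison`: `models` tibble (family,
#'   retained terms, F, df, adj R2, AIC), `anova` tibble of nested-model
#'   F-tests, and the final `lm` fits.
#' @export
compare_predictive_models <- function(blup, qtl = NULL, mr_expr = NULL,
                                      eigen = NULL, stay_p = 0.10) {
  parts <- purrr::compact(list(qtl = qtl, mr = mr_expr, eigengene = eigen))
  if (length(parts) == 0) abort("supply at least one predictor block")
  n <- length(blup)
  families <- c(purrr::imap(parts, function(d, nm) nm),
                if (length(parts) >= 2)
                  utils::combn(names(parts), 2, paste, collapse = "+",
                               simplify = FALSE),
                if (length(parts) == 3) list("qtl+mr+eigengene"))
  fits <- list(); rows <- list()
  for (fam in families) {
    blocks <- strsplit(fam, "+", fixed = TRUE)[[1]]
    df <- as.data.frame(do.call(cbind, lapply(parts[blocks], as.data.frame)))
    names(df) <- make.names(names(df), unique = TRUE)
    if (ncol(df) >= n) {
      abort(sprintf("family %s has %d predictors for %d lines; pre-filter",
                    fam, ncol(df), n))
    }
    df$.y <- as.numeric(blup)
    fit <- backward_eliminate(df, stay_p)
    s <- summary(fit)
    fstat <- s$fstatistic
    rows[[fam]] <- tibble(
      family = fam,
      n_terms = length(coef(fit)) - 1,
      terms = paste(names(coef(fit))[-1], collapse = ","),
      f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
      df1 = if (is.null(fstat)) NA_real_ else unname(fstat[2]),
      df2 = if (is.null(fstat)) NA_real_ else unname(fstat[3]),
      adj_r2 = s$adj.r.squared,
      aic = AIC(fit)
    )
    fits[[fam]] <- fit
  }
  models <- bind_rows(rows)
  # nested F-tests: each family against larger families containing it
  an <- list()
  for (i in seq_along(families)) {
    for (j in seq_along(families)) {
      bi <- strsplit(families[[i]], "+", fixed = TRUE)[[1]]
      bj <- strsplit(families[[j]], "+", fixed = TRUE)[[1]]
      if (i == j || !all(bi %in% bj)) next
      small <- fits[[families[[i]]]]; big <- fits[[families[[j]]]]
      if (!all(names(coef(small))[-1] %in% names(coef(big))[-1])) next
      av <- anova(small, big)  # same observations in both fits
      an[[paste(families[[i]], families[[j]], sep = " vs ")]] <- tibble(
        reduced = families[[i]], full = families[[j]],
        f = av$F[2], p.value = av$`Pr(>F)`[2]
      )
    }
  }
  structure(list(models = models, anova = bind_rows(an), fits = fits),
            class = "model_comparison")
}

backward_eliminate <- function(df, stay_p) {
  preds <- setdiff(names(df), ".y")
  repeat {
    if (length(preds) == 0) return(lm(.y ~ 1, data = df))
    fit <- lm(stats::reformulate(preds, ".y"), data = df)
    p <- summary(fit)$coefficients[-1, 4]
    # aliased terms (NA coefficients) are removed first
    ali <- preds[is.na(coef(fit)[-1])]
    if (length(ali) > 0) { preds <- setdiff(preds, ali[order(ali)][1]); next }
    if (all(p < stay_p)) return(fit)
    worst <- names(p)[p == max(p)]
    preds <- setdiff(preds, sort(worst)[1])
  }
}

#' @exportS3Method
tidy.model_comparison <- function(x, ...) x$models

#' @exportS3Method
glance.model_comparison <- function(x, ...) {
  best <- x$models %>% arrange(.data$aic) %>% slice(1)
  tibble(best_family = best$family, best_aic = best$aic,
         best_adj_r2 = best$adj_r2)
}
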