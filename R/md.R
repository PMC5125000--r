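#' Two-locus level counts
#'
#' Counts samples by their two-locus level combination (HH, HL, LH, LL) over
#' samples with a non-missing level at both loci. These counts, divided by
#' their total, are the methylecomtype frequencies p_H1H2, p_H1L2, p_L1H2,
#' p_L1L2 from which all MD coefficients derive. Combinations are observed
#' directly per sample — no phasing is involved.
#'
#' @param x A `meth_levels` object.
#' @param i,j Locus indices (row numbers) or locus names; `i != j`.
#' @return Named integer vector `c(n_hh, n_hl, n_lh, n_ll)`.
#' @examples
#' bm <- structure(list(statuses = c(1L, 0L, 1L, 0L),
#'                      loci = data.frame(name = c("a", "b"), chrom = "1",
#'                                        pos = c(100L, 200L)),
#'                      levels = rbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L)),
#'                      threshold = 0.5), class = "meth_levels")
#' pair_counts(bm, 1, 2)  # perfectly concordant: 2 HH, 2 LL
#' @export
pair_counts <- function(x, i, j) {
  stopifnot(inherits(x, "meth_levels"))
  if (is.character(i)) i <- match(i, x$loci$name)
  if (is.character(j)) j <- match(j, x$loci$name)
  stopifnot(length(i) == 1L, length(j) == 1L, !is.na(i), !is.na(j))
  if (i == j) stop("pair_counts requires two distinct loci")
  a <- x$levels[i, ]
  b <- x$levels[j, ]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  c(n_hh = sum(a == 1L & b == 1L), n_hl = sum(a == 1L & b == 0L),
    n_lh = sum(a == 0L & b == 1L), n_ll = sum(a == 0L & b == 0L))
}

unpack_counts <- function(n_hh, n_hl, n_lh, n_ll) {
  if (is.null(n_hl) && is.null(n_lh) && is.null(n_ll)) {
    m <- n_hh
    if (is.matrix(m) && ncol(m) == 4L)
      return(list(n_hh = m[, 1L], n_hl = m[, 2L], n_lh = m[, 3L], n_ll = m[, 4L]))
    if (length(m) == 4L)
      return(list(n_hh = m[[1L]], n_hl = m[[2L]], n_lh = m[[3L]], n_ll = m[[4L]]))
    stop("supply four count vectors, one length-4 vector, or a 4-column matrix")
  }
  list(n_hh = n_hh, n_hl = n_hl, n_lh = n_lh, n_ll = n_ll)
}

#' MD coefficients gd, gD' and gr2 from two-locus counts
#'
#' The raw methylation-disequilibrium coefficient is
#' `gd = p_H1H2 - p_H1 * p_H2`, the deviation of the joint high/high frequency
#' from independence. It is standardized two ways, following the classical
#' D'/r2 constructions of linkage-disequilibrium analysis:
#' `gD' = |gd| / gd_max`, where `gd_max = min(p_H1*p_L2, p_L1*p_H2)` when
#' `gd > 0` and `min(p_H1*p_H2, p_L1*p_L2)` when `gd < 0` (defined as 0 when
#' `gd = 0`); and `gr2 = gd^2 / (p_H1*p_L1*p_H2*p_L2)`. Both lie in `[0, 1]`
#' and are clamped there against floating-point overshoot.
#'
#' For a locus monomorphic in the pairwise-complete samples, MD is undefined:
#' `gd` is 0 and the standardized values are `NA`. With zero complete samples
#' all values are `NA`.
#'
#' @param n_hh,n_hl,n_lh,n_ll Count vectors (vectorized over pairs). A single
#'   length-4 vector or a 4-column matrix may be passed as the first argument.
#' @return A data.frame with columns `n`, `p_h1`, `p_h2`, `gd`, `gdprime`,
#'   `gr2`.
#' @examples
#' md_coef(c(n_hh = 2, n_hl = 0, n_lh = 0, n_ll = 2))  # gD' = 1, gr2 = 1
#' md_coef(1, 1, 1, 1)                                 # independence: all 0
#' @export
md_coef <- function(n_hh, n_hl = NULL, n_lh = NULL, n_ll = NULL) {
  cc <- unpack_counts(n_hh, n_hl, n_lh, n_ll)
  n <- cc$n_hh + cc$n_hl + cc$n_lh + cc$n_ll
  p_h1 <- (cc$n_hh + cc$n_hl) / n
  p_h2 <- (cc$n_hh + cc$n_lh) / n
  p_l1 <- 1 - p_h1
  p_l2 <- 1 - p_h2
  gd <- cc$n_hh / n - p_h1 * p_h2
  poly <- !is.na(gd) & p_h1 > 0 & p_h1 < 1 & p_h2 > 0 & p_h2 < 1
  gd_max <- ifelse(gd < 0, pmin(p_h1 * p_h2, p_l1 * p_l2),
                   pmin(p_h1 * p_l2, p_l1 * p_h2))
  gdprime <- ifelse(gd == 0, 0, abs(gd) / gd_max)
  gr2 <- gd^2 / (p_h1 * p_l1 * p_h2 * p_l2)
  gdprime <- pmin(pmax(gdprime, 0), 1)
  gr2 <- pmin(pmax(gr2, 0), 1)
  gd[!is.na(gd) & !poly] <- 0
  gdprime[!poly] <- NA_real_
  gr2[!poly] <- NA_real_
  data.frame(n = n, p_h1 = p_h1, p_h2 = p_h2, gd = gd,
             gdprime = gdprime, gr2 = gr2)
}

# column-wise cumulative sums via one BLAS multiply; U is upper-triangular ones
cumsum_rows <- function(w) {
  m <- ncol(w)
  U <- matrix(0, m, m)
  U[upper.tri(U, diag = TRUE)] <- 1
  w %*% U
}

#' Likelihood-grid confidence bounds on gD'
#'
#' One-sided confidence bounds in the Gabriel/Haploview style: for each value
#' d' on the grid `{0, step, ..., 1}`, the multinomial log-likelihood of the
#' observed 2x2 counts is evaluated under cell probabilities implied by the
#' observed marginals and `|gd| = d' * gd_max` (with the sign of the observed
#' gd). The exponentiated likelihoods are normalized to a discrete distribution
#' over the grid; `ci_low` is the smallest grid value whose cumulative mass
#' reaches `1 - level`, and `ci_high` the smallest reaching `level`.
#'
#' @inheritParams md_coef
#' @param level One-sided confidence level (default 0.95).
#' @param step Grid resolution on d' (default 0.01, a 101-point grid).
#' @return A data.frame with columns `ci_low`, `ci_high` (`NA` for degenerate
#'   pairs: fewer than 2 complete samples or a monomorphic locus).
#' @examples
#' dprime_ci(c(50, 0, 0, 50))   # mass piles at d' = 1
#' dprime_ci(c(25, 25, 25, 25)) # mass piles near d' = 0
#' @export
dprime_ci <- function(n_hh, n_hl = NULL, n_lh = NULL, n_ll = NULL,
                      level = 0.95, step = 0.01) {
  cc <- unpack_counts(n_hh, n_hl, n_lh, n_ll)
  n_hh <- as.numeric(cc$n_hh); n_hl <- as.numeric(cc$n_hl)
  n_lh <- as.numeric(cc$n_lh); n_ll <- as.numeric(cc$n_ll)
  n <- n_hh + n_hl + n_lh + n_ll
  k <- length(n)
  p_h1 <- (n_hh + n_hl) / n
  p_h2 <- (n_hh + n_lh) / n
  p_l1 <- 1 - p_h1
  p_l2 <- 1 - p_h2
  gd <- n_hh / n - p_h1 * p_h2
  ok <- n >= 2 & p_h1 > 0 & p_h1 < 1 & p_h2 > 0 & p_h2 < 1
  ok[is.na(ok)] <- FALSE
  out <- data.frame(ci_low = rep(NA_real_, k), ci_high = rep(NA_real_, k))
  if (!any(ok)) return(out)

  idx <- which(ok)
  sgn <- ifelse(gd[idx] < 0, -1, 1)
  gd_max <- ifelse(gd[idx] < 0,
                   pmin(p_h1[idx] * p_h2[idx], p_l1[idx] * p_l2[idx]),
                   pmin(p_h1[idx] * p_l2[idx], p_l1[idx] * p_h2[idx]))
  g <- seq(0, 1, by = step)
  D <- (sgn * gd_max) %o% g
  eps <- 1e-12
  # k x grid matrices; count vectors recycle down columns
  ll <- n_hh[idx] * log(pmax(p_h1[idx] * p_h2[idx] + D, eps)) +
        n_hl[idx] * log(pmax(p_h1[idx] * p_l2[idx] - D, eps)) +
        n_lh[idx] * log(pmax(p_l1[idx] * p_h2[idx] - D, eps)) +
        n_ll[idx] * log(pmax(p_l1[idx] * p_l2[idx] + D, eps))
  mx <- ll[, 1L]
  for (jc in 2:ncol(ll)) mx <- pmax(mx, ll[, jc])
  w <- exp(ll - mx)
  cum <- cumsum_rows(w)
  tot <- cum[, ncol(cum)]
  lo_q <- (1 - level) * tot - 1e-12
  hi_q <- level * tot - 1e-12
  out$ci_low[idx] <- g[max.col(1 * (cum >= lo_q), ties.method = "first")]
  out$ci_high[idx] <- g[max.col(1 * (cum >= hi_q), ties.method = "first")]
  out
}

#' Gabriel informativeness classification of a locus pair
#'
#' Applies the confidence-bound thresholds of the Gabriel block definition:
#' a pair is `strong_md` when `ci_low >= strong_low` and
#' `ci_high >= strong_high`; it shows `strong_recombination` when
#' `ci_high < recomb_high`; anything else (including missing bounds) is
#' `uninformative`. Defaults (0.70, 0.98, 0.90) are the Gabriel/Haploview
#' conventions.
#'
#' @param ci_low,ci_high Confidence bounds from [dprime_ci()] (vectorized).
#' @param strong_low,strong_high,recomb_high Classification thresholds.
#' @return A factor with levels `strong_md`, `strong_recombination`,
#'   `uninformative`.
#' @export
classify_md <- function(ci_low, ci_high, strong_low = 0.70,
                        strong_high = 0.98, recomb_high = 0.90) {
  cls <- rep("uninformative", length(ci_low))
  strong <- !is.na(ci_low) & !is.na(ci_high) &
    ci_low >= strong_low & ci_high >= strong_high
  recomb <- !is.na(ci_high) & ci_high < recomb_high & !strong
  cls[strong] <- "strong_md"
  cls[recomb] <- "strong_recombination"
  factor(cls, levels = c("strong_md", "strong_recombination", "uninformative"))
}

#' Full MD summary for one locus pair
#'
#' Convenience wrapper combining [pair_counts()], [md_coef()], [dprime_ci()]
#' and [classify_md()] for an ad-hoc query (cross-chromosome pairs allowed).
#'
#' @inheritParams pair_counts
#' @param level Confidence level for the gD' bounds.
#' @param f_min Minor-level frequency floor: a pair whose locus has
#'   `min(p_H, p_L) < f_min` is classified uninformative (0 disables).
#' @param ... Passed to [classify_md()].
#' @return One-row data.frame with locus metadata, counts, coefficients,
#'   confidence bounds and `md_class`.
#' @export
md_pair <- function(x, i, j, level = 0.95, f_min = 0.05, ...) {
  if (is.character(i)) i <- match(i, x$loci$name)
  if (is.character(j)) j <- match(j, x$loci$name)
  pc <- pair_counts(x, i, j)
  co <- md_coef(pc)
  ci <- dprime_ci(pc, level = level)
  cls <- classify_md(ci$ci_low, ci$ci_high, ...)
  if (!is.na(co$gdprime) &&
      (min(co$p_h1, 1 - co$p_h1) < f_min || min(co$p_h2, 1 - co$p_h2) < f_min))
    cls <- factor("uninformative", levels = levels(cls))
  if (is.na(co$gdprime)) cls <- factor("uninformative", levels = levels(cls))
  data.frame(locus1 = x$loci$name[i], locus2 = x$loci$name[j],
             chrom1 = x$loci$chrom[i], chrom2 = x$loci$chrom[j],
             pos1 = x$loci$pos[i], pos2 = x$loci$pos[j],
             n = co$n, n_hh = pc[["n_hh"]], n_hl = pc[["n_hl"]],
             n_lh = pc[["n_lh"]], n_ll = pc[["n_ll"]],
             gd = co$gd, gdprime = co$gdprime, gr2 = co$gr2,
             ci_low = ci$ci_low, ci_high = ci$ci_high, md_class = cls,
             stringsAsFactors = FALSE)
}

# Vectorized per-lag pair counts for one chromosome's level matrix.
# Returns, for lag d, counts for pairs (i, i+d), i = 1..L-d.
lag_pair_counts <- function(lv, d) {
  L <- nrow(lv)
  a <- seq_len(L - d)
  b <- a + d
  H <- lv
  H[is.na(H)] <- 0L
  storage.mode(H) <- "double"
  V <- matrix(as.double(!is.na(lv)), nrow(lv), ncol(lv))
  Ha <- H[a, , drop = FALSE]; Hb <- H[b, , drop = FALSE]
  Va <- V[a, , drop = FALSE]; Vb <- V[b, , drop = FALSE]
  n_hh <- rowSums(Ha * Hb)
  n1 <- rowSums(Ha * Vb)
  n2 <- rowSums(Va * Hb)
  nn <- rowSums(Va * Vb)
  cbind(n_hh = n_hh, n_hl = n1 - n_hh, n_lh = n2 - n_hh,
        n_ll = nn - n1 - n2 + n_hh)
}

# Pairwise engine for one chromosome: per-lag counts, coefficients, CI bounds
# and Gabriel classification (0 = uninformative, 1 = strong MD, 2 = strong
# recombination), with precomputed H/valid matrices shared across lags.
chrom_pair_engine <- function(lv, max_lag, f_min = 0.05, level = 0.95,
                              step = 0.01, strong_low = 0.70,
                              strong_high = 0.98, recomb_high = 0.90,
                              keep_stats = FALSE) {
  L <- nrow(lv)
  max_lag <- max(0L, min(max_lag, L - 1L))
  H <- lv
  H[is.na(H)] <- 0L
  storage.mode(H) <- "double"
  V <- matrix(as.double(!is.na(lv)), nrow(lv), ncol(lv))
  nv <- rowSums(V)
  ph <- ifelse(nv > 0, rowSums(H) / nv, NA_real_)
  locus_ok <- !is.na(ph) & ph > 0 & ph < 1 & pmin(ph, 1 - ph) >= f_min
  cls <- vector("list", max_lag)
  stats <- if (keep_stats) vector("list", max_lag) else NULL
  for (d in seq_len(max_lag)) {
    a <- seq_len(L - d)
    b <- a + d
    Ha <- H[a, , drop = FALSE]; Hb <- H[b, , drop = FALSE]
    Va <- V[a, , drop = FALSE]; Vb <- V[b, , drop = FALSE]
    n_hh <- rowSums(Ha * Hb)
    n1 <- rowSums(Ha * Vb)
    n2 <- rowSums(Va * Hb)
    nn <- rowSums(Va * Vb)
    counts <- cbind(n_hh, n1 - n_hh, n2 - n_hh, nn - n1 - n2 + n_hh)
    ci <- dprime_ci(counts, level = level, step = step)
    cd <- classify_md(ci$ci_low, ci$ci_high, strong_low = strong_low,
                      strong_high = strong_high, recomb_high = recomb_high)
    cdi <- c(1L, 2L, 0L)[as.integer(cd)]
    cdi[!(locus_ok[a] & locus_ok[b])] <- 0L
    cls[[d]] <- cdi
    if (keep_stats) {
      co <- md_coef(counts)
      stats[[d]] <- cbind(co, ci)
    }
  }
  list(L = L, cls = cls, stats = stats, locus_ok = locus_ok)
}

#' Pairwise MD table for all same-chromosome locus pairs
#'
#' Computes gd, gD', gr2, the gD' confidence bounds and the Gabriel
#' informativeness class for every pair of loci on the same chromosome,
#' optionally restricted to pairs at most `max_lag` loci apart.
#'
#' @param x A `meth_levels` object.
#' @param max_lag Maximum index distance between paired loci (`NULL` = all
#'   pairs per chromosome).
#' @param f_min Minor-level frequency floor below which a locus renders its
#'   pairs uninformative (default 0.05; 0 disables).
#' @param level Confidence level for gD' bounds.
#' @param step Grid resolution for [dprime_ci()].
#' @param strong_low,strong_high,recomb_high Thresholds for [classify_md()].
#' @return A data.frame, one row per pair: `locus1`, `locus2`, `chrom`,
#'   `pos1`, `pos2`, `n`, `gd`, `gdprime`, `gr2`, `ci_low`, `ci_high`,
#'   `md_class`.
#' @export
md_pairs <- function(x, max_lag = NULL, f_min = 0.05, level = 0.95,
                     step = 0.01, strong_low = 0.70, strong_high = 0.98,
                     recomb_high = 0.90) {
  stopifnot(inherits(x, "meth_levels"))
  chroms <- unique(x$loci$chrom)
  res <- list()
  for (ch in chroms) {
    idx <- which(x$loci$chrom == ch)
    L <- length(idx)
    if (L < 2L) next
    ml <- if (is.null(max_lag)) L - 1L else min(max_lag, L - 1L)
    eng <- chrom_pair_engine(x$levels[idx, , drop = FALSE], ml, f_min = f_min,
                             level = level, step = step,
                             strong_low = strong_low,
                             strong_high = strong_high,
                             recomb_high = recomb_high, keep_stats = TRUE)
    for (d in seq_len(ml)) {
      a <- seq_len(L - d)
      b <- a + d
      st <- eng$stats[[d]]
      cls <- factor(c("strong_md", "strong_recombination",
                      "uninformative")[match(eng$cls[[d]], c(1L, 2L, 0L))],
                    levels = c("strong_md", "strong_recombination",
                               "uninformative"))
      res[[length(res) + 1L]] <- data.frame(
        locus1 = x$loci$name[idx[a]], locus2 = x$loci$name[idx[b]],
        chrom = ch, pos1 = x$loci$pos[idx[a]], pos2 = x$loci$pos[idx[b]],
        n = st$n, gd = st$gd, gdprime = st$gdprime, gr2 = st$gr2,
        ci_low = st$ci_low, ci_high = st$ci_high, md_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(locus1 = character(), locus2 = character(),
                      chrom = character(), pos1 = integer(), pos2 = integer(),
                      n = numeric(), gd = numeric(), gdprime = numeric(),
                      gr2 = numeric(), ci_low = numeric(), ci_high = numeric(),
                      md_class = factor(levels = c("strong_md",
                        "strong_recombination", "uninformative")),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(chrom_rank(out$chrom), out$pos1, out$pos2), , drop = FALSE]
}
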