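#' Case/control association tests for methylecomtypes
#'
#' For each MD block and each methylecomtype whose overall frequency (among
#' complete case and control samples) reaches `min_comtype_freq`, a 2x2 table
#' (this pattern vs all others, case vs control) is tested with the Pearson
#' chi-square statistic (1 df, no continuity correction). The odds ratio is
#' `(a*d)/(b*c)`; when any cell is zero the Haldane-Anscombe correction adds
#' 0.5 to every cell before the OR and its confidence interval. The 95% CI is
#' `exp(log(OR) +/- 1.96 * sqrt(sum(1/cell)))` on the (possibly corrected)
#' cells. Unknown-status samples and samples with a missing level inside the
#' block are excluded from the tables.
#'
#' @param x A `meth_levels` object carrying case/control statuses.
#' @param blocks An `md_blocks` object from [md_blocks()].
#' @param min_comtype_freq Minimum overall pattern frequency for testing
#'   (default 0.01).
#' @param adjust Multiple-testing adjustment for an additional `p_adjusted`
#'   column: `"none"` (default, no column), `"bonferroni"` or `"BH"`.
#' @return A data.frame of class `comtype_assoc`, one row per tested pattern:
#'   block metadata, pattern, case/control counts and frequencies, `chi2`,
#'   `p_value`, `odds_ratio`, `or_ci_low`, `or_ci_high`.
#' @export
comtype_test <- function(x, blocks, min_comtype_freq = 0.01,
                         adjust = c("none", "bonferroni", "BH")) {
  stopifnot(inherits(x, "meth_levels"), inherits(blocks, "md_blocks"))
  adjust <- match.arg(adjust)
  st <- x$statuses
  if (!any(st == 1L) || !any(st == 0L))
    stop("association testing requires at least one case and one control")
  case_idx <- which(st == 1L)
  ctrl_idx <- which(st == 0L)
  b <- blocks$blocks
  rows <- list()
  for (k in seq_len(nrow(b))) {
    gi <- blocks$members[[k]]
    lv <- x$levels[gi, , drop = FALSE]
    complete <- colSums(is.na(lv)) == 0L
    cs <- intersect(which(complete), case_idx)
    ct <- intersect(which(complete), ctrl_idx)
    n_case <- length(cs)
    n_ctrl <- length(ct)
    if (n_case == 0L || n_ctrl == 0L) {
      warning("block ", b$name[k],
              " skipped: no complete case or control samples")
      next
    }
    ch <- matrix(c("L", "H")[lv + 1L], nrow(lv), ncol(lv))
    pats <- do.call(paste0, as.data.frame(t(ch), stringsAsFactors = FALSE))
    tc <- table(factor(pats[cs]))
    tt <- table(factor(pats[c(cs, ct)]))
    all_pat <- names(tt)
    a_vec <- as.integer(tc[all_pat]); a_vec[is.na(a_vec)] <- 0L
    tot <- as.integer(tt[all_pat])
    c_vec <- tot - a_vec
    freq <- tot / (n_case + n_ctrl)
    keep <- freq >= min_comtype_freq
    if (!any(keep)) next
    a <- as.numeric(a_vec[keep]); cc <- as.numeric(c_vec[keep])
    bb <- n_case - a; dd <- n_ctrl - cc
    n <- as.numeric(n_case + n_ctrl)
    denom <- (a + bb) * (cc + dd) * (a + cc) * (bb + dd)
    chi2 <- ifelse(denom > 0, n * (a * dd - bb * cc)^2 / denom, 0)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    zero <- a == 0L | bb == 0L | cc == 0L | dd == 0L
    af <- a + 0.5 * zero; bf <- bb + 0.5 * zero
    cf <- cc + 0.5 * zero; df_ <- dd + 0.5 * zero
    or <- (af * df_) / (bf * cf)
    se <- sqrt(1 / af + 1 / bf + 1 / cf + 1 / df_)
    pat_order <- order(-(a + cc), all_pat[keep], method = "radix")
    rows[[length(rows) + 1L]] <- data.frame(
      block = b$name[k], chrom = b$chrom[k], start = b$start[k],
      end = b$end[k], loci = b$loci[k], pattern = all_pat[keep],
      case_count = a, control_count = cc,
      case_other = bb, control_other = dd,
      case_freq = a / n_case, control_freq = cc / n_ctrl,
      chi2 = chi2, p_value = p, odds_ratio = or,
      or_ci_low = exp(log(or) - 1.96 * se),
      or_ci_high = exp(log(or) + 1.96 * se),
      stringsAsFactors = FALSE)[pat_order, , drop = FALSE]
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(), chrom = character(), start = integer(),
               end = integer(), loci = character(), pattern = character(),
               case_count = integer(), control_count = integer(),
               case_other = integer(), control_other = integer(),
               case_freq = numeric(), control_freq = numeric(),
               chi2 = numeric(), p_value = numeric(), odds_ratio = numeric(),
               or_ci_low = numeric(), or_ci_high = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (adjust != "none" && nrow(out))
    out$p_adjusted <- stats::p.adjust(out$p_value, method =
                                        if (adjust == "BH") "BH" else "bonferroni")
  class(out) <- c("comtype_assoc", "data.frame")
  out
}

#' Write the methylecomtype association table as TSV
#'
#' @param assoc A `comtype_assoc` data.frame from [comtype_test()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(assoc, path) {
  stopifnot(inherits(assoc, "data.frame"))
  cols <- c("chrom", "block", "start", "end", "loci", "pattern",
            "case_count", "control_count", "case_freq", "control_freq",
            "chi2", "p_value", "odds_ratio", "or_ci_low", "or_ci_high")
  if ("p_adjusted" %in% names(assoc)) cols <- c(cols, "p_adjusted")
  data.table::fwrite(as.data.frame(assoc)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-locus two-sample t test on raw beta values
#'
#' Welch's unequal-variance t test of case vs control beta values at every
#' locus, computed genewise on the raw (not binarized) matrix. Loci with
#' fewer than two non-missing case or control values are returned with `NA`
#' statistics. When both groups have zero variance, equal means give
#' `t = 0, p = 1`; unequal means give an infinite t with the p value floored
#' at the smallest positive double.
#'
#' @param x A `meth_data` object with at least 2 cases and 2 controls.
#' @param var_equal Use the pooled-variance (Student) test instead of Welch
#'   (default `FALSE`).
#' @return Data.frame: `name`, `chrom`, `pos`, `n_case`, `n_control`,
#'   `mean_case`, `mean_control`, `t_stat`, `df`, `p_value`.
#' @export
locus_ttest <- function(x, var_equal = FALSE) {
  stopifnot(inherits(x, "meth_data"))
  st <- x$statuses
  if (sum(st == 1L) < 2L || sum(st == 0L) < 2L)
    stop("the t test requires at least 2 cases and 2 controls")
  grp <- function(idx) {
    bb <- x$betas[, idx, drop = FALSE]
    V <- !is.na(bb)
    bb[!V] <- 0
    n <- rowSums(V)
    s1 <- rowSums(bb)
    s2 <- rowSums(bb^2)
    m <- ifelse(n > 0, s1 / n, NA_real_)
    v <- ifelse(n > 1, pmax(0, (s2 - n * m^2) / (n - 1)), NA_real_)
    list(n = n, m = m, v = v)
  }
  g1 <- grp(which(st == 1L))
  g0 <- grp(which(st == 0L))
  ok <- g1$n >= 2L & g0$n >= 2L
  t_stat <- df <- p <- rep(NA_real_, nrow(x$betas))
  if (any(ok)) {
    n1 <- g1$n[ok]; n0 <- g0$n[ok]
    m1 <- g1$m[ok]; m0 <- g0$m[ok]
    v1 <- g1$v[ok]; v0 <- g0$v[ok]
    if (var_equal) {
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      se2 <- sp2 * (1 / n1 + 1 / n0)
      dfe <- n1 + n0 - 2
    } else {
      se2 <- v1 / n1 + v0 / n0
      dfe <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
    }
    tt <- (m1 - m0) / sqrt(se2)
    pp <- 2 * stats::pt(-abs(tt), dfe)
    degen <- se2 == 0
    if (any(degen)) {
      same <- degen & m1 == m0
      diff_ <- degen & m1 != m0
      tt[same] <- 0; pp[same] <- 1
      dfe[same] <- n1[same] + n0[same] - 2
      tt[diff_] <- sign(m1[diff_] - m0[diff_]) * Inf
      pp[diff_] <- .Machine$double.xmin
      dfe[diff_] <- NA_real_
    }
    t_stat[ok] <- tt; df[ok] <- dfe; p[ok] <- pp
  }
  if (any(!ok))
    warning(sum(!ok), " locus/loci skipped: fewer than 2 case or 2 control values")
  data.frame(name = x$loci$name, chrom = x$loci$chrom, pos = x$loci$pos,
             n_case = g1$n, n_control = g0$n,
             mean_case = g1$m, mean_control = g0$m,
             t_stat = t_stat, df = df, p_value = p,
             stringsAsFactors = FALSE)
}
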