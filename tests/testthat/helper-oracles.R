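`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a meth_levels object directly from a loci x samples level matrix
# (1 = H, 0 = L, NA = missing).
make_levels <- function(mat, chrom = "1", pos = NULL, statuses = NULL,
                        threshold = 0.5) {
  mat <- rbind(mat)
  L <- nrow(mat)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(statuses)) statuses <- rep(-1L, ncol(mat))
  if (length(chrom) == 1L) chrom <- rep(chrom, L)
  structure(list(statuses = as.integer(statuses),
                 loci = data.frame(name = sprintf("cg%03d", seq_len(L)),
                                   chrom = chrom, pos = as.integer(pos),
                                   stringsAsFactors = FALSE),
                 levels = matrix(as.integer(mat), L, ncol(mat)),
                 threshold = threshold),
            class = "meth_levels")
}

# Construct a meth_data object from a loci x samples beta matrix.
make_meth <- function(betas, chrom = "1", pos = NULL, statuses = NULL,
                      sorted = FALSE) {
  betas <- rbind(betas)
  L <- nrow(betas)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(statuses)) statuses <- rep(-1L, ncol(betas))
  if (length(chrom) == 1L) chrom <- rep(chrom, L)
  structure(list(statuses = as.integer(statuses),
                 loci = data.frame(name = sprintf("cg%03d", seq_len(L)),
                                   chrom = chrom, pos = as.integer(pos),
                                   stringsAsFactors = FALSE),
                 betas = betas, sorted = sorted),
            class = "meth_data")
}

# Brute-force per-sample tally of two-locus level combinations.
oracle_pair_counts <- function(lv, i, j) {
  out <- c(n_hh = 0L, n_hl = 0L, n_lh = 0L, n_ll = 0L)
  for (s in seq_len(ncol(lv))) {
    a <- lv[i, s]; b <- lv[j, s]
    if (is.na(a) || is.na(b)) next
    key <- paste0(if (a == 1L) "h" else "l", if (b == 1L) "h" else "l")
    slot <- paste0("n_", key)
    out[slot] <- out[slot] + 1L
  }
  out
}

# Direct evaluation of the frequency definitions of gd, gD' and gr2.
oracle_md <- function(counts) {
  n <- sum(counts)
  p_hh <- counts[["n_hh"]] / n
  p_h1 <- (counts[["n_hh"]] + counts[["n_hl"]]) / n
  p_h2 <- (counts[["n_hh"]] + counts[["n_lh"]]) / n
  gd <- p_hh - p_h1 * p_h2
  if (p_h1 %in% c(0, 1) || p_h2 %in% c(0, 1))
    return(list(gd = 0, gdprime = NA_real_, gr2 = NA_real_))
  gd_max <- if (gd >= 0) min(p_h1 * (1 - p_h2), (1 - p_h1) * p_h2)
            else min(p_h1 * p_h2, (1 - p_h1) * (1 - p_h2))
  gdp <- if (gd == 0) 0 else abs(gd) / gd_max
  gr2 <- gd^2 / (p_h1 * (1 - p_h1) * p_h2 * (1 - p_h2))
  list(gd = gd, gdprime = min(1, max(0, gdp)), gr2 = min(1, max(0, gr2)))
}

# Brute-force per-sample methylecomtype tally over complete samples.
oracle_comtype <- function(lv, loci) {
  pats <- character(0)
  for (s in seq_len(ncol(lv))) {
    v <- lv[loci, s]
    if (anyNA(v)) next
    pats <- c(pats, paste(ifelse(v == 1L, "H", "L"), collapse = ""))
  }
  if (!length(pats))
    return(data.frame(pattern = character(), count = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  tab <- table(pats)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern, method = "radix"), , drop = FALSE]
  out$frequency <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

# Random level matrix with optional missingness.
random_levels <- function(n_loci, n_samp, p_na = 0.05) {
  m <- matrix(sample(c(0L, 1L), n_loci * n_samp, replace = TRUE),
              n_loci, n_samp)
  if (p_na > 0) m[runif(length(m)) < p_na] <- NA_integer_
  m
}

# Two-pattern block generator: D' = w between every pair, marginals from freq.
concordant_block <- function(n_loci, n_samp, p_high = 0.5, w = 1) {
  pat <- rbinom(n_samp, 1L, p_high)
  m <- matrix(rep(pat, each = n_loci), n_loci, n_samp)
  if (w < 1) {
    indep <- runif(n_samp) > w
    m[, indep] <- matrix(rbinom(n_loci * sum(indep), 1L, p_high),
                         n_loci, sum(indep))
  }
  m
}
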