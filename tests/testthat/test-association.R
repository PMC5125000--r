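# Build a meth_levels object with one committed block and the given per-sample
# block patterns, so association tables are fully controlled.
assoc_fixture <- function(case_pat, ctrl_pat) {
  k <- nchar(case_pat[1])
  to_lv <- function(p) as.integer(strsplit(p, "")[[1]] == "H")
  lv <- vapply(c(case_pat, ctrl_pat), to_lv, integer(k))
  bm <- make_levels(matrix(lv, k),
                    statuses = rep(c(1L, 0L), c(length(case_pat),
                                                length(ctrl_pat))))
  blocks <- structure(list(
    blocks = data.frame(name = "block_1_1", chrom = "1", start = 1000L,
                        end = 1000L * k, n_loci = k,
                        loci = paste(sprintf("cg%03d", seq_len(k)),
                                     collapse = ","),
                        stringsAsFactors = FALSE),
    members = list(seq_len(k)),
    comtypes = list(comtype_table(bm, seq_len(k))),
    params = list()), class = "md_blocks")
  list(bm = bm, blocks = blocks)
}

test_that("chi-square, p and OR match the closed forms on a 30/10 table", {
  fx <- assoc_fixture(c(rep("HH", 30), rep("LL", 10)),
                      c(rep("HH", 10), rep("LL", 30)))
  res <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0)
  hh <- res[res$pattern == "HH", ]
  expect_equal(hh$chi2, 20)
  expect_equal(hh$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(hh$odds_ratio, 9)
  # independent cross-check against the standard contingency-table test
  ct <- suppressWarnings(chisq.test(matrix(c(30, 10, 10, 30), 2),
                                    correct = FALSE))
  expect_equal(hh$chi2, unname(ct$statistic))
  expect_equal(hh$p_value, ct$p.value)
})

test_that("equal case/control distributions give chi2 = 0, p = 1, OR = 1", {
  fx <- assoc_fixture(c(rep("HL", 20), rep("LH", 20)),
                      c(rep("HL", 20), rep("LH", 20)))
  res <- comtype_test(fx$bm, fx$blocks)
  expect_equal(res$chi2, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_equal(res$odds_ratio, c(1, 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  fx <- assoc_fixture(rep("HH", 5), rep("LL", 5))
  res <- comtype_test(fx$bm, fx$blocks)
  hh <- res[res$pattern == "HH", ]
  expect_equal(hh$odds_ratio, (5.5 * 5.5) / (0.5 * 0.5))  # 121
  expect_true(is.finite(hh$or_ci_low) && is.finite(hh$or_ci_high))
  expect_true(hh$or_ci_low <= hh$odds_ratio &&
                hh$odds_ratio <= hh$or_ci_high)
})

test_that("swapping case and control labels inverts OR and preserves chi2/p", {
  set.seed(41)
  case_pat <- sample(c("HH", "HL", "LL"), 60, TRUE, prob = c(0.5, 0.2, 0.3))
  ctrl_pat <- sample(c("HH", "HL", "LL"), 50, TRUE, prob = c(0.3, 0.3, 0.4))
  fx <- assoc_fixture(case_pat, ctrl_pat)
  res <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0)
  fx2 <- assoc_fixture(ctrl_pat, case_pat)
  res2 <- comtype_test(fx2$bm, fx2$blocks, min_comtype_freq = 0)
  res2 <- res2[match(res$pattern, res2$pattern), ]
  expect_equal(res2$chi2, res$chi2)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$odds_ratio, 1 / res$odds_ratio)
})

test_that("the OR confidence interval brackets the estimate and tracks p at 0.05", {
  set.seed(42)
  for (rep in 1:40) {
    n <- 400
    case_pat <- ifelse(rbinom(n, 1, runif(1, 0.2, 0.6)) == 1, "HH", "LL")
    ctrl_pat <- ifelse(rbinom(n, 1, runif(1, 0.2, 0.6)) == 1, "HH", "LL")
    fx <- assoc_fixture(case_pat, ctrl_pat)
    res <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0)
    expect_true(all(res$or_ci_low <= res$odds_ratio &
                      res$odds_ratio <= res$or_ci_high))
    # asymptotically the Wald CI excludes 1 iff the chi2 p is below 0.05
    excl <- res$or_ci_low > 1 | res$or_ci_high < 1
    sig <- res$p_value < 0.05
    clear <- abs(res$p_value - 0.05) > 0.02
    expect_equal(excl[clear], sig[clear])
  }
})

test_that("rare patterns fall below the frequency floor and statuses gate the test", {
  fx <- assoc_fixture(c(rep("HH", 99), "HL"), rep("LL", 100))
  res <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0.01)
  expect_false("HL" %in% res$pattern)  # frequency 1/200 < 0.01
  res0 <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0)
  expect_true("HL" %in% res0$pattern)
  # unknown-status samples never enter the tables
  fx$bm$statuses[1] <- -1L
  res1 <- comtype_test(fx$bm, fx$blocks, min_comtype_freq = 0)
  expect_equal(sum(res1$case_count), 99)
  # no cases at all -> error
  fx$bm$statuses <- rep(0L, length(fx$bm$statuses))
  expect_error(comtype_test(fx$bm, fx$blocks), "case")
})

test_that("adjusted p columns are added on request", {
  fx <- assoc_fixture(c(rep("HH", 30), rep("LL", 10)),
                      c(rep("HH", 10), rep("LL", 30)))
  res <- comtype_test(fx$bm, fx$blocks, adjust = "bonferroni")
  expect_equal(res$p_adjusted, pmin(1, res$p_value * nrow(res)))
  resbh <- comtype_test(fx$bm, fx$blocks, adjust = "BH")
  expect_equal(resbh$p_adjusted, p.adjust(resbh$p_value, "BH"))
})

test_that("the per-locus Welch t matches stats::t.test locus by locus", {
  set.seed(43)
  x <- make_meth(matrix(runif(8 * 30), 8, 30),
                 statuses = rep(c(1L, 0L), c(14, 16)), sorted = TRUE)
  x$betas[3, c(2, 20)] <- NA
  tt <- locus_ttest(x)
  for (r in seq_len(8)) {
    ref <- t.test(x$betas[r, x$statuses == 1L], x$betas[r, x$statuses == 0L])
    expect_equal(tt$t_stat[r], unname(ref$statistic))
    expect_equal(tt$df[r], unname(ref$parameter))
    expect_equal(tt$p_value[r], ref$p.value)
  }
  # pooled variant matches var.equal = TRUE
  tp <- locus_ttest(x, var_equal = TRUE)
  refp <- t.test(x$betas[1, x$statuses == 1L], x$betas[1, x$statuses == 0L],
                 var.equal = TRUE)
  expect_equal(tp$t_stat[1], unname(refp$statistic))
  expect_equal(tp$p_value[1], refp$p.value)
})

test_that("degenerate t-test inputs follow the documented conventions", {
  x <- make_meth(rbind(rep(0.5, 8),
                       c(rep(0.9, 4), rep(0.1, 4))),
                 statuses = rep(c(1L, 0L), each = 4), sorted = TRUE)
  tt <- locus_ttest(x)
  expect_equal(tt$t_stat[1], 0)
  expect_equal(tt$p_value[1], 1)
  expect_equal(tt$t_stat[2], Inf)
  expect_equal(tt$p_value[2], .Machine$double.xmin)
  # insufficient group sizes: locus skipped with a warning
  x$betas[1, x$statuses == 1L] <- c(0.5, NA, NA, NA)
  expect_warning(t2 <- locus_ttest(x), "skipped")
  expect_true(is.na(t2$t_stat[1]))
})

test_that("t-test rejection rate under a mean shift matches its Monte-Carlo power", {
  set.seed(44)
  n <- 1000
  reps <- 300
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    x <- make_meth(rbind(pmin(1, pmax(0, c(rnorm(n, 0.55, 0.05),
                                           rnorm(n, 0.5, 0.05))))),
                   statuses = rep(c(1L, 0L), each = n), sorted = TRUE)
    rej[r] <- locus_ttest(x)$p_value[1] < 0.05
  }
  # delta/sigma = 1 at n = 1000 per arm: power is essentially 1
  expect_gte(mean(rej), 0.99)
})
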