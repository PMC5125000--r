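pipeline_spec <- function(seed = 71, n = 100) {
  synth_spec(
    n_case = n, n_control = n,
    chromosomes = list(list(label = "1", n_loci = 50, start_pos = 1e6,
                            spacing_bp = 2000)),
    blocks = list(list(chrom = "1", first_locus = 10, n_loci = 5,
                       within_dprime = 1,
                       pattern_freqs = stats::setNames(c(0.3, 0.7),
                                                       c("HHHHH", "LLLLL")))),
    effects = list(list(block = 1, risk_pattern = "HHHHH", odds_ratio = 3)),
    seed = seed)
}

test_that("the five-step pipeline finds the planted block and its risk pattern", {
  sim <- simulate_methylation(pipeline_spec())
  f <- withr::local_tempfile()
  write_betas(sim$data, f)
  prefix <- file.path(withr::local_tempdir(), "run")
  fit <- ewas(f, out_prefix = prefix)
  expect_s3_class(fit, "ewas")
  expect_equal(fit$n_case, 100L)
  expect_equal(nrow(fit$blocks$blocks), 1L)
  expect_equal(fit$blocks$blocks$start, sim$truth$blocks[[1]]$start)
  expect_equal(fit$blocks$blocks$end, sim$truth$blocks[[1]]$end)
  risk <- fit$associations[fit$associations$pattern == "HHHHH", ]
  expect_equal(nrow(risk), 1L)
  expect_gt(risk$odds_ratio, 1)
  expect_lt(risk$p_value, 0.05)
  # output files: sorted intermediate + blocks + associations
  expect_true(file.exists(file.path(dirname(prefix), "out_sort.txt")))
  expect_true(file.exists(paste0(prefix, "_blocks.tsv")))
  expect_true(file.exists(paste0(prefix, "_assoc.tsv")))
  at <- read.delim(paste0(prefix, "_assoc.tsv"))
  expect_equal(sort(at$pattern), sort(fit$associations$pattern))
})

test_that("all-unknown statuses downgrade to block-only mode", {
  sim <- simulate_methylation(pipeline_spec(seed = 72))
  sim$data$statuses[] <- -1L
  expect_message(fit <- ewas(sim$data), "block-only")
  expect_null(fit$associations)
  expect_equal(nrow(fit$blocks$blocks), 1L)
  # statuses present but one class missing -> explicit error
  sim$data$statuses[] <- 1L
  expect_error(ewas(sim$data), "no controls")
})

test_that("reruns on the same input are byte-identical", {
  sim <- simulate_methylation(pipeline_spec(seed = 73))
  f <- withr::local_tempfile()
  write_betas(sim$data, f)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ewas(f, out_prefix = file.path(d1, "r"))
  ewas(f, out_prefix = file.path(d2, "r"))
  for (suffix in c("r_blocks.tsv", "r_assoc.tsv", "out_sort.txt"))
    expect_identical(readLines(file.path(d1, suffix)),
                     readLines(file.path(d2, suffix)))
})

test_that("print, summary and plot methods run on a fitted scan", {
  sim <- simulate_methylation(pipeline_spec(seed = 74))
  fit <- ewas(sim$data)
  expect_output(print(fit), "Methylecomtype association scan")
  expect_output(print(fit), "MD blocks: 1")
  s <- summary(fit)
  expect_s3_class(s, "summary.ewas")
  expect_output(print(s), "Top associations")
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_invisible(plot(fit))
})

cli_path <- function() {
  p <- system.file("exec", "ewas.R", package = "mdewas")
  if (!nzchar(p)) p <- file.path(system.file(package = "mdewas"),
                                 "exec", "ewas.R")
  if (!file.exists(p)) p <- testthat::test_path("..", "..", "exec", "ewas.R")
  normalizePath(p)
}

run_cli <- function(...) {
  args <- c(cli_path(), ...)
  out <- suppressWarnings(system2("Rscript", shQuote(args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

test_that("the command-line interface runs every subcommand on the shipped example", {
  skip_if(!nzchar(Sys.which("Rscript")), "Rscript not on PATH")
  input <- system.file("extdata", "example_small.txt", package = "mdewas")
  if (!nzchar(input))
    input <- testthat::test_path("..", "..", "inst", "extdata",
                                 "example_small.txt")
  d <- withr::local_tempdir()

  r <- run_cli("coefficient", "--input", input,
               "--out-prefix", file.path(d, "c"))
  expect_equal(r$status, 0L)
  co <- read.delim(file.path(d, "c_coefficients.tsv"))
  expect_equal(nrow(co), choose(8, 2) + choose(4, 2))
  expect_true(all(co$gdprime >= 0 & co$gdprime <= 1, na.rm = TRUE))

  r <- run_cli("-ewas", "--input", input, "--out-prefix", file.path(d, "e"),
               "--bed")
  expect_equal(r$status, 0L)
  expect_true(file.exists(file.path(d, "e_blocks.tsv")))
  expect_true(file.exists(file.path(d, "e_assoc.tsv")))
  expect_true(file.exists(file.path(d, "e_blocks.bed")))
  expect_true(file.exists(file.path(d, "out_sort.txt")))

  r <- run_cli("block", "--input", input, "--out-prefix", file.path(d, "b"))
  expect_equal(r$status, 0L)
  expect_false(file.exists(file.path(d, "b_assoc.tsv")))

  r <- run_cli("ttest", "--input", input, "--out-prefix", file.path(d, "t"))
  expect_equal(r$status, 0L)
  tt <- read.delim(file.path(d, "t_ttest.tsv"))
  expect_equal(nrow(tt), 12L)

  # usage errors exit non-zero
  expect_gt(run_cli("ewas")$status, 0L)
  expect_gt(run_cli("frobnicate", "--input", input)$status, 0L)
  expect_gt(run_cli("ewas", "--input", file.path(d, "missing.txt"))$status, 0L)
})

test_that("CLI coefficient output agrees with md_pairs on the same data", {
  skip_if(!nzchar(Sys.which("Rscript")), "Rscript not on PATH")
  input <- system.file("extdata", "example_small.txt", package = "mdewas")
  if (!nzchar(input))
    input <- testthat::test_path("..", "..", "inst", "extdata",
                                 "example_small.txt")
  d <- withr::local_tempdir()
  r <- run_cli("coefficient", "--input", input,
               "--out-prefix", file.path(d, "c"))
  expect_equal(r$status, 0L)
  co <- read.delim(file.path(d, "c_coefficients.tsv"))
  bm <- binarize(sort_loci(read_betas(input)))
  pw <- md_pairs(bm)
  m <- merge(co, pw, by = c("locus1", "locus2"))
  expect_equal(nrow(m), nrow(co))
  expect_equal(m$gdprime.x, m$gdprime.y, tolerance = 1e-9)
  expect_equal(m$gr2.x, m$gr2.y, tolerance = 1e-9)
})
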