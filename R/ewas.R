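#' Epigenome-wide methylecomtype association scan
#'
#' Runs the full five-step pipeline on a beta-value dataset: (1) sort loci by
#' chromosome and position; (2) binarize beta values into H/L levels at
#' `threshold`; (3) scan each chromosome with the elastic sliding window and
#' identify MD blocks by the Gabriel rule; (4) tabulate methylecomtype
#' frequencies per block; (5) chi-square test each methylecomtype for
#' case/control association with odds ratios and confidence intervals.
#'
#' When every sample status is unknown (-1), the run downgrades to block-only
#' mode with a message; with statuses present but no cases or no controls, an
#' error is raised. The analysis path contains no randomness: repeated runs on
#' the same input are identical.
#'
#' @param input Path to an EWAS-dialect input file, or a `meth_data` object.
#' @param threshold Binarization threshold `T` in (0, 1) (default 0.5).
#' @param window Sliding-window size in loci (default 20).
#' @param elastic_factor One-shot window enlargement factor (default 2).
#' @param strong_fraction Gabriel strong-MD fraction (default 0.95).
#' @param f_min Minor-level frequency floor (default 0.05).
#' @param min_comtype_freq Minimum overall pattern frequency for association
#'   testing (default 0.01).
#' @param max_gap Optional maximum base-pair gap between adjacent block loci.
#' @param adjust Multiple-testing adjustment column: `"none"`, `"bonferroni"`
#'   or `"BH"`.
#' @param level,step Confidence-bound settings for the gD' grid.
#' @param out_prefix When non-`NULL`, result files are written:
#'   `<prefix>_blocks.tsv`, `<prefix>_assoc.tsv` and the sorted intermediate
#'   `out_sort.txt` (with level strings) next to the prefix.
#' @param sep Input field separator passed to [read_betas()].
#' @return An object of class `ewas`: list with the run configuration, sample
#'   and locus counts, `blocks` (an `md_blocks` object), `associations` (a
#'   `comtype_assoc` data.frame or `NULL` in block-only mode) and the paths of
#'   any files written.
#' @examples
#' spec <- synth_spec(n_case = 60, n_control = 60,
#'   chromosomes = list(list(label = "1", n_loci = 40, start_pos = 1e6,
#'                           spacing_bp = 2000)),
#'   blocks = list(list(chrom = "1", first_locus = 10, n_loci = 5,
#'                      within_dprime = 1,
#'                      pattern_freqs = c(HHHHH = 0.4, LLLLL = 0.6))),
#'   seed = 7)
#' sim <- simulate_methylation(spec)
#' fit <- ewas(sim$data)
#' fit
#' @export
ewas <- function(input, threshold = 0.5, window = 20L, elastic_factor = 2L,
                 strong_fraction = 0.95, f_min = 0.05,
                 min_comtype_freq = 0.01, max_gap = NULL,
                 adjust = c("none", "bonferroni", "BH"), level = 0.95,
                 step = 0.01, out_prefix = NULL, sep = "auto") {
  adjust <- match.arg(adjust)
  cl <- match.call()
  x <- if (inherits(input, "meth_data")) input else read_betas(input, sep = sep)
  x <- sort_loci(x)
  files <- character(0)
  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    sorted_path <- file.path(dirname(out_prefix), "out_sort.txt")
    write_sorted(x, sorted_path, threshold = threshold)
    files <- c(sorted = sorted_path)
  }
  bm <- binarize(x, threshold)
  blocks <- md_blocks(bm, window = window, elastic_factor = elastic_factor,
                      strong_fraction = strong_fraction, f_min = f_min,
                      level = level, step = step, max_gap = max_gap)
  st <- x$statuses
  assoc <- NULL
  if (all(st == -1L)) {
    message("all sample statuses are unknown (-1): association step skipped, ",
            "block-only output produced")
  } else if (!any(st == 1L) || !any(st == 0L)) {
    stop("association requested but the data contain ",
         if (any(st == 1L)) "no controls" else "no cases",
         "; set all statuses to -1 for block-only analysis")
  } else {
    assoc <- comtype_test(bm, blocks, min_comtype_freq = min_comtype_freq,
                          adjust = adjust)
  }
  if (!is.null(out_prefix)) {
    bpath <- paste0(out_prefix, "_blocks.tsv")
    write_blocks_tsv(blocks, bpath)
    files <- c(files, blocks = bpath)
    if (!is.null(assoc)) {
      apath <- paste0(out_prefix, "_assoc.tsv")
      write_assoc_tsv(assoc, apath)
      files <- c(files, assoc = apath)
    }
  }
  structure(list(call = cl, n_samples = length(st),
                 n_case = sum(st == 1L), n_control = sum(st == 0L),
                 n_unknown = sum(st == -1L), n_loci = nrow(x$loci),
                 threshold = threshold, window = window,
                 elastic_factor = elastic_factor,
                 strong_fraction = strong_fraction,
                 blocks = blocks, associations = assoc, files = files),
            class = "ewas")
}

#' @export
print.ewas <- function(x, ...) {
  cat("Methylecomtype association scan\n")
  cat(sprintf("  samples: %d (%d case / %d control / %d unknown)\n",
              x$n_samples, x$n_case, x$n_control, x$n_unknown))
  cat(sprintf("  loci: %d; threshold T = %g; window = %d (elastic x%d)\n",
              x$n_loci, x$threshold, x$window, x$elastic_factor))
  cat(sprintf("  MD blocks: %d\n", nrow(x$blocks$blocks)))
  if (is.null(x$associations)) {
    cat("  association: skipped (block-only mode)\n")
  } else {
    a <- x$associations
    cat(sprintf("  methylecomtype tests: %d\n", nrow(a)))
    if (nrow(a)) {
      top <- a[order(a$p_value), , drop = FALSE][seq_len(min(5L, nrow(a))), ]
      cat("  strongest associations:\n")
      print(data.frame(block = top$block, pattern = top$pattern,
                       chi2 = round(top$chi2, 2),
                       p_value = signif(top$p_value, 3),
                       OR = round(top$odds_ratio, 2), row.names = NULL))
    }
  }
  invisible(x)
}

#' @export
summary.ewas <- function(object, n_top = 10L, ...) {
  a <- object$associations
  top <- NULL
  if (!is.null(a) && nrow(a))
    top <- a[order(a$p_value), , drop = FALSE][seq_len(min(n_top, nrow(a))), ]
  structure(list(fit = object, top = top), class = "summary.ewas")
}

#' @export
print.summary.ewas <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$top)) {
    cat("\nTop associations (full rows):\n")
    print(x$top[, c("block", "pattern", "case_freq", "control_freq",
                    "chi2", "p_value", "odds_ratio", "or_ci_low",
                    "or_ci_high")], row.names = FALSE)
  }
  invisible(x)
}

#' Plot an EWAS scan result
#'
#' With association results, draws -log10(p) of each methylecomtype test
#' against its block start position, one panel colour per chromosome, with the
#' 0.05 level marked. In block-only mode, draws a histogram of block sizes.
#'
#' @param x An `ewas` object.
#' @param ... Passed to the underlying base-graphics call.
#' @return `x`, invisibly.
#' @export
plot.ewas <- function(x, ...) {
  a <- x$associations
  if (!is.null(a) && nrow(a)) {
    chf <- factor(a$chrom, levels = unique(a$chrom[order(chrom_rank(a$chrom))]))
    graphics::plot(a$start, -log10(a$p_value), col = as.integer(chf),
                   pch = 16, xlab = "block start position",
                   ylab = expression(-log[10](p)),
                   main = "methylecomtype association scan", ...)
    graphics::abline(h = -log10(0.05), lty = 2)
  } else {
    sizes <- x$blocks$blocks$n_loci
    if (!length(sizes)) {
      graphics::plot.new()
      graphics::title("no MD blocks found")
    } else {
      graphics::hist(sizes, breaks = seq(1.5, max(sizes) + 0.5),
                     xlab = "loci per block", main = "MD block sizes", ...)
    }
  }
  invisible(x)
}
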