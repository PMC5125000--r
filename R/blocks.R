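# Candidate-block search within one index range, given a per-lag
# classification list (cls[[d]][i] classifies pair (i, i+d); 1 = strong MD,
# 2 = strong recombination, 0 = uninformative) and per-lag prefix sums.
find_blocks_range <- function(cls, cumS, cumI, a0, b0, strong_fraction,
                              pos = NULL, max_gap = NULL) {
  if (b0 - a0 < 1L) return(data.frame(a = integer(), b = integer()))
  ca <- integer(0); cb <- integer(0)
  for (d in seq_len(b0 - a0)) {
    ii <- which(cls[[d]][a0:(b0 - d)] == 1L)
    if (length(ii)) {
      ca <- c(ca, a0 + ii - 1L)
      cb <- c(cb, a0 + ii - 1L + d)
    }
  }
  if (!length(ca)) return(data.frame(a = integer(), b = integer()))
  keep <- logical(length(ca))
  for (k in seq_along(ca)) {
    a <- ca[k]; b <- cb[k]
    S <- 0; I <- 0
    for (d in seq_len(b - a)) {
      S <- S + cumS[[d]][b - d + 1L] - cumS[[d]][a]
      I <- I + cumI[[d]][b - d + 1L] - cumI[[d]][a]
    }
    keep[k] <- I > 0 && S / I >= strong_fraction - 1e-12
    if (keep[k] && !is.null(max_gap) && b > a)
      keep[k] <- max(diff(pos[a:b])) <= max_gap
  }
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) return(data.frame(a = integer(), b = integer()))
  # longest candidate first, ties to the leftmost start; greedy non-overlap
  o <- order(-(cb - ca), ca)
  ca <- ca[o]; cb <- cb[o]
  sel_a <- integer(0); sel_b <- integer(0)
  occ <- rep(FALSE, b0)
  for (k in seq_along(ca)) {
    if (!any(occ[ca[k]:cb[k]])) {
      occ[ca[k]:cb[k]] <- TRUE
      sel_a <- c(sel_a, ca[k]); sel_b <- c(sel_b, cb[k])
    }
  }
  o2 <- order(sel_a)
  data.frame(a = sel_a[o2], b = sel_b[o2])
}

prefix_sums <- function(cls) {
  lapply(cls, function(v) c(0, cumsum(v == 1L)))
}

prefix_sums_inf <- function(cls) {
  lapply(cls, function(v) c(0, cumsum(v != 0L)))
}

#' MD blocks inside one window of loci
#'
#' Applies the Gabriel rule to the contiguous locus range `[first, last]`
#' (indices into the sorted loci of `x`, all on one chromosome): a candidate
#' block `[a, b]` must have a strong-MD outermost pair and a strong-MD
#' fraction of at least `strong_fraction` among its informative pairs.
#' Overlapping candidates are resolved longest-first, ties to the leftmost
#' start.
#'
#' @param x A `meth_levels` object.
#' @param first,last Index range (inclusive) of contiguous sorted loci on one
#'   chromosome.
#' @param strong_fraction Minimum strong-MD fraction among informative pairs
#'   (default 0.95).
#' @param f_min,level,step,strong_low,strong_high,recomb_high See [md_pairs()].
#' @param max_gap Optional maximum base-pair gap between adjacent block loci.
#' @return Data.frame with columns `first`, `last`: locus index bounds of each
#'   accepted block (empty when none).
#' @export
window_blocks <- function(x, first, last, strong_fraction = 0.95,
                          f_min = 0.05, level = 0.95, step = 0.01,
                          strong_low = 0.70, strong_high = 0.98,
                          recomb_high = 0.90, max_gap = NULL) {
  stopifnot(inherits(x, "meth_levels"), first >= 1L, last <= nrow(x$levels),
            first < last)
  ch <- unique(x$loci$chrom[first:last])
  if (length(ch) != 1L) stop("window spans more than one chromosome")
  lv <- x$levels[first:last, , drop = FALSE]
  L <- nrow(lv)
  eng <- chrom_pair_engine(lv, L - 1L, f_min = f_min, level = level,
                           step = step, strong_low = strong_low,
                           strong_high = strong_high,
                           recomb_high = recomb_high)
  bl <- find_blocks_range(eng$cls, prefix_sums(eng$cls),
                          prefix_sums_inf(eng$cls), 1L, L, strong_fraction,
                          pos = x$loci$pos[first:last], max_gap = max_gap)
  data.frame(first = bl$a + first - 1L, last = bl$b + first - 1L)
}

#' Genome scan for MD blocks with an elastic sliding window
#'
#' Each chromosome is scanned left to right with a window of `window` loci.
#' Candidate blocks inside the window are found with the Gabriel rule (see
#' [window_blocks()]). When a detected block reaches the window's last locus,
#' the window is re-run once at `elastic_factor * window` loci from the same
#' start, so real blocks larger than the window are not truncated. Committed
#' blocks are non-overlapping; after committing, the scan resumes at the locus
#' following the last committed block, otherwise it slides by one locus.
#' Windows never span chromosome boundaries.
#'
#' @param x A `meth_levels` object (sorted; produced by [binarize()]).
#' @param window Sliding-window size in loci (default 20).
#' @param elastic_factor Window enlargement factor applied once when a block
#'   touches the window end (default 2; 1 disables the extension).
#' @param strong_fraction Minimum strong-MD fraction among informative pairs
#'   (default 0.95).
#' @param f_min Minor-level frequency floor for informative loci (default
#'   0.05).
#' @param level,step Confidence-bound settings for [dprime_ci()].
#' @param strong_low,strong_high,recomb_high Thresholds for [classify_md()].
#' @param max_gap Optional maximum base-pair gap between adjacent loci of a
#'   block (`NULL` = not enforced).
#' @return An `md_blocks` object: list with `blocks` (data.frame: `name`,
#'   `chrom`, `start`, `end`, `n_loci`, `loci`), `members` (list of locus
#'   index vectors into `x`), `comtypes` (list of per-block methylecomtype
#'   tables from [comtype_table()]) and `params`.
#' @export
md_blocks <- function(x, window = 20L, elastic_factor = 2L,
                      strong_fraction = 0.95, f_min = 0.05, level = 0.95,
                      step = 0.01, strong_low = 0.70, strong_high = 0.98,
                      recomb_high = 0.90, max_gap = NULL) {
  stopifnot(inherits(x, "meth_levels"))
  if (window < 2L) stop("window must be at least 2 loci")
  if (elastic_factor < 1L) stop("elastic_factor must be >= 1")
  if (strong_fraction <= 0 || strong_fraction > 1)
    stop("strong_fraction must lie in (0, 1]")
  chroms <- unique(x$loci$chrom)
  members <- list()
  rows <- list()
  for (ch in chroms) {
    idx <- which(x$loci$chrom == ch)
    L <- length(idx)
    if (L < 2L) next
    max_lag <- min(elastic_factor * window - 1L, L - 1L)
    eng <- chrom_pair_engine(x$levels[idx, , drop = FALSE], max_lag,
                             f_min = f_min, level = level, step = step,
                             strong_low = strong_low,
                             strong_high = strong_high,
                             recomb_high = recomb_high)
    cumS <- prefix_sums(eng$cls)
    cumI <- prefix_sums_inf(eng$cls)
    pos <- x$loci$pos[idx]
    nb <- 0L
    s <- 1L
    while (s <= L - 1L) {
      e <- min(s + window - 1L, L)
      if (e - s < 1L) break
      bl <- find_blocks_range(eng$cls, cumS, cumI, s, e, strong_fraction,
                              pos = pos, max_gap = max_gap)
      e_eff <- e
      if (nrow(bl) && any(bl$b == e) && elastic_factor > 1L && e < L) {
        e2 <- min(s + elastic_factor * window - 1L, L)
        if (e2 > e) {
          bl <- find_blocks_range(eng$cls, cumS, cumI, s, e2, strong_fraction,
                                  pos = pos, max_gap = max_gap)
          e_eff <- e2
        }
      }
      # a block cut off by the window border would be truncated: defer it and
      # re-anchor the window at its first locus, unless it already starts
      # there (then one doubling is all the elasticity we grant)
      next_s <- NULL
      if (nrow(bl)) {
        last <- nrow(bl)
        if (bl$b[last] == e_eff && e_eff < L && bl$a[last] > s &&
            elastic_factor > 1L) {
          next_s <- bl$a[last]
          bl <- bl[-last, , drop = FALSE]
        }
      }
      if (nrow(bl) || !is.null(next_s)) {
        for (k in seq_len(nrow(bl))) {
          nb <- nb + 1L
          gi <- idx[bl$a[k]:bl$b[k]]
          members[[length(members) + 1L]] <- gi
          rows[[length(rows) + 1L]] <- data.frame(
            name = sprintf("block_%s_%d", ch, nb), chrom = ch,
            start = x$loci$pos[gi[1L]], end = x$loci$pos[gi[length(gi)]],
            n_loci = length(gi),
            loci = paste(x$loci$name[gi], collapse = ","),
            stringsAsFactors = FALSE)
        }
        s <- if (!is.null(next_s)) next_s else bl$b[nrow(bl)] + 1L
      } else {
        s <- s + 1L
      }
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), chrom = character(), start = integer(),
               end = integer(), n_loci = integer(), loci = character(),
               stringsAsFactors = FALSE)
  rownames(blocks) <- NULL
  comtypes <- lapply(members, function(gi) comtype_table(x, gi))
  structure(list(blocks = blocks, members = members, comtypes = comtypes,
                 params = list(window = window, elastic_factor = elastic_factor,
                               strong_fraction = strong_fraction,
                               f_min = f_min, level = level, step = step,
                               threshold = x$threshold, max_gap = max_gap)),
            class = "md_blocks")
}

#' @export
print.md_blocks <- function(x, ...) {
  b <- x$blocks
  cat(sprintf("md_blocks: %d block(s) (window = %d, elastic x%d, strong fraction %.2f)\n",
              nrow(b), x$params$window, x$params$elastic_factor,
              x$params$strong_fraction))
  if (nrow(b)) {
    sizes <- b$n_loci
    cat(sprintf("loci per block: min %d, median %g, max %d; chromosomes: %s\n",
                min(sizes), stats::median(sizes), max(sizes),
                paste(unique(b$chrom), collapse = ", ")))
    print(utils::head(b[, c("name", "chrom", "start", "end", "n_loci")], 10L))
    if (nrow(b) > 10L) cat("...", nrow(b) - 10L, "more\n")
  }
  invisible(x)
}

#' Methylecomtype table for a set of loci
#'
#' For every sample with a complete (non-missing) level at each of the given
#' loci, the H/L codes are concatenated in locus order into the sample's
#' methylecomtype pattern; with k loci there are at most `2^k` distinct
#' patterns. Counts are converted to frequencies over the counted samples.
#' Patterns are listed by descending count, ties broken lexicographically
#' (H before L).
#'
#' @param x A `meth_levels` object.
#' @param loci Locus indices (into the sorted loci) or locus names.
#' @param samples Optional sample index vector (default: all samples).
#' @return Data.frame with columns `pattern`, `count`, `frequency`. When no
#'   sample is complete, an empty table with a warning.
#' @export
comtype_table <- function(x, loci, samples = NULL) {
  stopifnot(inherits(x, "meth_levels"))
  if (is.character(loci)) loci <- match(loci, x$loci$name)
  stopifnot(!anyNA(loci), length(loci) >= 1L)
  lv <- x$levels[loci, , drop = FALSE]
  if (!is.null(samples)) lv <- lv[, samples, drop = FALSE]
  complete <- colSums(is.na(lv)) == 0L
  if (!any(complete)) {
    warning("no sample has complete levels across the given loci")
    return(data.frame(pattern = character(), count = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  lv <- lv[, complete, drop = FALSE]
  ch <- matrix(c("L", "H")[lv + 1L], nrow(lv), ncol(lv))
  pat <- do.call(paste0, as.data.frame(t(ch), stringsAsFactors = FALSE))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$pattern, method = "radix"), , drop = FALSE]
  out$frequency <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' Write MD blocks as a TSV table
#'
#' One row per (block, methylecomtype): block name, chromosome, start and end
#' position, member locus list, pattern and frequency.
#'
#' @param blocks An `md_blocks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  stopifnot(inherits(blocks, "md_blocks"))
  b <- blocks$blocks
  rows <- lapply(seq_len(nrow(b)), function(k) {
    ct <- blocks$comtypes[[k]]
    if (!nrow(ct))
      return(data.frame(block = b$name[k], chrom = b$chrom[k],
                        start = b$start[k], end = b$end[k], loci = b$loci[k],
                        comtype = NA_character_, count = NA_integer_,
                        frequency = NA_real_, stringsAsFactors = FALSE))
    data.frame(block = b$name[k], chrom = b$chrom[k], start = b$start[k],
               end = b$end[k], loci = b$loci[k], comtype = ct$pattern,
               count = ct$count, frequency = ct$frequency,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(block = character(), chrom = character(), start = integer(),
               end = integer(), loci = character(), comtype = character(),
               count = integer(), frequency = numeric(),
               stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Export MD blocks in BED format
#'
#' BED uses 0-based half-open coordinates: `bed_start = start - 1`,
#' `bed_end = end`, where `start`/`end` are the 1-based positions of the first
#' and last member locus.
#'
#' @param blocks An `md_blocks` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  stopifnot(inherits(blocks, "md_blocks"))
  b <- blocks$blocks
  out <- data.frame(chrom = b$chrom, start = b$start - 1L, end = b$end,
                    name = b$name, stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
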