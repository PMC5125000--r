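#' Read a beta-value matrix in the EWAS input dialect
#'
#' The input is a plain-text file whose first row lists one status code per
#' sample (`1` = case, `0` = control, `-1` = unknown) and whose remaining rows
#' each describe one CpG locus: locus name, chromosome, physical position, then
#' one beta value per sample. Beta values lie in `[0, 1]`; `NA` (or an empty
#' CSV field) marks a missing measurement. Fields are separated by whitespace
#' or, behind `sep = "csv"`, by commas.
#'
#' Sorted intermediate files written by [write_sorted()] may carry one extra
#' trailing column per locus row: the binarized level string (one `H`/`L`/`?`
#' character per sample). It is detected and dropped on read, so the sorted
#' file round-trips through this reader.
#'
#' @param path Path to the input file.
#' @param sep `"auto"` (default; comma vs whitespace detected from the first
#'   row), `"whitespace"`, or `"csv"`.
#' @return A `meth_data` object: a list with `statuses` (integer vector),
#'   `loci` (data.frame with `name`, `chrom`, `pos`), `betas` (numeric matrix,
#'   loci x samples) and `sorted` (logical).
#' @examples
#' f <- tempfile()
#' writeLines(c("1 0", "cgA 1 100 0.8 0.2", "cgB 1 200 0.1 0.9"), f)
#' x <- read_betas(f)
#' x$loci
#' @seealso [sort_loci()], [binarize()], [write_sorted()]
#' @export
read_betas <- function(path, sep = c("auto", "whitespace", "csv")) {
  sep <- match.arg(sep)
  if (!file.exists(path)) stop("input file not found: ", path)
  line1 <- readLines(path, n = 1L)
  if (length(line1) == 0L) stop("empty input file: ", path)
  if (sep == "auto") {
    sep <- if (grepl(",", line1) && !grepl("[ \t]", trimws(line1))) "csv" else "whitespace"
  }
  fsep <- if (sep == "csv") "," else ""
  toks <- if (sep == "csv") strsplit(trimws(line1), ",")[[1]] else
    strsplit(trimws(line1), "[ \t]+")[[1]]
  st <- suppressWarnings(as.integer(toks))
  if (anyNA(st) || any(st != toks | !(st %in% c(1L, 0L, -1L))))
    stop("sample statuses (first row) must be integers in {1, 0, -1}; got: ",
         paste(utils::head(toks[is.na(st) | !(st %in% c(1L, 0L, -1L))], 3L), collapse = ", "))
  n_samp <- length(st)

  nf <- utils::count.fields(path, sep = fsep, quote = "", comment.char = "")
  n_loci <- length(nf) - 1L
  if (n_loci == 0L) {
    return(new_meth_data(st,
                         data.frame(name = character(), chrom = character(),
                                    pos = integer(), stringsAsFactors = FALSE),
                         matrix(numeric(), 0L, n_samp)))
  }
  widths <- nf[-1L]
  has_levels <- FALSE
  if (widths[1L] == n_samp + 4L) {
    # a sorted intermediate file: the extra column must be a level string
    l2 <- readLines(path, n = 2L)[2L]
    toks2 <- if (sep == "csv") strsplit(trimws(l2), ",")[[1]] else
      strsplit(trimws(l2), "[ \t]+")[[1]]
    last <- toks2[length(toks2)]
    has_levels <- grepl("^[HL?]+$", last) && nchar(last) == n_samp
  }
  want <- n_samp + 3L + as.integer(has_levels)
  bad <- which(widths != want)
  if (length(bad))
    stop(sprintf("parse error at line %d: %d fields, expected %d (3 locus fields%s + %d samples)",
                 bad[1L] + 1L, widths[bad[1L]], want,
                 if (has_levels) " + level string" else "", n_samp))

  dsep <- if (sep == "csv") "," else detect_ws_sep(path)
  dt <- data.table::fread(path, skip = 1L, header = FALSE, sep = dsep,
                          colClasses = list(character = 1:2), na.strings = c("NA", ""),
                          strip.white = TRUE, data.table = TRUE, showProgress = FALSE)
  if (has_levels) {
    lvl <- as.character(dt[[ncol(dt)]])
    if (!all(grepl("^[HL?]+$", lvl) & nchar(lvl) == n_samp))
      stop("trailing column is neither a beta value column nor a valid level string")
    dt[[ncol(dt)]] <- NULL
  }
  name <- as.character(dt[[1L]])
  chrom <- as.character(dt[[2L]])
  pos <- suppressWarnings(as.integer(dt[[3L]]))
  if (anyNA(pos)) stop("non-integer physical position at data line ",
                       which(is.na(pos))[1L])
  bcols <- as.list(dt)[-(1:3)]
  for (k in seq_along(bcols)) {
    if (!is.numeric(bcols[[k]])) {
      raw <- as.character(bcols[[k]])
      num <- suppressWarnings(as.numeric(raw))
      badv <- !is.na(raw) & is.na(num)
      if (any(badv))
        stop("non-numeric beta value '", raw[which(badv)[1L]], "' in sample column ", k)
      bcols[[k]] <- num
    }
  }
  betas <- do.call(cbind, bcols)
  dimnames(betas) <- NULL
  if (any(betas < 0 | betas > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]; offending value: ",
         betas[which(betas < 0 | betas > 1)[1L]])
  new_meth_data(st, data.frame(name = name, chrom = chrom, pos = pos,
                               stringsAsFactors = FALSE), betas)
}

# fread needs a single-character sep; pick tab when the data lines use tabs
detect_ws_sep <- function(path) {
  l2 <- readLines(path, n = 2L)
  if (length(l2) >= 2L && grepl("\t", l2[2L])) "\t" else " "
}

new_meth_data <- function(statuses, loci, betas, sorted = FALSE) {
  stopifnot(nrow(loci) == nrow(betas), ncol(betas) == length(statuses))
  structure(list(statuses = as.integer(statuses), loci = loci,
                 betas = betas, sorted = isTRUE(sorted)),
            class = "meth_data")
}

#' @export
print.meth_data <- function(x, ...) {
  st <- x$statuses
  cat(sprintf("meth_data: %d loci x %d samples (%d case / %d control / %d unknown)%s\n",
              nrow(x$loci), length(st), sum(st == 1L), sum(st == 0L), sum(st == -1L),
              if (x$sorted) ", sorted" else ""))
  if (nrow(x$loci)) {
    cat(sprintf("chromosomes: %s\n", paste(unique(x$loci$chrom), collapse = ", ")))
  }
  invisible(x)
}

#' Rank chromosome labels for genomic sorting
#'
#' Numeric labels rank first in numeric order, then X, Y, MT (or M), then any
#' other labels lexicographically. A leading "chr" prefix is ignored for
#' ranking but preserved in the data.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Numeric rank vector (smaller = earlier).
#' @keywords internal
chrom_rank <- function(chrom) {
  key <- sub("^[Cc][Hh][Rr]", "", as.character(chrom))
  num <- suppressWarnings(as.numeric(key))
  r <- num
  up <- toupper(key)
  r[is.na(num) & up == "X"] <- 1e3
  r[is.na(num) & up == "Y"] <- 1e3 + 1
  r[is.na(num) & up %in% c("MT", "M")] <- 1e3 + 2
  oth <- is.na(r)
  if (any(oth)) {
    u <- sort(unique(key[oth]), method = "radix")
    r[oth] <- 2e3 + match(key[oth], u)
  }
  r
}

#' Sort loci by chromosome and physical position
#'
#' Stable sort on (chromosome rank, position): ties keep their input order.
#' Chromosome ranking is numeric 1..22, then X, Y, MT, then other labels
#' lexicographically (see [chrom_rank()]).
#'
#' @param x A `meth_data` object.
#' @return The same object with loci reordered and `sorted = TRUE`.
#' @export
sort_loci <- function(x) {
  stopifnot(inherits(x, "meth_data"))
  ord <- order(chrom_rank(x$loci$chrom), x$loci$pos, method = "radix")
  x$loci <- x$loci[ord, , drop = FALSE]
  rownames(x$loci) <- NULL
  x$betas <- x$betas[ord, , drop = FALSE]
  x$sorted <- TRUE
  x
}

#' Write a dataset in the EWAS input dialect
#'
#' Writes the status row followed by one row per locus. With `levels` supplied
#' (a character vector of per-locus `H`/`L`/`?` strings), each locus row gains
#' a trailing level-string column, which [read_betas()] detects and drops.
#'
#' @param x A `meth_data` object.
#' @param path Output path.
#' @param levels Optional character vector (one level string per locus).
#' @return `path`, invisibly.
#' @export
write_betas <- function(x, path, levels = NULL) {
  stopifnot(inherits(x, "meth_data"))
  con <- file(path, "w")
  ok <- FALSE
  tryCatch({
    writeLines(paste(x$statuses, collapse = " "), con)
    close(con)
    ok <- TRUE
  }, finally = if (!ok) close(con))
  if (nrow(x$loci)) {
    dt <- data.table::data.table(name = x$loci$name, chrom = x$loci$chrom,
                                 pos = x$loci$pos)
    dt <- cbind(dt, data.table::as.data.table(x$betas))
    if (!is.null(levels)) {
      stopifnot(length(levels) == nrow(x$loci))
      dt[["lvl"]] <- levels
    }
    data.table::fwrite(dt, path, append = TRUE, sep = " ", col.names = FALSE,
                       na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Write the sorted intermediate file ("out_sort.txt")
#'
#' Saves a genomically sorted dataset in the input dialect so it can be reused
#' for downstream or personalised analyses. When `threshold` is given, each
#' locus row additionally carries its binarized level string (`H`/`L`, `?` for
#' missing), computed at that threshold.
#'
#' @param x A sorted `meth_data` object (see [sort_loci()]).
#' @param path Output path (conventionally `out_sort.txt`).
#' @param threshold Optional binarization threshold in (0, 1); when supplied,
#'   level strings are appended.
#' @return `path`, invisibly.
#' @export
write_sorted <- function(x, path = "out_sort.txt", threshold = NULL) {
  stopifnot(inherits(x, "meth_data"))
  if (!x$sorted) stop("dataset is not sorted; call sort_loci() first")
  lv <- NULL
  if (!is.null(threshold)) {
    bm <- binarize(x, threshold)
    ch <- matrix("?", nrow(bm$levels), ncol(bm$levels))
    ch[bm$levels == 1L] <- "H"
    ch[bm$levels == 0L] <- "L"
    lv <- apply(ch, 1L, paste0, collapse = "")
    if (nrow(bm$levels) == 0L) lv <- character(0)
  }
  write_betas(x, path, levels = lv)
}

#' Binarize beta values into high/low methylation levels
#'
#' Each non-missing beta value becomes `H` (coded 1) when `beta >= threshold`
#' and `L` (coded 0) otherwise; ties at the threshold are H. Missing betas stay
#' missing. The dataset is sorted first if needed (all downstream MD analysis
#' assumes genomic order).
#'
#' @param x A `meth_data` object.
#' @param threshold Binarization threshold `T` in (0, 1); default 0.5.
#' @return A `meth_levels` object: list with `statuses`, `loci`, `levels`
#'   (integer matrix, 1 = H, 0 = L, `NA` = missing) and `threshold`.
#' @export
binarize <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "meth_data"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number strictly between 0 and 1")
  if (!x$sorted) x <- sort_loci(x)
  lv <- (x$betas >= threshold) + 0L
  structure(list(statuses = x$statuses, loci = x$loci, levels = lv,
                 threshold = threshold),
            class = "meth_levels")
}

#' @export
print.meth_levels <- function(x, ...) {
  cat(sprintf("meth_levels: %d loci x %d samples, binarized at T = %g\n",
              nrow(x$levels), ncol(x$levels), x$threshold))
  if (length(x$levels)) {
    ph <- mean(x$levels == 1L, na.rm = TRUE)
    cat(sprintf("overall H frequency: %.3f; missing cells: %d\n",
                ph, sum(is.na(x$levels))))
  }
  invisible(x)
}
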