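#' Specification for a synthetic methylation dataset
#'
#' Describes a dataset with known truth: chromosome layouts, planted MD blocks
#' and planted case/control methylecomtype effects. Defaults mirror a typical
#' 450K-style case/control study: 354 cases and 335 controls, loci spaced
#' 2 kb apart (inside the 1-10 kb range over which methylation disequilibrium
#' decays), H/L beta emission centred at 0.80/0.20 with sd 0.10.
#'
#' @param n_case,n_control,n_unknown Sample counts per status.
#' @param chromosomes List of chromosome layouts, each a list with `label`,
#'   `n_loci`, `start_pos`, `spacing_bp`.
#' @param blocks List of planted blocks, each a list with `chrom`,
#'   `first_locus` (1-based index within that chromosome), `n_loci`,
#'   `within_dprime` in \[0, 1\], and `pattern_freqs` (named numeric vector of
#'   H/L patterns of length `n_loci`, summing to 1).
#' @param effects List of planted effects, each a list with `block` (index
#'   into `blocks`), `risk_pattern`, `odds_ratio` (> 0): in cases, the odds of
#'   carrying the risk pattern are multiplied by `odds_ratio`.
#' @param beta_noise_sd Standard deviation of the truncated-normal beta
#'   emission around the level means.
#' @param mu_high,mu_low Beta emission means for H and L levels.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A validated `synth_spec` object.
#' @seealso [simulate_methylation()]
#' @export
synth_spec <- function(n_case = 354L, n_control = 335L, n_unknown = 0L,
                       chromosomes = list(list(label = "1", n_loci = 1000L,
                                               start_pos = 1e6,
                                               spacing_bp = 2000L)),
                       blocks = list(), effects = list(),
                       beta_noise_sd = 0.10, mu_high = 0.80, mu_low = 0.20,
                       seed = 1L) {
  stopifnot(n_case >= 0, n_control >= 0, n_unknown >= 0,
            n_case + n_control + n_unknown > 0,
            beta_noise_sd > 0, mu_low < mu_high, length(chromosomes) >= 1)
  labs <- vapply(chromosomes, function(ch) as.character(ch$label), "")
  if (anyDuplicated(labs)) stop("duplicate chromosome labels")
  for (bl in blocks) {
    ci <- match(as.character(bl$chrom), labs)
    if (is.na(ci)) stop("block references unknown chromosome ", bl$chrom)
    if (bl$first_locus < 1 ||
        bl$first_locus + bl$n_loci - 1 > chromosomes[[ci]]$n_loci)
      stop("block extends beyond chromosome ", bl$chrom)
    pf <- bl$pattern_freqs
    if (is.null(names(pf)) || any(nchar(names(pf)) != bl$n_loci) ||
        !all(grepl("^[HL]+$", names(pf))))
      stop("pattern_freqs names must be H/L strings of length n_loci")
    if (abs(sum(pf) - 1) > 1e-8) stop("pattern_freqs must sum to 1")
    if (is.null(bl$within_dprime) || bl$within_dprime < 0 ||
        bl$within_dprime > 1)
      stop("within_dprime must lie in [0, 1]")
  }
  # planted blocks on one chromosome must not overlap
  for (lab in labs) {
    bi <- which(vapply(blocks, function(b) as.character(b$chrom) == lab, TRUE))
    if (length(bi) > 1) {
      iv <- t(vapply(blocks[bi], function(b)
        c(b$first_locus, b$first_locus + b$n_loci - 1), c(0, 0)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("planted blocks overlap on chromosome ", lab)
    }
  }
  for (ef in effects) {
    if (ef$block < 1 || ef$block > length(blocks))
      stop("effect references unknown block ", ef$block)
    if (!(ef$risk_pattern %in% names(blocks[[ef$block]]$pattern_freqs)))
      stop("risk pattern ", ef$risk_pattern, " absent from block patterns")
    if (ef$odds_ratio <= 0) stop("odds_ratio must be > 0")
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_unknown = as.integer(n_unknown), chromosomes = chromosomes,
                 blocks = blocks, effects = effects,
                 beta_noise_sd = beta_noise_sd, mu_high = mu_high,
                 mu_low = mu_low, seed = as.integer(seed)),
            class = "synth_spec")
}

rtruncnorm01 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

#' Generate a synthetic methylation dataset with known truth
#'
#' Samples are laid out as cases, then controls, then unknowns. Outside
#' planted blocks each locus level is an independent Bernoulli(0.5) draw per
#' sample. Inside a planted block each sample draws a latent pattern from
#' `pattern_freqs` — for cases, the odds of any risk pattern are tilted by its
#' planted odds ratio — and keeps it with probability `within_dprime`;
#' otherwise each block locus is drawn independently from the pattern-implied
#' marginal H frequency of the sample's group, which makes `within_dprime` the
#' expected pairwise gD' for balanced two-pattern blocks. Levels become beta
#' values via truncated normals on \[0, 1\] centred at `mu_high`/`mu_low` with
#' sd `beta_noise_sd`.
#'
#' @param spec A [synth_spec()] object.
#' @return List with `data` (a sorted `meth_data` object) and `truth` (planted
#'   block coordinates, per-group pattern frequencies and planted effects).
#' @export
simulate_methylation <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n_samp <- spec$n_case + spec$n_control + spec$n_unknown
  statuses <- c(rep(1L, spec$n_case), rep(0L, spec$n_control),
                rep(-1L, spec$n_unknown))
  is_case <- statuses == 1L
  loci_list <- list()
  beta_list <- list()
  truth_blocks <- list()
  for (ch in spec$chromosomes) {
    L <- as.integer(ch$n_loci)
    pos <- as.integer(ch$start_pos + (seq_len(L) - 1L) * ch$spacing_bp)
    name <- sprintf("cg_%s_%05d", ch$label, seq_len(L))
    lv <- matrix(stats::rbinom(L * n_samp, 1L, 0.5), L, n_samp)
    bi <- which(vapply(spec$blocks,
                       function(b) as.character(b$chrom) == as.character(ch$label),
                       TRUE))
    for (k in bi) {
      bl <- spec$blocks[[k]]
      rows <- bl$first_locus:(bl$first_locus + bl$n_loci - 1L)
      pf <- bl$pattern_freqs
      pats <- names(pf)
      pmat <- vapply(pats, function(p)
        as.integer(strsplit(p, "")[[1]] == "H"), integer(bl$n_loci))
      pmat <- matrix(pmat, nrow = bl$n_loci)  # loci x patterns
      # case probabilities: odds of each risk pattern multiplied by its OR
      w_case <- pf
      for (ef in spec$effects) {
        if (ef$block == k)
          w_case[ef$risk_pattern] <- w_case[ef$risk_pattern] * ef$odds_ratio
      }
      w_case <- w_case / sum(w_case)
      pick <- integer(n_samp)
      if (any(is_case))
        pick[is_case] <- sample.int(length(pf), sum(is_case), replace = TRUE,
                                    prob = w_case)
      if (any(!is_case))
        pick[!is_case] <- sample.int(length(pf), sum(!is_case), replace = TRUE,
                                     prob = pf)
      blk <- pmat[, pick, drop = FALSE]  # loci x samples
      if (bl$within_dprime < 1) {
        ph_ctrl <- as.numeric(pmat %*% pf)
        ph_case <- as.numeric(pmat %*% w_case)
        indep <- stats::runif(n_samp) > bl$within_dprime
        if (any(indep)) {
          nm <- sum(indep)
          phm <- matrix(rep(ifelse(is_case[indep], 1, 0), each = bl$n_loci),
                        bl$n_loci, nm)
          phm <- phm * ph_case + (1 - phm) * ph_ctrl
          blk[, indep] <- matrix(stats::rbinom(bl$n_loci * nm, 1L, phm),
                                 bl$n_loci, nm)
        }
      }
      lv[rows, ] <- blk
      truth_blocks[[length(truth_blocks) + 1L]] <- list(
        chrom = as.character(ch$label), first_locus = bl$first_locus,
        n_loci = bl$n_loci, start = pos[rows[1L]],
        end = pos[rows[length(rows)]], loci = name[rows],
        within_dprime = bl$within_dprime,
        pattern_freqs_control = pf, pattern_freqs_case = w_case)
    }
    mu <- ifelse(lv == 1L, spec$mu_high, spec$mu_low)
    betas <- matrix(rtruncnorm01(length(mu), as.numeric(mu),
                                 spec$beta_noise_sd), L, n_samp)
    loci_list[[length(loci_list) + 1L]] <-
      data.frame(name = name, chrom = as.character(ch$label), pos = pos,
                 stringsAsFactors = FALSE)
    beta_list[[length(beta_list) + 1L]] <- betas
  }
  loci <- do.call(rbind, loci_list)
  betas <- do.call(rbind, beta_list)
  x <- new_meth_data(statuses, loci, betas)
  x <- sort_loci(x)
  truth <- list(blocks = truth_blocks, effects = spec$effects,
                n_case = spec$n_case, n_control = spec$n_control,
                n_unknown = spec$n_unknown, seed = spec$seed)
  list(data = x, truth = truth)
}
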