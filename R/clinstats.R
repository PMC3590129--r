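# --- qRT-PCR -----------------------------------------------------------------

#' Reference-normalized qRT-PCR abundance (2^-dCt)
#'
#' Relative transcript level of each target miR normalized to the endogenous
#' small nucleolar RNA reference (RNU48 by default), assuming doubling
#' amplification efficiency: `level = 2^-(Ct_target - Ct_reference)`.
#'
#' @param panel long tibble with columns `mir_id`, `ct` plus any identifying
#'   columns (subject, phase, group, ...); reference rows carry
#'   `mir_id == reference`. Ct values must be finite and positive.
#' @param reference miR/snoRNA id of the reference assay.
#' @return the target rows of `panel` with added `ct_reference` and `level`;
#'   records without a matching reference Ct are dropped with a warning.
#' @export
relative_abundance <- function(panel, reference = "RNU48") {
  assert_tbl_cols(panel, c("mir_id", "ct"), "panel")
  if (any(!is.finite(panel$ct) | panel$ct <= 0)) {
    abort("Ct values must be finite and positive")
  }
  keys <- setdiff(names(panel), c("mir_id", "ct"))
  ref_rows <- panel %>% filter(.data$mir_id == reference) %>%
    select(all_of(keys), ct_reference = "ct")
  out <- panel %>%
    filter(.data$mir_id != reference) %>%
    left_join(ref_rows, by = keys)
  if (anyNA(out$ct_reference)) {
    warn(paste(sum(is.na(out$ct_reference)),
               "record(s) lack a reference Ct and were skipped"))
    out <- filter(out, !is.na(.data$ct_reference))
  }
  mutate(out, level = 2^-(.data$ct - .data$ct_reference))
}

# --- exact rank tests --------------------------------------------------------

# exact null distribution of a sum over subsets of doubled ranks.
# signed-rank flavour: each rank included independently with prob 1/2.
signrank_null <- function(ranks2) {
  total <- sum(ranks2)
  probs <- numeric(total + 1)
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(total + 1 - r)])
    probs <- (probs + shifted) / 2
  }
  probs  # probs[w + 1] = P(2 * W == w)
}

two_sided_from_null <- function(probs, stat2) {
  p_le <- sum(probs[seq_len(stat2 + 1)])
  p_ge <- sum(probs[(stat2 + 1):length(probs)])
  min(1, 2 * min(p_le, p_ge))
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped and ties in the absolute differences receive
#' average ranks. For `n <= exact_max` usable pairs the two-sided p-value is
#' exact: the null distribution of the positive-rank sum `W` is built by
#' convolution over the `2^n` sign assignments (tie-adjusted), and the
#' smaller tail is doubled and capped at 1. Beyond that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired measurement vectors; alternatively pass the differences
#'   as `x` and leave `y = NULL`.
#' @param exact_max largest number of non-zero pairs for the exact mode.
#' @return one-row tibble: `statistic` (W, positive-rank sum), `p_value`,
#'   `n_pairs` (used, after dropping zeros), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = 0, p_value = 1, n_pairs = 0L,
                  method = "exact"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    probs <- signrank_null(as.integer(round(2 * r)))
    p <- two_sided_from_null(probs, as.integer(round(2 * W)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(statistic = W, p_value = p, n_pairs = n, method = method)
}

# exact null distribution of the rank sum of group A: number of ways to pick
# n_a of the doubled ranks with each possible sum (dynamic programme)
ranksum_null <- function(ranks2, n_a) {
  total <- sum(ranks2)
  ways <- matrix(0, nrow = n_a + 1, ncol = total + 1)
  ways[1, 1] <- 1
  for (r in ranks2) {
    for (k in seq(n_a, 1)) {
      cols <- (r + 1):(total + 1)
      ways[k + 1, cols] <- ways[k + 1, cols] + ways[k, cols - r]
    }
  }
  ways[n_a + 1, ]  # counts over rank-sum values 0..total (doubled scale)
}

#' Exact Mann-Whitney test for two independent groups
#'
#' Ties receive average ranks. For `n_A + n_B <= exact_max` the two-sided
#' p-value is exact: the null distribution of the group-A rank sum is built
#' by enumerating all `choose(N, n_A)` rank assignments (tie-adjusted,
#' via dynamic programming), and the smaller tail of the U statistic is
#' doubled and capped at 1. Larger samples use a normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y the two groups (both nonempty).
#' @param exact_max largest combined sample size for the exact mode.
#' @return one-row tibble: `statistic` (U for group `x`), `p_value`, `n_x`,
#'   `n_y`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 25) {
  stopifnot(length(x) > 0, length(y) > 0, all(is.finite(c(x, y))))
  n_a <- length(x)
  n_b <- length(y)
  r <- rank(c(x, y))
  ra <- sum(r[seq_len(n_a)])
  U <- ra - n_a * (n_a + 1) / 2
  if (n_a + n_b <= exact_max) {
    counts <- ranksum_null(as.integer(round(2 * r)), n_a)
    probs <- counts / sum(counts)
    ra2 <- as.integer(round(2 * ra))
    p <- two_sided_from_null(probs, ra2)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    N <- n_a + n_b
    ties <- table(r)
    sigma2 <- n_a * n_b / 12 *
      (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  tibble(statistic = U, p_value = p, n_x = n_a, n_y = n_b, method = method)
}

#' Spearman rank correlation
#'
#' Average ranks for ties, then the product-moment correlation of the ranks.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\]; `NA` with a warning when either vector is
#'   constant (undefined).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Spearman correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

# --- power simulation --------------------------------------------------------

#' Monte-Carlo power of the exact paired Wilcoxon signed-rank test
#'
#' Per replicate, `n_pairs` paired differences are drawn from a normal
#' distribution with mean `effect_size` and standard deviation 1 (the
#' standardized-effect convention), the exact two-sided signed-rank test is
#' applied, and power is the fraction of replicates with `p <= alpha`.
#' Continuous draws have no ties or zeros almost surely, so the exact
#' p-value depends only on the positive-rank sum; the simulation exploits
#' this with a precomputed lookup over the `2^n` sign-assignment null
#' distribution (identical to [wilcoxon_signed_rank()] on every draw).
#'
#' @param n_pairs number of subject pairs.
#' @param effect_size standardized mean of the paired differences.
#' @param alpha significance level.
#' @param reps Monte-Carlo replicates (>= 1000).
#' @param seed optional seed for reproducibility.
#' @return one-row tibble: `power`, `mc_se` (binomial standard error),
#'   `reps`, `n_pairs`, `effect_size`, `alpha`.
#' @export
power_paired_wilcoxon <- function(n_pairs = 12, effect_size = 1,
                                  alpha = 0.05, reps = 50000, seed = NULL) {
  stopifnot(reps >= 1000, alpha > 0, alpha < 1, n_pairs >= 2)
  run <- function() {
    probs <- signrank_null(2L * seq_len(n_pairs))
    # two-sided exact p for every possible W (doubled scale: only even sums)
    p_of_w <- vapply(0:(n_pairs * (n_pairs + 1) / 2), function(w) {
      two_sided_from_null(probs, 2L * w)
    }, numeric(1))
    d <- matrix(rnorm(reps * n_pairs, mean = effect_size, sd = 1),
                nrow = reps)
    w <- vapply(seq_len(reps), function(i) {
      di <- d[i, ]
      sum(rank(abs(di))[di > 0])
    }, numeric(1))
    rej <- p_of_w[w + 1] <= alpha
    power <- mean(rej)
    tibble(power = power, mc_se = sqrt(power * (1 - power) / reps),
           reps = as.integer(reps), n_pairs = as.integer(n_pairs),
           effect_size = effect_size, alpha = alpha)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# --- vesicle RNase protection ------------------------------------------------

#' Fraction of transcripts degraded after membrane disruption
#'
#' In the RNase-protection assay, transcripts inside intact phospholipid
#' vesicles survive RNase; disrupting the membrane with Triton before RNase
#' exposes them. The membrane-protected (vesicular) fraction is
#' `1 - level(triton_rnase) / level(rnase)`.
#'
#' @param assay tibble with columns `condition` (including `"rnase"` and
#'   `"triton_rnase"`) and `level` (relative transcript level, positive).
#' @return one-row tibble: `fraction` (clamped to \[0, 1\], with a warning
#'   when clamping occurred), `fraction_raw`, `level_rnase`,
#'   `level_triton_rnase`.
#' @export
vesicle_protected_fraction <- function(assay) {
  assert_tbl_cols(assay, c("condition", "level"), "assay")
  get_level <- function(cond) {
    lv <- assay$level[assay$condition == cond]
    if (length(lv) == 0) abort(paste0("missing assay condition: ", cond))
    if (length(lv) > 1) lv <- mean(lv)
    if (!is.finite(lv) || lv <= 0) {
      abort(paste0("condition ", cond, " must have a positive level"))
    }
    lv
  }
  l_rnase <- get_level("rnase")
  l_triton <- get_level("triton_rnase")
  raw <- 1 - l_triton / l_rnase
  clamped <- min(1, max(0, raw))
  if (clamped != raw) {
    warn(sprintf("raw degraded fraction %.3f clamped into [0, 1]", raw))
  }
  tibble(fraction = clamped, fraction_raw = raw, level_rnase = l_rnase,
         level_triton_rnase = l_triton)
}
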