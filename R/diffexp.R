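# --- count-matrix helpers ----------------------------------------------------

counts_to_matrix <- function(counts) {
  assert_tbl_cols(counts, "mir_id", "counts")
  m <- as.matrix(counts[setdiff(names(counts), "mir_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$mir_id
  m
}

#' Estimate library size factors (median-of-ratios)
#'
#' `s_j` is the median, over rows with all-positive counts, of
#' `k_ij / geometric-mean_v(k_iv)` -- the normalization constant of the
#' negative-binomial count model.
#'
#' @param counts wide count tibble (`mir_id` + one column per library) or a
#'   numeric matrix.
#' @param method `"ratio"` requires at least one all-positive row;
#'   `"poscounts"` is the fallback that takes geometric means over positive
#'   entries only, for matrices where every row contains a zero.
#' @return tibble: `library`, `size_factor`.
#' @export
estimate_size_factors <- function(counts, method = c("ratio", "poscounts")) {
  method <- match.arg(method)
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  if (method == "ratio") {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos)) {
      abort(paste("no row has all-positive counts; use",
                  'method = "poscounts" as a pseudo-reference fallback'))
    }
    logm <- log(m[pos, , drop = FALSE])
    loggeo <- rowMeans(logm)
    sf <- apply(exp(logm - loggeo), 2, median)
  } else {
    logm <- log(m)
    logm[!is.finite(logm)] <- NA
    loggeo <- rowMeans(logm, na.rm = TRUE)
    keep <- is.finite(loggeo)
    sf <- apply(exp(logm[keep, , drop = FALSE] - loggeo[keep]), 2, median,
                na.rm = TRUE)
  }
  tibble(library = colnames(m), size_factor = unname(sf))
}

#' Estimate per-row negative-binomial dispersions
#'
#' Method-of-moments estimate on normalized counts,
#' `alpha_i = max(0, (v_i - q_i * mean(1/s_j)) / q_i^2)`, where `q_i` is the
#' row's mean normalized count and `v_i` the pooled within-condition variance
#' of normalized counts; a mean-dispersion trend `a0 / q + a1` is fitted by
#' least squares over rows with positive raw estimates, and the final
#' dispersion is the conservative maximum of the raw estimate and the trend
#' value at the row's mean.
#'
#' @param counts wide count tibble or matrix.
#' @param size_factors tibble from [estimate_size_factors()].
#' @param samples sample sheet tibble: `library`, `condition` (2 levels, each
#'   with >= 2 libraries), optional `pair_id`.
#' @return tibble: `mir_id`, `mean_norm`, `dispersion_mom`, `dispersion_fit`,
#'   `dispersion`.
#' @export
estimate_dispersions <- function(counts, size_factors, samples) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  assert_tbl_cols(samples, c("library", "condition"), "samples")
  sf <- size_factors$size_factor[match(colnames(m), size_factors$library)]
  cond <- samples$condition[match(colnames(m), samples$library)]
  if (anyNA(sf) || anyNA(cond)) {
    abort("size factors / sample sheet do not cover all count columns")
  }
  lv <- unique(cond)
  if (length(lv) != 2) abort("exactly two conditions are required")
  if (any(table(cond) < 2)) {
    abort("each condition needs >= 2 libraries to estimate dispersion")
  }
  norm <- sweep(m, 2, sf, "/")
  qbar <- rowMeans(norm)
  ss <- 0
  df <- 0
  for (cv in lv) {
    sub <- norm[, cond == cv, drop = FALSE]
    mu <- rowMeans(sub)
    ss <- ss + rowSums((sub - mu)^2)
    df <- df + ncol(sub) - 1
  }
  v <- ss / df
  mom <- pmax(0, (v - qbar * mean(1 / sf)) / qbar^2)
  mom[!is.finite(mom)] <- 0

  fit_rows <- mom > 0 & qbar > 0
  if (sum(fit_rows) >= 2) {
    co <- coef(lm(mom[fit_rows] ~ I(1 / qbar[fit_rows])))
    a1 <- co[1]
    a0 <- co[2]
    fitted <- pmax(0, a0 / qbar + a1)
    fitted[qbar == 0] <- 0
  } else {
    fitted <- rep(0, length(qbar))
  }
  tibble(mir_id = rownames(m), mean_norm = qbar,
         dispersion_mom = unname(mom), dispersion_fit = unname(fitted),
         dispersion = pmax(unname(mom), unname(fitted)))
}

# NB density with mean/variance parametrization; Poisson when var <= mu
dnb_mv <- function(x, mu, v) {
  if (mu <= 0) return(as.numeric(x == 0))
  if (v > mu) dnbinom(x, size = mu^2 / (v - mu), mu = mu) else dpois(x, mu)
}

#' Conditional negative-binomial exact test for one row
#'
#' Given the row total `K`, enumerates every split `(a, K - a)` of the total
#' between the two conditions, scores each with the product of
#' negative-binomial probabilities whose means and variances are the
#' condition-summed `s_j * q0` and `s_j * q0 + alpha * (s_j * q0)^2`, and
#' returns the two-sided p-value: the summed probability of all splits no
#' more probable than the observed one, divided by the total.
#'
#' @param k integer vector of counts for one row.
#' @param condition vector of condition labels aligned with `k` (2 levels).
#' @param size_factors numeric vector aligned with `k`.
#' @param dispersion the row's dispersion alpha (>= 0).
#' @return two-sided p-value in (0, 1\]; `K = 0` gives 1.
#' @export
nb_exact_test <- function(k, condition, size_factors, dispersion) {
  stopifnot(length(k) == length(condition),
            length(k) == length(size_factors), dispersion >= 0)
  lv <- unique(condition)
  if (length(lv) != 2) abort("exactly two conditions are required")
  K <- sum(k)
  if (K == 0) return(1)
  in_a <- condition == lv[1]
  q0 <- sum(k) / sum(size_factors)
  mu_a <- q0 * sum(size_factors[in_a])
  mu_b <- q0 * sum(size_factors[!in_a])
  v_a <- mu_a + dispersion * q0^2 * sum(size_factors[in_a]^2)
  v_b <- mu_b + dispersion * q0^2 * sum(size_factors[!in_a]^2)
  a <- 0:K
  ps <- dnb_mv(a, mu_a, v_a) * dnb_mv(K - a, mu_b, v_b)
  p_obs <- ps[sum(k[in_a]) + 1]
  min(1, sum(ps[ps <= p_obs * (1 + 1e-8)]) / sum(ps))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

# variance-stabilized counts on the log2-ratio scale at large alpha*k;
# alpha ~ 0 degenerates to the square root, where a shifted log2 is used
vst_log2 <- function(x, alpha) {
  if (alpha > 1e-8) 2 * asinh(sqrt(alpha * x)) / log(2) else log2(x + 1)
}

#' Per-row fold changes: ratio of normalized means and VST difference
#'
#' `fold_change` is the ratio of mean normalized counts (condition A over
#' condition B; `NA` when the B mean is zero). `vst_log2fc` is the difference
#' of condition means of the variance-stabilizing transformation
#' `w(k) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * k))` rescaled so that it
#' approaches the plain log2 ratio for large `alpha * k`; rows with
#' dispersion ~ 0 use a shifted log2.
#'
#' @inheritParams estimate_dispersions
#' @param dispersions tibble from [estimate_dispersions()] (or a numeric
#'   vector aligned with the rows).
#' @param condition_a,condition_b condition labels for the numerator and
#'   denominator of the fold change.
#' @return tibble: `mir_id`, `mean_norm_a`, `mean_norm_b`, `fold_change`,
#'   `vst_log2fc`.
#' @export
fold_changes <- function(counts, size_factors, samples, dispersions,
                         condition_a = "acute",
                         condition_b = "convalescent") {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  sf <- size_factors$size_factor[match(colnames(m), size_factors$library)]
  cond <- samples$condition[match(colnames(m), samples$library)]
  alpha <- if (is.data.frame(dispersions)) {
    dispersions$dispersion[match(rownames(m), dispersions$mir_id)]
  } else {
    rep_len(dispersions, nrow(m))
  }
  norm <- sweep(m, 2, sf, "/")
  qa <- rowMeans(norm[, cond == condition_a, drop = FALSE])
  qb <- rowMeans(norm[, cond == condition_b, drop = FALSE])
  vst_diff <- vapply(seq_len(nrow(m)), function(i) {
    wa <- mean(vst_log2(norm[i, cond == condition_a], alpha[i]))
    wb <- mean(vst_log2(norm[i, cond == condition_b], alpha[i]))
    wa - wb
  }, numeric(1))
  tibble(mir_id = rownames(m), mean_norm_a = unname(qa),
         mean_norm_b = unname(qb),
         fold_change = unname(ifelse(qb > 0, qa / qb, NA_real_)),
         vst_log2fc = vst_diff)
}

#' Negative-binomial differential expression, acute vs convalescent
#'
#' The full DE stage: rows with zero total count are dropped, size factors
#' are estimated by median-of-ratios, per-row dispersions by method of
#' moments with a fitted `a0/q + a1` trend and the conservative maximum
#' rule, each remaining row is scored with the conditional NB exact test,
#' p-values are Benjamini-Hochberg adjusted (with `m` equal to the number of
#' tested rows), and fold changes are reported both as ratios of normalized
#' means and on the variance-stabilized log2 scale. The design is treated as
#' two independent groups; pairing enters only the validation statistics.
#'
#' @inheritParams estimate_dispersions
#' @param condition_a,condition_b the two condition labels (numerator first).
#' @param sf_method passed to [estimate_size_factors()].
#' @return object of class `mirkd_de`; see [tidy.mirkd_de()] /
#'   [glance.mirkd_de()] / [autoplot.mirkd_de()].
#' @export
run_diffexp <- function(counts, samples, condition_a = "acute",
                        condition_b = "convalescent",
                        sf_method = c("ratio", "poscounts")) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  assert_tbl_cols(samples, c("library", "condition"), "samples")
  keep_cols <- samples$library[samples$condition %in%
                                 c(condition_a, condition_b)]
  m <- m[, colnames(m) %in% keep_cols, drop = FALSE]
  expressed <- rowSums(m) > 0
  m_t <- m[expressed, , drop = FALSE]

  sf <- estimate_size_factors(m_t, method = match.arg(sf_method))
  disp <- estimate_dispersions(m_t, sf, samples)
  sfv <- sf$size_factor[match(colnames(m_t), sf$library)]
  cond <- samples$condition[match(colnames(m_t), samples$library)]
  p_raw <- vapply(seq_len(nrow(m_t)), function(i) {
    nb_exact_test(m_t[i, ], cond, sfv,
                  disp$dispersion[i])
  }, numeric(1))
  fc <- fold_changes(m_t, sf, samples, disp, condition_a, condition_b)
  results <- fc %>%
    mutate(p_raw = p_raw, p_adj = bh_adjust(p_raw)) %>%
    left_join(select(disp, "mir_id", "dispersion"), by = "mir_id") %>%
    arrange(.data$p_adj, .data$p_raw, .data$mir_id)
  structure(
    list(results = results, size_factors = sf, dispersions = disp,
         samples = samples,
         settings = list(condition_a = condition_a,
                         condition_b = condition_b,
                         n_dropped_zero_rows = sum(!expressed),
                         sf_method = match.arg(sf_method),
                         dispersion_trend = "a0/q + a1, max rule",
                         test = "conditional NB exact, two-sided")),
    class = "mirkd_de"
  )
}

#' @export
print.mirkd_de <- function(x, ...) {
  cat("<mirkd_de>", nrow(x$results), "miRs tested (",
      x$settings$condition_a, "vs", x$settings$condition_b, ");",
      sum(x$results$p_adj < 0.05), "at BH < 0.05\n")
  print(head(x$results, 10))
  invisible(x)
}

#' Simulate a count matrix with planted fold changes
#'
#' Direct negative-binomial count simulator used for operating-characteristic
#' studies of the DE stage (type-I error, FDR, power): row means are
#' log-normal, library size factors log-normal around 1, acute-column means
#' are multiplied by `2^log2fc`.
#'
#' @param n_rows number of rows (miRs).
#' @param n_per_group libraries per condition.
#' @param dispersion NB dispersion alpha.
#' @param log2fc scalar or per-row vector of planted log2 fold changes.
#' @param mean_log,mean_sdlog log-normal parameters of the row means.
#' @param seed optional seed.
#' @return list: `counts` (matrix), `samples` (tibble), `log2fc` (per row).
#' @export
simulate_counts <- function(n_rows, n_per_group = 12, dispersion = 0.1,
                            log2fc = 0, mean_log = log(20), mean_sdlog = 1,
                            seed = NULL) {
  run <- function() {
    mu0 <- rlnorm(n_rows, mean_log, mean_sdlog)
    lfc <- rep_len(log2fc, n_rows)
    sf <- exp(rnorm(2 * n_per_group, 0, 0.15))
    cond <- rep(c("acute", "convalescent"), each = n_per_group)
    libs <- sprintf("L%02d_%s", seq_along(cond), substr(cond, 1, 4))
    m <- matrix(0, n_rows, length(cond), dimnames = list(
      sprintf("row%04d", seq_len(n_rows)), libs))
    for (j in seq_along(cond)) {
      mu <- sf[j] * mu0 * (if (cond[j] == "acute") 2^lfc else 1)
      m[, j] <- if (dispersion > 0) {
        rnbinom(n_rows, size = 1 / dispersion, mu = mu)
      } else {
        rpois(n_rows, mu)
      }
    }
    list(counts = m, samples = tibble(library = libs, condition = cond),
         log2fc = lfc)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
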