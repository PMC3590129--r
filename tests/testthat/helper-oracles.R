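# Independent brute-force oracles used to check the implementations.
# These deliberately share no code with the package internals.

# exhaustive adapter-alignment oracle: score every (position, overlap) pair
oracle_trim <- function(seq, adapter, max_mismatch = 2, min_overlap = 6) {
  L <- nchar(seq)
  la <- nchar(adapter)
  if (L < min_overlap) return(NA_integer_)
  s <- strsplit(seq, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  for (p in 0:(L - min_overlap)) {
    o <- min(la, L - p)
    budget <- if (o < la) floor(max_mismatch * o / la) else max_mismatch
    mism <- sum(s[(p + 1):(p + o)] != a[seq_len(o)])
    if (mism <= budget) return(p)
  }
  NA_integer_
}

# naive substring scan over a named character vector, both strands
oracle_scan <- function(query, subjects) {
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  if (grepl("[^ACGT]", query) || !nzchar(query)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0)))
  }
  out <- list()
  for (id in names(subjects)) {
    subj <- subjects[[id]]
    L <- nchar(subj)
    w <- nchar(query)
    for (st in seq_len(L - w + 1)) {
      piece <- substr(subj, st, st + w - 1)
      if (piece == query) {
        out[[length(out) + 1]] <- data.frame(seq_id = id, start = st - 1L,
                                             strand = "+")
      }
      if (rc(piece) == query) {
        out[[length(out) + 1]] <- data.frame(seq_id = id, start = st - 1L,
                                             strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

# full 2^n enumeration of the signed-rank null (tie-adjusted, two-sided,
# doubling the smaller tail)
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_le <- mean(W_all <= W_obs + 1e-9)
  p_ge <- mean(W_all >= W_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# full choose(N, nA) enumeration of the rank-sum null
oracle_mw_p <- function(x, y) {
  n_a <- length(x)
  r <- rank(c(x, y))
  ra_obs <- sum(r[seq_len(n_a)])
  combs <- utils::combn(length(r), n_a)
  ra_all <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ra_all <= ra_obs + 1e-9)
  p_ge <- mean(ra_all >= ra_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive hypergeometric upper tail by enumerating every draw
oracle_hyper_p <- function(n_universe, n_pathway, n_targets, n_overlap) {
  combs <- utils::combn(n_universe, n_targets)
  in_pathway <- combs <= n_pathway  # label genes 1..n_pathway as pathway
  overlaps <- colSums(in_pathway)
  mean(overlaps >= n_overlap)
}

# literal median-of-ratios recomputation
oracle_size_factors <- function(m) {
  pos <- apply(m, 1, function(r) all(r > 0))
  mp <- m[pos, , drop = FALSE]
  geo <- apply(mp, 1, function(r) prod(r)^(1 / length(r)))
  vapply(seq_len(ncol(mp)), function(j) median(mp[, j] / geo), numeric(1))
}

# literal BH step-up: p_adj(i) = min over j with p_(j) >= p_(i) of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  vapply(seq_len(m), function(i) {
    js <- which(p[ord] >= p[i] - 1e-15)
    min(1, min(p[ord][js] * m / js))
  }, numeric(1))
}

# conditional binomial oracle for the NB exact test in the Poisson limit
oracle_cond_binom_p <- function(k, in_a, size_factors) {
  K <- sum(k)
  pr <- sum(size_factors[in_a]) / sum(size_factors)
  a <- 0:K
  ps <- stats::dbinom(a, K, pr)
  p_obs <- ps[sum(k[in_a]) + 1]
  min(1, sum(ps[ps <= p_obs * (1 + 1e-8)]))
}
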