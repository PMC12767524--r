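# Independent oracles used across tests. Each is a deliberately naive
# implementation (enumeration / closed form) kept separate from the code
# paths it checks.

# Rand index between two labelings (pair-counting definition)
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / choose(n, 2)
}

# Two-sided Fisher exact p by hypergeometric tail summation over all
# tables with the observed margins (include tables at most as probable
# as the observed one, with the same relative slack R uses)
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up from scratch
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided rank-sum p by enumeration of all group assignments
ranksum_oracle <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n1 <- length(x)
  idx <- utils::combn(length(all_v), n1)
  # Mann-Whitney U statistic for each assignment of n1 ranks to group 1
  stats_all <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_lo <- mean(stats_all <= obs); p_hi <- mean(stats_all >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force Ward's D agglomeration (Lance-Williams update) returning the
# merge order as sets of leaf labels
ward_oracle_merges <- function(d_mat) {
  labs <- rownames(d_mat)
  clusters <- as.list(labs)
  sizes <- rep(1, length(labs))
  d <- d_mat
  merges <- list()
  while (length(clusters) > 1) {
    nd <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(nd - 1)) for (j in (i + 1):nd)
      if (d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1]] <- sort(unlist(clusters[c(i, j)]))
    # Lance-Williams for ward.D
    ni <- sizes[i]; nj <- sizes[j]
    newd <- vapply(seq_len(nd), function(k) {
      if (k %in% c(i, j)) return(NA_real_)
      nk <- sizes[k]
      ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(nd), c(i, j))
    d_new <- matrix(0, nd - 1, nd - 1)
    if (length(keep))
      d_new[seq_along(keep), seq_along(keep)] <- d[keep, keep, drop = FALSE]
    d_new[nd - 1, seq_along(keep)] <- newd[keep]
    d_new[seq_along(keep), nd - 1] <- newd[keep]
    clusters <- c(clusters[keep],
                  list(sort(unlist(clusters[c(i, j)]))))
    sizes <- c(sizes[keep], ni + nj)
    d <- d_new
  }
  merges
}

# merge order of an hclust object as sets of leaf labels
hclust_merges <- function(hc) {
  sets <- list()
  out <- list()
  for (m in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[m, ], function(x)
      if (x < 0) hc$labels[-x] else sets[[x]]))
    sets[[m]] <- sort(members)
    out[[m]] <- sets[[m]]
  }
  out
}

# expand an IUPAC consensus into its full language (small L only)
iupac_language <- function(consensus) {
  sets <- promnex:::IUPAC_SETS[strsplit(consensus, "")[[1]]]
  apply(expand.grid(rev(sets), stringsAsFactors = FALSE), 1,
        function(row) paste(rev(row), collapse = ""))
}

# small default config for fast tests
tiny_config <- function(...) {
  synthetic_config(n_promoters_per_class = 5, seed = 42, ...)
}
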