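# Independent brute-force oracles used to pin expected values.

# best single change point by exhaustive least-squares scan; returns the
# 1-based index of the first point of the second segment
oracle_one_changepoint <- function(y, min_len = 2) {
  n <- length(y)
  best <- Inf
  best_k <- NA_integer_
  for (k in (min_len + 1):(n - min_len + 1)) {
    sse <- sum((y[1:(k - 1)] - mean(y[1:(k - 1)]))^2) +
      sum((y[k:n] - mean(y[k:n]))^2)
    if (sse < best) {
      best <- sse
      best_k <- k
    }
  }
  best_k
}

# best pair of change points by exhaustive scan (n small)
oracle_two_changepoints <- function(y, min_len = 2) {
  n <- length(y)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / (j - i + 1)
  best <- Inf
  best_kl <- c(NA, NA)
  for (k in (min_len + 1):(n - 2 * min_len + 1)) {
    for (l in (k + min_len):(n - min_len + 1)) {
      s <- sse(1, k - 1) + sse(k, l - 1) + sse(l, n)
      if (s < best) {
        best <- s
        best_kl <- c(k, l)
      }
    }
  }
  best_kl
}

# exact two-sided rank-sum p by direct enumeration over group assignments
oracle_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  n <- length(r)
  obs <- sum(r[seq_len(n1)])
  mid <- n1 * (n + 1) / 2
  sums <- apply(utils::combn(n, n1), 2, function(id) sum(r[id]))
  mean(abs(sums - mid) >= abs(obs - mid) - 1e-9)
}

# exact two-sample KS p by enumeration of all rank assignments (no ties)
oracle_ks_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- sort(c(x, y))
  d_of <- function(x_idx) {
    is_x <- seq_len(n + m) %in% x_idx
    max(abs(cumsum(ifelse(is_x, 1 / n, 0)) - cumsum(ifelse(is_x, 0, 1 / m))))
  }
  obs <- d_of(which(pooled %in% x))
  ds <- apply(utils::combn(n + m, n), 2, d_of)
  mean(ds >= obs - 1e-9)
}

# hypergeometric upper-tail p by enumeration of all query-sized subsets
oracle_hyper_p <- function(universe, term, query_size, observed_overlap) {
  subsets <- utils::combn(length(universe), query_size)
  overlaps <- apply(subsets, 2, function(id)
    length(intersect(universe[id], term)))
  mean(overlaps >= observed_overlap)
}

# Benjamini-Hochberg step-up by direct application of the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# a ratio profile tibble built directly (single chromosome unless given)
make_profile <- function(ratio, chrom = "chr1") {
  tibble::tibble(bin = seq_along(ratio) - 1L, chrom = chrom, ratio = ratio,
                 valid = TRUE)
}

# a bin grid with unit-named chromosomes for set-level tests
tiny_grid <- function(n_bins = 100, bin_size = 1e5) {
  build_bin_grid(genome_spec("chr1", n_bins * bin_size), bin_size)
}

# aberrant bin set literal
bin_set <- function(bins, direction = "gain") {
  tibble::tibble(bin = as.integer(bins),
                 direction = rep(direction, length.out = length(bins)))
}
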