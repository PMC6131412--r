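# Independent oracles used by the property and acceptance tests.  These are
# deliberately naive (enumeration, closed forms, step-by-step arithmetic) and
# share no code with the package implementation they check.

# exhaustive optimal penalized Gaussian change-in-mean segmentation:
# minimizes sum(segment costs) + beta * (number of change points) over all
# 2^(n-1) placements of cut points
brute_segment <- function(x, beta, sigma2, min_seg = 1L) {
  n <- length(x)
  segcost <- function(i, j) {
    v <- x[i:j]
    (sum(v^2) - sum(v)^2 / length(v)) / sigma2
  }
  best <- list(objective = Inf, cps = integer(0))
  cuts <- if (n >= 2) seq_len(n - 1) else integer(0)
  for (mask in 0:(2^length(cuts) - 1)) {
    cps <- cuts[bitwAnd(bitwShiftR(mask, seq_along(cuts) - 1), 1) == 1]
    bounds <- c(0, cps, n)
    lens <- diff(bounds)
    if (any(lens < min_seg)) next
    obj <- sum(vapply(seq_along(lens), function(k)
      segcost(bounds[k] + 1, bounds[k + 1]), numeric(1))) +
      beta * length(cps)
    if (obj < best$objective - 1e-12) best <- list(objective = obj, cps = cps)
  }
  best
}

# brute-force best monotone chain: maximal subset of hits with strictly
# increasing query ranks (gaps <= max_gap) and strictly monotone subject
# ranks (either direction, gaps <= max_gap); returns the best size and the
# best total bit score among subsets of that size
brute_chain <- function(h, max_gap) {
  n <- nrow(h)
  valid <- function(idx, orient) {
    q <- h$q_rank[idx]; s <- h$s_rank[idx]
    o <- order(q)
    q <- q[o]; s <- s[o]
    if (any(diff(q) <= 0) || any(diff(q) > max_gap)) return(FALSE)
    d <- if (orient == "same") diff(s) else -diff(s)
    all(d > 0 & d <= max_gap)
  }
  best_size <- 0L; best_bit <- 0
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1) == 1)
    if (length(idx) < best_size) next
    if (valid(idx, "same") || valid(idx, "inverted")) {
      bit <- sum(h$bitscore[idx])
      if (length(idx) > best_size ||
          (length(idx) == best_size && bit > best_bit)) {
        best_size <- length(idx); best_bit <- bit
      }
    }
  }
  list(size = best_size, bitscore = best_bit)
}

# textbook step-up BH: adj_(i) = min_{j >= i} min(1, n p_(j) / j) on the
# sorted scale, mapped back to input order
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(n * ps[i:n] / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# explicit hypergeometric upper tail P(X >= k) via binomial coefficients
brute_hyper_tail <- function(k, K, M, m) {
  kk <- k:min(K, m)
  sum(choose(K, kk) * choose(M - K, m - kk)) / choose(M, m)
}

# step-by-step TMM factor for one sample against a reference, following the
# published recipe literally (log ratios, precision weights, double trim,
# weighted mean); independent of the package's vectorized code path
brute_tmm_pair <- function(obs, ref) {
  No <- sum(obs); Nr <- sum(ref)
  keep <- which(obs > 0 & ref > 0)
  M <- log2((obs[keep] / No) / (ref[keep] / Nr))
  A <- 0.5 * log2((obs[keep] / No) * (ref[keep] / Nr))
  w <- (No - obs[keep]) / (No * obs[keep]) +
       (Nr - ref[keep]) / (Nr * ref[keep])
  n <- length(M)
  loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
  loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}
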