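# independent oracles used to cross-check the implementation

# linear-interpolation quantile by direct sort-and-interpolate
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo >= n - 1) return(xs[n])
    xs[lo + 1] + (h - lo) * (xs[lo + 2] - xs[lo + 1])
  }, numeric(1))
}

# Mann-Whitney U of x over y (ties counted half)
oracle_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (min-tail doubling, capped at 1, as in the exact rank-sum convention)
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) oracle_U(pooled[i], pooled[-i]))
  u_obs <- oracle_U(x, y)
  mu <- n1 * length(y) / 2
  p <- if (u_obs > mu) 2 * mean(us >= u_obs)
       else if (u_obs < mu) 2 * mean(us <= u_obs)
       else 1
  min(1, p)
}

# tie-corrected Kruskal-Wallis H computed from first principles
oracle_kw_H <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact permutation p for Kruskal-Wallis with two groups
oracle_kw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  g_obs <- rep(1:2, c(length(x), length(y)))
  h_obs <- oracle_kw_H(pooled, g_obs)
  idx <- utils::combn(length(pooled), length(x))
  hs <- apply(idx, 2, function(i)
    oracle_kw_H(pooled, replace(rep(2L, length(pooled)), i, 1L)))
  mean(hs >= h_obs - 1e-12)
}

# diversity indices by naive elementwise summation
oracle_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  s <- length(counts)
  h <- 0; d <- 0
  for (c_i in counts) {
    p <- c_i / n
    h <- h - p * log(p)
    d <- d + p * p
  }
  list(shannon = h, simpson = 1 - d,
       margalef = if (n == 1) NA_real_ else (s - 1) / log(n),
       evenness = if (s == 1) NA_real_ else h / log(s))
}

# box-plot discrimination decided with independently coded interval logic
oracle_boxplot <- function(ref, imp) {
  qr <- oracle_quantile(ref, c(.25, .5, .75))
  qi <- oracle_quantile(imp, c(.25, .5, .75))
  overlap <- max(qr[1], qi[1]) <= min(qr[3], qi[3])
  if (!overlap) return("IQR-disjoint")
  ref_med_out <- !(qr[2] >= qi[1] && qr[2] <= qi[3])
  imp_med_out <- !(qi[2] >= qr[1] && qi[2] <= qr[3])
  if (ref_med_out && imp_med_out) "median-outside" else "none"
}
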