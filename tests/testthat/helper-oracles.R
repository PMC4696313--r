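# Independent oracles, coded from first principles and kept separate
# from the package implementation paths they check.

# normalized entropy via natural logs and an explicit accumulation loop
se_oracle <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  h <- 0
  for (v in x) {
    p <- v / s
    h <- h - p * log(p)
  }
  h / log(length(x))
}

cv_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  sqrt(ss / (n - 1)) / abs(m)
}

dse_oracle <- function(a, b) abs(se_oracle(a) - se_oracle(b))

# exact permutation p-value by enumerating every way of choosing which
# pooled positions form group 1 (all orderings of the pool are equally
# likely, and entropy ignores within-group order, so position subsets
# carry the whole permutation distribution)
exact_perm_p <- function(a, b) {
  obs <- dse_oracle(a, b)
  pooled <- c(a, b)
  n1 <- length(a)
  splits <- utils::combn(length(pooled), n1)
  hits <- 0
  for (j in seq_len(ncol(splits))) {
    g1 <- pooled[splits[, j]]
    g2 <- pooled[-splits[, j]]
    if (dse_oracle(g1, g2) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(splits)
}

# Fligner-Killeen two-group statistic from its definition: median-center
# each group on the log scale, rank the pooled absolute deviations
# (mid-ranks for ties), map rank r to the normal score
# qnorm(1/2 + r / (2 (N + 1))), and compare group mean scores
fk_oracle <- function(a, b, logfun = log) {
  l1 <- logfun(a)
  l2 <- logfun(b)
  d <- c(abs(l1 - median(l1)), abs(l2 - median(l2)))
  g <- rep(1:2, c(length(l1), length(l2)))
  n <- length(d)
  r <- rank(d)
  scores <- qnorm(0.5 + r / (2 * (n + 1)))
  abar <- mean(scores)
  v2 <- sum((scores - abar)^2) / (n - 1)
  stat <- sum(tapply(scores, g, length) *
                (tapply(scores, g, mean) - abar)^2) / v2
  list(statistic = unname(stat),
       p.value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# hand-coded step-down / step-up adjustments
bonferroni_oracle <- function(p) pmin(1, p * length(p))

holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

hochberg_oracle <- function(p) {
  m <- length(p)
  i <- m:1
  ps <- sort(p, decreasing = TRUE)
  adj <- pmin(1, cummin((m - i + 1) * ps))
  out <- numeric(m)
  out[order(p, decreasing = TRUE)] <- adj
  out
}

bh_oracle <- function(p) {
  m <- length(p)
  i <- m:1
  ps <- sort(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / i * ps))
  out <- numeric(m)
  out[order(p, decreasing = TRUE)] <- adj
  out
}

by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  i <- m:1
  ps <- sort(p, decreasing = TRUE)
  adj <- pmin(1, cummin(cm * m / i * ps))
  out <- numeric(m)
  out[order(p, decreasing = TRUE)] <- adj
  out
}

rand_pos_vec <- function(n = sample(2:15, 1)) {
  exp(rnorm(n, 0, 2))
}

fixture_path <- function(which) {
  system.file("extdata", paste0(which, "_synthetic.tsv"),
              package = "entrovar")
}
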