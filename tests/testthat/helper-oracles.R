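# Independent brute-force statistical references shared by the evaluation
# and acceptance tests. Deliberately plain (loops, explicit formulas) and
# disjoint from the package's implementation paths.

brute_rmse <- function(a, b) {
  acc <- 0; n <- 0
  for (i in seq_along(a)) { acc <- acc + (a[i] - b[i])^2; n <- n + 1 }
  sqrt(acc / n)
}

brute_quantile7 <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

brute_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

brute_t_paired <- function(x, y) {
  d <- y - x; n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  2 * stats::pt(-abs(tt), n - 1)
}

brute_f <- function(x, y) {
  f <- stats::var(y) / stats::var(x)
  p <- stats::pf(f, length(y) - 1, length(x) - 1)
  2 * min(p, 1 - p)
}
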