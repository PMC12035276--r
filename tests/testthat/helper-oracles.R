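# Independent brute-force oracles: naive loops only, no reuse of package code.

make_series <- function(values, start = "2021-03-01 00:00:00", step_min = 5,
                        id = "p1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  glucose_series(id, t0 + (seq_along(values) - 1) * step_min * 60, values,
                 quiet = TRUE)
}

oracle_mean <- function(v) {
  s <- 0
  for (x in v) s <- s + x
  s / length(v)
}

oracle_sd <- function(v) {
  m <- oracle_mean(v)
  s <- 0
  for (x in v) s <- s + (x - m)^2
  sqrt(s / (length(v) - 1))
}

oracle_tir <- function(v) {
  n_in <- n_lo <- n_hi <- 0
  for (x in v) {
    if (x < 70) n_lo <- n_lo + 1
    else if (x > 180) n_hi <- n_hi + 1
    else n_in <- n_in + 1
  }
  c(tir = 100 * n_in / length(v),
    tor_below_70 = 100 * n_lo / length(v),
    tor_above_180 = 100 * n_hi / length(v))
}

oracle_sd_roc <- function(time, value, max_gap = 15) {
  rates <- c()
  for (i in 2:length(value)) {
    dt <- as.numeric(difftime(time[i], time[i - 1], units = "mins"))
    if (dt > 0 && dt <= max_gap) {
      rates <- c(rates, (value[i] - value[i - 1]) / dt)
    }
  }
  oracle_sd(rates)
}

oracle_lbgi_hbgi <- function(v) {
  lo <- hi <- 0
  for (g in v) {
    f <- 1.509 * (log(g)^1.084 - 5.381)
    r <- 10 * f^2
    if (f < 0) lo <- lo + r
    if (f > 0) hi <- hi + r
  }
  c(lbgi = lo / length(v), hbgi = hi / length(v))
}

# type-7 (linear interpolation) quantile, written from the definition
oracle_quantile7 <- function(v, p) {
  x <- sort(v)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_skewness <- function(v) {
  m <- oracle_mean(v)
  m2 <- m3 <- 0
  for (x in v) {
    m2 <- m2 + (x - m)^2
    m3 <- m3 + (x - m)^3
  }
  m2 <- m2 / length(v)
  m3 <- m3 / length(v)
  m3 / m2^1.5
}

# exact two-sided Mann-Whitney p by enumerating all assignments of the
# pooled sample into the two groups (no ties assumed)
oracle_mw_exact <- function(a, b) {
  na <- length(a)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * length(b) / 2
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(i) sum(rk[i]) - na * (na + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# brute-force symmetric-difference distance on raw pair sets
oracle_pair_distance <- function(pairs_a, pairs_b) {
  inter <- 0
  for (p in pairs_a) if (p %in% pairs_b) inter <- inter + 1
  uni <- length(pairs_a) + length(pairs_b) - inter
  list(n_common = inter, distance = (uni - inter) / uni)
}

# adjusted Rand index from the contingency table definition
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

random_cgm_values <- function(n, lo = 45, hi = 395) {
  round(stats::runif(n, lo, hi))
}
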