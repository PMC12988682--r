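# Independent oracles used to cross-check the package's computations.
# These are deliberately naive re-implementations: enumeration, two-pass
# formulas, explicit loops.

# Pinball loss, written independently of the package.
oracle_pinball <- function(u, tau) {
  sum(ifelse(u >= 0, tau * u, (tau - 1) * u))
}

# Exact quantile regression by enumerating every basic solution:
# the LP optimum interpolates p observations, so try all p-subsets.
oracle_rq_enumerate <- function(X, y, tau) {
  n <- nrow(X)
  p <- ncol(X)
  best_loss <- Inf
  best_coef <- NULL
  combos <- utils::combn(n, p)
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    Xb <- X[idx, , drop = FALSE]
    if (abs(det(Xb)) < 1e-10) next
    b <- solve(Xb, y[idx])
    loss <- oracle_pinball(y - drop(X %*% b), tau)
    if (loss < best_loss) {
      best_loss <- loss
      best_coef <- b
    }
  }
  list(loss = best_loss, coefficients = best_coef)
}

# Two-pass sample moments.
oracle_moments <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(n = n, mean = m, sd = sqrt(sum((x - m)^2) / (n - 1)))
}

# Type-7 order-statistic interpolation, written out explicitly.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# 3x3 transition counts by an explicit double loop.
oracle_transitions <- function(colA, colB) {
  lv <- c("green", "yellow", "red")
  m <- matrix(0L, 3, 3, dimnames = list(from = lv, to = lv))
  for (i in seq_along(colA)) {
    m[colA[i], colB[i]] <- m[colA[i], colB[i]] + 1L
  }
  m
}

# Fixture cache: expensive shared cohorts are built once per test run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

rw_cohort <- function() {
  fixture("rw_cohort", function() {
    generate_healthy_cohort(rdb_cohort_config("large_rdb", seed = 4830))
  })
}

small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_healthy_cohort(rdb_cohort_config("small_rdb", seed = 398))
  })
}
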