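# Arbitrary-precision non-negative integers as little-endian digit vectors
# in base 1e7, used to evaluate the hypergeometric tail exactly,
# independently of the package's log-space implementation.

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% BIG_BASE)
    x <- x %/% BIG_BASE
  }
  d
}

big_trim <- function(a) {
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

big_add <- function(a, b) {
  l <- max(length(a), length(b))
  a <- c(a, rep(0, l - length(a)))
  b <- c(b, rep(0, l - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(l)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  if (carry > 0) s <- c(s, carry)
  s
}

big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s < BIG_BASE)
  if (s == 0) return(0)
  r <- a * s
  carry <- 0
  for (i in seq_along(r)) {
    r[i] <- r[i] + carry
    carry <- r[i] %/% BIG_BASE
    r[i] <- r[i] %% BIG_BASE
  }
  while (carry > 0) {
    r <- c(r, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  big_trim(r)
}

big_div_small <- function(a, s) {
  # exact division only (remainder must be zero)
  stopifnot(s > 0)
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]
    q[i] <- cur %/% s
    rem <- cur %% s
  }
  stopifnot(rem == 0)
  big_trim(q)
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

big_eq <- function(a, b) {
  a <- big_trim(a); b <- big_trim(b)
  length(a) == length(b) && all(a == b)
}

# exact binomial via the multiplicative formula (each step divides evenly)
big_choose <- function(n, r) {
  if (r < 0 || r > n) return(0)
  r <- min(r, n - r)
  acc <- big_from_int(1)
  for (i in seq_len(r)) {
    acc <- big_mul_small(acc, n - r + i)
    acc <- big_div_small(acc, i)
  }
  acc
}

# brute-force hypergeometric upper tail: exact integer numerator summed
# term by term, converted to double only for the final division
oracle_phasing_tail <- function(n, k, m = 10, p = 21) {
  if (k == 0) return(1)
  num <- 0
  for (j in k:m) {
    if (n - j < 0 || n - j > (p - 1) * m) next
    term <- big_mul_small(big_choose((p - 1) * m, n - j),
                          big_to_double(big_choose(m, j)))
    num <- big_add(num, term)
  }
  big_to_double(num) / big_to_double(big_choose(p * m, n))
}
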