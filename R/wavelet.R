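# Daubechies wavelet (extremal phase, 5 vanishing moments, 10-tap filter),
# periodized pyramid transform.  Used to split IC mixing curves into
# fine-scale (motion) and coarse-scale (enhancement) energy.

DB5_LO <- c(0.160102397974125, 0.603829269797473, 0.724308528438574,
            0.138428145901103, -0.242294887066190, -0.032244869585030,
            0.077571493840065, -0.006241490213012, -0.012580751999016,
            0.003335725285002)
DB5_HI <- rev(DB5_LO) * (-1)^(seq_along(DB5_LO) - 1)

dwt_step <- function(x, lo, hi) {
  n <- length(x)
  m <- n / 2
  a <- numeric(m); d <- numeric(m)
  for (i in seq_len(m)) {
    idx <- ((2 * (i - 1) + seq_along(lo) - 1) %% n) + 1
    a[i] <- sum(lo * x[idx])
    d[i] <- sum(hi * x[idx])
  }
  list(approx = a, detail = d)
}

idwt_step <- function(a, d, lo, hi) {
  m <- length(a)
  n <- 2 * m
  x <- numeric(n)
  for (i in seq_len(m)) {
    idx <- ((2 * (i - 1) + seq_along(lo) - 1) %% n) + 1
    x[idx] <- x[idx] + lo * a[i] + hi * d[i]
  }
  x
}

# periodized pyramid of a power-of-two-length signal; details ordered finest
# first.  The recursion stops once the signal is shorter than the filter —
# beyond that the wrapped (folded) filter is no longer orthonormal and the
# transform would stop being invertible.
dwt_db5 <- function(x) {
  n <- length(x)
  if (n < 2 || bitwAnd(n, n - 1L) != 0) stop("dwt_db5 needs a power-of-two length")
  details <- list()
  a <- x
  while (length(a) >= length(DB5_LO)) {
    st <- dwt_step(a, DB5_LO, DB5_HI)
    details[[length(details) + 1L]] <- st$detail
    a <- st$approx
  }
  list(details = details, approx = a)
}

idwt_db5 <- function(w) {
  a <- w$approx
  for (lev in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[lev]], DB5_LO, DB5_HI)
  a
}

# reflect-pad to the next power of two
pad_pow2 <- function(x) {
  n <- length(x)
  n2 <- 2^ceiling(log2(n))
  if (n2 == n) return(list(x = x, n = n))
  pad <- n2 - n
  list(x = c(x, rev(x)[seq_len(pad)]), n = n)
}
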