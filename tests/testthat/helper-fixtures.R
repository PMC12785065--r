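# Small in-code fixtures shared across test files.

# dx1/dt = 0.1 x2 ; dx2/dt = -0.05 x1  (the linear toy system)
linear_toy_system <- function() {
  monomial_system(2, list(
    monomial(1, 0.1, c(0, 1), sign = 1),
    monomial(2, 0.05, c(1, 0), sign = -1)))
}

# single monomial F1 = 3 x1^2 x2^-1, F2 = 0
single_monomial_system <- function() {
  monomial_system(2, list(monomial(1, 3, c(2, -1))))
}

# constant-rate model: F identically equal to `rates`
constant_rate_model <- function(rates, dt = 1) {
  d <- length(rates)
  W2 <- matrix(0, d, d)
  b2 <- log(abs(rates) + (rates == 0))    # log|c|; zero rate handled via V
  V <- diag(ifelse(rates == 0, 0, sign(rates)))
  lazynet_model(lle_block(diag(d), numeric(d), W2, b2), V, dt = dt)
}

# deterministic toy count matrix with known QC pass/fail pattern
toy_counts <- function() {
  m <- matrix(0L, 5, 5,
              dimnames = list(paste0("g", 1:5), paste0("c", 1:5)))
  m["g1", ] <- c(5L, 3L, 2L, 1L, 4L)   # detected in 5 cells
  m["g2", ] <- c(0L, 2L, 1L, 0L, 3L)   # detected in 3 cells
  m["g3", ] <- c(1L, 0L, 0L, 0L, 2L)   # detected in 2 cells -> dropped
  m["g4", ] <- c(2L, 2L, 2L, 0L, 0L)   # detected in 3 cells
  m["g5", ] <- c(0L, 1L, 1L, 1L, 0L)   # detected in 3 cells
  m
}

# toy protein table with flags, duplicates and zeros
toy_protein_table <- function() {
  data.frame(
    symbol = c("gpx4", "GPX4", "Acsl4", "rev1", "cont1", "Sod2"),
    reverse = c("", "", "", "+", "", ""),
    contaminant = c("", "", "", "", "+", ""),
    intensity_a = c(2, 4, 10, 99, 99, 0),
    intensity_b = c(6, 8, 12, 99, 99, 5),
    intensity_c = c(3, 5, 14, 99, 99, 7),
    stringsAsFactors = FALSE)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
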