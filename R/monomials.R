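# Ground-truth monomial rate laws: dx_i/dt = sum_k s_k c_k prod_j x_j^alpha_kj.
# These systems drive the simulators and serve as exact oracles for the
# log-linear-exp embedding.

#' Monomial rate-law term
#'
#' A single signed monomial `s * c * prod_j x_j^alpha_j` contributing to the
#' rate of one output gene. Positive sign encodes production, negative decay.
#'
#' @param gene integer index of the output gene the term feeds.
#' @param coefficient strictly positive rate constant `c`.
#' @param exponents numeric exponent vector `alpha` (length = system dimension).
#' @param sign `+1` (production) or `-1` (decay).
#' @return A list of class `monomial`.
#' @export
monomial <- function(gene, coefficient, exponents, sign = 1) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient) || coefficient <= 0)
    stop_lazynet("monomial coefficient must be a positive finite scalar",
                 class = "lazynet_validation_error")
  check_finite(exponents, "monomial exponents")
  if (!sign %in% c(-1, 1))
    stop_lazynet("sign must be +1 or -1", class = "lazynet_validation_error")
  structure(list(gene = as.integer(gene), coefficient = as.numeric(coefficient),
                 exponents = as.numeric(exponents), sign = sign),
            class = "monomial")
}

#' Monomial dynamical system
#'
#' A sparse polynomial (power-law) ODE over `d` genes, stored as a list of
#' signed [monomial()] terms. A gene with no terms has rate exactly zero.
#'
#' @param d system dimension (number of genes).
#' @param terms list of [monomial()] objects; each exponent vector must have
#'   length `d`.
#' @param gene_ids optional gene symbols (defaults to `g1..gd`).
#' @return An object of class `monomial_system`.
#' @export
monomial_system <- function(d, terms, gene_ids = NULL) {
  d <- as.integer(d)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(d))
  if (length(gene_ids) != d || anyDuplicated(gene_ids))
    stop_lazynet("gene_ids must be %d unique symbols", d,
                 class = "lazynet_validation_error")
  for (tm in terms) {
    if (!inherits(tm, "monomial"))
      stop_lazynet("terms must be monomial objects",
                   class = "lazynet_validation_error")
    if (length(tm$exponents) != d)
      stop_lazynet("exponent vector length %d, expected %d",
                   length(tm$exponents), d, class = "lazynet_shape_error")
    if (tm$gene < 1L || tm$gene > d)
      stop_lazynet("term output gene %d outside 1..%d", tm$gene, d,
                   class = "lazynet_validation_error")
  }
  structure(list(d = d, gene_ids = gene_ids, terms = terms),
            class = "monomial_system")
}

#' @export
print.monomial_system <- function(x, ...) {
  cat(sprintf("Monomial system: %d genes, %d terms\n", x$d, length(x$terms)))
  invisible(x)
}

#' Evaluate a monomial system's rate law
#'
#' Direct evaluation of `F(x)`: for each gene, the signed sum of its monomial
#' terms at the positive state `x`. Used as the exact oracle for the
#' log-linear-exp embedding and as the generator inside the simulators.
#'
#' @param system a [monomial_system()].
#' @param x strictly positive numeric state of length `d`.
#' @return Numeric rate vector of length `d`.
#' @export
monomial_rates <- function(system, x) {
  x <- as_state_vector(x, system$d, "state")
  check_positive_state(x)
  rates <- numeric(system$d)
  lx <- log(x)
  for (tm in system$terms) {
    rates[tm$gene] <- rates[tm$gene] +
      tm$sign * tm$coefficient * exp(sum(tm$exponents * lx))
  }
  rates
}

#' Interaction support of a monomial system
#'
#' The ground-truth directed interaction pattern: entry `[j, i]` is 1 when
#' gene `j` appears with a nonzero exponent in some rate term of gene `i`
#' (rows are sources, columns targets — the same orientation as
#' [compute_elasticity()]).
#'
#' @param system a [monomial_system()].
#' @return A `d x d` 0/1 matrix with gene ids as dimnames.
#' @export
support_matrix <- function(system) {
  S <- matrix(0, system$d, system$d,
              dimnames = list(system$gene_ids, system$gene_ids))
  for (tm in system$terms) {
    nz <- which(tm$exponents != 0)
    S[nz, tm$gene] <- 1
  }
  S
}

#' Sample a random sparse monomial system
#'
#' Draws `K` signed monomial terms: each term feeds a uniformly chosen output
#' gene and has at most `ceiling(sparsity * d)` nonzero integer exponents
#' drawn from `exponent_set`, with a log-uniform coefficient in
#' `coefficient_range`.
#'
#' @param d system dimension.
#' @param K number of monomial terms.
#' @param sparsity fraction in `(0, 1]` bounding nonzero exponents per term.
#' @param exponent_set integer candidate exponents (zero excluded).
#' @param coefficient_range positive range for log-uniform coefficients.
#' @param seed integer seed; draws are bit-reproducible per seed.
#' @return A [monomial_system()] with attribute `"support"` — the planted
#'   interaction support matrix.
#' @export
sample_monomial_system <- function(d, K, sparsity = 0.15,
                                   exponent_set = c(-2L, -1L, 1L, 2L),
                                   coefficient_range = c(0.1, 1),
                                   seed = 1L) {
  if (K < 1L || sparsity <= 0 || sparsity > 1)
    stop_lazynet("need K >= 1 and 0 < sparsity <= 1",
                 class = "lazynet_validation_error")
  set.seed(seed)
  max_nz <- max(1L, ceiling(sparsity * d))
  terms <- vector("list", K)
  for (k in seq_len(K)) {
    n_nz <- sample.int(max_nz, 1L)
    idx <- sample.int(d, n_nz)
    alpha <- numeric(d)
    alpha[idx] <- sample(exponent_set, n_nz, replace = TRUE)
    co <- exp(runif(1, log(coefficient_range[1]), log(coefficient_range[2])))
    terms[[k]] <- monomial(gene = sample.int(d, 1L), coefficient = co,
                           exponents = alpha,
                           sign = sample(c(-1, 1), 1L))
  }
  sys <- monomial_system(d, terms)
  attr(sys, "support") <- support_matrix(sys)
  sys
}
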