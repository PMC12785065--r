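# One-step log-linear-exp (LLE) dynamics.
#
# A block computes m(x) = exp(W2 %*% log(pmax(W1 %*% x + b1, eps)) + b2),
# one strictly positive monomial-like rate per hidden unit.  The Euler-step
# model maps those rates to gene space through a signed output matrix V and
# applies one explicit Euler update:
#   x' = clamp(x + dt * V %*% m(x), eps).
# With W1 = I, b1 = 0, exponent rows in W2, log-coefficients in b2 and
# +/-1 entries in V, this reproduces any finite monomial rate law exactly.

#' Log-linear-exp residual block
#'
#' @param W1 `H x d` inner weight matrix (identity for exact monomial models).
#' @param b1 inner bias (length `H`); together with `W1 x` it forms the
#'   argument of the elementwise log, clamped below at `eps_floor`.
#' @param W2 `M x H` exponent matrix: row `k` holds the exponents of hidden
#'   rate unit `k`.
#' @param b2 log-coefficient bias (length `M`).
#' @param eps_floor small positive clamp applied to the log argument, keeping
#'   gradients finite when `W1 x + b1` drifts non-positive during training.
#' @return An object of class `lle_block`.
#' @export
lle_block <- function(W1, b1, W2, b2, eps_floor = 1e-8) {
  W1 <- as.matrix(W1); W2 <- as.matrix(W2)
  b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  if (length(b1) != nrow(W1) || ncol(W2) != nrow(W1) || length(b2) != nrow(W2))
    stop_lazynet("inconsistent LLE block shapes: W1 %dx%d, b1 %d, W2 %dx%d, b2 %d",
                 nrow(W1), ncol(W1), length(b1), nrow(W2), ncol(W2), length(b2),
                 class = "lazynet_shape_error")
  if (!is.numeric(eps_floor) || eps_floor <= 0)
    stop_lazynet("eps_floor must be positive", class = "lazynet_validation_error")
  for (nm in c("W1", "b1", "W2", "b2"))
    check_finite(get(nm), sprintf("LLE block %s", nm))
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 eps_floor = eps_floor),
            class = "lle_block")
}

#' Forward pass of the log-linear-exp block
#'
#' Computes `exp(W2 %*% log(pmax(W1 %*% x + b1, eps_floor)) + b2)`: one
#' strictly positive rate per hidden unit (row of `W2`). When each row of
#' `W2` carries an exponent vector and `b2` the log-coefficient, every output
#' is exactly one monomial `c * prod_j x_j^alpha_j`.
#'
#' @param x strictly positive state vector (length `d`) or `d x n` matrix of
#'   column states.
#' @param block an [lle_block()].
#' @return Positive rate vector of length `M = nrow(W2)` (or `M x n` matrix).
#' @export
lle_forward <- function(x, block) {
  stopifnot(inherits(block, "lle_block"))
  vec <- !is.matrix(x)
  X <- if (vec) matrix(as_state_vector(x), ncol = 1) else x
  if (nrow(X) != ncol(block$W1))
    stop_lazynet("state dimension %d does not match block input dimension %d",
                 nrow(X), ncol(block$W1), class = "lazynet_shape_error")
  if (any(!is.finite(X)) || (vec && any(X <= 0)))
    stop_lazynet("state must be strictly positive and finite",
                 class = "lazynet_validation_error")
  A <- pmax(block$W1 %*% X + block$b1, block$eps_floor)
  R <- exp(block$W2 %*% log(A) + block$b2)
  if (vec) as.numeric(R) else R
}

#' One-step Euler model
#'
#' Couples an [lle_block()] with a signed output matrix `V` (`d x M`) and a
#' step size `dt`, realizing `x' = x + dt * V %*% lle_forward(x)`. The signed
#' combination lets hidden rate units act as production (+) or decay (-)
#' terms, so expression can both rise and fall.
#'
#' @param block an [lle_block()].
#' @param V `d x M` signed output matrix (`M = nrow(block$W2)`).
#' @param dt positive Euler step size; absolute rates are not identifiable
#'   from two snapshots, so `dt` is conventionally 1 for fitted models and
#'   folds into `b2` (see [euler_step()] details).
#' @param gene_ids optional gene symbols of length `d`.
#' @return An object of class `lazynet_model`.
#' @export
lazynet_model <- function(block, V, dt = 1, gene_ids = NULL) {
  stopifnot(inherits(block, "lle_block"))
  V <- as.matrix(V)
  if (ncol(V) != nrow(block$W2))
    stop_lazynet("V has %d columns, block has %d hidden units",
                 ncol(V), nrow(block$W2), class = "lazynet_shape_error")
  if (nrow(V) != ncol(block$W1))
    stop_lazynet("V has %d rows, block input dimension is %d",
                 nrow(V), ncol(block$W1), class = "lazynet_shape_error")
  if (!is.numeric(dt) || dt <= 0)
    stop_lazynet("dt must be positive", class = "lazynet_validation_error")
  check_finite(V, "V")
  d <- nrow(V)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(d))
  if (length(gene_ids) != d || anyDuplicated(gene_ids))
    stop_lazynet("gene_ids must be %d unique symbols", d,
                 class = "lazynet_validation_error")
  structure(list(block = block, V = V, dt = dt, gene_ids = gene_ids, d = d),
            class = "lazynet_model")
}

#' @export
print.lazynet_model <- function(x, ...) {
  cat(sprintf("LazyNet one-step model: %d genes, %d hidden rate units, dt = %g\n",
              x$d, nrow(x$block$W2), x$dt))
  invisible(x)
}

model_rate <- function(model, X) {
  model$V %*% lle_forward(X, model$block)
}

#' One explicit Euler update
#'
#' `x' = pmax(x + dt * V %*% lle_forward(x), eps_floor)`; the clamp preserves
#' positivity of the state. Supplying `sign_weights` overrides the model's
#' output matrix `V` with `sign_weights * |V|` row-wise signs — convenient
#' when probing production/decay decompositions.
#'
#' @param state positive state vector or `d x n` matrix of column states.
#' @param model a [lazynet_model()].
#' @param sign_weights optional per-output sign vector (length `d`).
#' @return Updated state, same shape as the input.
#' @export
euler_step <- function(state, model, sign_weights = NULL) {
  stopifnot(inherits(model, "lazynet_model"))
  vec <- !is.matrix(state)
  X <- if (vec) matrix(as_state_vector(state, model$d), ncol = 1) else state
  if (any(!is.finite(X)) || any(X <= 0))
    stop_lazynet("state must be strictly positive", class = "lazynet_validation_error")
  V <- model$V
  if (!is.null(sign_weights)) {
    if (length(sign_weights) != model$d)
      stop_lazynet("sign_weights length %d, expected %d",
                   length(sign_weights), model$d, class = "lazynet_shape_error")
    V <- sign_weights * abs(V)
  }
  out <- pmax(X + model$dt * (V %*% lle_forward(X, model$block)),
              model$block$eps_floor)
  if (vec) {
    out <- as.numeric(out)
    names(out) <- model$gene_ids
  }
  out
}

#' Embed a monomial system exactly
#'
#' Builds a [lazynet_model()] that reproduces `monomial_rates(system, x)` to
#' machine precision on positive states: the inner layer is the identity
#' (`W1 = I`, `b1 = 0`), each hidden unit carries one term's exponent vector
#' in its `W2` row and `log(c)` in `b2`, and `V` routes the term to its
#' output gene with its sign. The embedded `K`-term law therefore uses
#' `K * (d + 1)` trainable scalars plus signs.
#'
#' @param system a [monomial_system()].
#' @param dt Euler step size of the returned model.
#' @param eps_floor log-argument clamp (must sit below any simulated state).
#' @return A [lazynet_model()].
#' @export
embed_monomial_system <- function(system, dt = 1, eps_floor = 1e-8) {
  stopifnot(inherits(system, "monomial_system"))
  d <- system$d
  K <- length(system$terms)
  if (K == 0L) {
    W2 <- matrix(0, 1, d); b2 <- -Inf
    stop_lazynet("system has no terms; use a zero-rate term list per gene",
                 class = "lazynet_validation_error")
  }
  W2 <- matrix(0, K, d)
  b2 <- numeric(K)
  V <- matrix(0, d, K)
  for (k in seq_len(K)) {
    tm <- system$terms[[k]]
    W2[k, ] <- tm$exponents
    b2[k] <- log(tm$coefficient)
    V[tm$gene, k] <- tm$sign
  }
  block <- lle_block(W1 = diag(d), b1 = numeric(d), W2 = W2, b2 = b2,
                     eps_floor = eps_floor)
  lazynet_model(block, V, dt = dt, gene_ids = system$gene_ids)
}

#' Count trainable scalars of a model
#'
#' For an embedded `K`-term law over `d` genes this is `K * (d + 1)`
#' (exponent rows plus log-coefficients); the +/-1 routing entries of `V`
#' are signs, not trained scalars.
#'
#' @param model a [lazynet_model()].
#' @param embedded if `TRUE`, count only exponents and coefficients (the
#'   exact-embedding parameter count); otherwise count all free parameters
#'   including `V` and `b1`.
#' @return Integer count.
#' @export
n_trainable <- function(model, embedded = TRUE) {
  K <- nrow(model$block$W2)
  if (embedded) K * (model$d + 1L)
  else length(model$block$W2) + length(model$block$b2) +
    length(model$block$b1) + length(model$V)
}

# Ensembles -------------------------------------------------------------------

new_lazynet_ensemble <- function(members, gene_ids, extra = list()) {
  if (length(members) == 0L)
    stop_lazynet("ensemble must be non-empty", class = "lazynet_validation_error")
  d <- members[[1]]$d
  for (m in members) {
    if (!inherits(m, "lazynet_model") || m$d != d ||
        !identical(m$gene_ids, gene_ids))
      stop_lazynet("ensemble members must share dimension and gene panel",
                   class = "lazynet_validation_error")
  }
  structure(c(list(members = members, gene_ids = gene_ids, d = d), extra),
            class = "lazynet")
}

#' Build an ensemble from fitted or embedded models
#'
#' @param members list of dimension-compatible [lazynet_model()] objects.
#' @return An object of class `lazynet` (see [lazynet()] for the fitted
#'   flavour with training metadata).
#' @export
lazynet_ensemble <- function(members) {
  new_lazynet_ensemble(members, members[[1]]$gene_ids)
}

#' Ensemble one-step prediction
#'
#' Arithmetic mean of the members' [euler_step()] outputs — the inference
#' rule used for replicate ensembles.
#'
#' @param state positive state vector or `d x n` matrix.
#' @param ensemble a `lazynet` ensemble.
#' @return Mean updated state, same shape as the input.
#' @export
ensemble_predict <- function(state, ensemble) {
  stopifnot(inherits(ensemble, "lazynet"))
  preds <- lapply(ensemble$members, function(m) euler_step(state, m))
  out <- Reduce(`+`, preds) / length(preds)
  out
}
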