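# Fitting one-step LLE models to two-snapshot pairs by first-order
# (Adam-style) minimization of a Huber loss.  The inner layer is held at the
# identity with a learnable positive offset b1, so every hidden unit is a
# learnable monomial in the (shifted) inputs; the signed output map V is
# learned freely.  Gradients are closed-form, so fitting is plain R matrix
# algebra and bitwise reproducible per seed.

#' Snapshot pair container
#'
#' Training data for the one-step model: a time-0 state, the observed
#' post-perturbation state, and a group key `(target_gene, guide_id, batch)`
#' used for leakage-safe splitting.
#'
#' @param time0 `d x n` matrix of time-0 states (genes in rows, strictly
#'   positive on the working scale).
#' @param post `d x n` matrix of matched post states.
#' @param groups data frame with `n` rows and columns `target_gene`,
#'   `guide_id` and optionally `batch`.
#' @param gene_ids gene symbols (defaults to `rownames(time0)`).
#' @return An object of class `snapshot_pairs`.
#' @export
snapshot_pairs <- function(time0, post, groups, gene_ids = rownames(time0)) {
  time0 <- as.matrix(time0); post <- as.matrix(post)
  if (!identical(dim(time0), dim(post)))
    stop_lazynet("time0 and post must have identical dimensions",
                 class = "lazynet_shape_error")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(time0)))
  if (nrow(groups) != ncol(time0))
    stop_lazynet("groups must have one row per pair",
                 class = "lazynet_shape_error")
  if (!all(c("target_gene", "guide_id") %in% names(groups)))
    stop_lazynet("groups needs target_gene and guide_id columns",
                 class = "lazynet_validation_error")
  if (is.null(groups$batch)) groups$batch <- "batch0"
  groups$key <- paste(groups$target_gene, groups$guide_id, groups$batch,
                      sep = "|")
  rownames(time0) <- rownames(post) <- gene_ids
  structure(list(time0 = time0, post = post, groups = groups,
                 gene_ids = gene_ids),
            class = "snapshot_pairs")
}

#' @export
print.snapshot_pairs <- function(x, ...) {
  cat(sprintf("%d snapshot pairs over %d genes (%d groups)\n",
              ncol(x$time0), nrow(x$time0), length(unique(x$groups$key))))
  invisible(x)
}

#' @export
length.snapshot_pairs <- function(x) ncol(x$time0)

#' Subset snapshot pairs by pair index
#' @param x a [snapshot_pairs()] object.
#' @param i integer or logical index over pairs.
#' @param ... unused.
#' @export
`[.snapshot_pairs` <- function(x, i, ...) {
  snapshot_pairs(x$time0[, i, drop = FALSE], x$post[, i, drop = FALSE],
                 x$groups[i, , drop = FALSE], x$gene_ids)
}

#' Huber loss
#'
#' Mean over elements of `0.5 e^2` for `|e| <= delta` and
#' `delta (|e| - 0.5 delta)` beyond, with `e = pred - target`. The small
#' default `delta` keeps heavy-tailed single-cell targets from dominating
#' the fit.
#'
#' @param pred,target equal-length numeric vectors or matrices.
#' @param delta positive transition point.
#' @return Scalar mean loss.
#' @export
huber_loss <- function(pred, target, delta = 0.1) {
  if (length(pred) == 0L || length(pred) != length(target))
    stop_lazynet("pred and target must be non-empty and of equal length",
                 class = "lazynet_validation_error")
  if (delta <= 0)
    stop_lazynet("delta must be positive", class = "lazynet_validation_error")
  e <- abs(as.numeric(pred) - as.numeric(target))
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}

# One Adam-fitted replica; returns a lazynet_model plus its loss history.
fit_replica <- function(X, Y, width, delta, lr, epochs, dt, eps_floor,
                        seed, weight_decay = 1e-4, val = NULL,
                        wall_time = Inf, u_cap = 30, eval_every = 25L) {
  d <- nrow(X); n <- ncol(X)
  set.seed(seed)
  W2 <- matrix(rnorm(width * d, sd = 0.05), width, d)
  b2 <- rnorm(width, mean = -2, sd = 0.1)
  b1 <- rep(1, d)
  V  <- matrix(rnorm(d * width, sd = 0.05), d, width)
  pars <- list(W2 = W2, b2 = b2, b1 = b1, V = V)
  mom <- lapply(pars, function(p) p * 0)
  vel <- lapply(pars, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  t0 <- Sys.time()
  history <- numeric(0)
  best <- list(loss = Inf, pars = pars)

  forward <- function(p, Xin) {
    A <- pmax(Xin + p$b1, eps_floor)
    Z <- log(A)
    U <- p$W2 %*% Z + p$b2
    U <- pmin(U, u_cap)
    Mh <- exp(U)
    P <- Xin + dt * (p$V %*% Mh)
    list(A = A, Z = Z, U = U, Mh = Mh, P = P)
  }

  for (ep in seq_len(epochs)) {
    fw <- forward(pars, X)
    E <- fw$P - Y
    ae <- abs(E)
    loss <- mean(ifelse(ae <= delta, 0.5 * E^2, delta * (ae - 0.5 * delta)))
    if (!is.finite(loss))
      stop_lazynet("training diverged (non-finite Huber loss at epoch %d); lower the learning rate or width",
                   ep, class = "lazynet_nan_error")
    history[ep] <- loss
    G <- pmin(pmax(E, -delta), delta) / length(E)
    dV  <- dt * (G %*% t(fw$Mh)) + weight_decay * pars$V
    dMh <- dt * (t(pars$V) %*% G)
    dU  <- dMh * fw$Mh * (fw$U < u_cap)
    dW2 <- dU %*% t(fw$Z) + weight_decay * pars$W2
    db2 <- rowSums(dU)
    dZ  <- t(pars$W2) %*% dU
    db1 <- rowSums(dZ * ((X + pars$b1 > eps_floor) / fw$A))
    grads <- list(W2 = dW2, b2 = db2, b1 = db1, V = dV)
    corr1 <- 1 - beta1^ep; corr2 <- 1 - beta2^ep
    for (nm in names(pars)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      pars[[nm]] <- pars[[nm]] -
        lr * (mom[[nm]] / corr1) / (sqrt(vel[[nm]] / corr2) + aeps)
    }
    if (!is.null(val) && (ep %% eval_every == 0L || ep == epochs)) {
      vp <- forward(pars, val$X)$P
      vl <- huber_loss(vp, val$Y, delta)
      if (vl < best$loss) best <- list(loss = vl, pars = pars)
    }
    if (as.numeric(difftime(Sys.time(), t0, units = "secs")) > wall_time)
      break
  }
  final <- if (!is.null(val) && is.finite(best$loss)) best$pars else pars
  block <- lle_block(W1 = diag(d), b1 = final$b1, W2 = final$W2,
                     b2 = final$b2, eps_floor = eps_floor)
  list(model = lazynet_model(block, final$V, dt = dt), history = history)
}

#' Fit a LazyNet ensemble to snapshot pairs
#'
#' Trains `replicas` independently seeded one-step LLE models by Adam-style
#' gradient descent on the mean Huber loss of one-step predictions, and
#' returns them as an ensemble whose prediction is the arithmetic mean of
#' member predictions. Fitting is deterministic for a fixed `seed`.
#'
#' @param pairs a [snapshot_pairs()] object with strictly positive states
#'   (zeros on the working log scale are tolerated: the inner offset `b1`
#'   keeps log arguments positive).
#' @param width hidden width — number of learnable monomial rate units.
#' @param replicas number of ensemble members (independent seeds).
#' @param delta Huber transition point.
#' @param lr learning rate.
#' @param epochs maximum training epochs (full-batch).
#' @param weight_decay L2 penalty on the exponent matrix `W2` and output
#'   map `V`; screen-style inputs vary along few directions, so a mild
#'   ridge keeps the interpolant's gradients identified.
#' @param dt Euler step size, fixed during training: with two snapshots only
#'   the product of step size and rate is identifiable, so `dt` folds into
#'   the log-coefficients `b2` (`dt = a` is exactly `dt = 1` with
#'   `b2 + log a`).
#' @param eps_floor log-argument clamp.
#' @param val_pairs optional held-out [snapshot_pairs()]; when given, the
#'   checkpoint with the best validation Huber loss is kept.
#' @param wall_time wall-clock cap in seconds per replica; the last
#'   checkpoint produced within the cap is used.
#' @param seed integer seed; replica `r` uses `seed + r - 1`.
#' @return An object of class `lazynet` with elements `members`,
#'   `loss_history`, `config`, and the training `pairs`.
#' @seealso [predict.lazynet()], [compute_elasticity()], [ensemble_predict()]
#' @export
lazynet <- function(pairs, width = 64L, replicas = 3L, delta = 0.1,
                    lr = 0.02, epochs = 1500L, weight_decay = 1e-4,
                    dt = 1, eps_floor = 1e-8,
                    val_pairs = NULL, wall_time = Inf, seed = 1L) {
  stopifnot(inherits(pairs, "snapshot_pairs"))
  if (ncol(pairs$time0) < 1L)
    stop_lazynet("need at least one snapshot pair",
                 class = "lazynet_validation_error")
  if (replicas < 1L)
    stop_lazynet("replicas must be >= 1", class = "lazynet_validation_error")
  val <- if (!is.null(val_pairs)) list(X = val_pairs$time0, Y = val_pairs$post)
  fits <- lapply(seq_len(replicas), function(r) {
    fit_replica(pairs$time0, pairs$post, width = width, delta = delta,
                lr = lr, epochs = epochs, dt = dt, eps_floor = eps_floor,
                seed = seed + r - 1L, weight_decay = weight_decay,
                val = val, wall_time = wall_time)
  })
  members <- lapply(fits, function(f) {
    f$model$gene_ids <- pairs$gene_ids
    f$model
  })
  new_lazynet_ensemble(
    members, pairs$gene_ids,
    extra = list(loss_history = lapply(fits, `[[`, "history"),
                 config = list(width = width, replicas = replicas,
                               delta = delta, lr = lr, epochs = epochs,
                               weight_decay = weight_decay,
                               dt = dt, eps_floor = eps_floor, seed = seed),
                 pairs = pairs, call = match.call()))
}

#' @export
print.lazynet <- function(x, ...) {
  cat(sprintf("LazyNet ensemble: %d member(s), %d genes", length(x$members), x$d))
  if (!is.null(x$config))
    cat(sprintf(", width %d, Huber delta %g", x$config$width, x$config$delta))
  cat("\n")
  if (!is.null(x$loss_history)) {
    fin <- vapply(x$loss_history, function(h) h[length(h)], numeric(1))
    cat(sprintf("final training Huber loss: %s\n",
                paste(signif(fin, 4), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.lazynet <- function(object, ...) {
  out <- list(n_members = length(object$members), d = object$d,
              config = object$config)
  if (!is.null(object$pairs)) {
    pred <- predict(object, object$pairs)
    out$train_metrics <- evaluate_regression(pred, object$pairs$post)
    out$train_huber <- huber_loss(pred, object$pairs$post,
                                  object$config$delta %||% 0.1)
  }
  structure(out, class = "summary.lazynet")
}

#' @export
print.summary.lazynet <- function(x, ...) {
  cat(sprintf("LazyNet ensemble: %d member(s), %d genes\n", x$n_members, x$d))
  if (!is.null(x$train_metrics)) {
    m <- x$train_metrics
    cat(sprintf("training one-step fit: RMSE %.4g, MAE %.4g, Pearson r %.4g, Huber %.4g\n",
                m$rmse, m$mae, m$pearson_r, x$train_huber))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict one-step responses from a fitted ensemble
#'
#' @param object a `lazynet` ensemble.
#' @param newdata a [snapshot_pairs()] object (its `time0` states are used)
#'   or a `d x n` matrix of positive states; defaults to the training pairs.
#' @param ... unused.
#' @return `d x n` matrix of ensemble-mean one-step predictions.
#' @export
predict.lazynet <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$pairs$time0
       else if (inherits(newdata, "snapshot_pairs")) newdata$time0
       else as.matrix(newdata)
  ensemble_predict(X, object)
}

#' @export
fitted.lazynet <- function(object, ...) predict(object)

#' @export
residuals.lazynet <- function(object, ...) {
  if (is.null(object$pairs))
    stop_lazynet("ensemble carries no training pairs",
                 class = "lazynet_validation_error")
  object$pairs$post - predict(object)
}

#' @export
coef.lazynet <- function(object, ...) {
  lapply(object$members, function(m)
    list(W1 = m$block$W1, b1 = m$block$b1, W2 = m$block$W2, b2 = m$block$b2,
         V = m$V, dt = m$dt))
}

#' Simulate multi-step trajectories from a fitted ensemble
#'
#' Iterates the ensemble-mean Euler update from a starting state. Because
#' only the product of rate and step size is identified from two snapshots,
#' multi-step trajectories are qualitative extrapolations.
#'
#' @param object a `lazynet` ensemble.
#' @param nsim number of Euler steps.
#' @param seed ignored (the update is deterministic); kept for the generic.
#' @param state starting positive state (defaults to the mean training time-0).
#' @param ... unused.
#' @return `d x (nsim + 1)` matrix of states, first column the start.
#' @export
simulate.lazynet <- function(object, nsim = 1, seed = NULL, state = NULL, ...) {
  if (is.null(state)) {
    if (is.null(object$pairs))
      stop_lazynet("supply a starting state", class = "lazynet_validation_error")
    state <- rowMeans(object$pairs$time0)
  }
  out <- matrix(NA_real_, object$d, nsim + 1,
                dimnames = list(object$gene_ids, NULL))
  out[, 1] <- state
  for (s in seq_len(nsim)) {
    state <- pmax(as.numeric(ensemble_predict(matrix(state, ncol = 1), object)),
                  object$members[[1]]$block$eps_floor)
    out[, s + 1] <- state
  }
  out
}

#' @export
plot.lazynet <- function(x, ...) {
  if (is.null(x$loss_history))
    stop_lazynet("no loss history recorded", class = "lazynet_validation_error")
  hs <- x$loss_history
  graphics::matplot(seq_along(hs[[1]]),
                    do.call(cbind, lapply(hs, function(h) h[seq_along(hs[[1]])])),
                    type = "l", lty = 1, xlab = "epoch",
                    ylab = "training Huber loss", main = "LazyNet training",
                    ...)
  invisible(x)
}

# Serialization ---------------------------------------------------------------

model_to_list <- function(m) {
  list(W1 = m$block$W1, b1 = m$block$b1, W2 = m$block$W2, b2 = m$block$b2,
       eps_floor = m$block$eps_floor, V = m$V, dt = m$dt,
       gene_ids = m$gene_ids)
}

model_from_list <- function(l) {
  block <- lle_block(do.call(rbind, lapply(l$W1, unlist)), unlist(l$b1),
                     do.call(rbind, lapply(l$W2, unlist)), unlist(l$b2),
                     eps_floor = l$eps_floor)
  lazynet_model(block, do.call(rbind, lapply(l$V, unlist)), dt = l$dt,
                gene_ids = unlist(l$gene_ids))
}

#' Write a model or ensemble to a single-file JSON container
#'
#' Stores all weights (`W1`, `b1`, `W2`, `b2`, signs/`V`), `eps_floor`,
#' `dt`, gene ids and the fitting seed at full double precision.
#'
#' @param object a `lazynet_model` or `lazynet` ensemble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lazynet <- function(object, path) {
  payload <- if (inherits(object, "lazynet_model")) {
    list(type = "lazynet_model", model = model_to_list(object))
  } else if (inherits(object, "lazynet")) {
    list(type = "lazynet_ensemble",
         members = lapply(object$members, model_to_list),
         seed = object$config$seed %||% NA)
  } else stop_lazynet("object must be a lazynet_model or lazynet ensemble",
                      class = "lazynet_validation_error")
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' Read a model or ensemble written by [write_lazynet()]
#' @param path file path.
#' @return A `lazynet_model` or `lazynet` ensemble.
#' @export
read_lazynet <- function(path) {
  payload <- jsonlite::read_json(path)
  if (identical(payload$type, "lazynet_model"))
    return(model_from_list(payload$model))
  members <- lapply(payload$members, model_from_list)
  new_lazynet_ensemble(members, members[[1]]$gene_ids,
                       extra = list(config = list(seed = payload$seed)))
}
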