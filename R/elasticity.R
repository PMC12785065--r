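# Elasticities: Jacobian sensitivities of the one-step prediction at a
# common baseline state, averaged over ensemble members, then expanded into
# directed subgraphs by seeded breadth-first search.
#
# Orientation: S[g, i] = d(predicted x_i) / d(x_g), so ROW g lists the genes
# downstream of g and COLUMN g the genes upstream of g.  The opposite
# convention is equally common elsewhere; every consumer in this package
# assumes rows-are-sources.

analytic_jacobian <- function(model, x) {
  blk <- model$block
  a <- as.numeric(blk$W1 %*% x + blk$b1)
  live <- a > blk$eps_floor
  a <- pmax(a, blk$eps_floor)
  m <- as.numeric(exp(blk$W2 %*% log(a) + blk$b2))
  Dh <- ifelse(live, 1 / a, 0)
  # du_k/dx_g = sum_h W2[k,h] * Dh_h * W1[h,g]
  Uprime <- blk$W2 %*% (Dh * blk$W1)
  JF <- model$V %*% (m * Uprime)    # JF[i, g] = dF_i/dx_g
  model$dt * JF
}

#' Elasticity matrix of an ensemble at a baseline state
#'
#' Computes the Jacobian of the one-step prediction at a common baseline
#' expression vector for each ensemble member and averages them. The result
#' is stored source-row-oriented: `S[g, i] = d(predicted x_i)/d(x_g)`. The
#' residual identity contribution (`d x_i / d x_i = 1` from the skip
#' connection) is excluded by default so that entries measure regulatory
#' influence only.
#'
#' @param object a `lazynet` ensemble or a single [lazynet_model()].
#' @param baseline positive baseline state (defaults to the mean training
#'   time-0 state for fitted ensembles), or a `d x n` matrix of states. In a
#'   two-snapshot screen the training inputs cover only a handful of edited
#'   states, so the derivative at one unobserved point is weakly identified;
#'   passing the observed time-0 states averages per-state Jacobians into a
#'   more robust elasticity summary (`S` = mean signed Jacobian, `A` = mean
#'   of per-state absolute Jacobians).
#' @param include_identity keep the residual identity on the diagonal.
#' @param method `"analytic"` (closed form) or `"fd"` (central finite
#'   differences, step `h`), retained as a cross-check route.
#' @param h finite-difference step.
#' @return An object of class `elasticity_matrix` with elements `S` (signed),
#'   `A` (absolute values), `baseline`, `gene_ids`.
#' @export
compute_elasticity <- function(object, baseline = NULL,
                               include_identity = FALSE,
                               method = c("analytic", "fd"), h = 1e-5) {
  method <- match.arg(method)
  members <- if (inherits(object, "lazynet")) object$members
             else if (inherits(object, "lazynet_model")) list(object)
             else stop_lazynet("object must be a lazynet ensemble or model",
                               class = "lazynet_validation_error")
  d <- members[[1]]$d
  gene_ids <- members[[1]]$gene_ids
  if (is.null(baseline)) {
    if (inherits(object, "lazynet") && !is.null(object$pairs))
      baseline <- rowMeans(object$pairs$time0)
    else stop_lazynet("supply a baseline state",
                      class = "lazynet_validation_error")
  }
  states <- if (is.matrix(baseline)) baseline else matrix(baseline, ncol = 1)
  if (nrow(states) != d)
    stop_lazynet("baseline has %d genes, model has %d", nrow(states), d,
                 class = "lazynet_shape_error")
  if (any(!is.finite(states)) || any(states < 0))
    stop_lazynet("baseline must be finite and non-negative",
                 class = "lazynet_validation_error")
  one_state <- function(x) {
    J <- matrix(0, d, d)
    for (m in members) {
      Jm <- if (method == "analytic") {
        analytic_jacobian(m, x)
      } else {
        cols <- vapply(seq_len(d), function(g) {
          xp <- x; xm <- x
          xp[g] <- xp[g] + h
          xm[g] <- max(xm[g] - h, m$block$eps_floor)
          (as.numeric(model_rate(m, matrix(xp, ncol = 1))) -
           as.numeric(model_rate(m, matrix(xm, ncol = 1)))) / (xp[g] - xm[g])
        }, numeric(d))
        m$dt * cols
      }
      J <- J + Jm
    }
    J <- J / length(members)
    if (include_identity) J <- J + diag(d)
    J
  }
  Ssum <- matrix(0, d, d)
  Asum <- matrix(0, d, d)
  for (j in seq_len(ncol(states))) {
    J <- one_state(states[, j])
    Ssum <- Ssum + J
    Asum <- Asum + abs(J)
  }
  J <- Ssum / ncol(states)
  Aj <- Asum / ncol(states)
  if (any(!is.finite(J))) {
    bad <- which(!is.finite(J), arr.ind = TRUE)
    stop_lazynet("non-finite elasticity entries, e.g. %s -> %s",
                 gene_ids[bad[1, 2]], gene_ids[bad[1, 1]],
                 class = "lazynet_validation_error")
  }
  S <- t(J)   # rows become sources
  A <- t(Aj)
  dimnames(S) <- dimnames(A) <- list(gene_ids, gene_ids)
  structure(list(S = S, A = A, baseline = rowMeans(states),
                 gene_ids = gene_ids),
            class = "elasticity_matrix")
}

#' @export
print.elasticity_matrix <- function(x, ...) {
  cat(sprintf("Elasticity matrix over %d genes (rows = sources); |S| range %.3g..%.3g\n",
              length(x$gene_ids), min(x$A), max(x$A)))
  invisible(x)
}

new_subgraph <- function(nodes, edges, seeds) {
  structure(list(nodes = nodes, edges = edges, seeds = seeds),
            class = "lazynet_subgraph")
}

#' @export
print.lazynet_subgraph <- function(x, ...) {
  cat(sprintf("Subgraph: %d genes, %d directed edges (seeds: %s)\n",
              length(x$nodes), nrow(x$edges),
              paste(x$seeds, collapse = ", ")))
  invisible(x)
}

empty_edges <- function() {
  data.frame(source = character(), target = character(), score = numeric(),
             sign = numeric(), hop = integer(), p_value = numeric(),
             q_value = numeric(), stringsAsFactors = FALSE)
}

#' Seeded breadth-first subgraph expansion
#'
#' Grows a directed subgraph from a seed gene over the absolute elasticity
#' matrix. At each frontier gene the candidate neighbors are the union of
#' its row (downstream) and column (upstream) entries; a candidate survives
#' if its score is at least `floor` **and** exceeds the `pct`-th percentile
#' of that gene's own ranked candidate list. The `top` strongest surviving
#' neighbor genes (ties broken by gene id) are added with their directed
#' edges; genes already visited contribute edges but are not re-expanded.
#' Empirical upper-tail p-values from the global off-diagonal elasticity
#' distribution are attached and Benjamini-Hochberg filtered at `bh_q`
#' (`bh_q = 1` keeps everything — no FDR filtering — while leaving the
#' machinery available for stricter thresholds).
#'
#' @param elasticity an `elasticity_matrix` from [compute_elasticity()].
#' @param seed_gene seed gene symbol (must be in the panel).
#' @param top neighbors kept per expanded gene.
#' @param depth number of breadth-first hops.
#' @param pct percentile cutoff (95 or 99 typical); `NULL` disables it.
#' @param floor absolute elasticity floor.
#' @param bh_q Benjamini-Hochberg q threshold on candidate edges.
#' @return A `lazynet_subgraph`: gene set plus a data frame of directed
#'   edges (`source`, `target`, `score`, `sign`, `hop`, `p_value`,
#'   `q_value`).
#' @export
expand_seed <- function(elasticity, seed_gene, top = 32L, depth = 4L,
                        pct = 99, floor = 0.001, bh_q = 1) {
  stopifnot(inherits(elasticity, "elasticity_matrix"))
  A <- elasticity$A; S <- elasticity$S
  ids <- elasticity$gene_ids
  if (!seed_gene %in% ids)
    stop_lazynet("seed gene '%s' not in panel", seed_gene,
                 class = "lazynet_validation_error")
  if (top < 1L || depth < 1L || floor <= 0)
    stop_lazynet("need top >= 1, depth >= 1, floor > 0",
                 class = "lazynet_validation_error")
  offdiag <- A[row(A) != col(A)]
  n_off <- length(offdiag)
  visited <- seed_gene
  frontier <- seed_gene
  edges <- empty_edges()
  for (hop in seq_len(depth)) {
    nxt <- character(0)
    for (g in frontier) {
      down <- A[g, ]; up <- A[, g]
      cand <- data.frame(
        neighbor = c(ids, ids),
        source = c(rep(g, length(ids)), ids),
        target = c(ids, rep(g, length(ids))),
        score = c(down, up),
        stringsAsFactors = FALSE)
      cand <- cand[cand$neighbor != g, , drop = FALSE]
      keep <- cand$score >= floor
      if (!is.null(pct) && !is.na(pct))
        keep <- keep & cand$score > quantile(cand$score, pct / 100,
                                             names = FALSE)
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0L) next
      cand <- cand[order(-cand$score, cand$neighbor), , drop = FALSE]
      kept_nb <- unique(cand$neighbor)[seq_len(min(top, length(unique(cand$neighbor))))]
      cand <- cand[cand$neighbor %in% kept_nb, , drop = FALSE]
      cand$p_value <- (1 + vapply(cand$score,
                                  function(s) sum(offdiag >= s), numeric(1))) /
                      (1 + n_off)
      cand$q_value <- p.adjust(cand$p_value, method = "BH")
      cand <- cand[cand$q_value <= bh_q, , drop = FALSE]
      if (nrow(cand) == 0L) next
      edges <- rbind(edges, data.frame(
        source = cand$source, target = cand$target, score = cand$score,
        sign = sign(S[cbind(match(cand$source, ids), match(cand$target, ids))]),
        hop = hop, p_value = cand$p_value, q_value = cand$q_value,
        stringsAsFactors = FALSE))
      new_nb <- setdiff(unique(cand$neighbor), visited)
      visited <- c(visited, new_nb)
      nxt <- c(nxt, new_nb)
    }
    frontier <- unique(nxt)
    if (length(frontier) == 0L) break
  }
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
  rownames(edges) <- NULL
  new_subgraph(sort(unique(c(seed_gene, edges$source, edges$target))),
               edges, seed_gene)
}

#' Merge seed subgraphs
#'
#' Node and edge union over a list of subgraphs from the same gene universe;
#' duplicate directed edges keep the maximum score (and smallest hop).
#'
#' @param graphs list of `lazynet_subgraph` objects.
#' @return A fused `lazynet_subgraph`.
#' @export
merge_subgraphs <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  edges <- do.call(rbind, lapply(graphs, `[[`, "edges"))
  if (nrow(edges) > 0L) {
    edges <- edges[order(edges$source, edges$target, -edges$score, edges$hop), ,
                   drop = FALSE]
    edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]
    rownames(edges) <- NULL
  }
  nodes <- sort(unique(c(unlist(lapply(graphs, `[[`, "nodes")),
                         edges$source, edges$target)))
  new_subgraph(nodes, edges, unique(unlist(lapply(graphs, `[[`, "seeds"))))
}

#' Benchmark recall and enrichment of a subgraph
#'
#' Counts benchmark genes recovered by the subgraph node set and compares
#' against the expectation under uniform random gene selection from the
#' background: `expected = |benchmark| * |nodes| / background_size`,
#' `enrichment = hits / expected`. Either supply a subgraph, or the printed
#' counts (`n_nodes`, `n_hits`, `benchmark_size`) to reproduce published
#' recall/enrichment arithmetic.
#'
#' @param graph a `lazynet_subgraph`, or `NULL` when using printed counts.
#' @param benchmark character vector of benchmark gene symbols (or `NULL`
#'   with `benchmark_size`).
#' @param background_size size of the selection background (e.g. the
#'   protein-coding panel); must be at least the node count.
#' @param seeds input seed genes; counted as hits by default
#'   (`count_seeds = TRUE`), excludable for a stricter reading.
#' @param count_seeds include seed genes that are benchmark members in hits.
#' @param n_nodes,n_hits,benchmark_size printed-count interface.
#' @return An object of class `recall_report`: `hits`, `recall`, `expected`,
#'   `enrichment`, `n_nodes`, `benchmark_size`, `background_size`.
#' @export
benchmark_recall <- function(graph = NULL, benchmark = NULL, background_size,
                             seeds = NULL, count_seeds = TRUE,
                             n_nodes = NULL, n_hits = NULL,
                             benchmark_size = NULL) {
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "lazynet_subgraph"))
    if (is.null(benchmark) || length(benchmark) == 0L)
      stop_lazynet("benchmark set must be non-empty",
                   class = "lazynet_validation_error")
    nodes <- graph$nodes
    hit_genes <- intersect(nodes, benchmark)
    if (!count_seeds && !is.null(seeds))
      hit_genes <- setdiff(hit_genes, seeds)
    n_nodes <- length(nodes)
    n_hits <- length(hit_genes)
    benchmark_size <- length(unique(benchmark))
  } else if (is.null(n_nodes) || is.null(n_hits) || is.null(benchmark_size)) {
    stop_lazynet("supply a graph or (n_nodes, n_hits, benchmark_size)",
                 class = "lazynet_validation_error")
  }
  if (background_size < n_nodes)
    stop_lazynet("background (%d) smaller than node set (%d)",
                 background_size, n_nodes, class = "lazynet_validation_error")
  expected <- benchmark_size * n_nodes / background_size
  structure(list(hits = n_hits, recall = n_hits / benchmark_size,
                 expected = expected, enrichment = n_hits / expected,
                 n_nodes = n_nodes, benchmark_size = benchmark_size,
                 background_size = background_size),
            class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  cat(sprintf("Recall %d/%d (%.0f%%); expected by chance %.2f; enrichment %.2f (graph of %d genes, background %d)\n",
              x$hits, x$benchmark_size, 100 * x$recall, x$expected,
              x$enrichment, x$n_nodes, x$background_size))
  invisible(x)
}

#' Per-seed recall of a benchmark set
#'
#' Runs [expand_seed()] with each benchmark gene as the sole seed and
#' reports the fraction of the benchmark recovered by each expansion.
#'
#' @inheritParams expand_seed
#' @param benchmark benchmark gene symbols (those absent from the panel are
#'   skipped).
#' @return Named numeric vector of per-seed recalls.
#' @export
per_seed_recall <- function(elasticity, benchmark, top = 32L, depth = 4L,
                            pct = 99, floor = 0.001) {
  present <- intersect(benchmark, elasticity$gene_ids)
  vapply(present, function(g) {
    sg <- expand_seed(elasticity, g, top = top, depth = depth, pct = pct,
                      floor = floor)
    length(intersect(sg$nodes, benchmark)) / length(unique(benchmark))
  }, numeric(1))
}

#' Write / read a subgraph edge table
#'
#' Tab-separated with columns `source`, `target`, `score`, `sign`, `hop`.
#'
#' @param graph a `lazynet_subgraph`.
#' @param path file path.
#' @return `path` invisibly; `read_subgraph()` returns a `lazynet_subgraph`.
#' @export
write_subgraph <- function(graph, path) {
  write.table(graph$edges[, c("source", "target", "score", "sign", "hop")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subgraph
#' @export
read_subgraph <- function(path) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  edges$p_value <- NA_real_; edges$q_value <- NA_real_
  new_subgraph(sort(unique(c(edges$source, edges$target))), edges,
               seeds = character(0))
}
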