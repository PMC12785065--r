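# Concordance of inferred subgraphs with external evidence: matched-null
# co-expression enrichment, hypergeometric edge overlap, size-matched
# density nulls, degree-preserving rewiring, and quartile edge classes.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\x01")

# Cut a numeric vector into ~n_bins quantile bins (ties collapse bins).
quantile_bin <- function(x, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, br, include.lowest = TRUE))
}

#' Matched-null co-expression enrichment
#'
#' Annotates each directed edge with a reference correlation `r` and asks
#' whether edges exceed `|r| >= tau` more often than matched random pairs.
#' For every edge, `n_pairs_per_edge` null pairs are sampled from the joint
#' strata of its endpoints — genes binned by control-cell mean expression
#' and by out-degree (source role) / in-degree (target role) in the edge
#' graph — so abundance and hubness are controlled. Reports observed and
#' expected tail fractions and their ratio (fold enrichment) for three
#' variants: unsigned `|r|`, sign-matched (`r` multiplied by the edge sign),
#' and opposite-sign. Edges without a reference value are excluded from
#' numerator and denominator alike. Deterministic per seed.
#'
#' @param edges data frame with `source`, `target`, `sign` columns.
#' @param reference data frame `geneA`, `geneB`, `r` of reference
#'   correlations (unordered pairs).
#' @param expression named numeric vector of mean control expression per
#'   gene (the stratification universe).
#' @param n_pairs_per_edge matched pairs sampled per edge.
#' @param expression_bins,degree_bins number of quantile bins per axis.
#' @param tau_grid thresholds for the tail fractions.
#' @param seed integer seed.
#' @return Data frame with one row per (tau, variant): `observed`,
#'   `expected`, `fold`, `n_edges`, `n_null`.
#' @export
matched_null_enrichment <- function(edges, reference, expression,
                                    n_pairs_per_edge = 400L,
                                    expression_bins = 5L, degree_bins = 5L,
                                    tau_grid = c(0.2, 0.4), seed = 1L) {
  genes <- names(expression)
  if (is.null(genes))
    stop_lazynet("expression must be a named vector",
                 class = "lazynet_validation_error")
  ref_r <- setNames(reference$r, pair_key(reference$geneA, reference$geneB))
  out_deg <- table(factor(edges$source, levels = genes))
  in_deg <- table(factor(edges$target, levels = genes))
  ebin <- quantile_bin(expression, expression_bins)
  obin_src <- quantile_bin(as.numeric(out_deg), degree_bins)
  obin_tgt <- quantile_bin(as.numeric(in_deg), degree_bins)
  src_stratum <- paste(ebin, obin_src)
  tgt_stratum <- paste(ebin, obin_tgt)
  names(src_stratum) <- names(tgt_stratum) <- genes

  sample_from <- function(stratum, role_strata, n, self) {
    pool <- genes[role_strata == stratum]
    pool <- setdiff(pool, self)
    widened <- FALSE
    if (length(pool) == 0L) {          # widen to the whole universe
      pool <- setdiff(genes, self)
      widened <- TRUE
    }
    list(draw = pool[sample.int(length(pool), n, replace = TRUE)],
         widened = widened)
  }

  set.seed(seed)
  edge_r <- ref_r[pair_key(edges$source, edges$target)]
  usable <- which(!is.na(edge_r))
  if (length(usable) == 0L)
    stop_lazynet("no edge has a reference correlation",
                 class = "lazynet_validation_error")
  null_r <- vector("list", length(usable))
  null_sign <- vector("list", length(usable))
  any_widened <- FALSE
  for (k in seq_along(usable)) {
    i <- usable[k]
    s <- sample_from(src_stratum[edges$source[i]], src_stratum,
                     n_pairs_per_edge, edges$source[i])
    t <- sample_from(tgt_stratum[edges$target[i]], tgt_stratum,
                     n_pairs_per_edge, edges$target[i])
    any_widened <- any_widened || s$widened || t$widened
    ok <- s$draw != t$draw
    r <- ref_r[pair_key(s$draw[ok], t$draw[ok])]
    null_r[[k]] <- r[!is.na(r)]
    null_sign[[k]] <- rep(edges$sign[i], length(null_r[[k]]))
  }
  if (any_widened)
    warning("some strata were empty; null pairs drawn from the full universe")
  nr <- unlist(null_r)
  ns <- unlist(null_sign)
  er <- edge_r[usable]
  es <- edges$sign[usable]
  rows <- list()
  for (tau in tau_grid) {
    variants <- list(
      unsigned = list(obs = abs(er) >= tau, nul = abs(nr) >= tau),
      sign_matched = list(obs = es * er >= tau, nul = ns * nr >= tau),
      opposite_sign = list(obs = -es * er >= tau, nul = -ns * nr >= tau))
    for (v in names(variants)) {
      o <- mean(variants[[v]]$obs)
      e <- mean(variants[[v]]$nul)
      rows[[length(rows) + 1L]] <- data.frame(
        tau = tau, variant = v, observed = o, expected = e,
        fold = if (e > 0) o / e else NA_real_,
        n_edges = length(er), n_null = length(nr),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Hypergeometric edge-overlap test
#'
#' Collapses directed model edges and reference links to deduplicated
#' unordered gene pairs within a universe and tests the overlap with a
#' one-tailed (upper) hypergeometric test whose population is all
#' `choose(|universe|, 2)` unordered pairs.
#'
#' @param edges data frame with `source`, `target` (directed model edges).
#' @param reference_edges data frame with `geneA`, `geneB`.
#' @param gene_universe character vector defining the pair population.
#' @return A list of class `overlap_result`: `n_edges`, `n_reference`,
#'   `n_overlap`, `population_pairs`, `p_hypergeometric`, `jaccard`.
#' @export
overlap_hypergeometric <- function(edges, reference_edges, gene_universe) {
  u <- unique(gene_universe)
  inu <- function(a, b) a %in% u & b %in% u & a != b
  ek <- unique(pair_key(edges$source, edges$target)[
    inu(edges$source, edges$target)])
  rk <- unique(pair_key(reference_edges$geneA, reference_edges$geneB)[
    inu(reference_edges$geneA, reference_edges$geneB)])
  npop <- choose(length(u), 2)
  if (length(ek) > npop)
    stop_lazynet("more edge pairs (%d) than population pairs (%g)",
                 length(ek), npop, class = "lazynet_validation_error")
  q <- length(intersect(ek, rk))
  p <- phyper(q - 1, length(rk), npop - length(rk), length(ek),
              lower.tail = FALSE)
  structure(list(n_edges = length(ek), n_reference = length(rk),
                 n_overlap = q, population_pairs = npop,
                 p_hypergeometric = p,
                 jaccard = if (length(ek) + length(rk) - q > 0)
                   q / (length(ek) + length(rk) - q) else NA_real_),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Edge overlap: %d of %d model pairs in %d reference pairs (population %g); hypergeometric p = %.3g, Jaccard = %.3g\n",
              x$n_overlap, x$n_edges, x$n_reference, x$population_pairs,
              x$p_hypergeometric, x$jaccard))
  invisible(x)
}

#' Reference-graph density of a gene set versus size-matched random sets
#'
#' Observed density = reference links among the node set divided by
#' `choose(n, 2)`; the null draws equally sized gene sets uniformly from the
#' background `n_draws` times. The empirical one-sided p-value uses the
#' add-one correction `(1 + #{null >= obs}) / (1 + n_draws)` so finite
#' resampling never reports zero.
#'
#' @param node_set character gene set (at least 2 genes).
#' @param reference_edges data frame `geneA`, `geneB` of undirected links.
#' @param background_genes background for the random draws.
#' @param n_draws number of null draws.
#' @param seed integer seed.
#' @return List: `observed_density`, `null_mean`, `null_sd`, `empirical_p`,
#'   `n_links`.
#' @export
density_random_gene_sets <- function(node_set, reference_edges,
                                     background_genes, n_draws = 1000L,
                                     seed = 1L) {
  node_set <- unique(node_set)
  if (length(node_set) < 2L)
    stop_lazynet("node set needs at least 2 genes",
                 class = "lazynet_validation_error")
  background_genes <- unique(background_genes)
  if (length(node_set) > length(background_genes))
    stop_lazynet("node set larger than background",
                 class = "lazynet_validation_error")
  a <- reference_edges$geneA; b <- reference_edges$geneB
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  dedup <- !duplicated(pair_key(a, b))
  a <- a[dedup]; b <- b[dedup]
  count_links <- function(s) {
    inset <- a %in% s & b %in% s
    sum(inset)
  }
  n <- length(node_set)
  obs_links <- count_links(node_set)
  obs <- obs_links / choose(n, 2)
  set.seed(seed)
  null <- vapply(seq_len(n_draws), function(i) {
    count_links(sample(background_genes, n)) / choose(n, 2)
  }, numeric(1))
  list(observed_density = obs, null_mean = mean(null), null_sd = sd(null),
       empirical_p = (1 + sum(null >= obs)) / (1 + n_draws),
       n_links = obs_links)
}

#' Degree-preserving Maslov-Sneppen rewiring
#'
#' Randomizes an undirected simple graph by repeated edge swaps that keep
#' every node's degree fixed and never introduce self-loops or multi-edges.
#' The number of swap attempts defaults to `n_per_edge` times the edge
#' count. Deterministic per seed.
#'
#' @param edges data frame `geneA`, `geneB` (undirected simple graph), or an
#'   `igraph` object.
#' @param n_per_edge swap attempts per edge.
#' @param seed integer seed.
#' @return Rewired edge data frame (`geneA`, `geneB`), or an `igraph` object
#'   if one was supplied.
#' @export
maslov_sneppen_rewire <- function(edges, n_per_edge = 1000L, seed = 1L) {
  as_df <- !igraph::is_igraph(edges)
  g <- if (as_df)
    igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  else edges
  if (igraph::ecount(g) < 2L) {
    warning("graph too small to swap; returned unchanged")
    return(edges)
  }
  set.seed(seed)
  rg <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = n_per_edge * igraph::ecount(g)))
  if (!as_df) return(rg)
  el <- igraph::as_edgelist(rg)
  data.frame(geneA = el[, 1], geneB = el[, 2], stringsAsFactors = FALSE)
}

#' Quartile dichotomy of model versus reference edge scores
#'
#' Dichotomizes both scores at their 75th percentile over the classified
#' edge set and assigns each edge to `both-high`, `reference-only`,
#' `model-only` or `neither`.
#'
#' @param model_score,reference_score numeric vectors over the same edges.
#' @return Factor of classes, with attribute `thresholds`.
#' @export
quartile_classify <- function(model_score, reference_score) {
  if (length(model_score) < 4L || length(model_score) != length(reference_score))
    stop_lazynet("need at least 4 edges with both scores",
                 class = "lazynet_validation_error")
  tm <- quantile(model_score, 0.75, names = FALSE)
  tr <- quantile(reference_score, 0.75, names = FALSE)
  mh <- model_score > tm
  rh <- reference_score > tr
  cls <- ifelse(mh & rh, "both-high",
         ifelse(rh, "reference-only",
         ifelse(mh, "model-only", "neither")))
  structure(factor(cls, levels = c("both-high", "reference-only",
                                   "model-only", "neither")),
            thresholds = c(model = tm, reference = tr))
}
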