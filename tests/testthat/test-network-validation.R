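test_that("hypergeometric overlap matches exact enumeration on a 4-gene universe", {
  uni <- c("a", "b", "c", "d")
  ref <- data.frame(geneA = c("a", "a", "b"), geneB = c("b", "c", "c"))
  edges <- data.frame(source = c("a", "c"), target = c("b", "a"))
  res <- overlap_hypergeometric(edges, ref, uni)
  expect_equal(res$population_pairs, 6)
  expect_equal(res$n_overlap, 2L)
  # P(X >= 2), X ~ Hypergeom(6 pairs, 3 reference, 2 draws) = C(3,2)/C(6,2)
  expect_equal(res$p_hypergeometric, 0.2)
  expect_equal(res$jaccard, 2 / 3)
  # zero overlap: p = 1
  edges0 <- data.frame(source = c("a", "b"), target = c("d", "d"))
  expect_equal(overlap_hypergeometric(edges0, ref, uni)$p_hypergeometric, 1)
  # extreme tail: overlap = draws = successes
  ref1 <- data.frame(geneA = "a", geneB = "b")
  e1 <- data.frame(source = "b", target = "a")
  expect_equal(overlap_hypergeometric(e1, ref1, uni)$p_hypergeometric, 1 / 6)
})

test_that("hypergeometric p matches brute-force subset enumeration on small universes", {
  set.seed(51)
  for (trial in 1:4) {
    n_genes <- sample(5:8, 1)
    uni <- letters[seq_len(n_genes)]
    all_pairs <- t(combn(uni, 2))
    np <- nrow(all_pairs)
    ref_idx <- sample(np, sample(2:4, 1))
    draw_idx <- sample(np, sample(2:4, 1))
    ref <- data.frame(geneA = all_pairs[ref_idx, 1],
                      geneB = all_pairs[ref_idx, 2])
    edges <- data.frame(source = all_pairs[draw_idx, 1],
                        target = all_pairs[draw_idx, 2])
    res <- overlap_hypergeometric(edges, ref, uni)
    # enumerate all equally likely draws of |edges| pairs from the population
    k <- length(draw_idx)
    combos <- combn(np, k)
    overlaps <- apply(combos, 2, function(ix) length(intersect(ix, ref_idx)))
    expect_equal(res$p_hypergeometric, mean(overlaps >= res$n_overlap),
                 tolerance = 1e-12)
  }
})

test_that("density null against size-matched random sets detects planted modules", {
  set.seed(52)
  background <- sprintf("g%03d", 1:60)
  module <- background[1:10]
  # dense planted module + sparse background
  ref <- rbind(
    data.frame(t(combn(module, 2))) |> stats::setNames(c("geneA", "geneB")),
    data.frame(geneA = sample(background, 40, replace = TRUE),
               geneB = sample(background, 40, replace = TRUE)))
  res <- density_random_gene_sets(module, ref, background, n_draws = 1000,
                                  seed = 4)
  expect_lte(res$empirical_p, 0.01)
  expect_gt(res$observed_density, res$null_mean)
  # node set = entire background: null degenerate at the observed density
  res2 <- density_random_gene_sets(background, ref, background,
                                   n_draws = 50, seed = 4)
  expect_equal(res2$empirical_p, 1)
  expect_equal(res2$null_sd, 0)
  expect_error(density_random_gene_sets("g001", ref, background),
               class = "lazynet_validation_error")
})

test_that("rewiring preserves the degree sequence exactly", {
  set.seed(53)
  for (trial in 1:3) {
    g <- igraph::sample_gnp(25, 0.15)
    df <- igraph::as_edgelist(g) |> as.data.frame() |>
      stats::setNames(c("geneA", "geneB"))
    rw <- maslov_sneppen_rewire(df, n_per_edge = 20, seed = trial)
    deg <- function(e) sort(table(c(e$geneA, e$geneB)))
    expect_equal(as.vector(deg(rw)), as.vector(deg(df)))
    # simple graph: no self-loops or duplicate edges
    expect_true(all(rw$geneA != rw$geneB))
    key <- paste(pmin(rw$geneA, rw$geneB), pmax(rw$geneA, rw$geneB))
    expect_false(any(duplicated(key)))
  }
})

test_that("rewiring is deterministic per seed and fixed on rigid graphs", {
  sq <- data.frame(geneA = c("a", "b", "c", "d"),
                   geneB = c("b", "c", "d", "a"))
  r1 <- maslov_sneppen_rewire(sq, n_per_edge = 50, seed = 9)
  r2 <- maslov_sneppen_rewire(sq, n_per_edge = 50, seed = 9)
  expect_identical(r1, r2)
  # every reachable 4-cycle configuration keeps all degrees at 2
  expect_true(all(table(c(r1$geneA, r1$geneB)) == 2))
  # triangle admits no legal swap
  tri <- data.frame(geneA = c("a", "b", "c"), geneB = c("b", "c", "a"))
  rt <- maslov_sneppen_rewire(tri, n_per_edge = 50, seed = 2)
  kt <- function(e) sort(paste(pmin(e$geneA, e$geneB),
                               pmax(e$geneA, e$geneB)))
  expect_identical(kt(rt), kt(tri))
})

test_that("quartile classes follow the 2x2 dichotomy at the 75th percentiles", {
  ms <- c(10, 9, 8, 7, 1, 2, 3, 4)
  rs <- c(10, 1, 9, 2, 8, 3, 7, 4)
  cls <- quartile_classify(ms, rs)
  tm <- quantile(ms, 0.75); tr <- quantile(rs, 0.75)
  expect_equal(as.character(cls),
               ifelse(ms > tm & rs > tr, "both-high",
               ifelse(rs > tr, "reference-only",
               ifelse(ms > tm, "model-only", "neither"))))
  # perfectly rank-correlated scores: no single-high classes beyond ties
  cls2 <- quartile_classify(1:8, (1:8) * 2)
  expect_equal(sum(cls2 %in% c("reference-only", "model-only")), 0L)
  # independent scores: each single-high class ~ 3/16
  set.seed(54)
  a <- rnorm(1e4); b <- rnorm(1e4)
  cls3 <- quartile_classify(a, b)
  expect_lt(abs(mean(cls3 == "model-only") - 3 / 16), 0.01)
  expect_lt(abs(mean(cls3 == "reference-only") - 3 / 16), 0.01)
  expect_error(quartile_classify(1:3, 1:3),
               class = "lazynet_validation_error")
})

make_coexpr_fixture <- function(signal_r, seed = 60, n_genes = 40,
                                n_edges = 60) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  edges <- data.frame(source = sample(genes, n_edges, replace = TRUE),
                      target = sample(genes, n_edges, replace = TRUE),
                      sign = sample(c(-1, 1), n_edges, replace = TRUE),
                      stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, ]
  all_pairs <- t(combn(genes, 2))
  r <- rnorm(nrow(all_pairs), 0, 0.05)
  ref <- data.frame(geneA = all_pairs[, 1], geneB = all_pairs[, 2], r = r)
  if (signal_r != 0) {
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target))
    hit <- paste(ref$geneA, ref$geneB) %in% key
    ref$r[hit] <- rnorm(sum(hit), signal_r, 0.05)
  }
  expr <- setNames(rlnorm(n_genes, 0, 0.5), genes)
  list(edges = edges, ref = ref, expr = expr)
}

test_that("matched-null enrichment is calibrated under exchangeable references", {
  # identical reference r for every pair: fold enrichment exactly 1
  fx <- make_coexpr_fixture(0, seed = 61)
  fx$ref$r <- 0.5
  res <- suppressWarnings(
    matched_null_enrichment(fx$edges, fx$ref, fx$expr,
                            n_pairs_per_edge = 50,
                            tau_grid = 0.3, seed = 1))
  un <- res[res$variant == "unsigned", ]
  expect_equal(un$fold, 1)
  expect_equal(un$observed, 1)
  # null reference: fold ~ 1 within Monte-Carlo error
  fx0 <- make_coexpr_fixture(0, seed = 62)
  expect_warning(
    res0 <- matched_null_enrichment(fx0$edges, fx0$ref, fx0$expr,
                                    n_pairs_per_edge = 200,
                                    tau_grid = 0.05, seed = 2),
    "strata")
  un0 <- res0[res0$variant == "unsigned", ]
  expect_lt(abs(un0$fold - 1), 0.35)
})

test_that("matched-null enrichment detects planted co-expression signal", {
  fx <- make_coexpr_fixture(0.5, seed = 63)
  res <- suppressWarnings(
    matched_null_enrichment(fx$edges, fx$ref, fx$expr,
                            n_pairs_per_edge = 200,
                            tau_grid = 0.2, seed = 3))
  un <- res[res$variant == "unsigned", ]
  expect_gt(un$fold, 1)
  expect_gt(un$observed, 0.8)
  # edges without a reference value are excluded from both sides
  fx$ref <- fx$ref[-seq_len(100), ]
  res2 <- suppressWarnings(
    matched_null_enrichment(fx$edges, fx$ref, fx$expr,
                            n_pairs_per_edge = 50,
                            tau_grid = 0.2, seed = 4))
  expect_lte(res2$n_edges[1], nrow(fx$edges))
})
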