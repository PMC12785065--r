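test_that("normalization scales cells to a common library and conserves totals", {
  m <- matrix(c(2, 2, 1, 3), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
  z <- normalize_counts(m, pseudocount = 1, target_library = 4)
  expect_equal(unname(z[, "c1"]), c(log(3), log(3)))
  # conservation: pre-log per-cell sums equal the target library
  set.seed(41)
  big <- matrix(rpois(50 * 20, 5), 50,
                dimnames = list(sprintf("g%d", 1:50), sprintf("c%d", 1:20)))
  zz <- normalize_counts(big, pseudocount = 1)
  target <- attr(zz, "target_library")
  pre_log <- exp(zz) - 1
  expect_true(all(abs(colSums(pre_log) - target) < 1e-9))
  # all-zero gene maps to a constant log(pseudocount) row
  big2 <- rbind(big, g0 = 0L)
  z2 <- normalize_counts(big2, pseudocount = 1)
  expect_true(all(z2["g0", ] == 0))
  # zero-total cells dropped with a warning
  m3 <- cbind(m, c3 = c(0, 0))
  expect_warning(z3 <- normalize_counts(m3, target_library = 4),
                 "zero-total")
  expect_equal(ncol(z3), 2)
})

test_that("QC filter applies inclusive detection bounds, gene-pass first", {
  m <- toy_counts()
  out <- qc_filter(m, min_cells_per_gene = 3, min_genes_per_cell = 2)
  expect_false("g3" %in% rownames(out))          # detected in only 2 cells
  expect_true(all(c("g1", "g2", "g4", "g5") %in% rownames(out)))
  # cell detection counted on retained genes: c4 has g1,g5 -> exactly 2, kept
  expect_true("c4" %in% colnames(out))
  # exact expected submatrix from hand enumeration
  expect_identical(out, m[c("g1", "g2", "g4", "g5"), ])
  expect_error(qc_filter(m, min_cells_per_gene = 6),
               class = "lazynet_validation_error")
})

test_that("HVG selection is a deterministic dispersion sort", {
  const <- matrix(1, 4, 6, dimnames = list(c("b", "d", "a", "c"), NULL))
  expect_equal(select_hvg(const, 0.5), c("a", "b"))   # ties: lexicographic
  set.seed(42)
  m <- matrix(rnorm(100 * 10), 100,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  m["g007", ] <- m["g007", ] * 10
  expect_true("g007" %in% select_hvg(m, 0.05))
  # brute-force sort oracle
  v <- apply(m, 1, var)
  oracle <- rownames(m)[order(-v, rownames(m))][1:25]
  expect_equal(select_hvg(m, 0.25), oracle)
  expect_error(select_hvg(m, 0), class = "lazynet_validation_error")
})

test_that("guide split partitions barcodes by multiplicity", {
  guides <- data.frame(
    barcode = paste0("c", 1:6),
    n_guides = c(0L, 1L, 2L, 1L, 3L, 0L),
    target_gene = c("", "A", "A,B", "B", "A,B,C", ""),
    modality = c("non-targeting", "CRISPRi", "CRISPRi", "CRISPRa",
                 "CRISPRi", "non-targeting"),
    stringsAsFactors = FALSE)
  sp <- guide_split(paste0("c", 1:6), guides)
  expect_equal(sp$baseline, c("c1", "c6"))
  expect_equal(sp$singlet, c("c2", "c4"))
  expect_equal(sp$multiplet, c("c3", "c5"))
  # unknown barcode treated as baseline, with a message
  expect_message(sp2 <- guide_split(paste0("c", 1:7), guides), "missing")
  expect_true("c7" %in% sp2$baseline)
  # partition property
  expect_equal(sort(unlist(sp2, use.names = FALSE)), paste0("c", 1:7))
})

test_that("time-0 construction edits exactly one coordinate", {
  controls <- matrix(5, 3, 4, dimnames = list(c("gA", "gB", "gC"), NULL))
  ko <- build_time0(controls, perturbation_spec("gB", "floor", 1e-3))
  expect_equal(unname(ko), c(5, 1e-3, 5))
  post <- matrix(c(9, 1, 2), 3, 5, dimnames = list(c("gA", "gB", "gC"), NULL))
  oe <- build_time0(controls, perturbation_spec("gA", "observed_post"),
                    post_cells = post)
  expect_equal(unname(oe), c(9, 5, 5))
  # non-target coordinates bit-identical to the control mean
  set.seed(43)
  controls2 <- matrix(rlnorm(30), 3, 10,
                      dimnames = list(c("gA", "gB", "gC"), NULL))
  t0 <- build_time0(controls2, perturbation_spec("gC", "floor", 1e-3))
  expect_identical(t0[c("gA", "gB")], rowMeans(controls2)[c("gA", "gB")])
  expect_error(build_time0(controls, perturbation_spec("gZ", "floor")),
               class = "lazynet_validation_error")
})

test_that("group split assigns whole groups deterministically at the ratios", {
  set.seed(44)
  X <- matrix(rlnorm(4 * 100), 4, dimnames = list(paste0("g", 1:4), NULL))
  groups <- data.frame(target_gene = rep(sprintf("t%02d", 1:10), each = 10),
                       guide_id = "g1", stringsAsFactors = FALSE)
  pr <- snapshot_pairs(X, X, groups)
  sp <- group_split(pr, seed = 5)
  ng <- function(p) length(unique(p$groups$key))
  expect_equal(c(ng(sp$train), ng(sp$validation), ng(sp$test)), c(8, 1, 1))
  sp2 <- group_split(pr, seed = 5)
  expect_identical(sp$train$groups, sp2$train$groups)
  # no group straddles partitions, over many seeds
  for (seed in 1:25) {
    s <- group_split(pr, seed = seed)
    parts <- lapply(s, function(p) unique(p$groups$key))
    expect_equal(sort(unlist(parts, use.names = FALSE)),
                 sort(paste(unique(groups$target_gene), "g1", "batch0",
                            sep = "|")))
    expect_equal(length(intersect(parts$train, parts$test)), 0)
    expect_equal(length(intersect(parts$train, parts$validation)), 0)
    expect_equal(length(intersect(parts$validation, parts$test)), 0)
    expect_equal(ncol(s$train$time0) + ncol(s$validation$time0) +
                   ncol(s$test$time0), 100)
  }
  two <- pr[pr$groups$target_gene %in% c("t01", "t02")]
  expect_error(group_split(two), class = "lazynet_validation_error")
})

test_that("matrix-market round trip preserves counts and names", {
  m <- toy_counts()
  dir <- tempfile()
  write_counts_mtx(m, dir)
  m2 <- read_counts_mtx(dir)
  expect_equal(as.matrix(m2), m, ignore_attr = FALSE, tolerance = 0)
})

test_that("prepared pairs are leakage-safe and joinable", {
  sim <- simulate_guide_screen(
    screen_sim_config(n_genes = 8, n_terms = 10, n_background_genes = 30,
                      n_control_cells = 60, n_singlet_cells = 160,
                      n_multiplet_cells = 20, seed = 3))
  prep <- prepare_snapshot_pairs(sim$counts, sim$guides, hvg_fraction = 1,
                                 min_cells_per_gene = 3,
                                 min_genes_per_cell = 5)
  pr <- prep$pairs
  expect_s3_class(pr, "snapshot_pairs")
  # each pair's time-0 equals the control baseline except at its target
  for (j in sample(length(pr), 10)) {
    tg <- pr$groups$target_gene[j]
    others <- setdiff(prep$panel, tg)
    expect_identical(pr$time0[others, j], prep$baseline[others])
  }
})
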