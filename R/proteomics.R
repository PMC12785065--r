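# Protein-layer concordance: table cleaning, left-censored MinProb
# imputation, log2 median-centering, per-edge rank correlations, and a
# degree-matched null with a rank-sum comparison.

#' Clean a protein quantification table
#'
#' Drops reverse-sequence and contaminant rows, upper-cases gene symbols,
#' averages duplicate symbols, and masks zero intensities as missing. Rows
#' without a symbol are dropped (count reported via message).
#'
#' @param table data frame with one row per protein group.
#' @param symbol_col name of the gene-symbol column.
#' @param intensity_cols character vector of intensity column names, or a
#'   regular expression (`intensity_regex`) selecting them.
#' @param intensity_regex regex used when `intensity_cols` is `NULL`.
#' @param reverse_col,contaminant_col flag columns; rows with a non-empty /
#'   `TRUE` / `"+"` value are discarded (either may be absent).
#' @return Numeric proteins x channels matrix with upper-case symbol
#'   rownames and `NA` for missing values.
#' @export
clean_protein_table <- function(table, symbol_col = "symbol",
                                intensity_cols = NULL,
                                intensity_regex = "^intensity",
                                reverse_col = "reverse",
                                contaminant_col = "contaminant") {
  flagged <- function(col) {
    if (is.null(col) || !col %in% names(table)) return(rep(FALSE, nrow(table)))
    v <- table[[col]]
    if (is.logical(v)) !is.na(v) & v
    else !is.na(v) & trimws(as.character(v)) %in% c("+", "TRUE", "true", "1")
  }
  drop <- flagged(reverse_col) | flagged(contaminant_col)
  table <- table[!drop, , drop = FALSE]
  sym <- toupper(trimws(as.character(table[[symbol_col]])))
  no_sym <- is.na(sym) | sym == ""
  if (any(no_sym))
    message(sprintf("dropping %d row(s) without a gene symbol", sum(no_sym)))
  table <- table[!no_sym, , drop = FALSE]
  sym <- sym[!no_sym]
  if (is.null(intensity_cols))
    intensity_cols <- grep(intensity_regex, names(table),
                           ignore.case = TRUE, value = TRUE)
  if (length(intensity_cols) == 0L)
    stop_lazynet("no intensity columns matched",
                 class = "lazynet_validation_error")
  m <- as.matrix(table[, intensity_cols, drop = FALSE])
  storage.mode(m) <- "double"
  m[m == 0] <- NA_real_
  # average duplicate symbols
  if (anyDuplicated(sym)) {
    m <- do.call(rbind, lapply(split(seq_along(sym), sym), function(i)
      colMeans(m[i, , drop = FALSE], na.rm = TRUE)))
    m[is.nan(m)] <- NA_real_
  } else {
    rownames(m) <- sym
    m <- m[order(rownames(m)), , drop = FALSE]
  }
  m
}

#' Keep well-quantified proteins
#'
#' Retains proteins observed in at least `min_channels` channels with
#' non-zero variance across their observed values.
#'
#' @param matrix proteins x channels matrix with `NA` missing values.
#' @param min_channels minimum observed channels.
#' @return Filtered matrix.
#' @export
filter_quantified <- function(matrix, min_channels = 3L) {
  n_obs <- rowSums(!is.na(matrix))
  v <- apply(matrix, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) 0 else var(r)
  })
  matrix[n_obs >= min_channels & v > 0, , drop = FALSE]
}

#' Left-censored MinProb imputation
#'
#' Replaces each missing value with a draw from a down-shifted narrow
#' normal: per channel column, `Normal(mu - shift * sigma, (width * sigma)^2)`
#' with `mu`, `sigma` estimated from that column's observed values — the
#' standard treatment of left-censored (below-detection) proteomic
#' intensities. Observed entries are untouched; deterministic per seed.
#'
#' @param matrix proteins x channels matrix (conventionally of
#'   log-intensities) with `NA` missing values.
#' @param shift down-shift in column SDs (default 1.8).
#' @param width imputation SD in column SDs (default 0.3).
#' @param seed integer seed.
#' @return Completed matrix.
#' @export
minprob_impute <- function(matrix, shift = 1.8, width = 0.3, seed = 1L) {
  if (width <= 0)
    stop_lazynet("width must be positive", class = "lazynet_validation_error")
  out <- matrix
  set.seed(seed)
  for (j in seq_len(ncol(matrix))) {
    col <- matrix[, j]
    obs <- col[!is.na(col)]
    miss <- which(is.na(col))
    if (length(miss) == 0L) next
    if (length(obs) < 2L)
      stop_lazynet("column %d has fewer than 2 observed values; sigma undefined",
                   j, class = "lazynet_validation_error")
    mu <- mean(obs); s <- sd(obs)
    out[miss, j] <- rnorm(length(miss), mu - shift * s, width * s)
  }
  out
}

#' Log2 transform and per-channel median centering
#'
#' @param matrix proteins x channels matrix of positive intensities (`NA`
#'   allowed).
#' @return Matrix of log2 intensities with every channel median at zero.
#' @export
log2_median_center <- function(matrix) {
  if (any(matrix <= 0, na.rm = TRUE))
    stop_lazynet("non-positive intensities cannot be log-transformed",
                 class = "lazynet_validation_error")
  l <- log2(matrix)
  sweep(l, 2, apply(l, 2, median, na.rm = TRUE))
}

#' Per-edge protein rank correlations
#'
#' Spearman's rho across channels for each edge whose two symbols are
#' quantified in at least `min_obs` shared finite channels. Edges failing
#' coverage, or with a constant profile, are excluded with a reason.
#'
#' @param matrix proteins x channels matrix (symbols as rownames).
#' @param edges data frame with `source`, `target` symbol columns.
#' @param min_obs minimum paired finite observations.
#' @return Data frame `source`, `target`, `rho`, `n_obs` for retained
#'   edges; attribute `"excluded"` tabulates exclusion reasons.
#' @export
edge_protein_correlation <- function(matrix, edges, min_obs = 3L) {
  syms <- rownames(matrix)
  res <- vector("list", nrow(edges))
  reasons <- character(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    a <- match(toupper(edges$source[i]), syms)
    b <- match(toupper(edges$target[i]), syms)
    if (is.na(a) || is.na(b)) { reasons[i] <- "unmapped"; next }
    x <- matrix[a, ]; y <- matrix[b, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_obs) { reasons[i] <- "coverage"; next }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) { reasons[i] <- "constant"; next }
    res[[i]] <- data.frame(source = edges$source[i], target = edges$target[i],
                           rho = cor(x[ok], y[ok], method = "spearman"),
                           n_obs = sum(ok), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(source = character(), target = character(),
                      rho = numeric(), n_obs = integer())
  attr(out, "excluded") <- table(reasons[reasons != ""])
  out
}

#' Degree-matched protein-pair null and rank-sum comparison
#'
#' Samples random protein pairs whose endpoint degree-bin profile matches
#' that of the real edges — degrees binned as `0, 1, ..., 19, 20+`
#' (`n_bins = 21`) to control hub bias — computes their |Spearman rho| from
#' the protein matrix, and compares real versus null |rho| with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param edge_cor output of [edge_protein_correlation()] for the real edges.
#' @param matrix quantified proteins x channels matrix.
#' @param degree_map named integer vector: each gene's degree in the model
#'   subgraph (missing proteins get degree 0).
#' @param n_bins number of degree bins (last bin open-ended).
#' @param n_null number of null pairs.
#' @param min_obs coverage threshold for null-pair correlations.
#' @param seed integer seed.
#' @return List: `p_value`, `median_real`, `median_null`, `null_rho`,
#'   `n_real`, `n_null`.
#' @export
degree_matched_protein_null <- function(edge_cor, matrix, degree_map,
                                        n_bins = 21L, n_null = 10000L,
                                        min_obs = 3L, seed = 1L) {
  if (nrow(edge_cor) == 0L)
    stop_lazynet("no real edges with correlations",
                 class = "lazynet_validation_error")
  prots <- rownames(matrix)
  deg <- degree_map[prots]
  deg[is.na(deg)] <- 0L
  bin <- pmin(as.integer(deg), n_bins - 1L)
  names(bin) <- prots
  by_bin <- split(prots, bin)
  edge_bins <- cbind(
    pmin(as.integer(degree_map[toupper(edge_cor$source)]), n_bins - 1L),
    pmin(as.integer(degree_map[toupper(edge_cor$target)]), n_bins - 1L))
  edge_bins[is.na(edge_bins)] <- 0L
  pick_bin <- function(b) {
    key <- as.character(b)
    if (!is.null(by_bin[[key]]) && length(by_bin[[key]]) > 0L)
      return(by_bin[[key]])
    # relax to the nearest populated bin
    avail <- as.integer(names(by_bin))
    by_bin[[as.character(avail[which.min(abs(avail - b))])]]
  }
  set.seed(seed)
  relaxed <- FALSE
  null_rho <- numeric(0)
  guard <- 0L
  while (length(null_rho) < n_null && guard < 50L) {
    guard <- guard + 1L
    need <- n_null - length(null_rho)
    rows <- edge_bins[sample.int(nrow(edge_bins), need, replace = TRUE), ,
                      drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      pa <- pick_bin(rows[i, 1]); pb <- pick_bin(rows[i, 2])
      if (!as.character(rows[i, 1]) %in% names(by_bin) ||
          !as.character(rows[i, 2]) %in% names(by_bin)) relaxed <- TRUE
      a <- pa[sample.int(length(pa), 1L)]
      b <- pb[sample.int(length(pb), 1L)]
      if (a == b) next
      x <- matrix[a, ]; y <- matrix[b, ]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_obs || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      null_rho[length(null_rho) + 1L] <- cor(x[ok], y[ok],
                                             method = "spearman")
    }
  }
  if (relaxed)
    warning("some degree bins had no proteins; relaxed to nearest bins")
  wt <- wilcox.test(abs(edge_cor$rho), abs(null_rho),
                    alternative = "two.sided", exact = FALSE)
  list(p_value = wt$p.value,
       median_real = median(abs(edge_cor$rho)),
       median_null = median(abs(null_rho)),
       null_rho = null_rho,
       n_real = nrow(edge_cor), n_null = length(null_rho))
}
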