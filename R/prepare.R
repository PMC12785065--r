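# Turning raw count matrices + guide calls into snapshot pairs:
# QC, library-size normalization, HVG panel selection, leakage-safe time-0
# construction and group-aware splits.

#' Quality-control filter on a count matrix
#'
#' Retains genes detected (count > 0) in at least `min_cells_per_gene`
#' cells, then cells with at least `min_genes_per_cell` detected genes among
#' the retained panel. Both bounds are inclusive and the two passes are
#' applied once, gene-pass first.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse) of
#'   non-negative counts with unique dimnames.
#' @param min_cells_per_gene,min_genes_per_cell inclusive detection bounds.
#' @return The filtered count matrix (same storage class).
#' @export
qc_filter <- function(counts, min_cells_per_gene = 3L,
                      min_genes_per_cell = 200L) {
  det <- counts > 0
  gene_keep <- Matrix::rowSums(det) >= min_cells_per_gene
  counts <- counts[gene_keep, , drop = FALSE]
  cell_keep <- Matrix::colSums(counts > 0) >= min_genes_per_cell
  counts <- counts[, cell_keep, drop = FALSE]
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop_lazynet("QC filter removed all genes or cells",
                 class = "lazynet_validation_error")
  counts
}

#' Library-size normalization and log transform
#'
#' Scales each cell to a common library size (the median per-cell total by
#' default), then applies `z = log(x + pseudocount)`. Cells with a zero
#' total are dropped with a warning. The pre-log per-cell sums equal the
#' target library exactly.
#'
#' @param counts genes x cells count matrix.
#' @param pseudocount positive shift applied before the log (counts scale).
#' @param target_library common library size; default median of per-cell
#'   totals.
#' @return Dense genes x cells matrix of working-scale values, with
#'   attributes `pseudocount` and `target_library`.
#' @export
normalize_counts <- function(counts, pseudocount = 1,
                             target_library = NULL) {
  if (pseudocount <= 0)
    stop_lazynet("pseudocount must be positive",
                 class = "lazynet_validation_error")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping %d zero-total cell(s)", sum(totals == 0)))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (is.null(target_library)) target_library <- median(totals)
  scaled <- sweep(as.matrix(counts), 2, target_library / totals, `*`)
  z <- log(scaled + pseudocount)
  attr(z, "pseudocount") <- pseudocount
  attr(z, "target_library") <- target_library
  z
}

#' Select a highly variable gene panel
#'
#' Ranks genes by the variance of their normalized working-scale values
#' across cells and returns the top `ceiling(fraction * G)` as a frozen
#' panel. Ties at the cutoff are broken by lexicographic gene id, so the
#' panel is deterministic.
#'
#' @param normalized genes x cells working-scale matrix with rownames.
#' @param fraction fraction of genes to keep, in `(0, 1]`.
#' @return Character vector of panel gene ids (in ranked order).
#' @export
select_hvg <- function(normalized, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1)
    stop_lazynet("fraction must be in (0, 1]",
                 class = "lazynet_validation_error")
  ids <- rownames(normalized) %||% sprintf("g%d", seq_len(nrow(normalized)))
  disp <- apply(normalized, 1, var)
  o <- order(-disp, ids)
  ids[o][seq_len(ceiling(fraction * nrow(normalized)))]
}

#' Partition barcodes by guide multiplicity
#'
#' Cells with 0 (or unknown) guides are baseline — used only to estimate
#' the time-0 state; singlets (exactly one guide) are the training material;
#' multiplets (>= 2 guides) are held out as the test stratum.
#'
#' @param counts genes x cells matrix with barcode colnames (or a character
#'   vector of barcodes).
#' @param guides data frame with columns `barcode`, `n_guides` (plus
#'   `target_gene`, `modality` as available).
#' @return A list of disjoint barcode vectors `baseline`, `singlet`,
#'   `multiplet`; barcodes missing from the guide table are treated as
#'   baseline and their count reported via message.
#' @export
guide_split <- function(counts, guides) {
  barcodes <- if (is.character(counts)) counts else colnames(counts)
  n <- guides$n_guides[match(barcodes, guides$barcode)]
  unknown <- sum(is.na(n))
  if (unknown > 0L)
    message(sprintf("%d barcode(s) missing from guide table; treated as baseline",
                    unknown))
  n[is.na(n)] <- 0L
  list(baseline = barcodes[n == 0L],
       singlet = barcodes[n == 1L],
       multiplet = barcodes[n >= 2L])
}

#' Perturbation encoding for time-0 construction
#'
#' @param target_gene perturbed gene symbol.
#' @param mode `"floor"` (CRISPR interference / knockout: set the gene to a
#'   small working-scale floor) or `"observed_post"` (CRISPR activation /
#'   overexpression: set it to the observed mean post level).
#' @param floor_value small positive working-scale floor; on a
#'   `log(x + 1)` working scale a zero count maps to 0, so the default sits
#'   just above that image.
#' @return A list of class `perturbation_spec`.
#' @export
perturbation_spec <- function(target_gene,
                              mode = c("floor", "observed_post"),
                              floor_value = 1e-3) {
  mode <- match.arg(mode)
  if (floor_value <= 0)
    stop_lazynet("floor_value must be positive",
                 class = "lazynet_validation_error")
  structure(list(target_gene = target_gene, mode = mode,
                 floor_value = floor_value),
            class = "perturbation_spec")
}

#' Construct a leakage-safe time-0 state
#'
#' The time-0 input for a perturbation of gene `g` is the per-gene mean over
#' control cells with a single edit at `g`: the floor value for
#' interference/knockout, or the mean observed post level of `g` across the
#' perturbed cells for activation/overexpression. No other coordinate is
#' touched, so no multi-gene pattern from any test cell can leak into the
#' input.
#'
#' @param controls genes x cells matrix of normalized control cells.
#' @param spec a [perturbation_spec()].
#' @param post_cells genes x cells matrix of the perturbed cells (required
#'   for `mode = "observed_post"`).
#' @return Named numeric time-0 vector over the panel.
#' @export
build_time0 <- function(controls, spec, post_cells = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (ncol(controls) == 0L)
    stop_lazynet("no control cells", class = "lazynet_validation_error")
  base <- rowMeans(controls)
  i <- match(spec$target_gene, rownames(controls))
  if (is.na(i))
    stop_lazynet("target gene '%s' not in panel", spec$target_gene,
                 class = "lazynet_validation_error")
  if (spec$mode == "floor") {
    base[i] <- spec$floor_value
  } else {
    if (is.null(post_cells) || ncol(post_cells) == 0L)
      stop_lazynet("observed_post mode needs post_cells",
                   class = "lazynet_validation_error")
    base[i] <- mean(post_cells[i, ])
  }
  base
}

#' Group-aware train/validation/test split
#'
#' Assigns whole groups (`target_gene x guide x batch`) to the three
#' partitions so that no group straddles a boundary — guarding against
#' guide- or batch-specific leakage. Group counts follow `ratios` up to
#' rounding (largest-remainder allocation) and the assignment is
#' deterministic per seed.
#'
#' @param pairs a [snapshot_pairs()] object.
#' @param ratios length-3 positive weights summing to 1.
#' @param seed integer seed.
#' @return List of three disjoint [snapshot_pairs()]: `train`, `validation`,
#'   `test`.
#' @export
group_split <- function(pairs, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(pairs, "snapshot_pairs"))
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L)
    stop_lazynet("ratios must be three values summing to 1",
                 class = "lazynet_validation_error")
  keys <- unique(pairs$groups$key)
  if (length(keys) < 3L)
    stop_lazynet("need at least 3 groups to split (have %d)", length(keys),
                 class = "lazynet_validation_error")
  set.seed(seed)
  keys <- sample(keys)
  n <- length(keys)
  sizes <- floor(n * ratios)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * ratios - sizes
    add <- order(-frac)[seq_len(rem)]
    sizes[add] <- sizes[add] + 1L
  }
  assign <- rep(1:3, times = sizes)
  part <- split(keys, assign)
  pick <- function(ks) pairs[pairs$groups$key %in% ks]
  list(train = pick(part[["1"]]), validation = pick(part[["2"]]),
       test = pick(part[["3"]]))
}

#' Prepare snapshot pairs from a screen
#'
#' End-to-end preparation: optional protein-coding restriction, QC,
#' normalization, HVG panel, guide-multiplicity split, per-perturbation
#' time-0 construction, and pairing of each singlet (and optionally
#' multiplet) cell's post state with its group key.
#'
#' @param counts genes x cells count matrix.
#' @param guides guide-call table (`barcode`, `n_guides`, `target_gene`,
#'   `modality`, optional `guide_id`, `batch`).
#' @param pseudocount,hvg_fraction,min_cells_per_gene,min_genes_per_cell
#'   preprocessing knobs (see [normalize_counts()], [select_hvg()],
#'   [qc_filter()]).
#' @param floor_value working-scale floor for interference/knockout edits.
#' @param coding_genes optional gene list restricting the panel.
#' @param include_multiplets also build pairs for multiplet cells (time-0
#'   edited at every listed target), returned separately.
#' @return List with `pairs` (singlet [snapshot_pairs()]), `multiplet_pairs`
#'   (or `NULL`), `panel`, `baseline` (control mean over the panel), and
#'   `normalized` (the working-scale matrix over the panel).
#' @export
prepare_snapshot_pairs <- function(counts, guides, pseudocount = 1,
                                   hvg_fraction = 0.25,
                                   min_cells_per_gene = 3L,
                                   min_genes_per_cell = 200L,
                                   floor_value = 1e-3,
                                   coding_genes = NULL,
                                   include_multiplets = FALSE) {
  if (!is.null(coding_genes))
    counts <- counts[rownames(counts) %in% coding_genes, , drop = FALSE]
  counts <- qc_filter(counts, min_cells_per_gene, min_genes_per_cell)
  z <- normalize_counts(counts, pseudocount = pseudocount)
  panel <- select_hvg(z, hvg_fraction)
  z <- z[panel, , drop = FALSE]
  split3 <- guide_split(z, guides)
  controls <- z[, split3$baseline, drop = FALSE]
  if (ncol(controls) == 0L)
    stop_lazynet("no baseline cells to estimate time-0",
                 class = "lazynet_validation_error")
  baseline <- rowMeans(controls)

  build_for <- function(barcodes, multi = FALSE) {
    g <- guides[match(barcodes, guides$barcode), , drop = FALSE]
    if (is.null(g$guide_id)) g$guide_id <- g$target_gene
    if (is.null(g$batch)) g$batch <- "batch0"
    keep <- logical(length(barcodes))
    t0 <- matrix(NA_real_, nrow(z), length(barcodes))
    for (j in seq_along(barcodes)) {
      targets <- strsplit(g$target_gene[j], ",", fixed = TRUE)[[1]]
      modes <- strsplit(g$modality[j], ",", fixed = TRUE)[[1]]
      if (length(modes) == 1L) modes <- rep(modes, length(targets))
      if (!all(targets %in% panel)) next
      v <- baseline
      for (k in seq_along(targets)) {
        sp <- perturbation_spec(
          targets[k],
          mode = if (modes[k] %in% c("CRISPRa", "OE", "activation"))
            "observed_post" else "floor",
          floor_value = floor_value)
        same <- barcodes[g$target_gene == g$target_gene[j]]
        v[match(targets[k], panel)] <-
          build_time0(controls, sp,
                      post_cells = z[, same, drop = FALSE])[match(targets[k],
                                                                  panel)]
      }
      t0[, j] <- v
      keep[j] <- TRUE
    }
    if (!any(keep)) return(NULL)
    snapshot_pairs(t0[, keep, drop = FALSE], z[, barcodes[keep], drop = FALSE],
                   data.frame(target_gene = g$target_gene[keep],
                              guide_id = g$guide_id[keep],
                              batch = g$batch[keep],
                              stringsAsFactors = FALSE),
                   gene_ids = panel)
  }

  list(pairs = build_for(split3$singlet),
       multiplet_pairs = if (include_multiplets && length(split3$multiplet))
         build_for(split3$multiplet, multi = TRUE),
       panel = panel, baseline = baseline, normalized = z)
}

# Readers / writers ------------------------------------------------------------

#' Read a 10x-style Matrix Market triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` (first column gene ids) and
#' `barcodes.tsv` under `dir`.
#'
#' @param dir directory path.
#' @return Sparse genes x cells `dgCMatrix` with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- read.delim(file.path(dir, "features.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  bcs <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                    stringsAsFactors = FALSE)
  dimnames(m) <- list(feats[[1]], bcs[[1]])
  methods::as(m, "CsparseMatrix")
}

#' Write a count matrix as a Matrix Market triplet directory
#' @param counts genes x cells matrix with dimnames.
#' @param dir output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  write.table(data.frame(rownames(counts)), file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(colnames(counts)), file.path(dir, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense TSV count matrix (genes in rows, first column gene ids)
#' @param path file path.
#' @return Dense numeric matrix.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a guide-call table
#'
#' TSV with columns `barcode`, `n_guides`, `target_gene`, `modality`
#' (`CRISPRi`/`CRISPRa`/`non-targeting`), optional `guide_id`, `batch`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_guide_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
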