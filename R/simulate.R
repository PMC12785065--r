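# Ground-truth generators: snapshot pairs from a known monomial law, full
# guide screens with control/singlet/multiplet structure and a
# negative-binomial count readout, and reference tables with planted signal
# on the true edges.  Everything is bit-reproducible per seed.

#' Screen simulation configuration
#'
#' Defaults describe the regime the rest of the package is tested in: a
#' 20-gene sparse monomial system with 30 rate terms, 300 control cells,
#' 2000 singlets and 200 multiplets, mild multiplicative noise, moderate
#' library-size variation and an overdispersed count readout.
#'
#' @param n_genes,n_terms system size.
#' @param n_background_genes non-dynamical transcriptome genes included in
#'   the count readout. Library-size normalization assumes the modeled panel
#'   is a small share of each cell's total; real screens measure tens of
#'   thousands of genes, so the readout carries a background transcriptome
#'   to keep per-cell totals insensitive to any single perturbation.
#' @param n_control_cells,n_singlet_cells,n_multiplet_cells cell counts.
#' @param noise_sd SD of the multiplicative log-normal expression noise.
#' @param library_size_cv coefficient of variation of per-cell library-size
#'   factors.
#' @param dt Euler substep of the true dynamics.
#' @param response_steps number of substeps the perturbation response
#'   develops before the post snapshot is read out. A screen measures cells
#'   after the response has unfolded for a while, not after one
#'   infinitesimal step; a few substeps give measurable direct effects while
#'   keeping multi-hop propagation subordinate — the regime the one-step
#'   treatment of two-snapshot data assumes.
#' @param count_scale mean counts per unit expression.
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`).
#' @param ko_factor,oe_factor multiplicative edit applied to the target gene
#'   for interference (floor) and activation (boost) singlets.
#' @param guides_per_target distinct guide ids per target gene.
#' @param seed integer seed.
#' @return List of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_genes = 20L, n_terms = 30L,
                              n_background_genes = 180L,
                              n_control_cells = 300L,
                              n_singlet_cells = 2000L,
                              n_multiplet_cells = 200L,
                              noise_sd = 0.1, library_size_cv = 0.2,
                              dt = 0.1, response_steps = 3L,
                              count_scale = 25,
                              dispersion = 0.3,
                              ko_factor = 0.05, oe_factor = 5,
                              guides_per_target = 2L, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$noise_sd >= 0, cfg$dt > 0, cfg$library_size_cv >= 0)
  structure(cfg, class = "screen_sim_config")
}

# Damped Euler iteration toward a quiet baseline state (not an exact fixed
# point; root-finding is deliberately avoided in fixtures).
damped_baseline <- function(model, d, n_steps = 25L) {
  x <- rep(1, d)
  for (s in seq_len(n_steps)) {
    f <- as.numeric(model_rate(model, matrix(x, ncol = 1)))
    x <- pmax(x + model$dt * 0.5^s * f, 0.05)
    x <- pmin(x, 50)
  }
  x
}

#' Simulate snapshot pairs from a monomial system
#'
#' Draws time-0 states from `state_distribution`, advances each one Euler
#' step of the exactly embedded system, applies multiplicative log-normal
#' noise, and enforces positivity. Pairs whose post state explodes beyond
#' `cap` are resampled (count reported via message).
#'
#' @param system a [monomial_system()].
#' @param n_pairs number of pairs.
#' @param state_distribution function `(n)` returning an `n`-vector of
#'   positive values (applied per gene); default log-normal around 1.
#' @param dt Euler step.
#' @param noise_sd multiplicative log-normal noise SD (0 for noiseless).
#' @param seed integer seed.
#' @param cap resampling threshold on the post state.
#' @return A [snapshot_pairs()] object (group key = pair index).
#' @export
simulate_snapshot_pairs <- function(system, n_pairs,
                                    state_distribution = function(n)
                                      rlnorm(n, 0, 0.4),
                                    dt = 0.1, noise_sd = 0.05, seed = 1L,
                                    cap = 1e3) {
  model <- embed_monomial_system(system, dt = dt)
  d <- system$d
  set.seed(seed)
  time0 <- matrix(NA_real_, d, n_pairs)
  post <- matrix(NA_real_, d, n_pairs)
  resampled <- 0L
  for (i in seq_len(n_pairs)) {
    repeat {
      x <- state_distribution(d)
      y <- euler_step(x, model)
      if (noise_sd > 0) y <- y * rlnorm(d, 0, noise_sd)
      y <- pmax(y, model$block$eps_floor)
      if (max(abs(y)) <= cap) break
      resampled <- resampled + 1L
    }
    time0[, i] <- x
    post[, i] <- y
  }
  if (resampled > 0L)
    message(sprintf("resampled %d exploding pair(s)", resampled))
  rownames(time0) <- rownames(post) <- system$gene_ids
  snapshot_pairs(time0, post,
                 data.frame(target_gene = sprintf("pair%d", seq_len(n_pairs)),
                            guide_id = "sim", stringsAsFactors = FALSE),
                 gene_ids = system$gene_ids)
}

#' Simulate a full guide screen with count readout
#'
#' Control cells sit at a stochastic quiet baseline; each singlet cell
#' perturbs one gene (multiplicative knock-down by `ko_factor` for
#' interference, boost by `oe_factor` for activation), advances one Euler
#' step of the true system, and is read out as negative-binomial counts
#' with per-cell library-size variation. Multiplet cells perturb two genes.
#'
#' @param config a [screen_sim_config()].
#' @param system optional [monomial_system()]; sampled from the config's
#'   seed when omitted.
#' @return List: `counts` (genes x cells integer matrix), `guides` (guide
#'   table data frame), `truth` (list with the system, its planted
#'   `support` matrix, the noiseless `baseline` expression state, and the
#'   embedded `model`).
#' @export
simulate_guide_screen <- function(config = screen_sim_config(),
                                  system = NULL) {
  stopifnot(inherits(config, "screen_sim_config"))
  set.seed(config$seed)
  if (is.null(system))
    system <- sample_monomial_system(config$n_genes, config$n_terms,
                                     seed = config$seed)
  d <- system$d
  model <- embed_monomial_system(system, dt = config$dt)
  baseline <- damped_baseline(model, d)
  genes <- system$gene_ids
  nb <- config$n_background_genes
  bg_genes <- if (nb > 0L) sprintf("BG%04d", seq_len(nb)) else character(0)
  bg_base <- if (nb > 0L) rlnorm(nb, 0, 1) else numeric(0)
  all_genes <- c(genes, bg_genes)

  n_cells <- config$n_control_cells + config$n_singlet_cells +
    config$n_multiplet_cells
  barcodes <- sprintf("cell%05d", seq_len(n_cells))
  counts <- matrix(0L, d + nb, n_cells, dimnames = list(all_genes, barcodes))
  guides <- data.frame(barcode = barcodes, n_guides = 0L,
                       target_gene = "", modality = "non-targeting",
                       guide_id = "none", stringsAsFactors = FALSE)

  lib <- rlnorm(n_cells, 0, config$library_size_cv)
  read_out <- function(expr, cell) {
    mu <- expr * lib[cell] * config$count_scale
    rnbinom(length(expr), mu = mu, size = 1 / config$dispersion)
  }
  noisy <- function(x) pmax(x * rlnorm(length(x), 0, config$noise_sd), 1e-6)

  develop <- function(x) {
    for (s in seq_len(config$response_steps))
      x <- pmin(as.numeric(euler_step(x, model)), 100)
    x
  }
  # control cells live through the same time window as perturbed cells, so
  # the shared unperturbed drift cancels out of response contrasts
  cell <- 0L
  for (i in seq_len(config$n_control_cells)) {
    cell <- cell + 1L
    counts[, cell] <- read_out(c(noisy(develop(baseline)), noisy(bg_base)),
                               cell)
  }
  modality_of <- function(target)
    if (match(target, genes) %% 2L == 0L) "CRISPRa" else "CRISPRi"
  perturb <- function(x, target) {
    g <- match(target, genes)
    x[g] <- if (modality_of(target) == "CRISPRa") x[g] * config$oe_factor
            else x[g] * config$ko_factor
    x
  }
  for (i in seq_len(config$n_singlet_cells)) {
    cell <- cell + 1L
    target <- genes[(i - 1L) %% d + 1L]
    gid <- sprintf("%s_g%d", target,
                   (i - 1L) %/% d %% config$guides_per_target + 1L)
    x <- perturb(noisy(baseline), target)
    y <- noisy(pmax(develop(x), 1e-6))
    counts[, cell] <- read_out(c(y, noisy(bg_base)), cell)
    guides$n_guides[cell] <- 1L
    guides$target_gene[cell] <- target
    guides$modality[cell] <- modality_of(target)
    guides$guide_id[cell] <- gid
  }
  for (i in seq_len(config$n_multiplet_cells)) {
    cell <- cell + 1L
    targets <- sample(genes, 2L)
    x <- noisy(baseline)
    for (tg in targets) x <- perturb(x, tg)
    y <- noisy(pmax(develop(x), 1e-6))
    counts[, cell] <- read_out(c(y, noisy(bg_base)), cell)
    guides$n_guides[cell] <- 2L
    guides$target_gene[cell] <- paste(targets, collapse = ",")
    guides$modality[cell] <- paste(vapply(targets, modality_of, ""),
                                   collapse = ",")
    guides$guide_id[cell] <- paste0(targets[1], "+", targets[2])
  }
  list(counts = counts, guides = guides,
       truth = list(system = system, support = support_matrix(system),
                    baseline = baseline, model = model))
}

#' Reference tables with planted signal on true edges
#'
#' Builds the external evidence fixtures the validation statistics consume:
#' a co-expression table whose correlation is about `signal_r` on true
#' interaction pairs and about 0 on decoys, a reference edge list containing
#' a configurable fraction of the true edges, and a protein matrix whose
#' true-edge partners co-vary across channels.
#'
#' @param system a [monomial_system()] (its [support_matrix()] defines the
#'   true edges).
#' @param signal_r planted correlation on true pairs.
#' @param n_decoy_pairs number of random decoy pairs with null correlation.
#' @param true_edge_fraction fraction of true edges included in the
#'   reference edge list.
#' @param n_channels protein channels.
#' @param seed integer seed.
#' @return List: `coexpression` (`geneA`, `geneB`, `r`), `reference_edges`
#'   (`geneA`, `geneB`, `score`), `protein_matrix` (proteins x channels),
#'   `true_pairs` (data frame of planted unordered pairs).
#' @export
make_reference_tables <- function(system, signal_r = 0.5,
                                  n_decoy_pairs = 500L,
                                  true_edge_fraction = 0.8,
                                  n_channels = 12L, seed = 1L) {
  set.seed(seed)
  genes <- system$gene_ids
  sup <- support_matrix(system)
  idx <- which(sup != 0 & row(sup) != col(sup), arr.ind = TRUE)
  true_pairs <- unique(data.frame(
    geneA = pmin(genes[idx[, 1]], genes[idx[, 2]]),
    geneB = pmax(genes[idx[, 1]], genes[idx[, 2]]),
    stringsAsFactors = FALSE))
  jitter_r <- function(n, center) {
    pmin(pmax(rnorm(n, center, 0.05), -0.99), 0.99)
  }
  co_true <- data.frame(true_pairs,
                        r = jitter_r(nrow(true_pairs), signal_r))
  a <- sample(genes, n_decoy_pairs, replace = TRUE)
  b <- sample(genes, n_decoy_pairs, replace = TRUE)
  ok <- a != b
  decoys <- unique(data.frame(geneA = pmin(a[ok], b[ok]),
                              geneB = pmax(a[ok], b[ok]),
                              stringsAsFactors = FALSE))
  decoys <- decoys[!paste(decoys$geneA, decoys$geneB) %in%
                     paste(co_true$geneA, co_true$geneB), , drop = FALSE]
  co <- rbind(co_true,
              data.frame(decoys, r = jitter_r(nrow(decoys), 0)))
  n_keep <- round(true_edge_fraction * nrow(true_pairs))
  ref_edges <- true_pairs[sample.int(nrow(true_pairs), n_keep), , drop = FALSE]
  ref_edges$score <- runif(n_keep, 0.4, 1)

  # protein matrix: every true pair owns one latent channel factor; a gene's
  # profile mixes the normalized sum of its pairs' latents with private
  # noise, so adjacent genes co-vary (corr ~ signal_r / sqrt(n_i n_j)) while
  # non-adjacent pairs stay uncorrelated
  n_prot <- length(genes)
  noise <- matrix(rnorm(n_prot * n_channels), n_prot, n_channels,
                  dimnames = list(toupper(genes), NULL))
  latent <- matrix(rnorm(nrow(true_pairs) * n_channels),
                   nrow(true_pairs), n_channels)
  w <- sqrt(min(abs(signal_r), 0.999))
  prot <- sqrt(1 - w^2) * noise
  if (nrow(true_pairs) > 0L && w > 0) {
    member <- lapply(seq_len(n_prot), function(i)
      which(true_pairs$geneA == genes[i] | true_pairs$geneB == genes[i]))
    for (i in seq_len(n_prot)) {
      ks <- member[[i]]
      if (length(ks))
        prot[i, ] <- prot[i, ] +
          w * colSums(latent[ks, , drop = FALSE]) / sqrt(length(ks))
    }
  }
  prot <- 20 + prot
  colnames(prot) <- sprintf("channel%02d", seq_len(n_channels))
  list(coexpression = co, reference_edges = ref_edges,
       protein_matrix = prot, true_pairs = true_pairs)
}
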