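#' Generate a paired ST + scRNA-seq fixture with known ground truth
#'
#' Simulates two modalities sharing the same cell-type latent structure: a
#' genome-wide "truth" spatial dataset, a panel-restricted and
#' noise-corrupted "observed" spatial dataset (probe dropout, sparse
#' false-positive background, per-gene modality batch effect), and a
#' scRNA-seq reference with type labels and a 2-D embedding.
#'
#' Generative model:
#' \enumerate{
#'   \item Per-gene baseline Poisson rates are log-normal. Non-marker genes
#'     vary across types by a per-type log-normal factor `exp(N(0, type_sd))`;
#'     marker genes (a `marker_frac` share, assigned round-robin to types)
#'     are boosted 8x in their type and suppressed to 0.02x elsewhere.
#'   \item A continuous per-cell state latent in `[0, 1]` (drawn in both
#'     modalities, spatially unstructured) modulates a `state_frac` subset
#'     of non-marker genes by `exp(±state_sd)` across its range — the
#'     within-type heterogeneity (activation/maturation-like) that real
#'     tissues have and that makes cross-modal neighbor quality matter.
#'   \item ST cells are placed in the unit square and typed by the layout:
#'     `layers` (horizontal bands), `gradient` (type mixture drifting along
#'     x), `islands` (Gaussian blobs).
#'   \item Truth counts are Poisson draws from the cell's type rates; the
#'     truth matrix is depth-normalized and log-transformed.
#'   \item Observed ST = the truth log matrix restricted to `n_panel` genes,
#'     with entries zeroed with probability `dropout_rate` (false
#'     negatives), raised with probability `fp_rate` to a level mimicking
#'     the gene's real signal (false positives from nonspecific probe
#'     binding), and the whole panel shifted up by `batch_shift` on the log
#'     scale (modality/technology offset). The panel contains a stratified
#'     sample of markers plus random fill, as probe panels do.
#'   \item Reference cells are drawn from the same type profiles (uniform
#'     type mix), without coordinates; their 2-D embedding is the fixture's
#'     own PCA.
#'   \item A gene is labelled a ground-truth spatially variable gene when its
#'     max/min type rate ratio is at least `svg_ratio` (types are spatially
#'     segregated by construction).
#' }
#'
#' @param n_types Number of shared cell types.
#' @param n_sc_cells,n_st_cells Reference / spatial cell counts.
#' @param n_genes Genome size; `n_panel` of these form the targeted panel.
#' @param n_panel Panel size (`<= n_genes`).
#' @param spatial_layout One of `"layers"`, `"gradient"`, `"islands"`.
#' @param batch_shift Additive log-scale modality shift applied to the
#'   observed panel (>= 0).
#' @param dropout_rate,fp_rate Per-entry false-negative / false-positive
#'   probabilities in `[0, 1]`.
#' @param marker_frac Fraction of genes that are type-specific markers.
#' @param type_sd Between-type log-SD for non-marker genes.
#' @param state_frac Fraction of genes modulated by the continuous
#'   within-type state latent.
#' @param state_sd Log-amplitude of the state modulation.
#' @param svg_ratio Type-rate ratio above which a gene is a truth SVG.
#' @param seed Integer seed; fixed seed => identical bundle.
#'
#' @return An object of class `fixture_bundle`: list with `spatial_truth`
#'   (genome-wide lognorm [spatial_dataset()]), `spatial_observed` (the
#'   noisy lognorm panel [spatial_dataset()]), `reference` (raw-count
#'   [reference_dataset()] with
#'   labels and embedding), `truth_svg_labels` (named logical),
#'   `st_types`, `ref_types`, `panel_genes`, `marker_genes`, `marker_types`
#'   (named by marker gene), `st_state` / `ref_state` (the latent state per
#'   cell), `state_genes`, `st_rates` (the per-cell Poisson rates behind the
#'   truth counts), `type_means` (gene x type rates) and `params`.
#' @export
generate_fixture <- function(n_types = 5, n_sc_cells = 2000, n_st_cells = 1000,
                             n_genes = 300, n_panel = 60,
                             spatial_layout = c("layers", "gradient", "islands"),
                             batch_shift = 0.5, dropout_rate = 0.2,
                             fp_rate = 0.02, marker_frac = 0.2, type_sd = 1,
                             state_frac = 0.3, state_sd = 0.5,
                             svg_ratio = 3, seed = 42) {
  spatial_layout <- match.arg(spatial_layout)
  if (n_panel > n_genes) stop("n_panel cannot exceed n_genes")
  for (r in c(dropout_rate, fp_rate, marker_frac)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  if (batch_shift < 0) stop("batch_shift must be >= 0")
  params <- list(n_types = n_types, n_sc_cells = n_sc_cells,
                 n_st_cells = n_st_cells, n_genes = n_genes, n_panel = n_panel,
                 spatial_layout = spatial_layout, batch_shift = batch_shift,
                 dropout_rate = dropout_rate, fp_rate = fp_rate,
                 marker_frac = marker_frac, type_sd = type_sd,
                 state_frac = state_frac, state_sd = state_sd,
                 svg_ratio = svg_ratio, seed = seed)
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    types <- sprintf("type%d", seq_len(n_types))

    # per-type Poisson rates
    base <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 1)
    fac <- exp(matrix(stats::rnorm(n_genes * n_types, 0, type_sd),
                      n_genes, n_types))
    n_markers <- round(marker_frac * n_genes)
    marker_genes <- if (n_markers > 0) sample(genes, n_markers) else character(0)
    marker_types <- stats::setNames(
      types[rep_len(seq_len(n_types), n_markers)], marker_genes)
    mi <- match(marker_genes, genes)
    if (n_markers > 0) {
      fac[mi, ] <- 0.02
      fac[cbind(mi, match(marker_types, types))] <- 8
    }
    lambda <- base * fac
    dimnames(lambda) <- list(genes, types)

    # continuous within-type state: a latent in [0, 1] per cell (both
    # modalities) modulates a subset of non-marker genes up or down
    n_state <- round(state_frac * n_genes)
    state_genes <- if (n_state > 0) {
      sample(setdiff(genes, marker_genes), min(n_state, n_genes - n_markers))
    } else {
      character(0)
    }
    state_loading <- stats::setNames(sample(c(-1, 1), length(state_genes),
                                            replace = TRUE), state_genes)
    state_factor <- function(states) {
      # genes x cells multiplier, identity for non-state genes
      f <- matrix(1, n_genes, length(states), dimnames = list(genes, NULL))
      if (length(state_genes)) {
        f[state_genes, ] <- exp(state_sd * outer(state_loading,
                                                 2 * states - 1))
      }
      f
    }

    # spatial layout and type assignment
    st_ids <- sprintf("st_%04d", seq_len(n_st_cells))
    xy <- switch(spatial_layout,
      layers = ,
      gradient = data.frame(x = stats::runif(n_st_cells),
                            y = stats::runif(n_st_cells)),
      islands = {
        centers <- cbind(stats::runif(n_types, 0.15, 0.85),
                         stats::runif(n_types, 0.15, 0.85))
        pick <- sample.int(n_types, n_st_cells, replace = TRUE)
        data.frame(
          x = pmin(pmax(centers[pick, 1] + stats::rnorm(n_st_cells, 0, 0.07), 0), 1),
          y = pmin(pmax(centers[pick, 2] + stats::rnorm(n_st_cells, 0, 0.07), 0), 1),
          island = pick)
      })
    st_type_idx <- switch(spatial_layout,
      layers = pmin(floor(xy$y * n_types) + 1L, n_types),
      gradient = {
        centers <- seq(0, 1, length.out = n_types)
        vapply(xy$x, function(x) {
          p <- stats::dnorm(x, centers, 0.25)
          sample.int(n_types, 1, prob = p / sum(p))
        }, integer(1))
      },
      islands = xy$island)
    st_types <- stats::setNames(types[st_type_idx], st_ids)
    coords <- data.frame(cell_id = st_ids, x = xy$x, y = xy$y)

    # truth counts and lognorm truth
    st_state <- stats::runif(n_st_cells)
    st_rates <- lambda[, st_type_idx] * state_factor(st_state)
    dimnames(st_rates) <- list(genes, st_ids)
    truth_counts <- matrix(
      stats::rpois(n_genes * n_st_cells, st_rates),
      n_genes, n_st_cells, dimnames = list(genes, st_ids))
    truth_lognorm <- normalize_lognorm(
      expression_matrix(truth_counts, norm_state = "raw_counts"))
    spatial_truth <- spatial_dataset(truth_lognorm, coords)

    # targeted panel: stratified markers + random fill
    panel <- character(0)
    if (n_markers > 0) {
      per_type <- floor(n_panel / (2 * n_types))
      for (t in types) {
        cand <- sort(marker_genes[marker_types == t])
        panel <- c(panel, utils::head(cand, per_type))
      }
    }
    fill <- sample(setdiff(genes, panel), n_panel - length(panel))
    panel <- sort(c(panel, fill))

    # observed panel on the log scale: FN dropout, FP spikes sized like the
    # gene's real signal, then the additive modality shift
    obs <- truth_lognorm$values[panel, , drop = FALSE]
    if (dropout_rate > 0) {
      obs[matrix(stats::runif(length(obs)) < dropout_rate,
                 nrow(obs), ncol(obs))] <- 0
    }
    if (fp_rate > 0) {
      spike <- apply(truth_lognorm$values[panel, , drop = FALSE], 1,
                     stats::quantile, 0.95)
      hit <- matrix(stats::runif(length(obs)) < fp_rate, nrow(obs), ncol(obs))
      nhit <- sum(hit)
      if (nhit > 0) {
        lvl <- matrix(spike, nrow(obs), ncol(obs))[hit] *
          stats::runif(nhit, 0.7, 1.3)
        obs[hit] <- pmax(obs[hit], lvl)
      }
    }
    if (batch_shift > 0) {
      obs <- obs + batch_shift
    }
    spatial_observed <- spatial_dataset(
      expression_matrix(obs, norm_state = "lognorm"), coords)

    # scRNA-seq reference: same type profiles, uniform mixture
    sc_ids <- sprintf("sc_%04d", seq_len(n_sc_cells))
    ref_type_idx <- sample.int(n_types, n_sc_cells, replace = TRUE)
    ref_types <- stats::setNames(types[ref_type_idx], sc_ids)
    ref_state <- stats::runif(n_sc_cells)
    ref_rates <- lambda[, ref_type_idx] * state_factor(ref_state)
    ref_counts <- matrix(
      stats::rpois(n_genes * n_sc_cells, ref_rates),
      n_genes, n_sc_cells, dimnames = list(genes, sc_ids))
    ref_raw <- expression_matrix(ref_counts, norm_state = "raw_counts")
    ref_lognorm <- suppressMessages(normalize_lognorm(ref_raw))
    hvg <- select_variable_genes(ref_lognorm, min(100, n_genes))
    ref_pca2 <- compute_pca(ref_lognorm, hvg, n_pcs = 2)
    embedding <- data.frame(cell_id = sc_ids,
                            dim1 = ref_pca2$coords[, 1],
                            dim2 = ref_pca2$coords[, 2])
    reference <- reference_dataset(ref_raw, embedding = embedding,
                                   cluster_labels = ref_types)

    ratio <- apply(lambda, 1, max) / pmax(apply(lambda, 1, min), 1e-12)
    truth_svg_labels <- stats::setNames(ratio >= svg_ratio, genes)

    structure(list(
      spatial_truth = spatial_truth,
      spatial_observed = spatial_observed,
      reference = reference,
      truth_svg_labels = truth_svg_labels,
      st_types = st_types, ref_types = ref_types,
      st_state = stats::setNames(st_state, st_ids),
      ref_state = stats::setNames(ref_state, sc_ids),
      state_genes = sort(state_genes),
      st_rates = st_rates,
      panel_genes = panel, marker_genes = sort(marker_genes),
      marker_types = marker_types,
      type_means = lambda, params = params
    ), class = "fixture_bundle")
  })
}

#' The canonical desk-scale test fixture
#'
#' Five shared cell types in horizontal layers, 2,000 reference and 1,000
#' spatial cells, 300 genes with a 60-gene targeted panel, 20% dropout, 2%
#' false-positive background and a 0.5 log-SD modality batch effect,
#' generated with seed 42.
#'
#' @param seed Seed override (default 42).
#' @return A `fixture_bundle`; see [generate_fixture()].
#' @export
standard_fixture <- function(seed = 42) {
  generate_fixture(n_types = 5, n_sc_cells = 2000, n_st_cells = 1000,
                   n_genes = 300, n_panel = 60, spatial_layout = "layers",
                   batch_shift = 0.5, dropout_rate = 0.2, fp_rate = 0.02,
                   seed = seed)
}

#' @export
print.fixture_bundle <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("<fixture_bundle> %d types, %d ST + %d reference cells, ",
                     "%d genes (%d panel), layout=%s, seed=%d\n"),
              p$n_types, p$n_st_cells, p$n_sc_cells, p$n_genes, p$n_panel,
              p$spatial_layout, p$seed))
  invisible(x)
}
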