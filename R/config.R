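#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its documented default. Unknown keys
#' in user configs are rejected.
#'
#' @return Nested named list with sections `preprocess` (`n_hvg`, `n_pcs`),
#'   `stabilize` (`enabled`, `k`, `alpha`, `neighbor_agg`, `metric`),
#'   `integration`
#'   (see [integration_params()]), `infer` (`k`, `beta`, `weight_mode`),
#'   `svg` (`n_bins`, `n_perm`, `test`, `p_threshold`, `n_groups`),
#'   `benchmark` (`n_bins`, `folds`, `n_train`) and the global `seed` and
#'   `verbose`.
#' @export
default_config <- function() {
  list(
    preprocess = list(n_hvg = 2000, n_pcs = 30),
    stabilize = list(enabled = TRUE, k = 10, alpha = 0.5,
                     neighbor_agg = "mean", metric = "correlation"),
    integration = list(rounds = 2, n_pcs = 30, k_mutual = 20,
                       anchor_min_cor = 0.25, k_weight = 50, k_score = 20,
                       min_shared_genes = 30,
                       harmony_theta = 2, harmony_sigma = 0.1,
                       harmony_lambda = 1, harmony_max_iter = 10,
                       harmony_nclust = NULL),
    infer = list(k = 30, beta = 0.5, weight_mode = "similarity"),
    svg = list(n_bins = 10, n_perm = 100, test = "mann_whitney",
               p_mode = "permutation", p_threshold = 0.05, n_groups = 6),
    benchmark = list(n_bins = 50, folds = 10, n_train = 3000),
    seed = 0,
    verbose = FALSE
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && length(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a YAML configuration file
#'
#' Values in the file override [default_config()]; keys not present in the
#' defaults raise an error.
#'
#' @param path Path to a YAML file (may be `NULL` for pure defaults).
#' @return The merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  merge_config(cfg, user)
}

# integration params derived from a full config (seed propagated)
integration_config <- function(config) {
  p <- config$integration
  p$seed <- config$seed
  p
}
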