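# Small in-code data builders shared across tests.

# random non-negative lognorm-scale expression matrix
rand_lognorm_em <- function(n_genes, n_cells, seed = 1, prefix = "c") {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_genes * n_cells, 1, 0.7)), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("%s%03d", prefix, seq_len(n_cells))))
  expression_matrix(m, norm_state = "lognorm")
}

rand_counts_em <- function(n_genes, n_cells, seed = 1, prefix = "c",
                           lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("%s%03d", prefix, seq_len(n_cells))))
  expression_matrix(m, norm_state = "raw_counts")
}

unit_coords <- function(cell_ids, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = cell_ids, x = runif(length(cell_ids)),
             y = runif(length(cell_ids)))
}

# a small paired fixture reused in several integration/inference tests
small_fixture <- function(seed = 7) {
  generate_fixture(n_types = 3, n_sc_cells = 300, n_st_cells = 150,
                   n_genes = 100, n_panel = 40, seed = seed)
}

# lean config for pipeline-level tests
fast_config <- function(rounds = 2) {
  cfg <- default_config()
  cfg$integration$rounds <- rounds
  cfg$integration$harmony_max_iter <- 5
  cfg$integration$min_shared_genes <- 20
  cfg$svg$n_perm <- 30
  cfg
}
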