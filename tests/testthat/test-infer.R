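make_embedding <- function(sp_coords, ref_coords) {
  joint_embedding(rbind(sp_coords, ref_coords),
                  c(rep("spatial", nrow(sp_coords)),
                    rep("reference", nrow(ref_coords))))
}

test_that("cross-modal neighbors handle coincident cells and k = n_ref", {
  set.seed(51)
  ref <- matrix(rnorm(20 * 3), 20, 3,
                dimnames = list(sprintf("sc%02d", 1:20), NULL))
  sp <- matrix(rnorm(4 * 3), 4, 3,
               dimnames = list(sprintf("st%02d", 1:4), NULL))
  sp[2, ] <- ref[7, ]                       # coincident with sc07
  emb <- make_embedding(sp, ref)
  g <- find_cross_knn(emb, k = 3)
  expect_identical(unname(g$neighbor_ids["st02", 1]), "sc07")
  expect_equal(unname(g$embed_dist["st02", 1]), 0)
  g_all <- find_cross_knn(emb, k = 20)
  expect_equal(g_all$k, 20)
  expect_true(all(apply(g_all$embed_dist, 1, function(d) !is.unsorted(d))))
  expect_setequal(g_all$neighbor_ids[1, ], rownames(ref))
})

test_that("cross-modal neighbors equal a brute-force distance-matrix oracle", {
  set.seed(52)
  ref <- matrix(rnorm(100 * 5), 100, 5,
                dimnames = list(sprintf("sc%03d", 1:100), NULL))
  sp <- matrix(rnorm(100 * 5), 100, 5,
               dimnames = list(sprintf("st%03d", 1:100), NULL))
  g <- find_cross_knn(make_embedding(sp, ref), k = 10)
  for (i in c(1, 17, 50, 100)) {
    d <- sqrt(colSums((t(ref) - sp[i, ])^2))
    expect_identical(g$neighbor_ids[i, ], names(sort(d))[1:10])
    expect_equal(unname(g$embed_dist[i, ]), unname(sort(d)[1:10]),
                 tolerance = 1e-9)
  }
})

test_that("weights follow the printed and the similarity formulas", {
  # engineer two neighbors at expression distances 0.2 and 0.4
  set.seed(53)
  # mean-centered orthonormal columns so Pearson correlations are exact
  q <- qr.Q(qr(scale(matrix(rnorm(30 * 3), 30, 3), scale = FALSE)))
  v <- q[, 1]
  base <- 5
  sp_em <- expression_matrix(
    matrix(v + base, ncol = 1, dimnames = list(sprintf("g%02d", 1:30), "st1")),
    norm_state = "lognorm")
  ref_vals <- cbind(sc1 = 0.8 * v + 0.6 * q[, 2] + base,
                    sc2 = 0.6 * v + 0.8 * q[, 3] + base)
  rownames(ref_vals) <- sprintf("g%02d", 1:30)
  ref_em <- expression_matrix(pmax(ref_vals, 0), norm_state = "lognorm")
  graph <- structure(list(
    spatial_ids = "st1",
    neighbor_ids = matrix(c("sc1", "sc2"), 1, dimnames = list("st1", NULL)),
    embed_dist = matrix(c(1, 2), 1), k = 2L), class = "cross_knn")
  lit <- compute_weights(sp_em, ref_em, graph, weight_mode = "literal")
  expect_equal(unname(lit$expr_dist[1, ]), c(0.2, 0.4), tolerance = 1e-8)
  expect_equal(unname(lit$weights[1, ]), c(0.2, 0.8), tolerance = 1e-8)
  sim <- compute_weights(sp_em, ref_em, graph, weight_mode = "similarity")
  expect_equal(unname(sim$weights[1, ]),
               c(1.8^2, 1.6^2) / (1.8^2 + 1.6^2), tolerance = 1e-8)
  expect_gt(sim$weights[1, 1], sim$weights[1, 2])  # closer neighbor favored
})

test_that("equidistant neighbors get uniform weights; zero-variance pairs d = 1", {
  sp_em <- rand_lognorm_em(20, 3, seed = 54, prefix = "st")
  # three identical neighbors
  ref_vals <- rand_lognorm_em(20, 1, seed = 55, prefix = "x")$values
  ref_vals <- cbind(sc1 = ref_vals[, 1], sc2 = ref_vals[, 1],
                    sc3 = ref_vals[, 1], sc4 = 2)  # sc4 is constant
  ref_em <- expression_matrix(ref_vals, norm_state = "lognorm")
  graph <- structure(list(
    spatial_ids = cell_ids(sp_em),
    neighbor_ids = matrix(rep(c("sc1", "sc2", "sc3"), each = 3), 3,
                          dimnames = list(cell_ids(sp_em), NULL)),
    embed_dist = matrix(1, 3, 3), k = 3L), class = "cross_knn")
  for (mode in c("similarity", "literal")) {
    w <- compute_weights(sp_em, ref_em, graph, weight_mode = mode)
    expect_equal(unname(w$weights), matrix(1 / 3, 3, 3), tolerance = 1e-9)
  }
  graph$neighbor_ids[1, 3] <- "sc4"
  expect_message(w2 <- compute_weights(sp_em, ref_em, graph), "undefined")
  expect_equal(unname(w2$expr_dist[1, 3]), 1)
})

test_that("inference has exact identity limits and preserves geometry", {
  fx <- small_fixture()
  prep <- stinfer:::prepare_inputs(fx$spatial_observed, fx$reference)
  emb <- integrate_two_round(prep$spatial, prep$reference)
  graph <- find_cross_knn(emb, k = 5)
  graph <- compute_weights(prep$spatial$expr, prep$reference$expr, graph)
  expect_equal(unname(rowSums(graph$weights)), rep(1, 150), tolerance = 1e-9)
  inf0 <- infer_expression(prep$spatial, prep$reference, graph, beta = 0)
  panel <- gene_ids(prep$spatial$expr)
  expect_equal(inf0$expr$values[panel, ], prep$spatial$expr$values[panel, ])
  expect_identical(inf0$coords, prep$spatial$coords)
  # k = 1, beta = 1: each cell copies its single neighbor
  g1 <- find_cross_knn(emb, k = 1)
  g1 <- compute_weights(prep$spatial$expr, prep$reference$expr, g1)
  inf1 <- infer_expression(prep$spatial, prep$reference, g1, beta = 1)
  ref_genes <- gene_ids(prep$reference$expr)
  for (i in c(1, 80)) {
    nb <- g1$neighbor_ids[i, 1]
    expect_equal(inf1$expr$values[ref_genes, i],
                 prep$reference$expr$values[, nb], tolerance = 1e-12)
  }
  # convexity: non-panel values lie within neighbor bounds
  inf5 <- infer_expression(prep$spatial, prep$reference, graph, beta = 0.5)
  nonpanel <- setdiff(ref_genes, panel)[1:10]
  for (i in c(3, 99)) {
    nb <- graph$neighbor_ids[i, ]
    vals <- prep$reference$expr$values[nonpanel, nb, drop = FALSE]
    est <- inf5$expr$values[nonpanel, i]
    expect_true(all(est >= apply(vals, 1, min) - 1e-12))
    expect_true(all(est <= apply(vals, 1, max) + 1e-12))
  }
  expect_true(all(inf5$expr$values >= 0))
  # beta-monotonicity (linearity in beta) for a panel gene
  g_pan <- intersect(panel, ref_genes)[1]
  v0 <- inf0$expr$values[g_pan, ]
  v5 <- inf5$expr$values[g_pan, ]
  v1 <- infer_expression(prep$spatial, prep$reference, graph,
                         beta = 1)$expr$values[g_pan, ]
  expect_equal(v5, 0.5 * v0 + 0.5 * v1, tolerance = 1e-9)
})

test_that("inference matches an independent dense brute-force implementation", {
  set.seed(61)
  n_sp <- 50
  n_ref <- 200
  n_panel <- 40
  n_genes <- 120
  genes <- sprintf("g%03d", seq_len(n_genes))
  panel <- genes[seq_len(n_panel)]
  sp_vals <- matrix(abs(rnorm(n_panel * n_sp, 2, 1)), n_panel, n_sp,
                    dimnames = list(panel, sprintf("st%03d", seq_len(n_sp))))
  ref_vals <- matrix(abs(rnorm(n_genes * n_ref, 2, 1)), n_genes, n_ref,
                     dimnames = list(genes, sprintf("sc%03d", seq_len(n_ref))))
  sp_em <- expression_matrix(sp_vals, norm_state = "lognorm")
  ref_em <- expression_matrix(ref_vals, norm_state = "lognorm")
  sp_ds <- spatial_dataset(sp_em, unit_coords(colnames(sp_vals), seed = 61))
  emb_sp <- matrix(rnorm(n_sp * 6), n_sp, 6,
                   dimnames = list(colnames(sp_vals), NULL))
  emb_ref <- matrix(rnorm(n_ref * 6), n_ref, 6,
                    dimnames = list(colnames(ref_vals), NULL))
  emb <- make_embedding(emb_sp, emb_ref)
  k <- 5
  beta <- 0.5
  graph <- find_cross_knn(emb, k = k)
  graph <- compute_weights(sp_em, ref_em, graph, weight_mode = "similarity")
  inferred <- infer_expression(sp_ds, ref_em, graph, beta = beta)

  # fully independent re-implementation with explicit loops
  expected <- matrix(0, n_genes, n_sp, dimnames = list(genes,
                                                       colnames(sp_vals)))
  for (i in seq_len(n_sp)) {
    d_emb <- sqrt(colSums((t(emb_ref) - emb_sp[i, ])^2))
    nb <- names(sort(d_emb))[seq_len(k)]
    d_expr <- vapply(nb, function(c_id) {
      1 - cor(sp_vals[, i], ref_vals[panel, c_id])
    }, numeric(1))
    w <- (2 - d_expr)^2
    w <- w / sum(w)
    agg <- as.vector(ref_vals[, nb, drop = FALSE] %*% w)
    expected[, i] <- agg
    expected[panel, i] <- (1 - beta) * sp_vals[, i] + beta * agg[
      match(panel, genes)]
  }
  expect_lt(max(abs(inferred$expr$values[genes, ] - expected)), 1e-9)
})

test_that("recommend_k returns scored candidates reproducibly", {
  fx <- small_fixture()
  cfg <- fast_config()
  one <- recommend_k(fx$spatial_observed, fx$reference, k_grid = 5,
                     folds = 3, config = cfg, seed = 4)
  expect_identical(one$best_k, 5)
  expect_true(is.finite(one$scores$mean_r))
  two_a <- recommend_k(fx$spatial_observed, fx$reference, k_grid = c(5, 30),
                       folds = 3, config = cfg, seed = 4)
  two_b <- recommend_k(fx$spatial_observed, fx$reference, k_grid = c(5, 30),
                       folds = 3, config = cfg, seed = 4)
  expect_identical(two_a$scores, two_b$scores)
  expect_true(two_a$best_k %in% c(5, 30))
  expect_error(recommend_k(fx$spatial_observed, fx$reference,
                           k_grid = 10000, folds = 3, config = cfg),
               "reference cell count")
})
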