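test_that("grid assignment covers corners, boundaries and matches a histogram", {
  co <- data.frame(cell_id = paste0("c", 1:4),
                   x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  g <- make_grid(co, n_bins = 2)
  expect_setequal(unname(g$index), 1:4)
  # maximal coordinate lands in the last bin, not out of range
  co2 <- data.frame(cell_id = "c", x = 1, y = 1)
  expect_equal(unname(make_grid(rbind(co, co2), 2)$index[5]), 4)
  # random cells: bin occupancy equals an independent 2-D histogram
  set.seed(71)
  co3 <- data.frame(cell_id = sprintf("c%04d", 1:1000),
                    x = runif(1000), y = runif(1000))
  g3 <- make_grid(co3, n_bins = 10)
  xi <- pmin(ceiling((co3$x - min(co3$x)) /
                       ((max(co3$x) - min(co3$x)) / 10) + 1e-12), 10)
  xi[co3$x == min(co3$x)] <- 1
  yi <- pmin(ceiling((co3$y - min(co3$y)) /
                       ((max(co3$y) - min(co3$y)) / 10) + 1e-12), 10)
  yi[co3$y == min(co3$y)] <- 1
  expect_equal(unname(tabulate(g3$index, 100)),
               unname(tabulate((yi - 1) * 10 + xi, 100)))
  # degenerate axis collapses with a warning
  co4 <- data.frame(cell_id = paste0("c", 1:3), x = rep(2, 3), y = 1:3)
  expect_warning(g4 <- make_grid(co4, 3), "degenerate")
  expect_equal(g4$n_bins_x, 1L)
})

test_that("grid means reproduce constructed patterns", {
  set.seed(72)
  n <- 200
  co <- data.frame(cell_id = sprintf("c%03d", 1:n), x = runif(n), y = runif(n))
  vals <- rbind(const = rep(2, n), point = rep(0, n), grad = co$x)
  colnames(vals) <- co$cell_id
  g <- make_grid(co, 4)
  vals["point", which.max(co$x)] <- 7
  f <- grid_mean_expression(expression_matrix(vals, norm_state = "lognorm"), g)
  occupied <- !is.na(f["const", ])
  expect_true(all(f["const", occupied] == 2))
  expect_equal(sum(f["point", occupied] > 0), 1)
  # x-gradient increases along x-bins within each y-row
  for (row in 0:3) {
    v <- f["grad", row * 4 + 1:4]
    v <- v[!is.na(v)]
    expect_false(is.unsorted(v))
  }
})

test_that("svg_test detects planted spatial patterns and passes nulls", {
  set.seed(73)
  n <- 2000
  co <- data.frame(cell_id = sprintf("c%04d", 1:n), x = runif(n), y = runif(n))
  vals <- rbind(
    # a localized (minority-region) pattern: rank-shifted grid means,
    # which the Mann-Whitney statistic sees
    corner = ifelse(co$x < 0.5 & co$y < 0.5, abs(rnorm(n, 2, 0.5)), 0),
    # a half-plane pattern: bimodal grid means with an unshifted mean
    # rank — only distribution-shape statistics (KS) can see it
    left = ifelse(co$x < 0.5, abs(rnorm(n, 2, 0.5)), 0),
    null1 = abs(rnorm(n, 1, 0.5)),
    zero = rep(0, n))
  colnames(vals) <- co$cell_id
  ds <- spatial_dataset(expression_matrix(vals, norm_state = "lognorm"), co)
  p <- svg_test(ds, n_bins = 10, n_perm = 1999, seed = 1)
  expect_lt(p["corner"], 1e-3)
  expect_gt(p["null1"], 0.01)
  expect_equal(unname(p["zero"]), 1)
  p_ks <- svg_test(ds, n_bins = 10, n_perm = 1999, test = "ks", seed = 1)
  expect_lt(p_ks["left"], 1e-3)
  expect_lt(p_ks["corner"], 1e-3)
})

test_that("null p-values are roughly uniform", {
  set.seed(74)
  n <- 400
  n_genes <- 80
  co <- data.frame(cell_id = sprintf("c%04d", 1:n), x = runif(n), y = runif(n))
  vals <- matrix(rpois(n_genes * n, 3), n_genes, n,
                 dimnames = list(sprintf("g%03d", 1:n_genes), co$cell_id))
  ds <- spatial_dataset(
    suppressMessages(normalize_lognorm(
      expression_matrix(vals, norm_state = "raw_counts"))), co)
  p <- svg_test(ds, n_bins = 8, n_perm = 60, seed = 2)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(p < 0.2) - 0.2), 0.12)
})

test_that("embedding test flags cluster-restricted genes and degrades gracefully", {
  # a small cluster of expressing cells vs a uniformly expressed gene on a
  # two-blob embedding
  set.seed(78)
  n1 <- 150
  n2 <- 850
  cells <- sprintf("sc%04d", seq_len(n1 + n2))
  emb <- data.frame(cell_id = cells,
                    dim1 = c(rnorm(n1, 0, 0.5), rnorm(n2, 5, 0.8)),
                    dim2 = rnorm(n1 + n2, 0, 0.8))
  vals <- rbind(restricted = c(abs(rnorm(n1, 3, 0.5)), rep(0, n2)),
                uniform = abs(rnorm(n1 + n2, 1, 0.5)))
  colnames(vals) <- cells
  ref <- reference_dataset(expression_matrix(vals, norm_state = "lognorm"),
                           embedding = emb)
  # grid occupancy on a clustered embedding is very uneven, so the
  # shape-sensitive KS variant is the powered choice here
  p <- svg_test_embedding(ref, n_bins = 8, n_perm = 199, test = "ks", seed = 3)
  expect_lt(p["restricted"], 0.01)
  expect_gt(p["uniform"], 0.05)
  # without embedding: warning, p = 1, combined p equals spatial p
  ref2 <- reference_dataset(ref$expr)
  expect_warning(p2 <- svg_test_embedding(ref2, gene_subset = "restricted"),
                 "no 2-D embedding")
  expect_equal(unname(p2), 1)
  tbl <- combine_and_adjust(c(a = 0.03, b = 0.6), NULL)
  expect_equal(tbl$p_combined, c(0.03, 0.6))
})

test_that("p-value combination is the clipped product with BH adjustment", {
  expect_equal(combine_and_adjust(c(g = 1), c(g = 1))$p_combined, 1)
  expect_equal(combine_and_adjust(c(g = 0.1), c(g = 0.2))$p_combined, 0.02)
  set.seed(75)
  ps <- setNames(runif(100), sprintf("g%03d", 1:100))
  pe <- setNames(runif(100), sprintf("g%03d", 1:100))
  tbl <- combine_and_adjust(ps, pe)
  expect_true(all(tbl$p_combined <= pmin(tbl$p_spatial, tbl$p_embedding)))
  # independent step-up BH oracle
  m <- 100
  ord <- order(tbl$p_combined)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, tbl$p_combined[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  expect_equal(tbl$p_adjusted, adj, tolerance = 1e-12)
})

test_that("pattern clustering separates orthogonal planted patterns", {
  set.seed(76)
  n <- 600
  co <- data.frame(cell_id = sprintf("c%04d", 1:n), x = runif(n), y = runif(n))
  left <- ifelse(co$x < 0.5, 2, 0)
  top <- ifelse(co$y > 0.5, 2, 0)
  vals <- rbind(
    matrix(rep(left, 5), 5, byrow = TRUE) + matrix(rnorm(5 * n, 0, 0.2), 5),
    matrix(rep(top, 5), 5, byrow = TRUE) + matrix(rnorm(5 * n, 0, 0.2), 5))
  vals <- pmax(vals, 0)
  dimnames(vals) <- list(sprintf("g%02d", 1:10), co$cell_id)
  ds <- spatial_dataset(expression_matrix(vals, norm_state = "lognorm"), co)
  cfg <- fast_config()
  cfg$svg$test <- "ks"   # half-plane patterns need a shape-sensitive test
  tbl <- run_svg(ds, config = cfg)
  cl <- cluster_svgs(tbl, n_groups = 2, p_threshold = 0.05)
  ids <- cl$table$cluster_id
  names(ids) <- cl$table$gene
  expect_equal(length(unique(ids[sprintf("g%02d", 1:5)])), 1)
  expect_equal(length(unique(ids[sprintf("g%02d", 6:10)])), 1)
  expect_false(ids["g01"] == ids["g06"])
  expect_equal(nrow(cl$cluster_means), 2)
  # duplicated gene rows always co-cluster; n_groups = genes -> singletons
  cl_all <- cluster_svgs(tbl, n_groups = 10)
  expect_equal(length(unique(cl_all$table$cluster_id)), 10)
  # clustering is invariant to gene input order
  perm <- sample(nrow(vals))
  ds2 <- spatial_dataset(expression_matrix(vals[perm, ],
                                           norm_state = "lognorm"), co)
  tbl2 <- run_svg(ds2, config = cfg)
  cl2 <- cluster_svgs(tbl2, n_groups = 2)
  ids2 <- cl2$table$cluster_id
  names(ids2) <- cl2$table$gene
  same <- outer(ids[rownames(vals)], ids[rownames(vals)], "==")
  same2 <- outer(ids2[rownames(vals)], ids2[rownames(vals)], "==")
  expect_identical(same, same2)
  expect_error(cluster_svgs(tbl, n_groups = 11), "groups")
})

test_that("signature scores and score-correlation ranking behave as defined", {
  vals <- rbind(Slc1a2 = c(2, 3, 1, 0, 4), Cyp2e1 = c(2, 1, 3, 0, 4),
                Cyp2f2 = c(0, 1, 0, 2, 1), Aldh1b1 = c(1, 0, 1, 2, 0),
                other = c(1, 1, 1, 1, 1))
  colnames(vals) <- paste0("c", 1:5)
  em <- expression_matrix(vals, norm_state = "lognorm")
  cv <- signature_score(em, c("Slc1a2", "Cyp2e1"), c("Cyp2f2", "Aldh1b1"))
  expect_equal(unname(cv),
               colMeans(vals[1:2, ]) - colMeans(vals[3:4, ]),
               ignore_attr = TRUE)
  expect_equal(unname(cv[1]), 1.5)
  expect_error(signature_score(em, "Slc1a2", "missing_gene"), "missing_gene")
  # equal positive and negative means give score zero
  z <- signature_score(em, c("Slc1a2", "Cyp2e1"), c("Slc1a2", "Cyp2e1"))
  expect_equal(unname(z), rep(0, 5))

  set.seed(77)
  n <- 100
  score <- rnorm(n)
  mat <- rbind(pos = 2 * score + rnorm(n, 0, 0.3),
               anti = -1.5 * score + rnorm(n, 0, 0.3),
               flat = rep(1, n),
               noise = rnorm(n))
  mat <- mat - min(mat)
  colnames(mat) <- sprintf("c%03d", 1:n)
  em2 <- expression_matrix(mat, norm_state = "lognorm")
  expect_message(rk <- rank_genes_by_score_correlation(em2, score,
                                                       cutoff = 0.3),
                 "zero-variance")
  expect_identical(rk$set[rk$gene == "pos"], "high")
  expect_identical(rk$set[rk$gene == "anti"], "low")
  expect_identical(rk$set[rk$gene == "flat"], "none")
  expect_equal(rk$r[rk$gene == "flat"], 0)
  rk1 <- suppressMessages(rank_genes_by_score_correlation(em2, score,
                                                          cutoff = 1))
  expect_true(all(rk1$set == "none"))
})
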