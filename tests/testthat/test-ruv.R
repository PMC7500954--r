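test_that("replicate map has one group per populated (patient, cluster)", {
  sim <- tiny_study(seed = 9, n_subpops = 4, cells_per_sample = 200,
                    n_patients = 3)
  cells <- arcsinh_transform(sim$cells)
  asg <- cluster_study(cells, n_meta = 4, grid_dims = c(3, 3), seed = 1)
  map <- build_replicate_map(asg, cells, sim$sheet,
                             reference_samples = c("P1", "P2"))
  keys <- t(vapply(map$groups, function(g)
    c(g$patient, g$metacluster), character(2)))
  expect_false(anyDuplicated(keys) > 0)
  expect_lte(nrow(keys), 2 * 4)
  expect_true(any(!vapply(map$groups, `[[`, TRUE, "single_batch")))
  # every grouped cell belongs to its reference patient
  pat <- sim$sheet$patient_id[match(cells$sample_id, sim$sheet$sample_id)]
  expect_true(all(pat[map$group_of_cell > 0] %in% c("P1", "P2")))

  # restriction to one cluster and one reference: at most one group
  map1 <- build_replicate_map(asg, cells, sim$sheet, "P1",
                              clusters_to_use = 2L)
  expect_lte(length(map1$groups), 1L)
})

test_that("replicate map validates references and cross-batch coverage", {
  sim <- tiny_study(seed = 10, cells_per_sample = 80)
  cells <- arcsinh_transform(sim$cells)
  asg <- cluster_study(cells, n_meta = 3, grid_dims = c(3, 3), seed = 1)
  expect_error(build_replicate_map(asg, cells, sim$sheet, "GHOST"), "GHOST")
  one_batch <- sim$sheet
  one_batch$batch <- 1L
  one_batch$sample_id <- paste0(one_batch$sample_id, seq_len(nrow(one_batch)))
  expect_error(build_replicate_map(asg, cells, one_batch, "P1"),
               "only 1 batch")
})

test_that("implementation matches the dense projection-formula oracle", {
  for (seed in 1:50) {
    inst <- random_instance(seed)
    k <- sample(1:3, 1)
    fit <- ruv_fit(inst$Y, inst$map, k)
    expect_lt(max(abs(fitted(fit) - dense_ruv_oracle(inst$Y, inst$map, k))),
              1e-8)
  }
})

test_that("cross-product SVD path equals the direct SVD path", {
  inst <- random_instance(99, m = 180, n = 6)   # m > 5n: crossprod route
  fit_fast <- ruv_fit(inst$Y, inst$map, 2)
  expect_lt(max(abs(fitted(fit_fast) -
                      dense_ruv_oracle(inst$Y, inst$map, 2))), 1e-8)
})

test_that("k = 0 fit is the identity adjustment", {
  inst <- random_instance(3)
  fit <- ruv_fit(inst$Y, inst$map, 0)
  expect_identical(residuals(fit), inst$Y)
  expect_equal(dim(coef(fit)), c(0L, ncol(inst$Y)))
  expect_identical(adjust(inst$Y, fit), inst$Y)
})

test_that("an aligned rank-1 batch effect is removed exactly", {
  # groups span 2 batches with identical within-batch means; the injected
  # effect w a' (w = batch-2 indicator) lies in the residual span and is
  # orthogonal to the remaining noise, so k = 1 removes it completely
  set.seed(21)
  m <- 120; n <- 6
  batch <- rep(1:2, each = m / 2)
  gid <- rep(1:4, times = m / 4)
  a <- rnorm(n); a <- a / sqrt(sum(a^2))
  Z <- matrix(rnorm(m * n), m, n)
  Z <- Z - Z %*% a %*% t(a)                 # noise orthogonal to a
  for (g in 1:4) for (b in 1:2) {           # equalize subgroup means
    i <- gid == g & batch == b
    Z[i, ] <- sweep(Z[i, , drop = FALSE], 2,
                    colMeans(Z[i, , drop = FALSE]), "-")
  }
  Y <- Z + 3 * (batch == 2) %*% t(a)
  groups <- lapply(1:4, function(g)
    list(patient = "P", metacluster = g, members = which(gid == g),
         batches = 1:2, single_batch = FALSE))
  map <- structure(list(group_of_cell = gid, groups = groups),
                   class = "replicate_map")
  adj <- residuals(ruv_fit(Y, map, 1))
  for (g in 1:4) {
    d <- colMeans(adj[gid == g & batch == 1, , drop = FALSE]) -
      colMeans(adj[gid == g & batch == 2, , drop = FALSE])
    expect_lt(max(abs(d)), 1e-8)
  }
})

test_that("W alpha is invariant to invertible reparameterization of alpha", {
  inst <- random_instance(7)
  fit <- ruv_fit(inst$Y, inst$map, 3)
  set.seed(1)
  Q <- matrix(rnorm(9), 3, 3)
  alpha2 <- Q %*% fit$alpha
  W2 <- inst$Y %*% t(alpha2) %*% solve(alpha2 %*% t(alpha2))
  expect_lt(max(abs(W2 %*% alpha2 - fitted(fit))), 1e-10)
})

test_that("the subtracted component grows monotonically with k", {
  inst <- random_instance(13, m = 150, n = 8)
  norms <- vapply(0:4, function(k)
    sqrt(sum(fitted(ruv_fit(inst$Y, inst$map, k))^2)), numeric(1))
  expect_true(all(diff(norms) >= -1e-10))
})

test_that("adjusted column means stay at zero", {
  inst <- random_instance(17)
  adj <- residuals(ruv_fit(inst$Y, inst$map, 2))
  expect_lt(max(abs(colMeans(adj))), 1e-10)
})

test_that("degenerate fits are rejected or capped", {
  inst <- random_instance(23, m = 60, n = 5)
  empty_map <- structure(list(group_of_cell = integer(60), groups = list()),
                         class = "replicate_map")
  expect_error(ruv_fit(inst$Y, empty_map, 1), "singleton")
  expect_error(ruv_fit(inst$Y, inst$map, 99), "exceed")
  # rank-1 residuals: requesting k = 3 caps to 1 with a warning
  one_group <- structure(list(
    group_of_cell = rep(c(1L, 0L), c(2, 58)),
    groups = list(list(patient = "P", metacluster = 1, members = 1:2,
                       batches = 1:2, single_batch = FALSE))),
    class = "replicate_map")
  expect_warning(fit <- ruv_fit(inst$Y, one_group, 3), "rank")
  expect_identical(fit$k, 1L)
})

test_that("normalize_study on a null study barely changes the data", {
  # full-size panel, zero shift/unit scale: with k = 5 the removal
  # concentrates on a few noise-dominated channels, so the median
  # per-protein change stays at the leakage level
  cfg <- default_study("two_batch_paper_like", seed = 30)
  cfg$cells_per_sample <- 400L
  cfg$batch_shift[] <- 0
  cfg$cluster_shift[] <- 0
  sim <- simulate_study(cfg)
  cells <- arcsinh_transform(sim$cells)
  nm <- normalize_study(cells, sim$sheet, c("HC1", "CLL2"), k = 5, seed = 1)
  med_change <- apply(abs(nm$adjusted$values - cells$values), 2,
                      stats::median)
  expect_lt(stats::median(med_change), 0.05)
})

test_that("normalize_study validates references before computing", {
  sim <- tiny_study(seed = 31, cells_per_sample = 60)
  cells <- arcsinh_transform(sim$cells)
  expect_error(normalize_study(cells, sim$sheet, "NOBODY", k = 1),
               "NOBODY")
})

test_that("percentile baseline equalizes reference percentiles exactly", {
  sim <- tiny_study(seed = 32, cells_per_sample = 300,
                    shift2 = rep(0.4, 8))
  raw <- sim$cells
  scaled <- percentile_scale_baseline(raw, sim$sheet, "P1")
  pat <- sim$sheet$patient_id[match(raw$sample_id, sim$sheet$sample_id)]
  q <- function(tbl, b) apply(tbl$values[pat == "P1" & tbl$batch == b, ],
                              2, quantile, probs = 0.95)
  expect_lt(max(abs(q(scaled, 1) - q(scaled, 2))), 1e-9)
  # batch 1 anchors: unchanged there
  expect_identical(scaled$values[raw$batch == 1, ],
                   raw$values[raw$batch == 1, ])

  # hand-made ratio check: reference 95th percentiles 10 vs 20 -> factor 0.5
  v <- matrix(c(seq(0, 10, length.out = 100),
                seq(0, 20, length.out = 100)), ncol = 1)
  cellsr <- tiny_cells(v, rep(c("R1", "R2"), each = 100),
                       rep(c(1L, 2L), each = 100), tiny_panel(1, 0),
                       scale = "raw")
  sheetr <- data.frame(sample_id = c("R1", "R2"), patient_id = "R",
                       condition = "x", batch = 1:2, file_path = NA)
  sc <- percentile_scale_baseline(cellsr, sheetr, "R")
  expect_equal(sc$values[101:200, 1], v[101:200, 1] * 0.5, tolerance = 1e-9)

  # identical batches: factors are 1, data unchanged
  same <- tiny_cells(rbind(v[1:100, , drop = FALSE], v[1:100, , drop = FALSE]),
                     rep(c("R1", "R2"), each = 100),
                     rep(c(1L, 2L), each = 100), tiny_panel(1, 0),
                     scale = "raw")
  expect_equal(percentile_scale_baseline(same, sheetr, "R")$values,
               same$values)
})
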