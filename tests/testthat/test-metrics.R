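test_that("emd_1d matches closed forms", {
  set.seed(1)
  x <- rnorm(500)
  expect_equal(emd_1d(x, x), 0)
  # two point masses one unit apart: W1 = 1
  expect_equal(emd_1d(rep(0, 100), rep(1, 100)), 1, tolerance = 1e-9)
  # translation: W1(x, x + c) = c, up to one bin width
  c0 <- 0.73
  expect_lt(abs(emd_1d(x, x + c0) - c0), 0.1)
  # equal-variance Gaussians: W1 = |mu1 - mu2|, error <= bin width at 0.1
  y <- rnorm(200000, mean = 1.5)
  x2 <- rnorm(200000)
  expect_lt(abs(emd_1d(x2, y, 0.1) - 1.5), 0.1)
  expect_error(emd_1d(numeric(0), x), "nonempty")
  expect_error(emd_1d(x, x, bin_width = 0), "positive")
})

test_that("emd_1d is symmetric and ordering-invariant", {
  set.seed(2)
  x <- rnorm(300); y <- rnorm(300, 0.4)
  expect_equal(emd_1d(x, y), emd_1d(y, x))
  expect_equal(emd_1d(sample(x), y), emd_1d(x, y))
})

test_that("emd_study reports per-protein cross-batch distances", {
  shift <- c(0.8, 0.6, 0, 0, 0.5, 0, 0.3, 0)
  sim <- tiny_study(seed = 40, cells_per_sample = 400, shift2 = shift)
  cells <- arcsinh_transform(sim$cells)
  emd <- emd_study(cells, NULL, sim$sheet)
  raw <- emd[emd$dataset == "raw" & emd$patient == "P1", ]
  # shift-only effect: per-protein EMD approximates the shift
  expect_lt(max(abs(raw$emd - shift)), 0.15)
  # identical "normalized" data give identical tables
  both <- emd_study(cells, cells, sim$sheet)
  expect_equal(both$emd[both$dataset == "raw"],
               both$emd[both$dataset == "norm"])
})

test_that("per-cluster EMD marks clusters absent from a batch as missing", {
  X <- rbind(matrix(rnorm(50 * 2), 50, 2),
             matrix(rnorm(50 * 2, 6), 50, 2),
             matrix(rnorm(50 * 2), 50, 2))   # cluster 2 absent in batch 2
  cells <- tiny_cells(X, rep(c("A_B1", "A_B2"), c(100, 50)),
                      rep(c(1L, 2L), c(100, 50)), tiny_panel(2, 0))
  sheet <- data.frame(sample_id = c("A_B1", "A_B2"), patient_id = "A",
                      condition = "x", batch = 1:2, file_path = NA)
  asg <- structure(list(node_id = rep(1L, 150),
                        metacluster_id = rep(c(1L, 2L, 1L), each = 50),
                        n_meta = 2L, mapping = 1:2),
                   class = "cluster_assignment")
  emd <- emd_study(cells, NULL, sheet, assignment = asg, by_cluster = TRUE)
  expect_true(all(is.na(emd$emd[emd$metacluster == 2])))
  expect_true(all(!is.na(emd$emd[emd$metacluster == 1])))
})

test_that("hellinger matches closed forms and is a [0,1] metric", {
  expect_equal(hellinger(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(hellinger(c(1, 0), c(0, 1)), 1)
  # closed form sqrt(1 - sqrt(2)/2)
  expect_equal(hellinger(c(0.5, 0.5), c(1, 0)), 0.541196, tolerance = 1e-6)
  expect_error(hellinger(c(0.5, 0.5), c(0.7, 0.4)), "sum to 1")
  expect_error(hellinger(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
  expect_error(hellinger(c(1), c(0.5, 0.5)), "equal length")
  # symmetry, range, triangle inequality on random simplex triples
  set.seed(3)
  for (i in 1:25) {
    p <- rgamma(5, 1); p <- p / sum(p)
    q <- rgamma(5, 1); q <- q / sum(q)
    r <- rgamma(5, 1); r <- r / sum(r)
    expect_equal(hellinger(p, q), hellinger(q, p))
    expect_gte(hellinger(p, q), 0)
    expect_lte(hellinger(p, q), 1)
    expect_lte(hellinger(p, q), hellinger(p, r) + hellinger(r, q) + 1e-12)
  }
})

test_that("hellinger_study compares replicated samples across batches", {
  set.seed(4)
  X <- matrix(rnorm(200 * 2), 200, 2)
  cells <- tiny_cells(rbind(X, X), rep(c("A_B1", "A_B2"), each = 200),
                      rep(c(1L, 2L), each = 200), tiny_panel(2, 0))
  sheet <- data.frame(sample_id = c("A_B1", "A_B2"), patient_id = "A",
                      condition = "x", batch = 1:2, file_path = NA)
  asg <- cluster_study(cells, n_meta = 3, grid_dims = c(2, 2), seed = 1)
  h <- hellinger_study(asg, cells, sheet)
  expect_equal(nrow(h), 1L)
  expect_equal(h$hellinger, 0)        # identical cell sets
})

test_that("silhouette matches the hand-computed 1D example", {
  # {0, 0.2 | 10, 10.2}: a = 0.2 everywhere; b = 10.1 or 9.9
  cells <- tiny_cells(matrix(c(0, 0.2, 10, 10.2), 4, 1), paste0("S", 1:4),
                      rep(1L, 4), tiny_panel(1, 0))
  res <- silhouette_scores(cells, grouping = c(1, 1, 2, 2),
                           subsample = Inf)
  expect_equal(res$score, 0.980, tolerance = 5e-4)
  expect_equal(sort(unique(round(res$s, 4))), c(0.9798, 0.9802))
})

test_that("silhouette equals the O(m^2) brute-force oracle exactly", {
  sim <- tiny_study(seed = 50, n_subpops = 3, cells_per_sample = 120,
                    n_patients = 2)
  cells <- arcsinh_transform(sim$cells)
  res <- silhouette_scores(cells, sim$truth$subpop, subsample = 60,
                           seed = 2)
  brute <- brute_silhouette(cells$values[res$index, , drop = FALSE],
                            sim$truth$subpop[res$index])
  expect_equal(res$s, brute, tolerance = 1e-12)
  # against the field-standard implementation as well
  ref <- cluster::silhouette(as.integer(factor(sim$truth$subpop[res$index])),
                             dist(cells$values[res$index, ]))
  expect_equal(res$score, mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("random labels on identical distributions give s near 0", {
  set.seed(5)
  X <- matrix(rnorm(400 * 3), 400, 3)
  cells <- tiny_cells(X, rep("S1", 400), rep(1L, 400), tiny_panel(3, 0))
  res <- silhouette_scores(cells, sample(1:2, 400, replace = TRUE),
                           subsample = Inf)
  expect_lt(abs(res$score), 0.05)
})

test_that("silhouette rejects under-filled groups with advice", {
  cells <- tiny_cells(matrix(rnorm(20), 10, 2), rep("S1", 10), rep(1L, 10),
                      tiny_panel(2, 0))
  expect_error(silhouette_scores(cells, c(1, rep(2, 9)), subsample = Inf),
               "increase")
  expect_error(silhouette_scores(cells, rep(1, 10), subsample = Inf),
               ">= 2 groups")
})

test_that("silhouette is invariant to cell ordering", {
  sim <- tiny_study(seed = 51, n_subpops = 3, cells_per_sample = 60,
                    n_patients = 2)
  cells <- arcsinh_transform(sim$cells)
  res1 <- silhouette_scores(cells, sim$truth$subpop, subsample = Inf)
  set.seed(6)
  perm <- sample(nrow(cells$values))
  res2 <- silhouette_scores(ct_subset(cells, perm),
                            sim$truth$subpop[perm], subsample = Inf)
  expect_equal(res1$score, res2$score, tolerance = 1e-12)
})

test_that("delta-delta medians behave like the definition", {
  sim <- tiny_study(seed = 52, cells_per_sample = 200)
  cells <- arcsinh_transform(sim$cells)
  # norm = raw: delta_delta is 0 everywhere
  dd0 <- delta_delta_medians(cells, cells, sim$sheet)
  expect_equal(dd0$delta_delta, rep(0, 8))
  # constructed: one marker shifted by +0.3 in batch 2, perfectly corrected
  shifted <- cells
  shifted$values[cells$batch == 2, 1] <-
    shifted$values[cells$batch == 2, 1] + 0.3
  dd <- delta_delta_medians(shifted, cells, sim$sheet)
  expect_equal(dd$delta_raw[1] - dd$delta_norm[1], dd$delta_delta[1])
  expect_equal(dd$delta_delta[1], 0.3, tolerance = 1e-9)
  expect_equal(dd$delta_delta[-1], rep(0, 7), tolerance = 1e-9)
  # swapping batch labels flips every delta's sign
  swapped <- shifted
  swapped$batch <- 3L - shifted$batch
  sheet_sw <- sim$sheet
  sheet_sw$batch <- 3L - sheet_sw$batch
  dd_sw <- delta_delta_medians(swapped, cells, sheet_sw)
  expect_equal(dd_sw$delta_raw, -dd$delta_raw, tolerance = 1e-12)
  # >2 batches is rejected
  sim3 <- tiny_study(seed = 53, n_batches = 3, cells_per_sample = 50)
  cells3 <- arcsinh_transform(sim3$cells)
  expect_error(delta_delta_medians(cells3, cells3, sim3$sheet),
               "exactly 2 batches")
})
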