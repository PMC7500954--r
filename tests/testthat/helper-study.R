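# Small in-code fixtures shared across test files.

# minimal panel: nl lineage + nf functional proteins
tiny_panel <- function(nl = 3, nf = 2) {
  n <- nl + nf
  data.frame(metal = sprintf("M%03d", seq_len(n)),
             antigen = sprintf("%s%02d", c(rep("LIN", nl), rep("FUN", nf)),
                               c(seq_len(nl), seq_len(nf))),
             class = c(rep("lineage", nl), rep("functional", nf)),
             stringsAsFactors = FALSE)
}

# cell table from an explicit matrix
tiny_cells <- function(values, sample_id, batch, panel = NULL,
                       scale = "arcsinh") {
  values <- as.matrix(values)
  if (is.null(panel)) panel <- tiny_panel(ncol(values), 0)
  colnames(values) <- panel$antigen
  cell_table(values, sample_id, batch, panel, scale = scale)
}

# scaled-down synthetic study: few subpopulations, few cells, fast
tiny_study <- function(seed = 1, n_subpops = 5, cells_per_sample = 150,
                       n_patients = 4, n_batches = 2, shift2 = NULL,
                       sds = 0.3, n_proteins = 8, n_lineage = 5) {
  set.seed(seed + 500)
  on_off <- matrix(rbinom(n_subpops * n_lineage, 1, 0.5),
                   n_subpops, n_lineage)
  while (anyDuplicated(on_off)) {
    dup <- which(duplicated(on_off))
    on_off[dup, ] <- rbinom(length(dup) * n_lineage, 1, 0.5)
  }
  means <- cbind(0.4 + 2.8 * on_off,
                 matrix(runif(n_subpops * (n_proteins - n_lineage), 0.5, 2.5),
                        n_subpops))
  patients <- data.frame(
    patient_id = paste0("P", seq_len(n_patients)),
    condition = rep(c("A", "B"), length.out = n_patients),
    stringsAsFactors = FALSE)
  ab <- matrix(rgamma(n_patients * n_subpops, 2), n_patients)
  ab <- ab / rowSums(ab)
  batch_shift <- matrix(0, n_batches, n_proteins)
  if (!is.null(shift2)) batch_shift[2, ] <- shift2
  cfg <- synthetic_config(
    n_proteins = n_proteins, n_lineage = n_lineage, n_subpops = n_subpops,
    n_batches = n_batches, patients = patients,
    cells_per_sample = cells_per_sample,
    subpop_means = means, subpop_sds = sds, abundance = ab,
    batch_shift = batch_shift,
    batch_scale = matrix(1, n_batches, n_proteins), seed = seed)
  simulate_study(cfg)
}

# independent dense-projection oracle for the unwanted-variation fit:
# residual operator built as an explicit (I - M (M'M)^{-1} M') matrix, full
# SVD, pseudo-inverse regression for W. Never shares code with ruv_fit().
dense_ruv_oracle <- function(Y, map, k) {
  m <- nrow(Y)
  # membership design matrix: every cell in exactly one column
  # (its group, or its own singleton column)
  gid <- map$group_of_cell
  singles <- which(gid == 0)
  cols <- length(map$groups) + length(singles)
  M <- matrix(0, m, cols)
  for (g in seq_along(map$groups))
    M[map$groups[[g]]$members, g] <- 1
  for (j in seq_along(singles))
    M[singles[j], length(map$groups) + j] <- 1
  P <- diag(m) - M %*% solve(crossprod(M)) %*% t(M)
  R <- P %*% Y
  sv <- svd(R)
  a <- diag(sv$d[seq_len(k)], k, k) %*% t(sv$v[, seq_len(k), drop = FALSE])
  W <- Y %*% t(a) %*% solve(a %*% t(a))
  W %*% a
}

# brute-force silhouette, O(m^2) double loop over cells
brute_silhouette <- function(X, labels) {
  m <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(vapply(own, function(j) d(i, j), 1))
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(vapply(which(labels == g), function(j) d(i, j), 1))
    }, 1))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# random small instance: standardized matrix + replicate map
random_instance <- function(seed, m = NULL, n = NULL) {
  set.seed(seed)
  if (is.null(m)) m <- sample(30:200, 1)
  if (is.null(n)) n <- sample(4:10, 1)
  Y <- scale(matrix(rnorm(m * n), m, n))
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  n_groups <- sample(2:5, 1)
  gid <- integer(m)
  pool <- sample(m, min(m, n_groups * sample(3:8, 1)))
  gid[pool] <- sample(n_groups, length(pool), replace = TRUE)
  groups <- list()
  for (g in seq_len(n_groups)) {
    members <- which(gid == g)
    if (length(members) < 2) { gid[members] <- 0L; next }
    groups[[length(groups) + 1L]] <- list(patient = "P", metacluster = g,
                                          members = members, batches = 1:2,
                                          single_batch = FALSE)
  }
  gid2 <- integer(m)
  for (g in seq_along(groups)) gid2[groups[[g]]$members] <- g
  map <- structure(list(group_of_cell = gid2, groups = groups),
                   class = "replicate_map")
  list(Y = Y, map = map)
}

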