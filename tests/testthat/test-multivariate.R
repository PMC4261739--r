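# Full-matrix selection, NIPALS PCA, correlated pairs, distances, trees.

test_that("full-matrix selection reproduces the worked traces", {
  v <- matrix(rnorm(60), 10, 6,
              dimnames = list(sprintf("c%02d", 1:10), NULL))
  v[1:3, 3] <- NA
  v[4, 5] <- NA
  # mpc = 0.10: budget 1 chain; column 3 would need 3 -> loop exits;
  # columns 3 and 5 dropped
  f1 <- select_full_matrix(dm(v), mpc = 0.10)
  expect_equal(f1$kept_chains, sprintf("c%02d", 1:10))
  expect_equal(f1$kept_columns, c(1, 2, 4, 6))
  expect_equal(f1$removed_chain_fraction, 0)
  # mpc = 0.40: budget 4; chains 1-3 then 4 removed, all columns kept
  f2 <- select_full_matrix(dm(v), mpc = 0.40)
  expect_equal(f2$kept_chains, sprintf("c%02d", 5:10))
  expect_equal(f2$kept_columns, 1:6)
  expect_equal(f2$removed_chain_fraction, 0.4)
  # gap-free input unchanged
  f3 <- select_full_matrix(dm(matrix(1:12, 3, 4)), 0.1)
  expect_equal(dim(f3$values), c(3L, 4L))
  expect_equal(f3$removed_chain_fraction, 0)
})

test_that("full-matrix selection agrees with the loop simulation on random gaps", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    m <- sample(4:10, 1)
    v <- matrix(rnorm(n * m), n, m,
                dimnames = list(sprintf("c%02d", 1:n), NULL))
    v[sample(n * m, round(0.15 * n * m))] <- NA
    mpc <- sample(c(0.1, 0.25, 0.4), 1)
    ref <- o_select_full(v, mpc)
    got <- tryCatch(select_full_matrix(dm(v), mpc), error = function(e) e)
    if (length(ref$chains) == 0 || length(ref$cols) == 0) {
      expect_s3_class(got, "error")
    } else {
      expect_equal(sort(match(got$kept_chains, rownames(v))), ref$chains)
      expect_equal(got$kept_columns, ref$cols)
      expect_false(anyNA(got$values))
      expect_lte(nrow(v) - length(ref$chains), floor(mpc * n))
    }
  }
})

test_that("NIPALS reproduces the SVD on complete matrices", {
  set.seed(13)
  X <- matrix(rnorm(40), 8, 5)
  pca <- nipals_pca(X, k = 3)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  for (comp in 1:3) {
    p_ref <- sv$v[, comp]
    if (p_ref[which.max(abs(p_ref))] < 0) p_ref <- -p_ref
    expect_equal(pca$loadings[, comp], p_ref, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(abs(pca$scores[, comp]), abs(Xc %*% sv$v[, comp])[, 1],
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(pca$explained_variance_fraction[comp],
                 sv$d[comp]^2 / sum(sv$d^2), tolerance = 1e-6)
  }
  expect_true(all(abs(colSums(pca$loadings^2) - 1) < 1e-9))
})

test_that("a rank-1 matrix loads everything on PC1", {
  set.seed(14)
  X <- outer(rnorm(6), rnorm(4))
  pca <- nipals_pca(X, k = 2)
  expect_equal(pca$explained_variance_fraction[1], 1.0, tolerance = 1e-9)
})

test_that("PC1 separates a two-cluster ensemble by sign", {
  set.seed(15)
  centr <- rbind(rep(0, 6), rep(4, 6))
  lab <- rep(1:2, each = 10)
  X <- centr[lab, ] + matrix(rnorm(120, 0, 0.3), 20, 6)
  pca <- nipals_pca(X, k = 1)
  s <- pca$scores[, 1]
  expect_true(all(s[lab == 1] * mean(s[lab == 1]) > 0))
  expect_true(all(s[lab == 2] * mean(s[lab == 2]) > 0))
  expect_true(mean(s[lab == 1]) * mean(s[lab == 2]) < 0)
})

test_that("PCA variables interleave positions with provenance labels", {
  k <- dm(matrix(rnorm(12), 3, 4), "kappa")
  t <- dm(matrix(rnorm(12), 3, 4), "tau")
  vars <- assemble_pca_variables(list(kappa = k, tau = t))
  expect_equal(colnames(vars$values),
               c("p1_kappa", "p1_tau", "p2_kappa", "p2_tau",
                 "p3_kappa", "p3_tau", "p4_kappa", "p4_tau"))
  # a fully masked component column contributes no variable
  t$values[, 2] <- NA
  vars2 <- assemble_pca_variables(list(kappa = k, tau = t))
  expect_false("p2_tau" %in% colnames(vars2$values))
})

test_that("hinge-pivot variables dominate PC1 loadings", {
  q <- quick_ens(n_chains = 16, length = 40, seed = 21, jitter_sd = 0.05,
                 features = list(hinge = list(pivot = 20, angle = 30)))
  geo <- backbone_geometry(q$ens)
  vars <- assemble_pca_variables(list(kappa = standardise(geo$kappa),
                                      tau = standardise(geo$tau)))
  pca <- nipals_pca(select_full_matrix(vars, 0.1), k = 1)
  top <- rownames(pca$loadings)[which.max(abs(pca$loadings[, 1]))]
  pos <- as.integer(sub("^p([0-9]+)_.*", "\\1", top))
  expect_lte(abs(pos - 20), 2)
})

test_that("correlated pairs honour the separation cutoff and find planted signal", {
  set.seed(31)
  n <- 60; m <- 50
  v <- matrix(rnorm(n * m), n, m, dimnames = list(sprintf("c%02d", 1:n),
                                                  NULL))
  z <- rnorm(n)
  v[, 5] <- z
  v[, 45] <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  v[, 10] <- v[, 39]            # separation 29: must not appear
  cp <- correlated_pairs(list(dm(v)), min_separation = 30, top_k = 10)
  expect_equal(c(cp$position_a[1], cp$position_b[1]), c(5, 45))
  expect_lt(abs(cp$r[1] - 0.9), 0.1)
  expect_false(any(cp$position_a == 10 & cp$position_b == 39))
  expect_true(all(abs(cp$position_a - cp$position_b) >= 30))
  expect_true(all(diff(abs(cp$r)) <= 1e-12))
})

test_that("constant columns and short overlaps are excluded from pairing", {
  v <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("c%02d", 1:10),
                                                NULL))
  v[, 2] <- 7                       # zero variance
  v[3:10, 4] <- NA                  # only 2 complete pairs vs column 1
  cp <- correlated_pairs(list(dm(v)), min_separation = 1, top_k = 100)
  expect_false(any(cp$position_a == 2 | cp$position_b == 2))
  expect_false(any(cp$position_a == 1 & cp$position_b == 4))
})

test_that("chain distances satisfy their definitions and metric properties", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(chain_distance(a, a), 0)
  expect_equal(chain_distance(a, -a + 10), 1)
  expect_equal(chain_distance(a, a, mode = "tanimoto"), 0)
  bits_a <- c(TRUE, TRUE, TRUE, FALSE)
  bits_b <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(chain_distance(bits_a, bits_b, mode = "tanimoto"), 0.5)
  expect_equal(chain_distance(logical(4), logical(4), mode = "tanimoto"), 0)
  expect_warning(d <- chain_distance(c(1, 2, NA, NA), c(1, NA, 2, NA)),
                 "fewer than 3")
  expect_true(is.na(d))
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(chain_distance(x, y), o_pearson_dist(x, y),
                 tolerance = 1e-12)
    bx <- runif(12) > 0.5; by <- runif(12) > 0.5
    d <- chain_distance(bx, by, mode = "tanimoto")
    expect_equal(d, o_tanimoto_dist(bx, by), tolerance = 1e-12)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(chain_distance(y, x), chain_distance(x, y),
                 tolerance = 1e-12)
  }
})

test_that("clustering recovers planted groups and round-trips Newick", {
  set.seed(51)
  base1 <- rnorm(30); base2 <- rnorm(30)
  rows <- rbind(
    t(replicate(4, base1 + rnorm(30, 0, 0.05))),
    t(replicate(4, base2 + rnorm(30, 0, 0.05))))
  rownames(rows) <- sprintf("c%02d", 1:8)
  D <- descriptor_distances(dm(rows))
  res <- cluster_chains(D, cut = 0.2)
  expect_equal(length(unique(res$grouping)), 2)
  expect_equal(length(unique(res$grouping[1:4])), 1)
  expect_equal(length(unique(res$grouping[5:8])), 1)
  phy <- ape::read.tree(text = res$tree$newick)
  expect_setequal(phy$tip.label, rownames(rows))
  # merge heights non-decreasing
  expect_true(all(diff(res$tree$hclust$height) >= -1e-12))
  # identical chains collapse into one group at a 1% cut
  same <- matrix(rep(rnorm(20), each = 4), 4, 20,
                 dimnames = list(letters[1:4], NULL))
  res2 <- cluster_chains(descriptor_distances(dm(same)), cut = 0.01)
  expect_equal(length(unique(res2$grouping)), 1)
})
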