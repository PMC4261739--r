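# Per-position statistics against their definitional oracles.

test_that("variability reproduces hand-computed cases", {
  # identical chains -> 0 everywhere
  v0 <- variability(list(dm(matrix(1.7, 5, 4))))
  expect_true(all(v0$values == 0))
  # kappa {0,0,0,4}, tau all 0 -> median 0, mean distance 1.0
  k <- dm(matrix(c(0, 0, 0, 4), 4, 1), "kappa")
  t <- dm(matrix(0, 4, 1), "tau")
  expect_equal(variability(list(k, t))$values, 1.0)
  # 40% coverage below min_fraction 0.5 -> masked
  x <- matrix(rnorm(10), 10, 1)
  x[5:10, 1] <- NA
  expect_true(is.na(variability(list(dm(x)), 0.5)$values))
})

test_that("dihedral order-parameter variability handles canonical cases", {
  # identical angles -> 0
  phi <- dm(matrix(-57, 4, 2), "phi")
  psi <- dm(matrix(-47, 4, 2), "psi")
  expect_equal(dihedral_variability(phi, psi)$values, c(0, 0))
  # psi antipodal in two chains -> S(psi) = 0, variability 0.5
  phi2 <- dm(matrix(10, 2, 1))
  psi2 <- dm(matrix(c(30, 30 - 180), 2, 1))
  expect_equal(dihedral_variability(phi2, psi2)$values, 0.5,
               tolerance = 1e-12)
  # four phis at 0/90/180/270 -> S(phi) = 0, variability 0.5
  phi3 <- dm(matrix(c(0, 90, 180, 270), 4, 1))
  psi3 <- dm(matrix(77, 4, 1))
  expect_equal(dihedral_variability(phi3, psi3)$values, 0.5,
               tolerance = 1e-12)
  # single-chain column masked
  phi4 <- dm(matrix(c(10, NA), 2, 1))
  expect_true(is.na(dihedral_variability(phi4, dm(matrix(1, 2, 1)),
                                         min_fraction = 0)$values))
})

test_that("grouped variance matches its worked examples", {
  g2 <- as_grouping(c(a = 0, b = 0, c = 1, d = 1))
  m1 <- dm(matrix(c(0, 0, 1, 1), 4, 1,
                  dimnames = list(c("a", "b", "c", "d"), NULL)))
  gv <- group_variance(m1, g2)
  expect_equal(gv$S, 0.25)
  expect_equal(unname(gv$s[, 1]), c(0.25, 0.25))
  m2 <- dm(matrix(c(0, 1, 0, 1), 4, 1,
                  dimnames = list(c("a", "b", "c", "d"), NULL)))
  expect_equal(group_variance(m2, g2)$S, 0.25)
  expect_equal(group_variance(dm(matrix(3, 4, 2,
                                        dimnames = list(letters[1:4],
                                                        NULL))),
                              g2)$S, c(0, 0))
})

test_that("statistics match brute-force oracles on random masked inputs", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:9, 1)
    m <- sample(3:8, 1)
    v1 <- matrix(rnorm(n * m), n, m)
    v2 <- matrix(rnorm(n * m), n, m)
    v1[sample(n * m, n)] <- NA
    v2[is.na(v1)] <- NA
    ids <- sprintf("c%02d", 1:n)
    rownames(v1) <- rownames(v2) <- ids
    groups <- sample(0:2, n, replace = TRUE)
    expect_equal(variability(list(dm(v1), dm(v2)), 0.25)$values,
                 o_variability(list(v1, v2), 0.25), tolerance = 1e-9)
    ph <- v1 * 40; ps <- v2 * 40
    expect_equal(dihedral_variability(dm(ph), dm(ps), 0.25)$values,
                 o_dihedral_var(ph, ps, 0.25), tolerance = 1e-9)
    expect_equal(group_variance(dm(v1),
                                as_grouping(setNames(groups, ids)))$S,
                 o_group_variance(v1, groups), tolerance = 1e-9)
  }
})

test_that("window RMSF vanishes for identical or rigidly moved chains", {
  q <- quick_ens(n_chains = 4, length = 15, seed = 3, jitter_sd = 0)
  ref <- names(q$ens$chains)[1]
  r <- rmsf_window(q$ens, ref)
  expect_true(all(r$values[!is.na(r$values)] < 1e-9))
  # rigid global motions are removed by the window fit
  moved <- lapply(seq_along(q$fx$chains), function(i) {
    set.seed(i)
    transform_chain(q$fx$chains[[i]], ensflex:::.random_rotation(),
                    rnorm(3, 0, 20))
  })
  ens2 <- build_ensemble(moved, q$fx$alignment)
  r2 <- rmsf_window(ens2, ref)
  expect_true(all(r2$values[!is.na(r2$values)] < 1e-9))
})

test_that("window RMSF equals the quaternion-superposition oracle", {
  q <- quick_ens(n_chains = 5, length = 14, seed = 9, jitter_sd = 0.15)
  ref <- names(q$ens$chains)[2]
  mine <- rmsf_window(q$ens, ref)
  ids <- names(q$ens$chains)
  A <- array(NA_real_, c(length(ids), q$ens$m, 3),
             dimnames = list(ids, NULL, NULL))
  for (cid in ids) {
    ca <- t(vapply(q$ens$chains[[cid]]$residues,
                   function(r) r$xyz["CA", ], numeric(3)))
    A[cid, q$ens$col_of[[cid]], ] <- ca
  }
  expect_equal(mine$values, o_rmsf(A, ref), tolerance = 1e-9)
  # a 2 A perpendicular displacement of one CA registers at its column
  ch2 <- q$fx$chains
  ch2[[3]]$residues[[7]]$xyz["CA", ] <-
    ch2[[3]]$residues[[7]]$xyz["CA", ] + c(0, 0, 2)
  ens3 <- build_ensemble(ch2, q$fx$alignment)
  r3 <- rmsf_window(ens3, ref)
  A[ids[3], 7, ] <- A[ids[3], 7, ] + c(0, 0, 2)
  expect_equal(r3$values, o_rmsf(A, ref), tolerance = 1e-9)
  expect_gt(r3$values[7], mine$values[7])
})

test_that("B-factor normalisation trims outliers iteratively", {
  mk <- function(b) {
    residues <- lapply(seq_along(b), function(i)
      list(resname = "ALA", resseq = i, icode = "",
           xyz = matrix(c(i * 3.8, 0, 0), 1, 3, dimnames = list("CA", NULL)),
           b = c(CA = b[i])))
    new_chain("b_A_m1", residues)
  }
  expect_warning(z <- normalise_bfactors(mk(rep(12, 8))), "zero B-factor")
  expect_true(all(z == 0))
  # twenty 10s and one 200: the 200 trims away, sd collapses to 0
  expect_warning(z2 <- normalise_bfactors(mk(c(rep(10, 20), 200))),
                 "zero B-factor")
  expect_true(all(z2 == 0))
  set.seed(33)
  b <- c(rnorm(40, 20, 5), 80, 80)
  z3 <- normalise_bfactors(mk(b))
  expect_equal(z3, o_bnorm(b), tolerance = 1e-9)
  expect_true(all(z3[41:42] > 10))
  expect_lt(abs(mean(z3[1:40])), 0.5)
})

test_that("contact fractions equal the O(N^2) distance oracle", {
  q <- quick_ens(n_chains = 3, length = 10, seed = 5, jitter_sd = 0.05)
  ids <- names(q$ens$chains)
  # no partners -> all zero
  none <- contact_fraction(q$ens, setNames(vector("list", 3), ids))
  expect_true(all(none$values == 0))
  # partner at 4.9 A from one residue's CA in every chain
  partners <- lapply(ids, function(cid) {
    ca <- q$ens$chains[[cid]]$residues[[5]]$xyz["CA", ]
    matrix(ca + c(4.9, 0, 0), 1, 3)
  })
  names(partners) <- ids
  cf <- contact_fraction(q$ens, partners, cutoff = 5.0)
  expect_equal(cf$values[5], 1.0)
  # random clouds vs brute force
  set.seed(55)
  clouds <- lapply(ids, function(cid)
    matrix(rnorm(30, 0, 10), 10, 3))
  names(clouds) <- ids
  cf2 <- contact_fraction(q$ens, clouds, cutoff = 6.0)
  brute <- sapply(seq_len(q$ens$m), function(j) {
    hits <- sapply(ids, function(cid) {
      i <- q$ens$res_of[[cid]][j]
      if (is.na(i)) return(NA)
      o_contact_bits(q$ens$chains[[cid]]$residues[[i]]$xyz,
                     clouds[[cid]], 6.0)
    })
    mean(hits, na.rm = TRUE)
  })
  expect_equal(cf2$values, brute, tolerance = 1e-12)
})
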