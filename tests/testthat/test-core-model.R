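# Chain parsing, alignment mapping and the masked matrix container.

write_test_pdb <- function(path, models = 1, chains = c("A", "B"),
                           n_res = 8, altloc = FALSE) {
  lines <- character(0)
  serial <- 0
  for (mdl in seq_len(models)) {
    if (models > 1) lines <- c(lines, sprintf("MODEL     %4d", mdl))
    for (ch in chains) {
      nr <- if (is.list(n_res)) n_res[[ch]] else n_res
      for (i in seq_len(nr)) {
        serial <- serial + 1
        x <- i * 3.8 + mdl * 0.01
        emit <- function(alt, occ, xoff)
          sprintf("ATOM  %5d  CA %s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                  serial, alt, "ALA", ch, i, x + xoff,
                  1.0 * (ch == "B"), 0.0, occ, 20.0)
        if (altloc && i == 2) {
          lines <- c(lines, emit("A", 0.4, 0), emit("B", 0.6, 5))
        } else {
          lines <- c(lines, emit(" ", 1.0, 0))
        }
      }
      lines <- c(lines, "TER")
    }
    if (models > 1) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

test_that("multi-model multi-chain files expand per model policy", {
  f <- write_test_pdb(tempfile(fileext = ".pdb"), models = 2)
  expect_length(read_chains(f, model_policy = "all"), 4)
  expect_length(read_chains(f, model_policy = "first"), 2)
  ids <- vapply(read_chains(f, model_policy = "all"), `[[`, "", "chain_id")
  expect_true(all(grepl("_(A|B)_m[12]$", ids)))
})

test_that("short chains are skipped with a warning; missing file is an error", {
  f <- write_test_pdb(tempfile(fileext = ".pdb"),
                      chains = c("A", "C"), n_res = list(A = 8, C = 3))
  expect_warning(chains <- read_chains(f), "skipped")
  expect_length(chains, 1)
  expect_match(chains[[1]]$chain_id, "_A_m1$")
  expect_error(read_chains("/nonexistent/file.pdb"), "cannot read")
})

test_that("alternate locations resolve to highest occupancy", {
  f <- write_test_pdb(tempfile(fileext = ".pdb"), chains = "A",
                      altloc = TRUE)
  # bio3d flags the duplicated serial numbers of the altloc copies
  ch <- suppressWarnings(read_chains(f))[[1]]
  # occupancy 0.6 copy sits at x + 5
  expect_equal(unname(ch$residues[[2]]$xyz["CA", 1]),
               2 * 3.8 + 0.01 + 5, tolerance = 1e-6)
  expect_length(ch$residues, 8)
})

test_that("build_ensemble maps residues through alignment gaps", {
  # chain ACDE vs alignment row AC-DE: residue 3 (D) -> column 4
  P <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0, 11.4, 0, 0), 4, 3,
              byrow = TRUE)
  residues <- lapply(1:4, function(i) {
    list(resname = c("ALA", "CYS", "ASP", "GLU")[i], resseq = i,
         icode = "", xyz = matrix(P[i, ], 1, 3, dimnames = list("CA", NULL)),
         b = c(CA = 10))
  })
  ch <- new_chain("x_A_m1", residues)
  aln <- list(ali = matrix(c("A", "C", "-", "D", "E"), 1, 5), id = "r1")
  class(aln) <- "fasta"
  ens <- build_ensemble(list(ch), aln)
  expect_equal(ens$m, 5)
  expect_equal(ens$col_of[["x_A_m1"]], c(1, 2, 4, 5))
  expect_equal(ens$res_of[["x_A_m1"]], c(1L, 2L, NA, 3L, 4L))
})

test_that("unresolved residues mask their columns without shifting the map", {
  q <- quick_ens(n_chains = 4, length = 12, seed = 7, jitter_sd = 0,
                 features = list(disorder = list(range = c(4, 5),
                                                 fraction = 0.5)))
  dis <- q$fx$truth$disorder_chains
  expect_length(dis, 2)
  cid <- names(q$ens$chains)[dis[1]]
  expect_true(all(is.na(q$ens$res_of[[cid]][4:5])))
  expect_equal(q$ens$res_of[[cid]][6], 4L)  # residue 6 still at column 6
  # derived matrices inherit the mask
  geo <- backbone_geometry(q$ens)
  expect_true(all(is.na(geo$kappa$values[cid, 4:5])))
})

test_that("chains reproduce their alignment rows and mismatches error", {
  q <- quick_ens(n_chains = 3, length = 10, seed = 1, jitter_sd = 0.05)
  for (cid in names(q$ens$chains)) {
    row <- q$ens$aln[cid, ]
    expect_identical(row[row != "-"],
                     chain_sequence(q$ens$chains[[cid]]))
  }
  bad <- q$fx$chains[[1]]
  bad$residues[[3]]$resname <- "TRP"   # sequence no longer matches
  expect_error(build_ensemble(list(bad), q$fx$alignment),
               "best partial match")
})

test_that("descriptor_matrix enforces its fill contract", {
  q <- quick_ens(n_chains = 2, length = 8, seed = 2, jitter_sd = 0)
  ens <- q$ens
  cid <- names(ens$chains)[1]
  ok <- descriptor_matrix(ens, "const",
                          fill = data.frame(chain_id = cid, column = 3,
                                            value = 1.0))
  expect_equal(ok$values[cid, 3], 1.0)
  expect_true(all(is.na(ok$values[, -3])))
  expect_error(
    descriptor_matrix(ens, "bad",
                      fill = data.frame(chain_id = cid, column = 2,
                                        value = NaN)),
    "non-finite")
  # a masked (disordered) cell rejects fills
  q2 <- quick_ens(n_chains = 2, length = 8, seed = 3, jitter_sd = 0,
                  features = list(disorder = list(range = c(4, 4),
                                                  fraction = 1)))
  cid2 <- names(q2$ens$chains)[1]
  expect_error(
    descriptor_matrix(q2$ens, "bad",
                      fill = data.frame(chain_id = cid2, column = 4,
                                        value = 1)),
    "masked cell")
  # empty fill -> fully masked
  expect_true(all(is.na(descriptor_matrix(ens, "empty")$values)))
})

test_that("descriptor TSV round-trips values and mask", {
  v <- matrix(rnorm(12), 3, 4)
  v[2, 3] <- NA
  x <- dm(v, "test")
  f <- tempfile(fileext = ".tsv")
  write_descriptor_tsv(x, f)
  y <- read_descriptor_tsv(f)
  expect_equal(y$values, x$values, tolerance = 1e-12)
})

test_that("per-column statistics are invariant to chain order", {
  q <- quick_ens(n_chains = 6, length = 20, seed = 5, jitter_sd = 0.1)
  geo <- backbone_geometry(q$ens)
  kz <- standardise(geo$kappa)
  v1 <- variability(list(kz))$values
  perm <- rev(seq_along(q$fx$chains))
  ens2 <- build_ensemble(q$fx$chains[perm], q$fx$alignment)
  kz2 <- standardise(backbone_geometry(ens2)$kappa)
  v2 <- variability(list(kz2))$values
  expect_equal(v1, v2, tolerance = 1e-12)
})
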