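# Seeded synthetic-ensemble generators. Every statistic in the package is
# testable against these because the planted features (hinge pivot, flipped
# loop, switched rotamer, disordered stretch, latent correlation) are known
# ground truth, and generation is a pure function of the spec (seed
# included).

#' Specify a synthetic ensemble
#'
#' @param n_chains number of chains (ensemble members).
#' @param length residues per chain.
#' @param seed RNG seed; the whole fixture is reproducible from it.
#' @param features list of planted features, any of:
#'   \describe{
#'     \item{hinge}{`list(pivot =, angle =)` - residues past `pivot` are
#'       rigidly rotated by `angle` degrees (about the local backbone
#'       normal at the pivot) in the second half of the chains: a two-state
#'       hinge ensemble.}
#'     \item{loop_flip}{`list(range = c(r1, r2), phi =, psi =)` - in the
#'       second half of the chains the entry and exit residues of the range
#'       take the alternate dihedrals, re-orienting the loop while leaving
#'       its interior geometry intact (the classic compensated flip: two
#'       hinge points, quiet in between).}
#'     \item{rotamer_switch}{`list(position =, chi1_a = -60, chi1_b = 180)` -
#'       the residue becomes Ser whose OG sits at `chi1_a` in the first half
#'       of the chains and `chi1_b` in the second.}
#'     \item{disorder}{`list(range = c(r1, r2), fraction =)` - the residues
#'       are deleted (as unmodelled) in a seeded random `fraction` of
#'       chains.}
#'     \item{latent_correlation}{`list(pos_a =, pos_b =, r_true =,
#'       scale = 0.4)` - both residues are displaced along their local
#'       backbone normals by amounts driven by one latent N(0,1) variable
#'       per chain, with population correlation `r_true`.}
#'   }
#' @param jitter_sd Gaussian coordinate noise, Angstrom (thermal-like;
#'   crystallographic coordinate uncertainty is of order 0.1 A).
#' @param phi,psi backbone dihedrals of the ideal chain, degrees
#'   (alpha-helical defaults exercise nonzero curvature and torsion
#'   simultaneously).
#' @param resname default residue type (`"ALA"`; full N, CA, C, O, CB).
#' @return a `"fixture_spec"` list.
#' @export
fixture_spec <- function(n_chains = 20, length = 60, seed = 1,
                         features = list(), jitter_sd = 0.1,
                         phi = -57, psi = -47, resname = "ALA") {
  stopifnot(jitter_sd >= 0, length >= 5, n_chains >= 1)
  for (f in names(features))
    if (!f %in% c("hinge", "loop_flip", "rotamer_switch", "disorder",
                  "latent_correlation"))
      stop("unknown fixture feature: ", f)
  structure(list(n_chains = n_chains, length = length, seed = seed,
                 features = features, jitter_sd = jitter_sd,
                 phi = phi, psi = psi, resname = resname),
            class = "fixture_spec")
}

# Ideal-geometry peptide builder (internal-coordinate chain extension).
# phi/psi/omega are per-residue vectors in degrees. Returns a list of
# residues in the chain data model; CB is placed with L-configuration
# (same improper as the sidechain reference frame), O anti to the next N.
.build_peptide <- function(n, phi, psi, omega = rep(180, n),
                           resnames = rep("ALA", n), chi1 = rep(NA, n)) {
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  ref <- .reference_frame()
  cb_improper <- .dihedral(ref["C", ], ref["N", ], ref["CA", ],
                           ref["CB", ]) * 180 / pi
  deg <- pi / 180
  N <- matrix(0, n, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- CA[1, ] + 1.525 * c(cos(pi - 111.2 * deg), sin(111.2 * deg), 0)
  for (i in 2:n) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                          1.329, 116.2, psi[i - 1])
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                           1.458, 121.7, omega[i])
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ],
                          1.525, 111.2, phi[i])
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    atoms <- rbind(N = N[i, ], CA = CA[i, ], C = C[i, ])
    o_ref <- if (i < n) N[i + 1, ] else
      .place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi[i])
    O <- .place_atom(o_ref, CA[i, ], C[i, ], 1.231, 120.5, 180)
    atoms <- rbind(atoms, O = O)
    if (resnames[i] != "GLY") {
      CB <- .place_atom(C[i, ], N[i, ], CA[i, ], 1.530, 110.4, cb_improper)
      atoms <- rbind(atoms, CB = CB)
      if (resnames[i] == "SER" && !is.na(chi1[i])) {
        OG <- .place_atom(N[i, ], CA[i, ], CB, 1.417, 110.8, chi1[i])
        atoms <- rbind(atoms, OG = OG)
      }
    }
    b <- rep(20, nrow(atoms))
    names(b) <- rownames(atoms)
    residues[[i]] <- list(resname = resnames[i], resseq = i, icode = "",
                          xyz = atoms, b = b)
  }
  residues
}

# Rotation matrix about a unit axis (Rodrigues).
.axis_rotation <- function(axis, angle_deg) {
  a <- axis / .norm3(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic structural ensemble
#'
#' Builds `n_chains` copies of an ideal-geometry chain, applies the planted
#' features of the spec, adds seeded coordinate jitter, and (optionally)
#' writes standard single-model PDB files plus an aligned FASTA so the
#' complete input pipeline can be exercised. Output is byte-identical for
#' identical specs.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created); ignored when `write = FALSE`.
#' @param write write PDB/FASTA/ground-truth files (default TRUE).
#' @return list with `chains` (in-memory `"chain"` objects), `alignment`
#'   (bio3d-style `"fasta"`), `truth` (states per chain + planted feature
#'   record), and when written: `pdb_paths`, `fasta_path`, `truth_path`.
#' @export
make_ensemble <- function(spec, dir = tempfile("fixture"), write = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_chains
  L <- spec$length
  set.seed(spec$seed)
  state <- rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2)))
  feats <- spec$features

  resnames <- rep(spec$resname, L)
  chi1 <- rep(NA_real_, L)
  rs <- feats$rotamer_switch
  if (!is.null(rs)) resnames[rs$position] <- "SER"

  disorder_chains <- integer(0)
  if (!is.null(feats$disorder)) {
    k <- floor(feats$disorder$fraction * n)
    disorder_chains <- sort(sample.int(n, k))
  }

  lat <- feats$latent_correlation
  zs <- NULL
  if (!is.null(lat)) {
    if (is.null(lat$scale)) lat$scale <- 0.4
    z <- stats::rnorm(n)
    e <- stats::rnorm(n)
    zs <- cbind(a = z, b = lat$r_true * z + sqrt(1 - lat$r_true^2) * e)
  }

  chains <- vector("list", n)
  for (j in seq_len(n)) {
    phi <- rep(spec$phi, L)
    psi <- rep(spec$psi, L)
    lf <- feats$loop_flip
    if (!is.null(lf) && state[j] == "B") {
      ends <- c(lf$range[1], lf$range[2])
      phi[ends] <- if (is.null(lf$phi)) -120 else lf$phi
      psi[ends] <- if (is.null(lf$psi)) 120 else lf$psi
    }
    ch1 <- if (!is.null(rs)) {
      cc <- chi1
      cc[rs$position] <- if (state[j] == "A") rs$chi1_a else rs$chi1_b
      cc
    } else chi1
    residues <- .build_peptide(L, phi, psi, resnames = resnames, chi1 = ch1)
    ca <- t(vapply(residues, function(r) r$xyz["CA", ], numeric(3)))

    hg <- feats$hinge
    if (!is.null(hg) && state[j] == "B") {
      p <- hg$pivot
      axis <- .cross3(ca[p, ] - ca[p - 1, ], ca[p + 1, ] - ca[p, ])
      R <- .axis_rotation(axis, hg$angle)
      ctr <- ca[p, ]
      for (i in seq_len(L)) if (i > p) {
        residues[[i]]$xyz <-
          sweep(sweep(residues[[i]]$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
      }
    }
    if (!is.null(lat)) {
      for (side in c("a", "b")) {
        pos <- if (side == "a") lat$pos_a else lat$pos_b
        nrm <- .cross3(ca[pos, ] - ca[pos - 1, ], ca[pos + 1, ] - ca[pos, ])
        nrm <- nrm / .norm3(nrm)
        shift <- lat$scale * zs[j, side] * nrm
        residues[[pos]]$xyz <- sweep(residues[[pos]]$xyz, 2, shift, "+")
      }
    }
    if (j %in% disorder_chains) {
      dr <- feats$disorder$range
      residues <- residues[-(dr[1]:dr[2])]
    }
    if (spec$jitter_sd > 0) {
      residues <- lapply(residues, function(r) {
        r$xyz <- r$xyz + matrix(stats::rnorm(length(r$xyz), 0,
                                             spec$jitter_sd),
                                nrow(r$xyz), 3)
        r
      })
    }
    cid <- sprintf("sim%02d_A_m1", j)
    chains[[j]] <- new_chain(cid, residues, source_path = NA_character_)
  }

  seq1 <- .aa1(resnames)
  alignment <- list(ali = matrix(seq1, 1, L,
                                 dimnames = list("ideal", NULL)),
                    id = "ideal")
  class(alignment) <- "fasta"
  truth <- list(state = stats::setNames(state,
                                        vapply(chains, `[[`, "", "chain_id")),
                features = feats,
                disorder_chains = disorder_chains,
                latent = zs,
                seed = spec$seed)

  out <- list(chains = chains, alignment = alignment, truth = truth,
              spec = spec)
  if (write) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$pdb_paths <- character(n)
    for (j in seq_len(n)) {
      path <- file.path(dir, sprintf("sim%02d.pdb", j))
      .write_chain_pdb(chains[[j]], path)
      out$pdb_paths[j] <- path
      chains[[j]]$source_path <- path
    }
    out$chains <- chains
    out$fasta_path <- file.path(dir, "alignment.fasta")
    writeLines(c(">ideal", paste(seq1, collapse = "")), out$fasta_path)
    out$truth_path <- file.path(dir, "ground_truth.tsv")
    utils::write.table(
      data.frame(chain_id = names(truth$state), state = truth$state),
      out$truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    out$dir <- dir
  }
  out
}

# Deterministic minimal PDB writer for fixture chains (chain letter from the
# chain_id convention <stem>_<letter>_m<model>).
.write_chain_pdb <- function(chain, path) {
  letter <- sub(".*_([A-Za-z0-9])_m[0-9]+$", "\\1", chain$chain_id)
  lines <- character(0)
  serial <- 0L
  for (r in chain$residues) {
    for (a in rownames(r$xyz)) {
      serial <- serial + 1L
      el <- substr(gsub("[0-9]", "", a), 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, paste0(" ", a), " ", r$resname, letter, r$resseq,
        ifelse(r$icode == "", " ", r$icode),
        r$xyz[a, 1], r$xyz[a, 2], r$xyz[a, 3], 1.00, r$b[a], el))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Generate a synthetic pocket-score matrix
#'
#' Background pockets get Dscores drawn below any sensible cutoff; planted
#' pockets are placed exactly as specified, so the three-stage
#' distinct-pocket algorithm has known ground truth.
#'
#' @param n structures, `m` alignment positions.
#' @param m alignment length.
#' @param pockets list of `list(structure =, columns =, dscore =)`.
#' @param n_noise background pockets per structure (Dscore ~ U(0.1, 0.85)).
#' @param seed RNG seed.
#' @return a `"pocket_scores"` object (chain ids `s01`, `s02`, ...).
#' @export
make_pocket_scores <- function(n, m, pockets = list(), n_noise = 2,
                               seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  D <- matrix(NA_real_, n, m, dimnames = list(ids, NULL))
  P <- matrix(NA_character_, n, m, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    for (k in seq_len(n_noise)) {
      w <- sample(2:5, 1)
      start <- sample.int(max(m - w, 1), 1)
      cols <- start:(start + w - 1)
      d <- stats::runif(1, 0.1, 0.85)
      better <- is.na(D[i, cols]) | D[i, cols] < d
      D[i, cols[better]] <- d
      P[i, cols[better]] <- paste0("noise", k)
    }
  }
  for (k in seq_along(pockets)) {
    pk <- pockets[[k]]
    i <- if (is.character(pk$structure)) match(pk$structure, ids) else
      pk$structure
    D[i, pk$columns] <- pk$dscore
    P[i, pk$columns] <- paste0("planted", k)
  }
  new_pocket_scores(D, P, present = matrix(TRUE, n, m,
                                           dimnames = list(ids, NULL)))
}
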