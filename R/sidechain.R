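# Side-chain conformation as sentinel-atom coordinates in a local backbone
# frame. Each residue's (N, CA, C, CB) is superposed onto a fixed ideal
# reference quadruplet at the origin and the transform is applied to a
# designated "sentinel" atom near the side-chain terminus; the sentinel's
# (x, y, z) then encode the side-chain conformation independently of the
# chain's placement in space.

#' Sentinel atom table
#'
#' One sentinel atom per residue type, chosen as the terminal-most side-chain
#' atom that X-ray crystallography assigns unambiguously (so e.g. Asp uses CG
#' rather than the swappable OD1/OD2). Val, Thr and His carry two candidate
#' atoms separated by `|`; the member giving a positive C-CA-CB-T pseudo
#' dihedral is used, which resolves the crystallographic naming ambiguity
#' geometrically. Gly and Ala have no entry and are always masked. The table
#' ships as an editable CSV (`resname,atom`).
#'
#' @param path CSV path; default = the file shipped with the package.
#' @return named list: resname -> character vector of 1 or 2 atom names.
#' @export
sentinel_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sentinel_atoms.csv", package = "ensflex")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(df$atom, function(a) strsplit(a, "|", fixed = TRUE)[[1]])
  names(out) <- df$resname
  out
}

#' Choose the sentinel atom of one residue
#'
#' @param residue a residue (element of `chain$residues`).
#' @param table from [sentinel_table()].
#' @return the atom name, or `NA` if the residue is masked (Gly/Ala,
#'   unlisted type, missing frame atoms, or no candidate with a positive
#'   C-CA-CB-T dihedral).
#' @export
sentinel_atom <- function(residue, table = sentinel_table()) {
  cand <- table[[residue$resname]]
  if (is.null(cand)) return(NA_character_)
  an <- rownames(residue$xyz)
  if (!all(c("N", "CA", "C", "CB") %in% an)) return(NA_character_)
  if (length(cand) == 1) {
    return(if (cand %in% an) cand else NA_character_)
  }
  # ambiguous pair: strictly positive pseudo dihedral wins
  C <- residue$xyz["C", ]; CA <- residue$xyz["CA", ]; CB <- residue$xyz["CB", ]
  dihs <- vapply(cand, function(a) {
    if (!a %in% an) return(NA_real_)
    .dihedral(C, CA, CB, residue$xyz[a, ])
  }, 0)
  if (all(is.na(dihs))) return(NA_character_)
  if (all(abs(dihs) < 1e-9, na.rm = TRUE)) {
    warning("degenerate C-CA-CB-T dihedral for ", residue$resname, " ",
            residue$resseq, "; first candidate used", call. = FALSE)
    return(cand[which(!is.na(dihs))[1]])
  }
  pos <- which(!is.na(dihs) & dihs > 0)
  if (length(pos)) cand[pos[1]] else NA_character_
}

# Ideal reference quadruplet: CA at the origin, CA->C along +x, N in the
# xy-plane (y > 0), CB completing an L-configured tetrahedral centre
# (chiral volume (N-CA).((C-CA)x(CB-CA)) = +2.5 A^3 as in real L-amino
# acids). Bond lengths N-CA 1.458, CA-C 1.525, CA-CB 1.530 A; angles
# N-CA-C 111.2, N-CA-CB 110.4, C-CA-CB 110.5 degrees. Any fixed chiral frame
# is equivalent up to one global rotation of descriptor space, which all
# downstream distance and PCA statistics are invariant to.
.reference_frame <- function() {
  deg <- pi / 180
  CA <- c(0, 0, 0)
  C <- c(1.525, 0, 0)
  N <- 1.458 * c(cos(111.2 * deg), sin(111.2 * deg), 0)
  # CB direction from the two angle constraints + unit norm
  nh <- N / .norm3(N)
  dx <- cos(110.5 * deg)
  dy <- (cos(110.4 * deg) - nh[1] * dx) / nh[2]
  dz2 <- 1 - dx^2 - dy^2
  dz <- sqrt(max(dz2, 0))
  CB <- 1.530 * c(dx, dy, dz)
  chir <- sum((N - CA) * .cross3(C - CA, CB - CA))
  if (chir < 0) CB <- 1.530 * c(dx, dy, -dz)
  rbind(N = N, CA = CA, C = C, CB = CB)
}

#' Sentinel coordinates of one residue in the reference frame
#'
#' Least-squares rigid superposition (proper rotation + translation, no
#' scaling) of the residue's (N, CA, C, CB) onto the ideal reference
#' quadruplet, applied to the sentinel atom.
#'
#' @param residue a residue.
#' @param sentinel sentinel atom name (see [sentinel_atom()]).
#' @return named numeric `(x, y, z)` in Angstrom with attribute
#'   `frame_rmsd` (fit RMSD of the four backbone atoms), or `NULL` if the
#'   frame is degenerate or an atom is absent.
#' @export
sidechain_frame_coords <- function(residue, sentinel) {
  an <- rownames(residue$xyz)
  need <- c("N", "CA", "C", "CB")
  if (is.na(sentinel) || !all(need %in% an) || !sentinel %in% an)
    return(NULL)
  M <- residue$xyz[need, , drop = FALSE]
  if (.norm3(.cross3(M["N", ] - M["CA", ], M["C", ] - M["CA", ])) < 1e-6) {
    warning("degenerate backbone frame (collinear N, CA, C) at residue ",
            residue$resseq, call. = FALSE)
    return(NULL)
  }
  fit <- .kabsch(M, .reference_frame())
  out <- as.vector(.apply_rigid(matrix(residue$xyz[sentinel, ], 1, 3), fit))
  names(out) <- c("x", "y", "z")
  attr(out, "frame_rmsd") <- fit$rmsd
  out
}

#' Side-chain descriptor matrices for an ensemble
#'
#' @param ensemble an `"ensemble"`.
#' @param table sentinel table (see [sentinel_table()]).
#' @return list of three `"descriptor_matrix"` objects `sc_x`, `sc_y`,
#'   `sc_z` (Angstrom) sharing one mask: a cell is masked where the residue
#'   is absent, is Gly/Ala, or lacks its frame or sentinel atoms.
#' @export
sidechain_matrices <- function(ensemble, table = sentinel_table()) {
  per <- list(x = list(), y = list(), z = list())
  for (cid in names(ensemble$chains)) {
    ch <- ensemble$chains[[cid]]
    n <- length(ch$residues)
    vx <- rep(NA_real_, n); vy <- vx; vz <- vx
    for (i in seq_len(n)) {
      r <- ch$residues[[i]]
      s <- sentinel_atom(r, table)
      if (is.na(s)) next
      co <- sidechain_frame_coords(r, s)
      if (is.null(co)) next
      vx[i] <- co["x"]; vy[i] <- co["y"]; vz[i] <- co["z"]
    }
    per$x[[cid]] <- vx; per$y[[cid]] <- vy; per$z[[cid]] <- vz
  }
  list(sc_x = .dm_from_per_residue(ensemble, "sc_x", "Angstrom", per$x),
       sc_y = .dm_from_per_residue(ensemble, "sc_y", "Angstrom", per$y),
       sc_z = .dm_from_per_residue(ensemble, "sc_z", "Angstrom", per$z))
}
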