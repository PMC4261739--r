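# Chain data model and PDB input.

.WATERS <- c("HOH", "WAT", "DOD", "H2O")

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.aa1 <- function(resname) {
  out <- .AA3[resname]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Construct a chain object
#'
#' A chain is one protein chain from one model of one structure file: an
#' ordered list of residues, each holding its atoms' coordinates and
#' B-factors under the original author numbering. Chains are the ensemble
#' members every descriptor matrix is computed over.
#'
#' @param chain_id unique identifier, conventionally
#'   `<file stem>_<chain letter>_m<model>`.
#' @param residues list of residues; each is a list with elements `resname`
#'   (3-letter code), `resseq` (integer), `icode` (string, `""` if none),
#'   `xyz` (atoms x 3 matrix, rownames = PDB v3 atom names) and `b` (named
#'   numeric B-factors, Angstrom^2).
#' @param source_path file the chain came from.
#' @param ligand_xyz optional matrix of non-water HETATM coordinates from the
#'   same model, kept for contact analyses.
#' @return an object of class `"chain"`.
#' @export
new_chain <- function(chain_id, residues, source_path = NA_character_,
                      ligand_xyz = NULL) {
  keys <- vapply(residues, function(r) paste0(r$resseq, "|", r$icode), "")
  if (anyDuplicated(keys))
    stop("duplicated (resseq, icode) in chain ", chain_id)
  structure(list(chain_id = chain_id, residues = residues,
                 source_path = source_path, ligand_xyz = ligand_xyz),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat("<chain>", x$chain_id, "-", length(x$residues), "residues\n")
  invisible(x)
}

#' One-letter sequence of a chain's present residues
#' @param chain a `"chain"` object.
#' @return character vector of one-letter codes (`X` for non-standard).
#' @export
chain_sequence <- function(chain) {
  .aa1(vapply(chain$residues, `[[`, "", "resname"))
}

# Coordinates of one named atom of residue i, or NULL.
.atom_xyz <- function(chain, i, name) {
  xyz <- chain$residues[[i]]$xyz
  if (name %in% rownames(xyz)) xyz[name, ] else NULL
}

# n_res x 3 matrix of C-alpha coordinates (NA rows where absent).
.ca_matrix <- function(chain) {
  n <- length(chain$residues)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    p <- .atom_xyz(chain, i, "CA")
    if (!is.null(p)) out[i, ] <- p
  }
  out
}

# Split residue indices into maximal contiguous segments. Residue i+1
# continues a segment iff author numbering is consecutive (resseq + 1, or an
# insertion-code successor at the same resseq) and, when both have CA, the
# CA-CA distance is chemically plausible (2.5..4.75 A covers cis and trans
# peptides); larger jumps indicate an unmodelled stretch.
.segments <- function(chain, require_ca = TRUE, spacing_check = TRUE) {
  n <- length(chain$residues)
  if (n == 0) return(list())
  ca <- .ca_matrix(chain)
  ok <- if (require_ca) !is.na(ca[, 1]) else rep(TRUE, n)
  segs <- list()
  cur <- integer(0)
  for (i in seq_len(n)) {
    if (!ok[i]) {
      if (length(cur)) segs[[length(segs) + 1L]] <- cur
      cur <- integer(0)
      next
    }
    if (length(cur)) {
      j <- cur[length(cur)]
      ri <- chain$residues[[i]]
      rj <- chain$residues[[j]]
      consec <- (ri$resseq == rj$resseq + 1L) ||
        (ri$resseq == rj$resseq && ri$icode != rj$icode)
      dist_ok <- TRUE
      if (spacing_check && !is.na(ca[i, 1]) && !is.na(ca[j, 1])) {
        d <- sqrt(sum((ca[i, ] - ca[j, ])^2))
        dist_ok <- d > 2.5 && d < 4.75
      }
      if (!(consec && dist_ok)) {
        segs[[length(segs) + 1L]] <- cur
        cur <- integer(0)
      }
    }
    cur <- c(cur, i)
  }
  if (length(cur)) segs[[length(segs) + 1L]] <- cur
  segs
}

#' Read protein chains from PDB files
#'
#' Parses one or more PDB files (single- or multi-model) into chain objects,
#' one per (file, chain letter, model) combination. Alternate locations are
#' resolved to the highest-occupancy copy (ties: first in file order). Waters
#' are discarded; other HETATM groups are excluded from the residue list but
#' their coordinates are retained on each chain as `ligand_xyz` for contact
#' analyses. HETATM residues that carry a CA atom (e.g. MSE) are kept as
#' residues. Chains with fewer than 5 CA atoms are skipped with a warning,
#' since the backbone-geometry descriptors need a 5-residue window.
#'
#' @param paths character vector of PDB file paths.
#' @param model_policy `"all"` turns every model of a multi-model file into an
#'   independent ensemble member (the natural reading of NMR bundles and MD
#'   snapshot files); `"first"` keeps model 1 only.
#' @return list of `"chain"` objects.
#' @export
read_chains <- function(paths, model_policy = c("all", "first")) {
  model_policy <- match.arg(model_policy)
  out <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("cannot read PDB file: ", path)
    pdb <- tryCatch(
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
      error = function(e) stop("cannot read PDB file: ", path, " (",
                               conditionMessage(e), ")"))
    stem <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
    at <- pdb$atom
    at$row <- seq_len(nrow(at))
    at$icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
    at$chain[is.na(at$chain)] <- " "
    nmodel <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
    models <- if (model_policy == "first") 1L else seq_len(nmodel)
    # occupancy-based altloc resolution, once (atom table is shared by models)
    occ <- ifelse(is.na(at$o), 1, at$o)
    key <- paste(at$chain, at$resno, at$icode, at$elety, sep = "|")
    keep <- rep(TRUE, nrow(at))
    for (dup in unique(key[duplicated(key)])) {
      rows <- which(key == dup)
      win <- rows[which.max(occ[rows])]   # ties: first listed
      keep[setdiff(rows, win)] <- FALSE
    }
    at <- at[keep, , drop = FALSE]
    is_water <- at$resid %in% .WATERS
    reskey <- paste(at$chain, at$resno, at$icode, sep = "|")
    has_ca <- reskey %in% reskey[at$elety == "CA"]
    is_res <- !is_water & (at$type == "ATOM" | has_ca)
    is_lig <- !is_water & !is_res
    for (mdl in models) {
      xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[mdl, ] else as.vector(pdb$xyz)
      getxyz <- function(rows) {
        idx <- rep((at$row[rows] - 1L) * 3L, each = 3L) + 1:3
        matrix(xyz[idx], ncol = 3, byrow = TRUE)
      }
      lig <- if (any(is_lig)) getxyz(which(is_lig)) else NULL
      for (ch in unique(at$chain[is_res])) {
        rows <- which(is_res & at$chain == ch)
        rk <- reskey[rows]
        residues <- list()
        for (k in unique(rk)) {
          rr <- rows[rk == k]
          co <- getxyz(rr)
          rownames(co) <- at$elety[rr]
          b <- at$b[rr]
          names(b) <- at$elety[rr]
          residues[[length(residues) + 1L]] <- list(
            resname = at$resid[rr[1]],
            resseq = at$resno[rr[1]],
            icode = at$icode[rr[1]],
            xyz = co, b = b)
        }
        n_ca <- sum(vapply(residues, function(r) "CA" %in% rownames(r$xyz),
                           TRUE))
        cid <- paste0(stem, "_", ch, "_m", mdl)
        if (n_ca < 5) {
          warning("chain ", cid, " has ", n_ca,
                  " CA atoms (< 5); skipped", call. = FALSE)
          next
        }
        out[[length(out) + 1L]] <- new_chain(cid, residues, path, lig)
      }
    }
  }
  out
}

# Apply a rigid motion (and optional mirror) to every atom of a chain.
# Exported because superposition independence is the premise of the whole
# descriptor set and users may want to verify it on their own data.
#' Rigidly transform a chain
#' @param chain a `"chain"` object.
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation.
#' @return the transformed chain.
#' @export
transform_chain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  chain$residues <- lapply(chain$residues, function(r) {
    r$xyz <- sweep(r$xyz %*% R, 2, t, "+")
    r
  })
  if (!is.null(chain$ligand_xyz))
    chain$ligand_xyz <- sweep(chain$ligand_xyz %*% R, 2, t, "+")
  chain
}
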