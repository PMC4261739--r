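# Pocket druggability scores across an ensemble and the distinct-pocket
# selection algorithm.

#' Construct a pocket score matrix
#'
#' @param dscore chains x positions matrix of druggability scores in [0, 1]
#'   (NA where the residue belongs to no pocket), dimnames set.
#' @param pocket_id matrix of the same shape giving the within-structure
#'   pocket identifier of each scored residue (all residues of one pocket
#'   share one Dscore).
#' @param present logical matrix: is the residue present in the structure at
#'   all (pocket membership is only defined for present residues).
#' @return object of class `"pocket_scores"`.
#' @export
new_pocket_scores <- function(dscore, pocket_id = NULL, present = NULL) {
  if (is.null(present)) present <- !is.na(dscore) | TRUE
  if (is.null(pocket_id)) {
    pocket_id <- dscore
    pocket_id[] <- NA
  }
  obs <- dscore[!is.na(dscore)]
  if (length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("Dscores must lie in [0, 1]")
  structure(list(dscore = dscore, pocket_id = pocket_id, present = present),
            class = "pocket_scores")
}

#' Read per-residue pocket scores from a TSV table
#'
#' Plain dialect: tab-separated columns `chain_id`, `resseq`, `icode`,
#' `pocket_id`, `dscore`. Residues are mapped to alignment columns through
#' the ensemble; a reference to an unknown residue is skipped with a
#' warning, a malformed score is a hard error. Where two pockets overlap on
#' one residue the higher Dscore wins.
#'
#' @param path TSV file.
#' @param ensemble an `"ensemble"`.
#' @return a `"pocket_scores"` object.
#' @export
read_pocket_table <- function(path, ensemble) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("chain_id", "resseq", "icode", "pocket_id", "dscore")
  if (!all(need %in% names(df))) stop("pocket table needs columns: ",
                                      paste(need, collapse = ", "))
  ds <- suppressWarnings(as.numeric(df$dscore))
  if (anyNA(ds)) stop("malformed dscore value(s): ",
                      paste(unique(df$dscore[is.na(ds)]), collapse = ", "))
  ids <- names(ensemble$chains)
  m <- ensemble$m
  D <- matrix(NA_real_, length(ids), m, dimnames = list(ids, NULL))
  P <- matrix(NA_character_, length(ids), m, dimnames = list(ids, NULL))
  for (i in seq_len(nrow(df))) {
    cid <- df$chain_id[i]
    if (!cid %in% ids) {
      warning("pocket table references unknown chain ", cid, "; skipped",
              call. = FALSE)
      next
    }
    ch <- ensemble$chains[[cid]]
    hit <- which(vapply(ch$residues, function(r)
      r$resseq == as.integer(df$resseq[i]) &&
        r$icode == ifelse(is.na(df$icode[i]), "", df$icode[i]), TRUE))
    if (!length(hit)) {
      warning("pocket table references unknown residue ", df$resseq[i],
              df$icode[i], " of ", cid, "; skipped", call. = FALSE)
      next
    }
    col <- ensemble$col_of[[cid]][hit[1]]
    if (is.na(D[cid, col]) || ds[i] > D[cid, col]) {
      D[cid, col] <- ds[i]
      P[cid, col] <- df$pocket_id[i]
    }
  }
  present <- matrix(FALSE, length(ids), m, dimnames = list(ids, NULL))
  for (cid in ids) present[cid, ensemble$col_of[[cid]]] <- TRUE
  new_pocket_scores(D, P, present)
}

#' Read Fpocket output for one structure
#'
#' Parses the `*_info.txt` summary (pocket numbers and their
#' "Druggability Score") together with the `pockets/pocket<N>_atm.pdb`
#' atom files that carry each pocket's residues, and returns the rows of a
#' pocket table (the same dialect [read_pocket_table()] consumes) for the
#' given chain.
#'
#' @param info_path path to the Fpocket `*_info.txt` file.
#' @param pocket_dir directory with `pocket<N>_atm.pdb` files (defaults to
#'   `pockets/` next to the info file).
#' @param chain_id the ensemble chain id the structure corresponds to.
#' @param chain_letter PDB chain letter to keep (default: all).
#' @return data.frame in the pocket-table dialect.
#' @export
read_fpocket_info <- function(info_path, pocket_dir = NULL, chain_id,
                              chain_letter = NULL) {
  if (is.null(pocket_dir))
    pocket_dir <- file.path(dirname(info_path), "pockets")
  lines <- readLines(info_path)
  pock <- grep("^Pocket[[:space:]]+[0-9]+", lines)
  out <- list()
  for (k in seq_along(pock)) {
    hdr <- lines[pock[k]]
    num <- as.integer(sub("^Pocket[[:space:]]+([0-9]+).*", "\\1", hdr))
    end <- if (k < length(pock)) pock[k + 1] - 1 else length(lines)
    blk <- lines[pock[k]:end]
    dln <- grep("Druggability Score", blk, value = TRUE, ignore.case = TRUE)
    if (!length(dln)) next
    dsc <- as.numeric(sub(".*:[[:space:]]*", "", dln[1]))
    pf <- file.path(pocket_dir, paste0("pocket", num, "_atm.pdb"))
    if (!file.exists(pf)) next
    at <- bio3d::read.pdb(pf, verbose = FALSE)$atom
    if (!is.null(chain_letter)) at <- at[at$chain %in% chain_letter, ]
    res <- unique(at[, c("resno", "insert")])
    out[[length(out) + 1L]] <- data.frame(
      chain_id = chain_id,
      resseq = res$resno,
      icode = ifelse(is.na(res$insert), "", res$insert),
      pocket_id = as.character(num),
      dscore = dsc, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(chain_id = character(0),
                                      resseq = integer(0),
                                      icode = character(0),
                                      pocket_id = character(0),
                                      dscore = numeric(0)))
  do.call(rbind, out)
}

#' Distinct druggable pockets across an ensemble
#'
#' Three-stage reduction of the chains x positions Dscore matrix to a small
#' set of structures that jointly display the ensemble's distinct
#' high-scoring pockets:
#' \enumerate{
#'   \item per alignment position, find the structure with the maximal
#'     Dscore and discard the position if that score is below `cutoff`
#'     (because all residues of one pocket share its Dscore, whole pockets
#'     win together);
#'   \item rank structures by their count of stage-1 wins - effectively by
#'     pocket size - and keep the top `t`;
#'   \item label each surviving position with its winning structure's rank
#'     0..t-1; everything else stays unassigned.
#' }
#' Ties (equal column maxima, equal win counts) are broken by chain id sort
#' order so the outcome is deterministic. The 0.9 default cutoff is
#' conservative; Fpocket's own authors favour 0.7 for single structures,
#' but with hundreds of ensemble members higher-scoring pockets are common
#' enough that the stricter threshold is more selective.
#'
#' @param scores a `"pocket_scores"` object.
#' @param cutoff minimal winning Dscore (default 0.9).
#' @param t number of structures to keep (default 5).
#' @return object of class `"pocket_selection"`: `labels` (per position,
#'   NA = unassigned), `selected_structures` (ordered chain ids), `cutoff`,
#'   `t`.
#' @export
distinct_pockets <- function(scores, cutoff = 0.9, t = 5) {
  stopifnot(t >= 1)
  D <- scores$dscore
  ids <- sort(rownames(D))
  D <- D[ids, , drop = FALSE]
  m <- ncol(D)
  win <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    col <- D[, j]
    if (all(is.na(col))) next
    best <- max(col, na.rm = TRUE)
    if (best < cutoff) next
    win[j] <- ids[which(col == best)[1]]      # ties: first in sorted order
  }
  counts <- table(factor(win, levels = ids))
  ord <- ids[order(-as.vector(counts), ids)]
  sel <- ord[seq_len(min(t, sum(counts > 0)))]
  sel <- sel[counts[sel] > 0]
  labels <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    if (is.na(win[j])) next
    rk <- match(win[j], sel)
    if (!is.na(rk)) labels[j] <- rk - 1L
  }
  structure(list(labels = labels, selected_structures = sel,
                 cutoff = cutoff, t = t),
            class = "pocket_selection")
}

#' Format pocket labels in the compact visual style
#'
#' `- - 0 4 - ...`: one token per alignment position, `-` for unassigned.
#' @param x a `"pocket_selection"`.
#' @return single string.
#' @export
format_pocket_labels <- function(x) {
  paste(ifelse(is.na(x$labels), "-", as.character(x$labels)),
        collapse = " ")
}

#' @export
print.pocket_selection <- function(x, ...) {
  cat("<pocket_selection>", sum(!is.na(x$labels)), "labelled positions,",
      length(x$selected_structures), "structures (cutoff", x$cutoff,
      ", t =", x$t, ")\n")
  invisible(x)
}

#' Pocket occurrence percentage per alignment position
#'
#' 100 x (chains in which the residue belongs to any pocket) / (chains in
#' which the residue is present). Positions with no present residues are
#' masked.
#'
#' @param scores a `"pocket_scores"` object.
#' @return a `"variability_profile"` of percentages in [0, 100].
#' @export
pocket_occurrence <- function(scores) {
  m <- ncol(scores$dscore)
  vals <- rep(NA_real_, m)
  nvec <- integer(m)
  for (j in seq_len(m)) {
    pres <- scores$present[, j]
    nvec[j] <- sum(pres)
    if (nvec[j] == 0) next
    vals[j] <- 100 * sum(!is.na(scores$dscore[pres, j])) / nvec[j]
  }
  .new_profile(vals, nvec, "pocket_occurrence")
}
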