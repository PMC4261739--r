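# Aligned ensemble and the masked descriptor-matrix container.

#' Map chains onto a multiple sequence alignment
#'
#' Builds the aligned ensemble every per-position statistic is computed over.
#' Each chain's present-residue sequence is matched to a gapped row of the
#' alignment; residues missing from the model (disorder) are located through
#' gaps in the author numbering, so an unresolved stretch leaves its
#' alignment columns masked for that chain rather than shifting the mapping.
#'
#' @param chains list of `"chain"` objects (see [read_chains()]).
#' @param alignment an aligned FASTA file path or a `bio3d` `"fasta"` object
#'   (equal-length gapped rows, `-` for gaps).
#' @return an object of class `"ensemble"` with elements `chains` (named
#'   list), `m` (alignment length), `aln` (row per chain, character matrix),
#'   `col_of` (per chain: residue index -> alignment column) and `res_of`
#'   (per chain: alignment column -> residue index or NA). Columns are
#'   1-based everywhere.
#' @details A chain whose sequence matches no row is a hard error reporting
#'   the closest row; several chains may reuse one row (identical sequences
#'   are the common case). Matching tolerates `X` on either side for
#'   non-standard residues, and zero mismatches otherwise.
#' @export
build_ensemble <- function(chains, alignment) {
  if (is.character(alignment)) alignment <- bio3d::read.fasta(alignment)
  rows <- alignment$ali
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows[rows == "."] <- "-"
  m <- ncol(rows)
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids)) stop("duplicated chain_id in input chains")
  names(chains) <- ids

  col_of <- list()
  res_of <- list()
  aln <- matrix("-", length(chains), m,
                dimnames = list(ids, NULL))
  for (cid in ids) {
    ch <- chains[[cid]]
    s <- chain_sequence(ch)
    e <- .expanded_index(ch)
    best <- .match_alignment_row(s, e, rows)
    if (is.null(best$row))
      stop("chain ", cid, " matches no alignment row; best partial match: ",
           "row '", best$partial_row, "' (", best$partial_n, "/",
           length(s), " residues)")
    row <- rows[best$row, ]
    nongap <- which(row != "-")
    cols <- nongap[e + best$offset]
    col_of[[cid]] <- cols
    ro <- rep(NA_integer_, m)
    ro[cols] <- seq_along(cols)
    res_of[[cid]] <- ro
    aln[cid, ] <- row
  }
  structure(list(chains = chains, m = m, aln = aln,
                 col_of = col_of, res_of = res_of),
            class = "ensemble")
}

# Expanded residue index: position of each present residue within the chain's
# full (SEQRES-like) sequence, inferred from author numbering. Gaps in
# numbering widen the index; insertion codes advance it by one.
.expanded_index <- function(chain) {
  res <- chain$residues
  n <- length(res)
  e <- integer(n)
  e[1] <- 1L
  if (n > 1) for (i in 2:n) {
    d <- res[[i]]$resseq - res[[i - 1]]$resseq
    e[i] <- e[i - 1] + if (d >= 1) d else 1L
  }
  e
}

.match_alignment_row <- function(s, e, rows) {
  best_n <- -1L
  best_row <- NA_integer_
  for (ri in seq_len(nrow(rows))) {
    r <- rows[ri, ]
    ug <- r[r != "-"]
    span <- max(e)
    if (length(ug) < span) {
      n_ok <- 0L
    } else {
      for (off in 0:(length(ug) - span)) {
        tgt <- ug[e + off]
        ok <- tgt == s | s == "X" | tgt == "X"
        if (all(ok)) {
          return(list(row = ri, offset = off))
        }
        n_ok <- sum(ok)
        if (n_ok > best_n) {
          best_n <- n_ok
          best_row <- ri
        }
      }
    }
  }
  list(row = NULL, partial_row = best_row, partial_n = max(best_n, 0L))
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble>", length(x$chains), "chains over", x$m,
      "alignment columns\n")
  invisible(x)
}

# ---- DescriptorMatrix ------------------------------------------------------

#' Create a masked descriptor matrix over an ensemble
#'
#' The core container: a chains x alignment-positions real matrix in which
#' `NA` marks a masked cell. Gap and disorder cells of the ensemble are
#' always masked; a descriptor may mask more (e.g. segment ends), never less.
#'
#' @param ensemble an `"ensemble"`.
#' @param name short descriptor name (`"kappa"`, `"tau"`, `"phi"`, ...).
#' @param fill optional data.frame with columns `chain_id`, `column`, `value`
#'   giving the unmasked cells. Filling a gap/disorder cell or a non-finite
#'   value is an error naming the offender.
#' @param units unit string (informational).
#' @return object of class `"descriptor_matrix"`: list with `name`, `values`
#'   (matrix, rownames = chain ids, colnames = 1-based columns), `units`.
#' @export
descriptor_matrix <- function(ensemble, name, fill = NULL, units = "") {
  ids <- names(ensemble$chains)
  v <- matrix(NA_real_, length(ids), ensemble$m,
              dimnames = list(ids, as.character(seq_len(ensemble$m))))
  if (!is.null(fill) && nrow(fill)) {
    for (i in seq_len(nrow(fill))) {
      cid <- as.character(fill$chain_id[i])
      col <- as.integer(fill$column[i])
      val <- fill$value[i]
      if (!cid %in% ids) stop("fill references unknown chain ", cid)
      if (col < 1 || col > ensemble$m)
        stop("fill column out of range for chain ", cid, ": ", col)
      if (is.na(ensemble$res_of[[cid]][col]))
        stop("fill on masked cell: chain ", cid, ", column ", col)
      if (!is.finite(val))
        stop("non-finite fill value at chain ", cid, ", column ", col)
      v[cid, col] <- val
    }
  }
  structure(list(name = name, values = v, units = units),
            class = "descriptor_matrix")
}

# Internal builder: scatter per-residue values of one chain into its columns.
.dm_from_per_residue <- function(ensemble, name, units, per_chain) {
  ids <- names(ensemble$chains)
  v <- matrix(NA_real_, length(ids), ensemble$m,
              dimnames = list(ids, as.character(seq_len(ensemble$m))))
  for (cid in ids) {
    vals <- per_chain[[cid]]
    if (is.null(vals)) next
    cols <- ensemble$col_of[[cid]]
    v[cid, cols] <- vals
  }
  structure(list(name = name, values = v, units = units),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat("<descriptor_matrix>", x$name,
      paste0("[", nrow(x$values), " x ", ncol(x$values), "]"),
      if (nzchar(x$units)) paste0("(", x$units, ")") else "",
      sprintf("- %.1f%% masked\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Mask of a descriptor matrix (TRUE = missing)
#' @param x a `"descriptor_matrix"`.
#' @export
dm_mask <- function(x) is.na(x$values)

#' Write / read a descriptor matrix as TSV
#'
#' Tab-separated, header row of 1-based alignment positions, one row per
#' chain id, `NA` for masked cells.
#' @param x a `"descriptor_matrix"`.
#' @param path output file.
#' @export
write_descriptor_tsv <- function(x, path) {
  df <- data.frame(chain_id = rownames(x$values), x$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_tsv
#' @param name,units metadata to attach on read.
#' @export
read_descriptor_tsv <- function(path, name = "descriptor", units = "") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = NA)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df[[1]]
  structure(list(name = name, values = v, units = units),
            class = "descriptor_matrix")
}
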