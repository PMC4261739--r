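# Per-residue binary interaction fingerprints.

#' Per-residue contact fingerprint
#'
#' The simplest structure interaction fingerprint: one bit per (chain,
#' alignment position), true iff any atom of the residue lies strictly
#' within `cutoff` of any partner atom. Partners are external to the chain -
#' the other protein chains of the crystal, user-supplied symmetry-mate
#' coordinates for crystal contacts, or ligand atoms. No interaction typing
#' is attempted; presence/absence is what the downstream comparisons use.
#'
#' @param ensemble an `"ensemble"`.
#' @param partners named list chain_id -> k x 3 partner coordinate matrix,
#'   or NULL entries for chains with no partners.
#' @param cutoff Angstrom, strict `<` (5.0 for protein/crystal contacts,
#'   4.5 for ligands by convention).
#' @param kind label: `"protein"`, `"ligand"` or `"crystal"`.
#' @return object of class `"fingerprint_matrix"`: `bits` (logical chains x
#'   positions, NA where the residue is absent), `kind`, `cutoff`.
#' @export
contact_fingerprint <- function(ensemble, partners, cutoff = 5.0,
                                kind = c("protein", "ligand", "crystal")) {
  kind <- match.arg(kind)
  ids <- names(ensemble$chains)
  m <- ensemble$m
  bits <- matrix(NA, length(ids), m,
                 dimnames = list(ids, as.character(seq_len(m))))
  cut2 <- cutoff^2
  for (cid in ids) {
    ch <- ensemble$chains[[cid]]
    cols <- ensemble$col_of[[cid]]
    P <- partners[[cid]]
    has_partner <- !is.null(P) && nrow(P) > 0
    for (i in seq_along(ch$residues)) {
      if (!has_partner) {
        bits[cid, cols[i]] <- FALSE
        next
      }
      xyz <- ch$residues[[i]]$xyz
      hit <- FALSE
      for (a in seq_len(nrow(xyz))) {
        d2 <- (P[, 1] - xyz[a, 1])^2 + (P[, 2] - xyz[a, 2])^2 +
          (P[, 3] - xyz[a, 3])^2
        if (any(d2 < cut2)) {
          hit <- TRUE
          break
        }
      }
      bits[cid, cols[i]] <- hit
    }
  }
  structure(list(bits = bits, kind = kind, cutoff = cutoff),
            class = "fingerprint_matrix")
}

#' Partner atom sets from within an ensemble
#'
#' Convenience constructor for [contact_fingerprint()] partners:
#' `"protein"` gives, per chain, all atoms of other chains sharing its
#' source file and model (interface contacts); `"ligand"` gives each
#' chain's retained non-water HETATM coordinates.
#'
#' @param ensemble an `"ensemble"`.
#' @param kind `"protein"` or `"ligand"`.
#' @return named list chain_id -> coordinate matrix (possibly NULL).
#' @export
partner_atoms <- function(ensemble, kind = c("protein", "ligand")) {
  kind <- match.arg(kind)
  ids <- names(ensemble$chains)
  out <- stats::setNames(vector("list", length(ids)), ids)
  if (kind == "ligand") {
    for (cid in ids) out[[cid]] <- ensemble$chains[[cid]]$ligand_xyz
    return(out)
  }
  src <- vapply(ensemble$chains, function(ch)
    paste0(ch$source_path, "::", sub(".*_(m[0-9]+)$", "\\1", ch$chain_id)),
    "")
  for (cid in ids) {
    sibs <- ids[src == src[cid] & ids != cid]
    if (!length(sibs)) next
    out[[cid]] <- do.call(rbind, lapply(sibs, function(s)
      do.call(rbind, lapply(ensemble$chains[[s]]$residues, `[[`, "xyz"))))
  }
  out
}

#' Group contact fractions and their difference
#'
#' Per column and group, the fraction of chains with the bit set; with a
#' two-group grouping also the absolute between-group difference -- the
#' pattern used to spot residues that contact a partner in one functional
#' state but not the other.
#'
#' @param fp a `"fingerprint_matrix"`.
#' @param grouping a named grouping (see [as_grouping()]).
#' @param difference compute the |group0 - group1| difference (requires
#'   exactly 2 groups; error otherwise).
#' @return data.frame: `position`, one `frac_<g>` column per group, and
#'   `difference` when requested (NA at fully masked columns).
#' @export
fingerprint_differences <- function(fp, grouping, difference = TRUE) {
  grouping <- as_grouping(grouping)
  grouping <- grouping[rownames(fp$bits)]
  glab <- sort(unique(grouping))
  if (difference && length(glab) != 2)
    stop("difference requires exactly 2 groups, got ", length(glab))
  m <- ncol(fp$bits)
  out <- data.frame(position = seq_len(m))
  fr <- matrix(NA_real_, m, length(glab))
  for (k in seq_along(glab)) {
    rows <- names(grouping)[grouping == glab[k]]
    sub <- fp$bits[rows, , drop = FALSE]
    fr[, k] <- vapply(seq_len(m), function(j) {
      b <- sub[, j]
      b <- b[!is.na(b)]
      if (!length(b)) NA_real_ else mean(b)
    }, 0)
    out[[paste0("frac_", glab[k])]] <- fr[, k]
  }
  if (difference) out$difference <- abs(fr[, 1] - fr[, 2])
  out
}

#' Write / read a fingerprint matrix as TSV
#'
#' Long format: `chain_id`, `column` (1-based), `bit` (0/1); masked cells
#' are omitted and read back as NA.
#' @param fp a `"fingerprint_matrix"`.
#' @param path file path.
#' @export
write_fingerprint_tsv <- function(fp, path) {
  idx <- which(!is.na(fp$bits), arr.ind = TRUE)
  df <- data.frame(chain_id = rownames(fp$bits)[idx[, 1]],
                   column = idx[, 2],
                   bit = as.integer(fp$bits[idx]))
  df <- df[order(df$chain_id, df$column), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_tsv
#' @param chain_ids,m full matrix shape to reconstruct.
#' @param kind,cutoff metadata to attach.
#' @export
read_fingerprint_tsv <- function(path, chain_ids, m, kind = "protein",
                                 cutoff = NA_real_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bits <- matrix(NA, length(chain_ids), m,
                 dimnames = list(chain_ids, as.character(seq_len(m))))
  for (i in seq_len(nrow(df)))
    bits[df$chain_id[i], df$column[i]] <- df$bit[i] == 1
  structure(list(bits = bits, kind = kind, cutoff = cutoff),
            class = "fingerprint_matrix")
}
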