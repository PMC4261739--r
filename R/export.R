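# Writers: Jalview sequence features, molecular-graphics attribute scripts,
# profile TSVs.

#' Write a profile or matrix as Jalview sequence features
#'
#' Jalview's plain-text feature format: first the colour definition
#' (`featureType<TAB>colour`), then one line per feature:
#' `description<TAB>sequenceId<TAB>-1<TAB>start<TAB>end<TAB>featureType<TAB>score`.
#' Positions are 1-based alignment columns; masked cells emit no line.
#'
#' @param x a `"variability_profile"` (one row, `sequence_id` names it) or a
#'   `"descriptor_matrix"` (one feature row per chain).
#' @param path output file.
#' @param feature_type Jalview feature type name.
#' @param colour Jalview colour word or `RRGGBB`.
#' @param sequence_id sequence id for profile input.
#' @export
write_jalview_features <- function(x, path, feature_type = "ensflex",
                                   colour = "red",
                                   sequence_id = "consensus") {
  lines <- paste0(feature_type, "\t", colour)
  emit <- function(id, pos, val)
    paste0(feature_type, "\t", id, "\t-1\t", pos, "\t", pos, "\t",
           feature_type, "\t", format(val, digits = 15))
  if (inherits(x, "variability_profile")) {
    for (j in which(!is.na(x$values)))
      lines <- c(lines, emit(sequence_id, j, x$values[j]))
  } else if (inherits(x, "descriptor_matrix")) {
    for (cid in rownames(x$values))
      for (j in which(!is.na(x$values[cid, ])))
        lines <- c(lines, emit(cid, j, x$values[cid, j]))
  } else stop("unsupported input for Jalview export")
  writeLines(lines, path)
  invisible(path)
}

#' Parse a Jalview feature file written by [write_jalview_features()]
#'
#' @param path feature file.
#' @return data.frame with `sequence_id`, `position`, `score`.
#' @export
read_jalview_features <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  feat <- parts[lengths(parts) >= 7]
  if (!length(feat))
    return(data.frame(sequence_id = character(0), position = integer(0),
                      score = numeric(0)))
  data.frame(
    sequence_id = vapply(feat, `[[`, "", 2),
    position = as.integer(vapply(feat, `[[`, "", 4)),
    score = as.numeric(vapply(feat, `[[`, "", 7)))
}

#' Write a molecular-graphics attribute script
#'
#' Emits a plain-text PyMOL-style script that loads a per-residue numeric
#' attribute into the B-factor slot of a representative structure, the
#' usual route to "putty"-cartoon or colour-ramp summaries of an ensemble
#' statistic. Residues masked in the profile receive the sentinel value
#' documented in the script header.
#'
#' @param profile a `"variability_profile"` over alignment columns.
#' @param ensemble the `"ensemble"`.
#' @param representative chain_id to map columns onto (error if absent).
#' @param path output file.
#' @param sentinel value for masked positions (default -1).
#' @param object molecular-graphics object name used in the commands.
#' @export
write_attribute_script <- function(profile, ensemble, representative, path,
                                   sentinel = -1, object = "rep") {
  if (!representative %in% names(ensemble$chains))
    stop("representative chain ", representative, " not in ensemble")
  ch <- ensemble$chains[[representative]]
  letter <- sub(".*_([A-Za-z0-9])_m[0-9]+$", "\\1", representative)
  cols <- ensemble$col_of[[representative]]
  lines <- c(
    paste0("# per-residue attribute: ", profile$metric),
    paste0("# masked positions carry the sentinel value ", sentinel),
    paste0("alter ", object, ", b=", sentinel))
  for (i in seq_along(ch$residues)) {
    v <- profile$values[cols[i]]
    val <- if (is.na(v)) sentinel else v
    r <- ch$residues[[i]]
    lines <- c(lines, paste0(
      "alter (", object, " and chain ", letter, " and resi ", r$resseq,
      r$icode, "), b=", format(val, digits = 10)))
  }
  lines <- c(lines, "rebuild")
  writeLines(lines, path)
  invisible(path)
}

#' Write a variability profile as TSV
#'
#' Columns: `position` (1-based), `value` (`NA` if masked), `n_contributing`,
#' `mask_reason` (`""`, `"low_coverage"` or `"undefined"`).
#' @param profile a `"variability_profile"`.
#' @param path output file.
#' @export
write_profile_tsv <- function(profile, path) {
  m <- length(profile$values)
  reason <- ifelse(!is.na(profile$values), "",
                   ifelse(profile$n > 0, "low_coverage", "undefined"))
  df <- data.frame(position = seq_len(m),
                   value = profile$values,
                   n_contributing = profile$n,
                   mask_reason = reason)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
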