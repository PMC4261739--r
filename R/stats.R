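# Per-alignment-position ensemble statistics.

.new_profile <- function(values, n, metric, min_fraction = NA_real_) {
  structure(list(values = values, n = n, metric = metric,
                 min_fraction = min_fraction),
            class = "variability_profile")
}

#' @export
print.variability_profile <- function(x, ...) {
  cat("<variability_profile>", x$metric, "-", length(x$values), "positions,",
      sum(!is.na(x$values)), "unmasked\n")
  invisible(x)
}

#' Conformational variability per alignment position
#'
#' For each position, the mean over chains of the Euclidean distance between
#' the chain's descriptor tuple and the componentwise median tuple. With the
#' standardised (kappa, tau) pair this is the backbone variability; with the
#' raw sentinel (x, y, z) triplet the side-chain variability. A position is
#' masked when fewer than `min_fraction` of the chains contribute (the
#' default 0.5 mirrors flagging positions disordered in more than half the
#' structures).
#'
#' @param mats list of `"descriptor_matrix"` objects sharing dimensions; a
#'   chain contributes at a position only if unmasked in every component.
#' @param min_fraction minimum contributing fraction of chains in (0, 1].
#' @return a `"variability_profile"` (values, per-position n).
#' @export
variability <- function(mats, min_fraction = 0.5) {
  if (inherits(mats, "descriptor_matrix")) mats <- list(mats)
  V <- lapply(mats, `[[`, "values")
  nch <- nrow(V[[1]])
  m <- ncol(V[[1]])
  vals <- rep(NA_real_, m)
  nvec <- integer(m)
  for (j in seq_len(m)) {
    X <- vapply(V, function(v) v[, j], numeric(nch))   # chains x components
    if (is.null(dim(X))) X <- matrix(X, ncol = length(V))
    ok <- rowSums(is.na(X)) == 0
    nvec[j] <- sum(ok)
    if (nvec[j] == 0 || nvec[j] / nch < min_fraction) next
    Xo <- X[ok, , drop = FALSE]
    med <- apply(Xo, 2, stats::median)
    vals[j] <- mean(sqrt(rowSums(sweep(Xo, 2, med)^2)))
  }
  metric <- paste(vapply(mats, `[[`, "", "name"), collapse = "+")
  .new_profile(vals, nvec, metric, min_fraction)
}

#' Dihedral-angle variability via the circular order parameter
#'
#' Per position and angle, the order parameter
#' S(theta) = ||sum_j (cos theta_j, sin theta_j)|| / n lies in [0, 1]:
#' 1 when all chains share the angle, 0 when the angle vectors cancel.
#' Variability = 1 - (S(phi) + S(psi)) / 2, in [0, 1].
#'
#' @param phi,psi `"descriptor_matrix"` objects in degrees.
#' @param min_fraction mask positions with fewer contributing chains.
#' @return a `"variability_profile"`; positions with fewer than 2 chains for
#'   either angle are masked.
#' @export
dihedral_variability <- function(phi, psi, min_fraction = 0.5) {
  P <- phi$values * pi / 180
  S <- psi$values * pi / 180
  nch <- nrow(P)
  m <- ncol(P)
  ordp <- function(th) {
    th <- th[!is.na(th)]
    if (length(th) < 2) return(NA_real_)
    sqrt(sum(cos(th))^2 + sum(sin(th))^2) / length(th)
  }
  vals <- rep(NA_real_, m)
  nvec <- integer(m)
  for (j in seq_len(m)) {
    sp <- ordp(P[, j])
    ss <- ordp(S[, j])
    nvec[j] <- min(sum(!is.na(P[, j])), sum(!is.na(S[, j])))
    if (is.na(sp) || is.na(ss) || nvec[j] / nch < min_fraction) next
    vals[j] <- 1 - (sp + ss) / 2
  }
  .new_profile(vals, nvec, "phipsi_order", min_fraction)
}

#' Grouped variance statistic S
#'
#' Separates thermal-scale fluctuation from significant conformational
#' change. Per alignment position, with the pooled mean x-bar over all
#' unmasked values, each group i of chains contributes
#' s_i = (1/n_i) sum_j (x_ij - x-bar)^2 over its unmasked members, and
#' S = mean of s_i over non-empty groups. When the groups are clusters of
#' near-identical structures, pure thermal noise gives tiny within-group
#' deviations from the pooled mean at every position, while a genuine
#' two-state change leaves whole groups far from the pooled mean and S
#' large at the hinge. For the backbone, kappa and tau are combined
#' additively on the variance scale: pass both matrices and S = S(kappa) +
#' S(tau) per position.
#'
#' @param x a `"descriptor_matrix"` (typically standardised) or a list of
#'   them (summed component-wise, e.g. `list(kappa_z, tau_z)`).
#' @param grouping named integer vector chain_id -> group label 0..n-1
#'   (see [as_grouping()]).
#' @return object of class `"group_variance"`: `s` (groups x positions),
#'   `S` (per position, NA where fully masked), `descriptor`.
#' @export
group_variance <- function(x, grouping) {
  if (inherits(x, "descriptor_matrix")) x <- list(x)
  grouping <- as_grouping(grouping)
  parts <- lapply(x, .group_variance_one, grouping = grouping)
  S <- Reduce(function(a, b) ifelse(is.na(a) & is.na(b), NA,
                                    rowSums(cbind(a, b), na.rm = TRUE)),
              lapply(parts, `[[`, "S"))
  s <- Reduce(`+`, lapply(parts, function(p) {
    q <- p$s
    q[is.na(q)] <- 0
    q
  }))
  structure(list(
    s = s, S = S,
    descriptor = paste(vapply(x, `[[`, "", "name"), collapse = "+")),
    class = "group_variance")
}

.group_variance_one <- function(mat, grouping) {
  v <- mat$values
  grouping <- grouping[rownames(v)]
  if (anyNA(grouping)) stop("grouping does not cover all chains")
  m <- ncol(v)
  glab <- sort(unique(grouping))
  s <- matrix(NA_real_, length(glab), m,
              dimnames = list(as.character(glab), colnames(v)))
  S <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    xj <- v[, j]
    ok <- !is.na(xj)
    if (!any(ok)) next
    xbar <- mean(xj[ok])
    si <- c()
    for (g in glab) {
      mem <- ok & grouping == g
      ni <- sum(mem)
      if (ni == 0) next
      sg <- sum((xj[mem] - xbar)^2) / ni
      s[as.character(g), j] <- sg
      si <- c(si, sg)
    }
    S[j] <- mean(si)
  }
  list(s = s, S = S)
}

#' Validate / coerce a grouping
#'
#' @param x named vector (chain_id -> label); labels are made contiguous
#'   integers 0..n-1, ordered by first appearance of the sorted labels.
#' @return named integer vector with class `"grouping"`.
#' @export
as_grouping <- function(x) {
  if (is.null(names(x))) stop("grouping must be named by chain_id")
  f <- factor(x, levels = sort(unique(x)))
  out <- as.integer(f) - 1L
  names(out) <- names(x)
  class(out) <- "grouping"
  out
}

#' Sliding-window RMSF over an ensemble
#'
#' Classic fluctuation profile made superposition-local: for each alignment
#' column, the `window` surrounding columns' CA atoms of every chain are
#' least-squares fitted onto the reference chain's same window, and the RMSF
#' at the centre column is the root mean squared deviation of the fitted
#' centre CA positions about their mean. The window fit removes rigid-body
#' motion, so only local deformation remains - the backbone analogue the
#' curvature/torsion statistics are compared against.
#'
#' @param ensemble an `"ensemble"`.
#' @param reference chain_id of the reference chain.
#' @param window odd window width >= 3 (default 5).
#' @return a `"variability_profile"` in Angstrom; columns masked where the
#'   reference window is incomplete or fewer than 2 chains contribute.
#' @export
rmsf_window <- function(ensemble, reference, window = 5) {
  stopifnot(window >= 3, window %% 2 == 1)
  ids <- names(ensemble$chains)
  if (!reference %in% ids) stop("reference chain not in ensemble")
  m <- ensemble$m
  hw <- (window - 1) / 2
  # CA coordinate array: chain x column x 3
  A <- array(NA_real_, c(length(ids), m, 3), dimnames = list(ids, NULL, NULL))
  for (cid in ids) {
    ca <- .ca_matrix(ensemble$chains[[cid]])
    cols <- ensemble$col_of[[cid]]
    A[cid, cols, ] <- ca
  }
  vals <- rep(NA_real_, m)
  nvec <- integer(m)
  for (c0 in seq_len(m)) {
    if (c0 - hw < 1 || c0 + hw > m) next
    win <- (c0 - hw):(c0 + hw)
    refw <- A[reference, win, ]
    if (anyNA(refw)) next
    pts <- list()
    for (cid in ids) {
      w <- A[cid, win, ]
      if (anyNA(w)) next
      fit <- .kabsch(w, refw)
      pts[[cid]] <- .apply_rigid(w, fit)[hw + 1, ]
    }
    nvec[c0] <- length(pts)
    if (length(pts) < 2) next
    P <- do.call(rbind, pts)
    ctr <- colMeans(P)
    vals[c0] <- sqrt(mean(rowSums(sweep(P, 2, ctr)^2)))
  }
  .new_profile(vals, nvec, "rmsf")
}

#' Normalised C-alpha B-factors of a chain
#'
#' Iterative outlier-trimmed z-scores: the mean and sd of the CA B-factors
#' are computed, residues beyond 3 sd are removed, and the cycle repeats
#' until nothing is removed or at most 50% of residues remain; the final
#' mean and sd then standardise ALL residues, outliers included. This keeps
#' a few extreme residues (often poorly modelled termini) from compressing
#' the scale of the rest.
#'
#' @param chain a `"chain"` with >= 5 CA B-factors.
#' @return numeric vector of z-scores per residue (NA where no CA B-factor).
#' @export
normalise_bfactors <- function(chain) {
  b <- vapply(chain$residues, function(r)
    if ("CA" %in% names(r$b)) unname(r$b["CA"]) else NA_real_, 0)
  obs <- which(!is.na(b))
  if (length(obs) < 5) stop("need >= 5 CA B-factors")
  keep <- obs
  n0 <- length(obs)
  repeat {
    mu <- mean(b[keep])
    sg <- stats::sd(b[keep])
    if (is.na(sg) || sg == 0) break
    out <- keep[abs(b[keep] - mu) > 3 * sg]
    if (!length(out)) break
    keep <- setdiff(keep, out)
    if (length(keep) <= n0 / 2) break
  }
  mu <- mean(b[keep])
  sg <- stats::sd(b[keep])
  if (is.na(sg) || sg == 0) {
    warning("zero B-factor spread in chain ", chain$chain_id,
            "; all z-scores 0", call. = FALSE)
    z <- ifelse(is.na(b), NA_real_, 0)
    return(z)
  }
  (b - mu) / sg
}

#' Per-position contact fraction with partner atoms
#'
#' Fraction of chains in which the residue at each alignment position has at
#' least one atom strictly within `cutoff` of any partner atom. Partners are
#' whatever atom set the question calls for: other chains of the crystal for
#' interface contacts, user-supplied symmetry mates for crystal contacts
#' (5 A is the usual cutoff), or ligand atoms (4.5 A).
#'
#' @param ensemble an `"ensemble"`.
#' @param partners named list chain_id -> partner coordinate matrix (k x 3)
#'   or NULL (no partners = no contacts for that chain).
#' @param cutoff distance cutoff in Angstrom (strict `<`).
#' @return a `"variability_profile"` of fractions in [0, 1]; denominator =
#'   chains whose residue is present at the position.
#' @export
contact_fraction <- function(ensemble, partners, cutoff = 5.0) {
  fp <- contact_fingerprint(ensemble, partners, cutoff)
  bits <- fp$bits
  m <- ncol(bits)
  vals <- rep(NA_real_, m)
  nvec <- integer(m)
  for (j in seq_len(m)) {
    ok <- !is.na(bits[, j])
    nvec[j] <- sum(ok)
    if (nvec[j] == 0) next
    vals[j] <- mean(bits[ok, j])
  }
  .new_profile(vals, nvec, "contact_fraction")
}
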