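# Gap-free submatrix selection, NIPALS PCA, correlated conformational
# change, chain distances and hierarchical clustering.

#' Select a complete (gap-free) submatrix
#'
#' Many multivariate methods need complete data, but crystallographic
#' ensembles are full of disorder gaps. This implements the simple
#' two-phase reduction: first drop the most-disordered chains (never more
#' than a fraction `mpc` of them), then drop every column that still
#' contains a gap. Columns are visited in decreasing gap count (ties:
#' leftmost first); before processing a column, if removing its gapped
#' chains would push the cumulative removals above floor(mpc * n) the loop
#' exits.
#'
#' @param x a `"descriptor_matrix"` (or a plain matrix with dimnames; NA =
#'   gap).
#' @param mpc maximum fraction of chains to discard, in [0, 1) (default
#'   0.10).
#' @return object of class `"full_matrix"`: `values` (complete submatrix),
#'   `kept_chains`, `kept_columns` (original 1-based columns, in order),
#'   `removed_chain_fraction`.
#' @export
select_full_matrix <- function(x, mpc = 0.10) {
  stopifnot(mpc >= 0, mpc < 1)
  v <- if (inherits(x, "descriptor_matrix")) x$values else x
  n <- nrow(v)
  budget <- floor(mpc * n)
  gaps0 <- colSums(is.na(v))
  ord <- order(-gaps0, seq_len(ncol(v)))     # decreasing gaps, ties leftmost
  removed <- character(0)
  alive <- rownames(v)
  for (j in ord) {
    if (gaps0[j] == 0) break
    gapped <- alive[is.na(v[alive, j])]
    if (length(removed) + length(gapped) > budget) break
    removed <- c(removed, gapped)
    alive <- setdiff(alive, gapped)
  }
  keep_cols <- unname(which(colSums(is.na(v[alive, , drop = FALSE])) == 0))
  if (length(alive) == 0 || length(keep_cols) == 0)
    stop("no complete submatrix at mpc = ", mpc,
         "; increase mpc or reduce disorder")
  structure(list(values = v[alive, keep_cols, drop = FALSE],
                 kept_chains = alive,
                 kept_columns = keep_cols,
                 removed_chain_fraction = length(removed) / n),
            class = "full_matrix")
}

#' NIPALS principal component analysis
#'
#' Non-linear iterative partial least squares: components are extracted
#' sequentially, each by alternating score/loading regressions until
#' convergence, and deflated from the matrix. On complete data the result
#' coincides with the SVD's leading components (up to sign); NIPALS is used
#' because it extracts only the `k` components asked for and generalises
#' naturally to the incomplete-data setting the full-matrix step avoids.
#' Columns are mean-centred internally; no per-variable rescaling is done
#' (backbone descriptors are already ensemble-standardised).
#'
#' Each loading vector is oriented so that its largest-magnitude entry is
#' positive, making outputs reproducible across platforms.
#'
#' @param full a `"full_matrix"` (or complete plain matrix).
#' @param k number of components.
#' @param tol convergence tolerance on the score vector.
#' @param max_iter iteration cap per component (warning on hit).
#' @return object of class `"nipals_pca"`: `scores` (chains x k),
#'   `loadings` (variables x k, unit columns), `explained_variance_fraction`,
#'   `converged` (logical per component).
#' @export
nipals_pca <- function(full, k, tol = 1e-9, max_iter = 1000) {
  X <- if (inherits(full, "full_matrix")) full$values else full
  stopifnot(nrow(X) >= 2, ncol(X) >= 2, !anyNA(X))
  X <- scale(X, center = TRUE, scale = FALSE)
  total_ss <- sum(X^2)
  k <- min(k, nrow(X) - 1, ncol(X))
  scores <- matrix(0, nrow(X), k, dimnames = list(rownames(X), NULL))
  loadings <- matrix(0, ncol(X), k, dimnames = list(colnames(X), NULL))
  evf <- numeric(k)
  converged <- logical(k)
  for (comp in seq_len(k)) {
    t_vec <- X[, which.max(apply(X, 2, stats::var))]
    if (sum(t_vec^2) < 1e-300) break
    for (it in seq_len(max_iter)) {
      p <- as.vector(crossprod(X, t_vec)) / sum(t_vec^2)
      p <- p / sqrt(sum(p^2))
      t_new <- as.vector(X %*% p)
      if (sqrt(sum((t_new - t_vec)^2)) < tol * sqrt(sum(t_new^2))) {
        t_vec <- t_new
        converged[comp] <- TRUE
        break
      }
      t_vec <- t_new
    }
    if (!converged[comp])
      warning("NIPALS component ", comp, " did not converge in ",
              max_iter, " iterations", call. = FALSE)
    # deterministic orientation
    if (p[which.max(abs(p))] < 0) {
      p <- -p
      t_vec <- -t_vec
    }
    scores[, comp] <- t_vec
    loadings[, comp] <- p
    evf[comp] <- sum(t_vec^2) / total_ss
    X <- X - tcrossprod(t_vec, p)
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction = evf, k = k,
                 converged = converged),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat("<nipals_pca>", x$k, "components; explained:",
      paste0(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
             collapse = ", "), "\n")
  invisible(x)
}

#' Assemble per-position descriptors into a PCA variable matrix
#'
#' Interleaves the component matrices position by position so that loadings
#' map straight back to residues: backbone mode yields variables
#' `p<j>_kappa`, `p<j>_tau`; side-chain mode `p<j>_sc_x` etc. (Gly/Ala
#' columns contribute nothing because they are fully masked). Columns where
#' every chain is masked in a component are dropped.
#'
#' @param mats named list of `"descriptor_matrix"` objects (e.g.
#'   `list(kappa = ..., tau = ...)`), typically standardised.
#' @return a `"descriptor_matrix"` of chains x variables whose colnames
#'   carry the position/component provenance.
#' @export
assemble_pca_variables <- function(mats) {
  stopifnot(length(mats) >= 1, !is.null(names(mats)))
  m <- ncol(mats[[1]]$values)
  blocks <- list()
  for (j in seq_len(m)) {
    for (nm in names(mats)) {
      col <- mats[[nm]]$values[, j]
      if (all(is.na(col))) next
      blocks[[paste0("p", j, "_", nm)]] <- col
    }
  }
  v <- do.call(cbind, blocks)
  structure(list(name = "pca_variables", values = v, units = "mixed"),
            class = "descriptor_matrix")
}

#' Correlated conformational change between distant positions
#'
#' For every pair of alignment positions at least `min_separation` columns
#' apart, the Pearson correlation of each descriptor component across chains
#' (pairwise-complete) is computed and the components' coefficients
#' averaged; pairs are ranked by absolute averaged correlation and the top
#' `top_k` returned. Distant residue pairs that move together across an
#' ensemble are candidates for allosteric coupling.
#'
#' @param mats list of `"descriptor_matrix"` objects sharing dimensions
#'   (e.g. standardised kappa and tau, or the three sentinel coordinates).
#' @param min_separation minimum |column difference| (default 30).
#' @param top_k number of pairs to return (default 25).
#' @param min_n minimum pairwise-complete chains per component (default 3).
#' @return data.frame (class `"correlation_pairs"`) with `position_a`,
#'   `position_b`, `r`, sorted by |r| descending.
#' @export
correlated_pairs <- function(mats, min_separation = 30, top_k = 25,
                             min_n = 3) {
  if (inherits(mats, "descriptor_matrix")) mats <- list(mats)
  m <- ncol(mats[[1]]$values)
  rsum <- matrix(0, m, m)
  rcnt <- matrix(0L, m, m)
  for (mat in mats) {
    v <- mat$values
    ok <- !is.na(v)
    npair <- crossprod(ok)                     # pairwise-complete counts
    sdv <- apply(v, 2, stats::sd, na.rm = TRUE)
    cc <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
    bad <- is.na(cc) | npair < min_n |
      outer(sdv, sdv, function(a, b) is.na(a) | is.na(b) | a == 0 | b == 0)
    cc[bad] <- NA
    has <- !is.na(cc)
    cc[!has] <- 0
    rsum <- rsum + cc
    rcnt <- rcnt + has
  }
  ravg <- ifelse(rcnt > 0, rsum / rcnt, NA)
  pairs <- which(upper.tri(ravg) &
                   abs(row(ravg) - col(ravg)) >= min_separation &
                   !is.na(ravg), arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    out <- data.frame(position_a = integer(0), position_b = integer(0),
                      r = numeric(0))
  } else {
    r <- ravg[pairs]
    ord <- order(-abs(r), pairs[, 1], pairs[, 2])
    sel <- ord[seq_len(min(top_k, length(ord)))]
    out <- data.frame(position_a = pairs[sel, 1],
                      position_b = pairs[sel, 2],
                      r = r[sel], row.names = NULL)
  }
  class(out) <- c("correlation_pairs", "data.frame")
  attr(out, "min_separation") <- min_separation
  attr(out, "top_k") <- top_k
  out
}

#' Distance between two chains' descriptor vectors
#'
#' `"pearson"`: d = (1 - r) / 2 over the pairwise-complete entries of the
#' two vectors (capped standardised kappa/tau is the intended input - the
#' capping tames the outlier sensitivity of r); in [0, 1], 0 for identical,
#' 1 for perfectly anti-correlated profiles. `"tanimoto"`: 1 minus the
#' Tanimoto similarity |A&B| / |A|B| of two fingerprint bit sets; two empty
#' sets have distance 0.
#'
#' @param a,b numeric vectors (pearson; NA = masked) or logical vectors
#'   (tanimoto; NA treated as FALSE).
#' @param mode `"pearson"` or `"tanimoto"`.
#' @return distance in [0, 1], or NA (with warning) when fewer than 3
#'   shared entries support a Pearson correlation.
#' @export
chain_distance <- function(a, b, mode = c("pearson", "tanimoto")) {
  mode <- match.arg(mode)
  if (mode == "pearson") {
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) {
      warning("fewer than 3 shared entries; Pearson distance undefined",
              call. = FALSE)
      return(NA_real_)
    }
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    r <- stats::cor(a[ok], b[ok])
    (1 - r) / 2
  } else {
    a <- !is.na(a) & a
    b <- !is.na(b) & b
    un <- sum(a | b)
    if (un == 0) return(0)
    1 - sum(a & b) / un
  }
}

#' All pairwise chain distances over a descriptor matrix
#'
#' @param x a `"descriptor_matrix"` (rows = chains; for the backbone metric
#'   pass the column-bound standardised kappa/tau, e.g.
#'   `cbind(kappa_z$values, tau_z$values)` wrapped in a matrix) or a logical
#'   fingerprint matrix.
#' @param mode passed to [chain_distance()].
#' @return symmetric matrix of distances (NA where undefined).
#' @export
descriptor_distances <- function(x, mode = c("pearson", "tanimoto")) {
  mode <- match.arg(mode)
  v <- if (inherits(x, "descriptor_matrix")) x$values else
    if (inherits(x, "fingerprint_matrix")) x$bits else x
  n <- nrow(v)
  D <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- suppressWarnings(chain_distance(v[i, ], v[j, ], mode))
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Hierarchical clustering of chains with Newick export
#'
#' Average-linkage (default) agglomerative clustering of a chain distance
#' matrix; the flat cut at height `cut` defines the grouping fed to
#' [group_variance()] (a 1% Pearson-distance cut collects near-identical
#' structures, the grouping that suppresses thermal noise). Chains involved
#' in undefined distances are placed in singleton groups with a warning and
#' excluded from the tree.
#'
#' @param D symmetric distance matrix (dimnames = chain ids).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @param cut flat-cut height.
#' @return list with `grouping` (named 0-based integer labels, class
#'   `"grouping"`) and `tree` (class `"chain_tree"`: `hclust`, `newick`,
#'   `distance_metric`).
#' @export
cluster_chains <- function(D, linkage = c("average", "complete", "single"),
                           cut = 0.01) {
  linkage <- match.arg(linkage)
  ids <- sort(rownames(D))
  D <- D[ids, ids]
  bad <- ids[apply(D, 1, anyNA)]
  if (length(bad))
    warning("undefined distances; singleton groups for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  good <- setdiff(ids, bad)
  labels <- integer(0)
  tree <- NULL
  if (length(good) >= 2) {
    hc <- stats::hclust(stats::as.dist(D[good, good]), method = linkage)
    grp <- stats::cutree(hc, h = cut)
    phy <- ape::as.phylo(hc)
    tree <- structure(list(hclust = hc,
                           newick = ape::write.tree(phy),
                           distance_metric = linkage),
                      class = "chain_tree")
    labels <- grp
  } else if (length(good) == 1) {
    labels <- stats::setNames(1L, good)
  }
  if (length(bad))
    labels <- c(labels, stats::setNames(
      max(labels, 0L) + seq_along(bad), bad))
  grouping <- as_grouping(labels[ids])
  list(grouping = grouping, tree = tree)
}

#' Write a chain tree as a Newick file
#' @param tree a `"chain_tree"`.
#' @param path output file.
#' @export
write_chain_tree <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}
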