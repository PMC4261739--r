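# Independent brute-force oracles. Each re-derives a statistic from its
# definition with plain loops (or a different algorithm entirely), never
# calling the package's implementation path.

# C-alpha points on a circular helix: radius a (A), rise per residue (A),
# turn per residue (degrees). Closed-form curvature/torsion of the curve:
# kappa = a/(a^2+b^2), tau = b/(a^2+b^2) with b = rise per radian.
helix_ca <- function(n, a = 2.3, rise = 1.5, turn = 100) {
  th <- (seq_len(n) - 1) * turn * pi / 180
  b <- rise / (turn * pi / 180)
  cbind(a * cos(th), a * sin(th), b * th)
}

helix_truth <- function(a = 2.3, rise = 1.5, turn = 100) {
  b <- rise / (turn * pi / 180)
  c(kappa = a / (a^2 + b^2), tau = b / (a^2 + b^2))
}

# Chain of CA-only residues from a coordinate matrix.
ca_chain <- function(P, id = "ca_A_m1") {
  residues <- lapply(seq_len(nrow(P)), function(i) {
    xyz <- matrix(P[i, ], 1, 3, dimnames = list("CA", NULL))
    list(resname = "ALA", resseq = i, icode = "", xyz = xyz,
         b = c(CA = 20))
  })
  new_chain(id, residues)
}

# Wrap a plain matrix as a descriptor matrix.
dm <- function(values, name = "x", units = "") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- as.character(seq_len(ncol(values)))
  structure(list(name = name, values = values, units = units),
            class = "descriptor_matrix")
}

# In-memory ensemble from a fixture spec.
quick_ens <- function(...) {
  fx <- make_ensemble(fixture_spec(...), write = FALSE)
  list(fx = fx, ens = build_ensemble(fx$chains, fx$alignment))
}

# --- definitional oracles ---------------------------------------------------

o_variability <- function(mats, min_fraction = 0.5) {
  nch <- nrow(mats[[1]])
  m <- ncol(mats[[1]])
  out <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    rows <- which(apply(sapply(mats, function(v) !is.na(v[, j])), 1, all))
    if (length(rows) == 0 || length(rows) / nch < min_fraction) next
    med <- sapply(mats, function(v) stats::median(v[rows, j]))
    d <- sapply(rows, function(i) {
      x <- sapply(mats, function(v) v[i, j])
      sqrt(sum((x - med)^2))
    })
    out[j] <- mean(d)
  }
  out
}

o_order_param <- function(theta_deg) {
  th <- theta_deg[!is.na(theta_deg)] * pi / 180
  if (length(th) < 2) return(NA_real_)
  sqrt(sum(cos(th))^2 + sum(sin(th))^2) / length(th)
}

o_dihedral_var <- function(phiM, psiM, min_fraction = 0.5) {
  m <- ncol(phiM)
  nch <- nrow(phiM)
  out <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    sp <- o_order_param(phiM[, j])
    ss <- o_order_param(psiM[, j])
    n <- min(sum(!is.na(phiM[, j])), sum(!is.na(psiM[, j])))
    if (is.na(sp) || is.na(ss) || n / nch < min_fraction) next
    out[j] <- 1 - (sp + ss) / 2
  }
  out
}

o_group_variance <- function(v, groups) {
  m <- ncol(v)
  S <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x <- v[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    xbar <- mean(x[ok])
    si <- c()
    for (g in unique(groups)) {
      mem <- which(ok & groups == g)
      if (!length(mem)) next
      si <- c(si, sum((x[mem] - xbar)^2) / length(mem))
    }
    S[j] <- mean(si)
  }
  S
}

# Horn quaternion absolute orientation: an algorithmically independent
# rigid-superposition oracle (the implementation uses SVD/Kabsch).
o_superpose <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  P <- sweep(moving, 2, cm)
  Q <- sweep(fixed, 2, cf)
  M <- crossprod(P, Q)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  fit <- sweep(P %*% t(R), 2, cf, "+")
  # fitted point for any x: (x - cm) %*% rot + cf
  list(coords = fit, rmsd = sqrt(mean(rowSums((fit - fixed)^2))),
       rot = t(R), cm = cm, cf = cf)
}

o_rmsf <- function(ca_array, reference, window = 5) {
  ids <- dimnames(ca_array)[[1]]
  m <- dim(ca_array)[2]
  hw <- (window - 1) / 2
  out <- rep(NA_real_, m)
  for (c0 in seq_len(m)) {
    if (c0 - hw < 1 || c0 + hw > m) next
    win <- (c0 - hw):(c0 + hw)
    refw <- ca_array[reference, win, ]
    if (anyNA(refw)) next
    pts <- NULL
    for (cid in ids) {
      w <- ca_array[cid, win, ]
      if (anyNA(w)) next
      pts <- rbind(pts, o_superpose(w, refw)$coords[hw + 1, ])
    }
    if (is.null(pts) || nrow(pts) < 2) next
    ctr <- colMeans(pts)
    out[c0] <- sqrt(mean(rowSums(sweep(pts, 2, ctr)^2)))
  }
  out
}

o_bnorm <- function(b) {
  obs <- which(!is.na(b))
  keep <- obs
  repeat {
    mu <- mean(b[keep]); sg <- stats::sd(b[keep])
    if (is.na(sg) || sg == 0) break
    out <- keep[abs(b[keep] - mu) > 3 * sg]
    if (!length(out)) break
    keep <- setdiff(keep, out)
    if (length(keep) <= length(obs) / 2) break
  }
  mu <- mean(b[keep]); sg <- stats::sd(b[keep])
  if (is.na(sg) || sg == 0) return(ifelse(is.na(b), NA, 0))
  (b - mu) / sg
}

# O(N^2) contact bits: residue_atoms = list(list(cols = j, xyz = matrix)).
o_contact_bits <- function(res_xyz, partner, cutoff) {
  if (is.null(partner) || nrow(partner) == 0) return(FALSE)
  for (a in seq_len(nrow(res_xyz)))
    for (p in seq_len(nrow(partner)))
      if (sqrt(sum((res_xyz[a, ] - partner[p, ])^2)) < cutoff) return(TRUE)
  FALSE
}

o_pearson_dist <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  (1 - stats::cor(a[ok], b[ok])) / 2
}

o_tanimoto_dist <- function(a, b) {
  a <- which(!is.na(a) & a); b <- which(!is.na(b) & b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

# Direct simulation of the stated full-matrix loop.
o_select_full <- function(v, mpc) {
  n <- nrow(v)
  budget <- floor(mpc * n)
  gaps <- colSums(is.na(v))
  ord <- order(-gaps, seq_len(ncol(v)))
  removed <- integer(0)
  for (j in ord) {
    if (gaps[j] == 0) break
    gapped <- setdiff(which(is.na(v[, j])), removed)
    if (length(removed) + length(gapped) > budget) break
    removed <- c(removed, gapped)
  }
  chains <- setdiff(seq_len(n), removed)
  cols <- which(colSums(is.na(v[chains, , drop = FALSE])) == 0)
  list(chains = sort(chains), cols = cols)
}

# Brute-force three-stage distinct-pocket trace.
o_distinct_pockets <- function(D, cutoff, t) {
  ids <- sort(rownames(D))
  D <- D[ids, , drop = FALSE]
  m <- ncol(D)
  winner <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    col <- D[, j]
    if (all(is.na(col))) next
    best <- -Inf; who <- NA_character_
    for (i in ids) {
      if (!is.na(col[i]) && col[i] > best) { best <- col[i]; who <- i }
    }
    if (best >= cutoff) winner[j] <- who
  }
  wins <- sapply(ids, function(i) sum(winner == i, na.rm = TRUE))
  ranked <- ids[order(-wins, ids)]
  ranked <- ranked[wins[ranked] > 0]
  sel <- utils::head(ranked, t)
  labels <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    if (is.na(winner[j])) next
    rk <- match(winner[j], sel)
    if (!is.na(rk)) labels[j] <- rk - 1L
  }
  list(labels = labels, selected = sel)
}
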