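# Backbone differential geometry: per-residue curvature and torsion of the
# C-alpha trace, phi/psi dihedrals, Ramachandran regions and ensemble
# standardisation.

#' Curvature and torsion of a chain's C-alpha trace
#'
#' Computes the per-residue curvature kappa (1/A, always >= 0) and signed
#' torsion tau (1/A) of the space curve through the chain's CA atoms.
#' kappa measures local deviation from a straight line, tau deviation from a
#' plane curve; together they characterise backbone conformation completely
#' and, being intrinsic, need no superposition.
#'
#' The default estimator fits, at every interior residue, the unique circular
#' helix reproducing the local discrete geometry of the trace (mean chord
#' length, chord angle, and the circular mean of the two flanking CA virtual
#' dihedrals) and reports that helix's kappa and tau. A circular helix of
#' radius a and rise-per-radian b has kappa = a/(a^2+b^2) and
#' tau = b/(a^2+b^2); the estimator is exact on such curves at any sampling
#' density, which matters because consecutive CA atoms sample the backbone
#' curve very coarsely (~3.8 A apart, ~100 degrees of helical turn). The
#' closed form used is cos(delta) = (cos|phi| (1+cos gamma) - (1-cos gamma))/2
#' for the helix turn-per-residue delta, from which radius and pitch follow.
#'
#' `method = "bspline"` instead interpolates the CA atoms with a chord-length
#' parameterised cubic spline and evaluates the parameterisation-invariant
#' formulas kappa = |r' x r''| / |r'|^3, tau = (r' x r'').r''' / |r' x r''|^2
#' from the analytic spline derivatives. With real CA spacing this carries
#' tens of percent of interpolation bias and is provided for comparison only.
#'
#' The chain is split into maximal contiguous segments (author numbering and
#' CA-CA distance); a segment contributes only with >= 5 CA atoms, and the
#' first and last two residues of every segment - including the frayed ends
#' around unmodelled stretches - are masked. Locally collinear residues get
#' kappa ~ 0 and a masked tau (torsion is undefined on a straight line).
#'
#' @param chain a `"chain"` object.
#' @param method `"helix"` (default) or `"bspline"`.
#' @param spacing_check break segments at chemically implausible CA-CA
#'   distances (outside 2.5..4.75 A). Disable only for abstract space-curve
#'   input whose sampling interval is not a peptide bond.
#' @return data.frame with one row per residue: `kappa`, `tau` (NA = masked).
#' @export
ca_curvature_torsion <- function(chain, method = c("helix", "bspline"),
                                 spacing_check = TRUE) {
  method <- match.arg(method)
  n <- length(chain$residues)
  kappa <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  ca <- .ca_matrix(chain)
  for (seg in .segments(chain, spacing_check = spacing_check)) {
    if (length(seg) < 5) next
    P <- ca[seg, , drop = FALSE]
    dup <- which(rowSums(abs(diff(P))) < 1e-9)
    if (length(dup)) {
      warning("degenerate repeated CA coordinates in chain ", chain$chain_id,
              "; residues masked", call. = FALSE)
      next
    }
    kt <- if (method == "helix") .kt_helix(P) else .kt_bspline(P)
    kappa[seg] <- kt$kappa
    tau[seg] <- kt$tau
  }
  data.frame(kappa = kappa, tau = tau)
}

# Osculating-helix estimator over a segment's CA points (k x 3).
.kt_helix <- function(P) {
  k <- nrow(P)
  kappa <- rep(NA_real_, k)
  tau <- rep(NA_real_, k)
  V <- diff(P)                       # chord vectors
  len <- sqrt(rowSums(V^2))
  nd <- k - 3                        # virtual dihedrals 1..(k-3)
  dih <- vapply(seq_len(nd), function(i)
    .dihedral(P[i, ], P[i + 1, ], P[i + 2, ], P[i + 3, ]), 0)
  for (i in 3:(k - 2)) {
    v1 <- V[i - 1, ]; v2 <- V[i, ]
    g <- sum(v1 * v2) / (len[i - 1] * len[i])
    g <- max(-1, min(1, g))
    ell <- (len[i - 1] + len[i]) / 2
    gam <- acos(g)
    if (gam < 1e-6) {                # locally collinear: kappa ~ 0, tau undefined
      kappa[i] <- 2 * sin(gam / 2) / ell
      next
    }
    ph1 <- dih[i - 2]; ph2 <- dih[i - 1]
    if (is.na(ph1) || is.na(ph2)) next
    phm <- atan2(sin(ph1) + sin(ph2), cos(ph1) + cos(ph2))  # circular mean
    Cp <- cos(abs(phm))
    x <- (Cp * (1 + g) - (1 - g)) / 2          # cos(delta), delta >= gamma
    x <- max(-1, min(g, x))
    delta <- acos(x)
    u2 <- max((g - x) / (1 - g), 0)
    b1 <- sqrt(u2) * 2 * sin(delta / 2) / delta     # rise/radian at a = 1
    chord1 <- sqrt(4 * sin(delta / 2)^2 + b1^2 * delta^2)
    a <- ell / chord1
    b <- b1 * a
    kappa[i] <- a / (a^2 + b^2)
    tau[i] <- sign(phm) * b / (a^2 + b^2)
  }
  list(kappa = kappa, tau = tau)
}

# Chord-length cubic-spline estimator (comparison method).
.kt_bspline <- function(P) {
  k <- nrow(P)
  kappa <- rep(NA_real_, k)
  tau <- rep(NA_real_, k)
  t <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  fx <- stats::splinefun(t, P[, 1], method = "fmm")
  fy <- stats::splinefun(t, P[, 2], method = "fmm")
  fz <- stats::splinefun(t, P[, 3], method = "fmm")
  h <- max(t) * 1e-7
  for (i in 3:(k - 2)) {
    r1 <- c(fx(t[i], 1), fy(t[i], 1), fz(t[i], 1))
    r2 <- c(fx(t[i], 2), fy(t[i], 2), fz(t[i], 2))
    # third derivative jumps at the knots; average the one-sided limits
    r3l <- c(fx(t[i] - h, 3), fy(t[i] - h, 3), fz(t[i] - h, 3))
    r3r <- c(fx(t[i] + h, 3), fy(t[i] + h, 3), fz(t[i] + h, 3))
    r3 <- (r3l + r3r) / 2
    cr <- .cross3(r1, r2)
    ncr <- .norm3(cr)
    kappa[i] <- ncr / .norm3(r1)^3
    if (ncr >= 1e-8 * sum(r1 * r1)) tau[i] <- sum(cr * r3) / ncr^2
  }
  list(kappa = kappa, tau = tau)
}

#' Backbone phi/psi dihedrals of a chain
#'
#' Standard IUPAC phi (C-, N, CA, C) and psi (N, CA, C, N+) in degrees in
#' (-180, 180]. A dihedral is masked (NA) when any defining atom is absent or
#' the flanking residues are not consecutive in author numbering (an
#' unmodelled stretch breaks both dihedrals spanning it). The first residue
#' of each segment has no phi, the last no psi.
#'
#' @param chain a `"chain"` object.
#' @return data.frame with per-residue `phi`, `psi` (degrees).
#' @export
phi_psi <- function(chain) {
  n <- length(chain$residues)
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (seg in .segments(chain, require_ca = FALSE)) {
    for (k in seq_along(seg)) {
      i <- seg[k]
      N <- .atom_xyz(chain, i, "N")
      CA <- .atom_xyz(chain, i, "CA")
      C <- .atom_xyz(chain, i, "C")
      if (is.null(N) || is.null(CA) || is.null(C)) next
      if (k > 1) {
        Cm <- .atom_xyz(chain, seg[k - 1], "C")
        if (!is.null(Cm)) {
          d <- .dihedral(Cm, N, CA, C)
          if (!is.na(d)) phi[i] <- .wrap180(d * 180 / pi)
        }
      }
      if (k < length(seg)) {
        Np <- .atom_xyz(chain, seg[k + 1], "N")
        if (!is.null(Np)) {
          d <- .dihedral(N, CA, C, Np)
          if (!is.na(d)) psi[i] <- .wrap180(d * 180 / pi)
        }
      }
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Backbone geometry matrices for an ensemble
#'
#' Computes kappa, tau, phi and psi for every chain and scatters them into
#' masked descriptor matrices over the alignment.
#'
#' @param ensemble an `"ensemble"`.
#' @param method passed to [ca_curvature_torsion()].
#' @return list with `"descriptor_matrix"` elements `kappa`, `tau` (1/A) and
#'   `phi`, `psi` (degrees).
#' @export
backbone_geometry <- function(ensemble, method = c("helix", "bspline")) {
  method <- match.arg(method)
  per_k <- list(); per_t <- list(); per_f <- list(); per_s <- list()
  for (cid in names(ensemble$chains)) {
    ch <- ensemble$chains[[cid]]
    kt <- ca_curvature_torsion(ch, method = method)
    fp <- phi_psi(ch)
    per_k[[cid]] <- kt$kappa
    per_t[[cid]] <- kt$tau
    per_f[[cid]] <- fp$phi
    per_s[[cid]] <- fp$psi
  }
  list(kappa = .dm_from_per_residue(ensemble, "kappa", "1/Angstrom", per_k),
       tau = .dm_from_per_residue(ensemble, "tau", "1/Angstrom", per_t),
       phi = .dm_from_per_residue(ensemble, "phi", "degrees", per_f),
       psi = .dm_from_per_residue(ensemble, "psi", "degrees", per_s))
}

# ---- Ramachandran regions --------------------------------------------------

#' Load a Ramachandran region definition
#'
#' Regions are polygons in (phi, psi) space read from a CSV with columns
#' `label`, `piece`, `phi`, `psi` (vertices in order; a label may have
#' several pieces where it crosses the +-180 degree seam). Points are
#' classified by the first matching label in file order; anything unmatched
#' is `"outlier"`, so the region set always tiles the torus without overlap.
#' The shipped default delineates core-alpha, core-beta, core-L (left-handed
#' helix) and a generous allowed band. The file is deliberately editable:
#' region conventions differ between validation schools.
#'
#' @param path CSV path; default = the file shipped with the package.
#' @return data.frame of polygon vertices (class `"rama_regions"`).
#' @export
load_rama_regions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rama_regions.csv", package = "ensflex")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "piece", "phi", "psi") %in% names(df)))
  class(df) <- c("rama_regions", "data.frame")
  df
}

#' Classify (phi, psi) pairs into Ramachandran regions
#'
#' @param phi,psi numeric vectors, degrees (any value; reduced mod 360).
#' @param regions region polygons from [load_rama_regions()].
#' @return character vector of labels (`"outlier"` if no polygon matches).
#' @export
ramachandran_region <- function(phi, psi, regions = load_rama_regions()) {
  phi <- .wrap180(phi)
  psi <- .wrap180(psi)
  out <- rep("outlier", length(phi))
  done <- rep(FALSE, length(phi))
  for (lab in unique(regions$label)) {
    sub <- regions[regions$label == lab, ]
    for (pc in unique(sub$piece)) {
      poly <- sub[sub$piece == pc, ]
      idx <- which(!done & !is.na(phi) & !is.na(psi))
      if (!length(idx)) next
      inp <- pracma::inpolygon(phi[idx], psi[idx], poly$phi, poly$psi,
                               boundary = TRUE)
      out[idx[inp]] <- lab
      done[idx[inp]] <- TRUE
    }
  }
  out[is.na(phi) | is.na(psi)] <- NA_character_
  out
}

# ---- Standardisation -------------------------------------------------------

#' Standardise a descriptor matrix over the whole ensemble
#'
#' z = (x - mean) / sd over all unmasked cells of the matrix (sample sd,
#' n-1 denominator), clipped to +-`cap_sd`. Capping keeps the Pearson-based
#' chain comparisons from being driven by single outlier residues.
#'
#' @param x a `"descriptor_matrix"`.
#' @param cap_sd cap in z-units (default 3).
#' @return a `"standardised_matrix"`: the capped z-value matrix plus
#'   `center`, `scale`, `cap` attributes (itself a valid descriptor matrix).
#' @export
standardise <- function(x, cap_sd = 3) {
  v <- x$values
  obs <- v[!is.na(v)]
  if (length(obs) < 2) stop("standardise needs >= 2 unmasked cells")
  ctr <- mean(obs)
  scl <- stats::sd(obs)
  if (scl == 0) {
    warning("constant matrix '", x$name, "': all z-scores set to 0",
            call. = FALSE)
    z <- v
    z[!is.na(z)] <- 0
    scl <- 1
  } else {
    z <- (v - ctr) / scl
    z[z > cap_sd] <- cap_sd
    z[z < -cap_sd] <- -cap_sd
  }
  structure(list(name = paste0(x$name, "_z"), values = z, units = "z",
                 center = ctr, scale = scl, cap = cap_sd),
            class = c("standardised_matrix", "descriptor_matrix"))
}
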