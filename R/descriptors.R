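# Per-residue structural descriptors computed directly from atomic
# coordinates: solvent accessibility (Shrake-Rupley quadrature),
# secondary structure (Kabsch-Sander hydrogen-bond patterns), backbone
# torsions, half-sphere exposure, depth (DPX) and protrusion (CX)
# indices, geometric hydrogen-bond counts, mean B-factor and local
# packing density.

# van der Waals radii by element (Angstrom); unknown elements fall back
# to the carbon radius with a warning.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.70

# theoretical maximum all-atom ASA of residue X in an extended tripeptide
# (Tien et al. 2013 style), used to express accessibility in percent
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, E = 223,
             Q = 225, G = 104, H = 224, I = 197, L = 201, K = 236,
             M = 224, F = 240, P = 159, S = 155, T = 172, W = 285,
             Y = 263, V = 174)

vdw_radius <- function(element) {
  r <- unname(VDW_RADII[element])
  if (anyNA(r)) {
    warning("unknown element(s) ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using default vdW radius ", VDW_DEFAULT)
    r[is.na(r)] <- VDW_DEFAULT
  }
  r
}

pairwise_dist <- function(p, q = p) {
  d2 <- outer(rowSums(p^2), rowSums(q^2), `+`) - 2 * p %*% t(q)
  sqrt(pmax(d2, 0))
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley numerical quadrature: each atom's sphere of radius
#' (vdW + probe) is sampled with a deterministic golden-section point set
#' and a point counts as accessible when it lies outside every other
#' atom's probe-expanded sphere.
#'
#' @param structure a `pdb_structure`.
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points quadrature points per atom.
#' @return numeric vector of per-atom areas (Angstrom^2), aligned with
#'   `structure$atoms`.
#' @export
compute_sasa <- function(structure, probe = 1.4, n_points = 960) {
  xyz <- atom_xyz(structure)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  n <- nrow(xyz)
  radii <- vdw_radius(structure$atoms$element)
  pts <- sphere_points(n_points)
  d <- pairwise_dist(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    nb <- which(d[i, ] < ri + radii + probe & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * ri^2
      next
    }
    sp <- sweep(pts * ri, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      rj <- radii[j] + probe
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 >= rj^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  out
}

#' Five-category residue solvent accessibility
#'
#' Aggregates per-atom areas into all-atom, main-chain, side-chain,
#' non-polar side-chain and polar side-chain absolute accessibility, plus
#' the corresponding relative values in percent of the residue type's
#' extended-state reference area.  Following the reference-tool
#' convention, glycine's CA is counted as side chain.  Non-polar side
#' chain = C/S atoms, polar = N/O atoms.
#'
#' @param structure a `pdb_structure`.
#' @param atom_sasa per-atom areas from [compute_sasa()].
#' @return data frame with one row per residue: `resi`, `sasa_all`,
#'   `sasa_main`, `sasa_side`, `sasa_nonpolar`, `sasa_polar` (Angstrom^2)
#'   and `rel_all`, `rel_main`, `rel_side`, `rel_nonpolar`, `rel_polar`
#'   (percent; `NA` for residue types without a reference value).
#' @export
residue_accessibility <- function(structure, atom_sasa) {
  at <- structure$atoms
  stopifnot(length(atom_sasa) == nrow(at))
  main_names <- c("N", "CA", "C", "O", "OXT")
  is_main <- at$name %in% main_names & !(at$aa == "G" & at$name == "CA")
  is_side <- !is_main
  is_np <- is_side & at$element %in% c("C", "S")
  is_pol <- is_side & at$element %in% c("N", "O")
  agg <- function(mask) {
    v <- tapply(atom_sasa * mask, at$resi, sum)
    as.numeric(v[as.character(structure$residues$resi)])
  }
  res <- structure$residues
  out <- data.frame(
    resi = res$resi,
    sasa_all = agg(TRUE),
    sasa_main = agg(is_main),
    sasa_side = agg(is_side),
    sasa_nonpolar = agg(is_np),
    sasa_polar = agg(is_pol))
  ref <- unname(MAX_ASA[res$aa])
  for (cat in c("all", "main", "side", "nonpolar", "polar")) {
    out[[paste0("rel_", cat)]] <- 100 * out[[paste0("sasa_", cat)]] / ref
  }
  out
}

# --- backbone continuity and imputed amide hydrogens --------------------

backbone_coords <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  get <- function(name) {
    m <- matrix(NA_real_, n, 3)
    a <- structure$atoms
    hit <- a$name == name
    m[match(a$resi[hit], res$resi), ] <-
      cbind(a$x[hit], a$y[hit], a$z[hit])
    m
  }
  list(N = get("N"), CA = get("CA"), C = get("C"), O = get("O"),
       CB = get("CB"))
}

# continuity[i] is TRUE when residue i is peptide-bonded to residue i+1
chain_continuity <- function(bb, max_cn = 2.5) {
  n <- nrow(bb$N)
  if (n < 2) return(logical(0))
  d <- sqrt(rowSums((bb$C[-n, , drop = FALSE] -
                     bb$N[-1, , drop = FALSE])^2))
  !is.na(d) & d < max_cn
}

# DSSP-style imputed amide H: 1.0 A from N opposite the previous carbonyl
imputed_amide_h <- function(bb, cont, aa) {
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (!cont[i - 1] || aa[i] == "P") next
    d <- bb$C[i - 1, ] - bb$O[i - 1, ]
    if (anyNA(d) || anyNA(bb$N[i, ])) next
    H[i, ] <- bb$N[i, ] + unitv(d)
  }
  H
}

# Kabsch-Sander electrostatic H-bond energy matrix: hb[i, j] is TRUE when
# the carbonyl of residue i accepts a hydrogen bond from the amide of j
ks_hbond_matrix <- function(bb, cont, aa, cutoff = -0.5) {
  n <- nrow(bb$N)
  H <- imputed_amide_h(bb, cont, aa)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (anyNA(bb$C[i, ]) || anyNA(bb$O[i, ])) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || anyNA(H[j, ]) || anyNA(bb$N[j, ])) next
      r_on <- vnorm(bb$O[i, ] - bb$N[j, ])
      r_ch <- vnorm(bb$C[i, ] - H[j, ])
      r_oh <- vnorm(bb$O[i, ] - H[j, ])
      r_cn <- vnorm(bb$C[i, ] - bb$N[j, ])
      if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
        e <- -9.9  # clashing contact, treated as bonded (DSSP convention)
      } else {
        e <- 0.084 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn) * 332
      }
      hb[i, j] <- e < cutoff
    }
  }
  hb
}

#' Secondary-structure assignment from backbone hydrogen bonds
#'
#' Kabsch-Sander style assignment: amide hydrogens are imputed from the
#' preceding carbonyl, hydrogen bonds are scored with the electrostatic
#' energy E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) * 332 kcal/mol and
#' accepted below -0.5, and helices (H/G/I), beta bridges and ladders
#' (E/B), turns (T) and bends (S) are derived from the bond pattern.
#' The three-class reduction maps H,G,I to H; E,B to E; the rest to L
#' (coil).
#'
#' @param structure a `pdb_structure`.
#' @return data frame with per-residue `resi`, `ss8` and `ss3`.
#' @export
assign_secondary_structure <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  ss8 <- rep("-", n)
  if (n >= 3) {
    bb <- backbone_coords(structure)
    cont <- chain_continuity(bb)
    ok <- !apply(is.na(bb$N) | is.na(bb$CA) | is.na(bb$C) | is.na(bb$O),
                 1, any)
    hb <- ks_hbond_matrix(bb, cont, res$aa)

    turn <- list()
    for (k in c(3, 4, 5)) {
      t_k <- rep(FALSE, n)
      for (i in seq_len(n - k)) t_k[i] <- hb[i, i + k]
      turn[[as.character(k)]] <- t_k
    }
    mark <- function(ss8, t_k, k, code) {
      for (i in 2:max(1, n - k)) {
        if (t_k[i - 1] && t_k[i]) {
          span <- i:(i + k - 1)
          free <- ss8[span] %in% c("-", "T", "S")
          ss8[span[free]] <- code
        }
      }
      ss8
    }
    ss8 <- mark(ss8, turn[["4"]], 4, "H")

    # beta bridges (parallel and antiparallel patterns)
    bridge <- rep(FALSE, n)
    partner <- vector("list", n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) <= 2) next
        par <- (hb[i - 1, j] && hb[j, i + 1]) ||
               (hb[j - 1, i] && hb[i, j + 1])
        anti <- (hb[i, j] && hb[j, i]) ||
                (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (par || anti) {
          bridge[i] <- TRUE
          partner[[i]] <- c(partner[[i]], j)
        }
      }
    }
    for (i in which(bridge)) {
      if (ss8[i] == "H") next
      ladder <- any(vapply(partner[[i]], function(j) {
        (i > 1 && bridge[i - 1] &&
           any(abs(unlist(partner[[i - 1]]) - j) == 1)) ||
        (i < n && bridge[i + 1] &&
           any(abs(unlist(partner[[i + 1]]) - j) == 1))
      }, logical(1)))
      ss8[i] <- if (ladder) "E" else "B"
    }
    ss8 <- mark(ss8, turn[["3"]], 3, "G")
    ss8 <- mark(ss8, turn[["5"]], 5, "I")

    # turns and bends on whatever is still unassigned
    for (k in c(3, 4, 5)) {
      for (i in which(turn[[as.character(k)]])) {
        span <- (i + 1):(i + k - 1)
        span <- span[span <= n & ss8[span] == "-"]
        ss8[span] <- "T"
      }
    }
    for (i in 3:(n - 2)) {
      if (ss8[i] != "-" || !ok[i] || !ok[i - 2] || !ok[i + 2]) next
      u <- bb$CA[i, ] - bb$CA[i - 2, ]
      v <- bb$CA[i + 2, ] - bb$CA[i, ]
      kappa <- acos(max(-1, min(1, sum(unitv(u) * unitv(v))))) * 180 / pi
      if (kappa > 70) ss8[i] <- "S"
    }
    ss8[!ok] <- "-"
  }
  ss3 <- ifelse(ss8 %in% c("H", "G", "I"), "H",
                ifelse(ss8 %in% c("E", "B"), "E", "L"))
  data.frame(resi = res$resi, ss8 = ss8, ss3 = ss3,
             stringsAsFactors = FALSE)
}

#' Backbone phi/psi torsion angles
#'
#' Standard IUPAC dihedrals in degrees; angles across a chain break
#' (C-N distance >= 2.5 A) and at chain termini are `NA`.
#'
#' @param structure a `pdb_structure`.
#' @return data frame with per-residue `resi`, `phi`, `psi`.
#' @export
backbone_torsions <- function(structure) {
  res <- structure$residues
  n <- nrow(res)
  bb <- backbone_coords(structure)
  cont <- chain_continuity(bb)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && isTRUE(cont[i - 1]) &&
        !anyNA(c(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ]))) {
      phi[i] <- dihedral_angle(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ],
                               bb$C[i, ])
    }
    if (i < n && isTRUE(cont[i]) &&
        !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ]))) {
      psi[i] <- dihedral_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ],
                               bb$N[i + 1, ])
    }
  }
  data.frame(resi = res$resi, phi = phi, psi = psi)
}

#' Half-sphere exposure and contact number
#'
#' Counts CA neighbours within `radius` of each residue's CA (the contact
#' number CN) and splits them into upper/lower half-spheres along two
#' directions: the pseudo-CB direction built from the flanking CA atoms
#' (HSE-A: `hseau`/`hsead`) and the real or reconstructed CA-CB direction
#' (HSE-B: `hsebu`/`hsebd`).  A neighbour is "upper" when its direction
#' from the CA has a strictly positive dot product with the axis; ties
#' count as lower.  The residue itself is excluded, and
#' `hseau + hsead == cn` holds exactly.
#'
#' @param structure a `pdb_structure`.
#' @param radius sphere radius in Angstrom.
#' @return data frame with `resi`, `cn`, `hseau`, `hsead`, `hsebu`,
#'   `hsebd`.
#' @export
half_sphere_exposure <- function(structure, radius = 13.0) {
  res <- structure$residues
  n <- nrow(res)
  bb <- backbone_coords(structure)
  out <- data.frame(resi = res$resi, cn = 0L, hseau = 0L, hsead = 0L,
                    hsebu = 0L, hsebd = 0L)
  if (n == 0) return(out)
  ca_ok <- !apply(is.na(bb$CA), 1, any)
  for (i in seq_len(n)) {
    if (!ca_ok[i]) next
    # HSE-B axis: real CB, else tetrahedral reconstruction from backbone
    cb <- bb$CB[i, ]
    if (anyNA(cb) && !anyNA(c(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))) {
      cb <- virtual_cbeta(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
    dir_b <- if (!anyNA(cb)) cb - bb$CA[i, ] else c(0, 0, 1)
    # HSE-A axis: away from the two flanking CA atoms
    dir_a <- NULL
    if (i > 1 && i < n && ca_ok[i - 1] && ca_ok[i + 1]) {
      dir_a <- 2 * bb$CA[i, ] - bb$CA[i - 1, ] - bb$CA[i + 1, ]
    }
    if (is.null(dir_a) || vnorm(dir_a) < 1e-8) dir_a <- dir_b
    for (j in seq_len(n)) {
      if (j == i || !ca_ok[j]) next
      v <- bb$CA[j, ] - bb$CA[i, ]
      if (vnorm(v) > radius) next
      out$cn[i] <- out$cn[i] + 1L
      if (sum(v * dir_a) > 0) out$hseau[i] <- out$hseau[i] + 1L
      else out$hsead[i] <- out$hsead[i] + 1L
      if (sum(v * dir_b) > 0) out$hsebu[i] <- out$hsebu[i] + 1L
      else out$hsebd[i] <- out$hsebd[i] + 1L
    }
  }
  out
}

#' Atom depth index (DPX)
#'
#' Distance from each buried atom to the nearest solvent-accessible atom;
#' accessible atoms (SASA above `sasa_threshold`) have depth 0.
#'
#' @param structure a `pdb_structure`.
#' @param atom_sasa per-atom areas from [compute_sasa()].
#' @param sasa_threshold accessibility cutoff in Angstrom^2.
#' @return list with `atom` (per-atom depth, Angstrom) and `residue`
#'   (data frame `resi`, `dpx` with the per-residue mean).
#' @export
depth_index <- function(structure, atom_sasa, sasa_threshold = 0.0) {
  exposed <- atom_sasa > sasa_threshold
  if (!any(exposed)) stop("no solvent-accessible atoms in structure")
  xyz <- atom_xyz(structure)
  dpx <- numeric(nrow(xyz))
  if (any(!exposed)) {
    d <- pairwise_dist(xyz[!exposed, , drop = FALSE],
                       xyz[exposed, , drop = FALSE])
    dpx[!exposed] <- apply(d, 1, min)
  }
  resid <- structure$atoms$resi
  per_res <- tapply(dpx, resid, mean)
  list(atom = dpx,
       residue = data.frame(
         resi = structure$residues$resi,
         dpx = as.numeric(per_res[as.character(structure$residues$resi)])))
}

#' Atom protrusion index (CX)
#'
#' Ratio of empty to occupied volume inside a sphere of `sphere_radius`
#' centred on each atom, with occupied volume estimated as the number of
#' heavy atoms inside the sphere (including the centre atom) times
#' `mean_atom_volume`, clamped to the sphere volume.
#'
#' @param structure a `pdb_structure`.
#' @param sphere_radius sphere radius in Angstrom.
#' @param mean_atom_volume mean heavy-atom volume in Angstrom^3.
#' @return list with `atom` (per-atom cx) and `residue` (data frame
#'   `resi`, `cx` with the per-residue mean).
#' @export
protrusion_index <- function(structure, sphere_radius = 10.0,
                             mean_atom_volume = 20.1) {
  stopifnot(sphere_radius > 0)
  xyz <- atom_xyz(structure)
  d <- pairwise_dist(xyz)
  v_sphere <- 4 / 3 * pi * sphere_radius^3
  n_in <- rowSums(d <= sphere_radius)   # includes self (distance 0)
  v_int <- pmin(n_in * mean_atom_volume, v_sphere)
  cx <- (v_sphere - v_int) / v_int
  resid <- structure$atoms$resi
  per_res <- tapply(cx, resid, mean)
  list(atom = cx,
       residue = data.frame(
         resi = structure$residues$resi,
         cx = as.numeric(per_res[as.character(structure$residues$resi)])))
}

HB_DONOR_NAMES <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2",
                    "NZ", "OG", "OG1", "OH", "SG")
HB_ACCEPTOR_NAMES <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2", "OG",
                       "OG1", "OH", "ND1", "NE2", "SD")

#' Geometric hydrogen-bond counts per residue
#'
#' A bond is counted when a donor-acceptor pair is closer than 3.9 A and,
#' where a hydrogen position can be imputed (backbone amides), the
#' D-H...A angle exceeds 90 degrees.  Donor/acceptor atoms are taken from
#' fixed backbone and side-chain name tables; pairs within the same
#' residue, and backbone-backbone pairs of sequence separation < 2, are
#' excluded.  Each bond increments the count of both participating
#' residues.
#'
#' @param structure a `pdb_structure`.
#' @return data frame with `resi`, `hbonds`.
#' @export
hydrogen_bond_counts <- function(structure) {
  at <- structure$atoms
  res <- structure$residues
  bb <- backbone_coords(structure)
  cont <- chain_continuity(bb)
  H <- imputed_amide_h(bb, cont, res$aa)
  don <- which(at$name %in% HB_DONOR_NAMES)
  acc <- which(at$name %in% HB_ACCEPTOR_NAMES)
  counts <- integer(nrow(res))
  dense <- match(at$resi, res$resi)
  for (di in don) {
    for (ai in acc) {
      ri <- dense[di]; rj <- dense[ai]
      if (ri == rj) next
      backbone_pair <- at$name[di] == "N" &&
        at$name[ai] %in% c("O", "OXT")
      if (backbone_pair && abs(ri - rj) < 2) next
      dvec <- c(at$x[ai] - at$x[di], at$y[ai] - at$y[di],
                at$z[ai] - at$z[di])
      dda <- vnorm(dvec)
      if (dda >= 3.9 || dda < 1.5) next
      if (at$name[di] == "N" && !anyNA(H[ri, ])) {
        d <- c(at$x[di], at$y[di], at$z[di])
        a <- c(at$x[ai], at$y[ai], at$z[ai])
        ang <- bond_angle(d, H[ri, ], a)
        if (ang <= 90) next
      }
      counts[ri] <- counts[ri] + 1L
      counts[rj] <- counts[rj] + 1L
    }
  }
  data.frame(resi = res$resi, hbonds = counts)
}

#' Mean B-factor and packing density per residue
#'
#' Packing is the heavy-atom count within `packing_radius` of the residue
#' centroid (own atoms included) divided by the sphere volume.
#'
#' @param structure a `pdb_structure`.
#' @param packing_radius sphere radius in Angstrom.
#' @return data frame with `resi`, `bfactor_mean` (Angstrom^2, `NA` when
#'   no B-factors are present) and `packing` (atoms / Angstrom^3).
#' @export
bfactor_and_packing <- function(structure, packing_radius = 8.0) {
  at <- structure$atoms
  res <- structure$residues
  xyz <- atom_xyz(structure)
  bmean <- tapply(at$bfactor, at$resi, function(b) {
    b <- b[!is.na(b)]
    if (length(b)) mean(b) else NA_real_
  })
  v_sphere <- 4 / 3 * pi * packing_radius^3
  cen <- cbind(tapply(at$x, at$resi, mean), tapply(at$y, at$resi, mean),
               tapply(at$z, at$resi, mean))
  d <- pairwise_dist(cen, xyz)
  packing <- rowSums(d <= packing_radius) / v_sphere
  key <- as.character(res$resi)
  data.frame(resi = res$resi,
             bfactor_mean = as.numeric(bmean[key]),
             packing = as.numeric(packing[match(key, rownames(cen))]))
}

# the full default structural feature set, in the order used throughout
STRUCT_FEATURES <- c("cx", "dpx", "sasa_all", "sasa_main", "sasa_side",
                     "sasa_nonpolar", "sasa_polar", "rel_all", "rel_main",
                     "rel_side", "rel_nonpolar", "rel_polar", "packing",
                     "ss3_H", "ss3_E", "ss3_L", "phi", "psi", "hbonds",
                     "cn", "hseau", "hsead", "hsebu", "hsebd",
                     "bfactor_mean")

# descriptor families derived from the hydrogen-bond / secondary-structure
# machinery only (the "smooth DSSP" feature arm)
DSSP_FEATURES <- c("ss3_H", "ss3_E", "ss3_L", "phi", "psi", "hbonds")

#' All per-residue descriptors for one chain
#'
#' Runs every descriptor computation and assembles a single per-residue
#' table; the three-class secondary structure additionally enters as
#' three 0/1 indicator columns (`ss3_H`, `ss3_E`, `ss3_L`) so that it can
#' be smoothed as a numeric profile.
#'
#' @param structure a `pdb_structure`.
#' @param probe,n_points passed to [compute_sasa()].
#' @return data frame with one row per residue and columns `resi`, `aa`,
#'   `ss8`, `ss3` plus all numeric descriptors in `STRUCT_FEATURES`.
#' @export
#' @examples
#' s <- build_backbone(list(c("helix", 12), c("coil", 6)), seed = 2)
#' d <- residue_descriptors(s)
#' head(d[, c("resi", "aa", "ss3", "rel_all", "cn")])
residue_descriptors <- function(structure, probe = 1.4, n_points = 960) {
  sasa <- compute_sasa(structure, probe = probe, n_points = n_points)
  acc <- residue_accessibility(structure, sasa)
  ss <- assign_secondary_structure(structure)
  tor <- backbone_torsions(structure)
  hse <- half_sphere_exposure(structure)
  dpx <- depth_index(structure, sasa)$residue
  cx <- protrusion_index(structure)$residue
  hb <- hydrogen_bond_counts(structure)
  bp <- bfactor_and_packing(structure)
  out <- data.frame(resi = structure$residues$resi,
                    aa = structure$residues$aa,
                    ss8 = ss$ss8, ss3 = ss$ss3,
                    stringsAsFactors = FALSE)
  out$ss3_H <- as.numeric(ss$ss3 == "H")
  out$ss3_E <- as.numeric(ss$ss3 == "E")
  out$ss3_L <- as.numeric(ss$ss3 == "L")
  for (tbl in list(acc, tor, hse, dpx, cx, hb, bp)) {
    out <- merge(out, tbl, by = "resi", sort = FALSE)
  }
  out[order(out$resi), , drop = FALSE]
}
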