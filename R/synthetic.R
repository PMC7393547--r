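# Synthetic fixtures: toy protein structures with controlled backbone
# geometry and cleavage annotation tables with planted sequence and/or
# structural signal.  Everything is seed-deterministic so fixtures can be
# regenerated byte-identically instead of being stored.
#
# Backbones are grown residue-by-residue from ideal internal coordinates
# (bond lengths/angles below, omega fixed at 180 degrees); only N, CA, C, O
# and CB atoms are built.  Side chains beyond CB are deliberately absent:
# descriptors that touch side-chain atoms degrade gracefully to CB-level
# approximations on fixtures, which keeps fixture-derived golden values
# stable.

IDEAL_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.5,
  omega = 180)

SEGMENT_TORSIONS <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -119, psi = 113))

# coil torsions are drawn uniformly from this (extended/PPII-like) region
COIL_PHI_RANGE <- c(-150, -60)
COIL_PSI_RANGE <- c(60, 170)

#' Build a backbone structure from secondary-structure segments
#'
#' Places backbone N, CA, C, O (and CB by tetrahedral reconstruction,
#' except glycine) atoms from ideal internal coordinates.  Helix segments
#' use (phi, psi) = (-57, -47), strand segments (-119, +113); coil torsions
#' are drawn per residue from a fixed extended-region window.  B-factors
#' are drawn per segment from `bfactor_model`: helix/strand residues from
#' the "core" component, coil residues from the "loop" component.
#'
#' @param segments list of segments, each a `c(type, length)` pair where
#'   type is `"helix"`, `"strand"` or `"coil"` and length a positive count.
#' @param sequence optional one-letter amino-acid string (length must match
#'   the total segment length); random when `NULL`.
#' @param seed integer seed controlling coil torsions, sequence and
#'   B-factors.
#' @param id structure identifier written to the header.
#' @param bfactor_model list with numeric `core = c(mean, sd)` and
#'   `loop = c(mean, sd)` components (Angstrom^2).
#' @return a `pdb_structure` (chain `"A"`, experiment `"X-RAY DIFFRACTION"`)
#'   with an extra `segment_types` element giving each residue's segment
#'   type.
#' @export
#' @examples
#' s <- build_backbone(list(c("helix", 10), c("coil", 5)), seed = 1)
#' s$segment_types
build_backbone <- function(segments, sequence = NULL, seed = 1,
                           id = "synth",
                           bfactor_model = list(core = c(15, 3),
                                                loop = c(40, 8))) {
  set.seed(seed)
  seg_type <- character(0)
  for (s in segments) {
    len <- as.integer(s[[2]])
    if (len <= 0) stop("zero-length segment")
    if (!s[[1]] %in% c("helix", "strand", "coil")) {
      stop("unknown segment type: ", s[[1]])
    }
    seg_type <- c(seg_type, rep(s[[1]], len))
  }
  n <- length(seg_type)
  if (is.null(sequence)) {
    sequence <- paste(sample(names(AA1TO3), n, replace = TRUE),
                      collapse = "")
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n) stop("sequence length != total segment length")

  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    if (seg_type[i] == "coil") {
      phi[i] <- stats::runif(1, COIL_PHI_RANGE[1], COIL_PHI_RANGE[2])
      psi[i] <- stats::runif(1, COIL_PSI_RANGE[1], COIL_PSI_RANGE[2])
    } else {
      t <- SEGMENT_TORSIONS[[seg_type[i]]]
      phi[i] <- t["phi"]
      psi[i] <- t["psi"]
    }
  }
  bf <- numeric(n)
  core <- seg_type != "coil"
  bf[core] <- stats::rnorm(sum(core), bfactor_model$core[1],
                           bfactor_model$core[2])
  bf[!core] <- stats::rnorm(sum(!core), bfactor_model$loop[1],
                            bfactor_model$loop[2])
  bf <- pmax(bf, 1)

  g <- IDEAL_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    # carbonyl O trans to the next amide N about the CA-C bond
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] - 180)
    if (aa[i] != "G") {
      CB[i, ] <- virtual_cbeta(N[i, ], CA[i, ], C[i, ])
    }
  }
  assemble_structure(id, aa, seg_type, N, CA, C, O, CB, bf)
}

assemble_structure <- function(id, aa, seg_type, N, CA, C, O, CB, bf) {
  n <- length(aa)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    el <- c("N", "C", "C", "O")
    if (!anyNA(CB[i, ])) {
      nm <- c(nm, "CB")
      xyz <- rbind(xyz, CB[i, ])
      el <- c(el, "C")
    }
    rows[[i]] <- data.frame(
      serial = 0L, name = nm,
      resname = unname(AA1TO3[aa[i]]), aa = aa[i],
      resno = i, icode = "", resi = i,
      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
      z = round(xyz[, 3], 3),
      occupancy = 1, bfactor = round(bf[i], 2), element = el,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$serial <- seq_len(nrow(atoms))
  out <- list(id = id, chain = "A", experiment = "X-RAY DIFFRACTION",
              atoms = atoms,
              residues = data.frame(resi = seq_len(n), resno = seq_len(n),
                                    icode = "", aa = aa,
                                    stringsAsFactors = FALSE),
              segment_types = seg_type)
  class(out) <- "pdb_structure"
  out
}

#' Convenience wrapper around [build_backbone()]
#'
#' @inheritParams build_backbone
#' @param ... passed on to [build_backbone()].
#' @return a `pdb_structure`.
#' @export
synthetic_structure <- function(segments, seed = 1, ...) {
  build_backbone(segments, seed = seed, ...)
}

#' Two antiparallel beta strands as one structure
#'
#' Builds one extended strand from ideal torsions, then places a second,
#' two-fold-rotated copy next to it, tuning the inter-strand offset by a
#' small grid search so that backbone hydrogen bonds form between the
#' strands.  The two strands are separated in sequence by a spatial jump
#' (a chain break by the backbone-continuity criterion), mimicking a
#' beta-hairpin without modelling the turn.
#'
#' @param n_per_strand residues per strand.
#' @param seed passed to the strand builder.
#' @return a `pdb_structure` with `2 * n_per_strand` residues.
#' @export
build_sheet_pair <- function(n_per_strand = 6, seed = 1) {
  a <- build_backbone(list(c("strand", n_per_strand)), seed = seed,
                      id = "sheet")
  xyz <- atom_xyz(a)
  # strand axis ~ first-to-last CA direction
  ca <- xyz[a$atoms$name == "CA", , drop = FALSE]
  axis <- unitv(ca[nrow(ca), ] - ca[1, ])
  ctr <- colMeans(ca)
  # perpendicular direction in which to offset the partner strand
  perp <- unitv(cross3(axis, c(0, 0, 1)))
  if (vnorm(cross3(axis, c(0, 0, 1))) < 1e-3) {
    perp <- unitv(cross3(axis, c(0, 1, 0)))
  }
  rot180 <- function(p, axis_dir, center) {
    # 180-degree rotation about the line through `center` along `axis_dir`
    v <- sweep(p, 2, center)
    proj <- outer(drop(v %*% axis_dir), axis_dir)
    sweep(2 * proj - v, 2, center, `+`)
  }
  # strand A backbone pieces, and its imputed amide hydrogens
  bbA <- backbone_coords(a)
  contA <- chain_continuity(bbA)
  HA <- imputed_amide_h(bbA, contA, a$residues$aa)
  pair_energy <- function(Ci, Oi, Nj, Hj) {
    if (anyNA(Hj)) return(0)
    r_on <- vnorm(Oi - Nj); r_ch <- vnorm(Ci - Hj)
    r_oh <- vnorm(Oi - Hj); r_cn <- vnorm(Ci - Nj)
    if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-9.9)
    0.084 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn) * 332
  }
  # count antiparallel bridge pairs (mutual CO...HN bonds) between the
  # original strand and a rigidly transformed copy
  score_pairing <- function(transform) {
    Nb <- transform(bbA$N); Cb <- transform(bbA$C)
    Ob <- transform(bbA$O); Hb <- transform(HA)
    n <- n_per_strand
    bridges <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        e1 <- pair_energy(bbA$C[i, ], bbA$O[i, ], Nb[j, ], Hb[j, ])
        e2 <- pair_energy(Cb[j, ], Ob[j, ], bbA$N[i, ], HA[i, ])
        if (e1 < -0.5 && e2 < -0.5) bridges <- bridges + 1
      }
    }
    bridges
  }
  make_transform <- function(d, shift, flip) {
    ax <- if (flip) perp else axis
    function(p) {
      q <- rot180(p, ax, ctr)
      sweep(q, 2, d * perp + shift * axis, `+`)
    }
  }
  best <- list(score = -Inf, d = 4.8, shift = 0, flip = FALSE)
  for (flip in c(FALSE, TRUE)) {
    for (d in seq(3.8, 5.8, by = 0.1)) {
      for (shift in seq(-4, 4, by = 0.2)) {
        s <- score_pairing(make_transform(d, shift, flip))
        if (s > best$score) {
          best <- list(score = s, d = d, shift = shift, flip = flip)
        }
      }
    }
  }
  tr <- make_transform(best$d, best$shift, best$flip)
  b <- tr(xyz)
  atoms_b <- a$atoms
  atoms_b[, c("x", "y", "z")] <- round(b, 3)
  atoms_b$resno <- atoms_b$resno + n_per_strand
  atoms_b$resi <- atoms_b$resi + n_per_strand
  atoms <- rbind(a$atoms, atoms_b)
  atoms$serial <- seq_len(nrow(atoms))
  res <- data.frame(resi = seq_len(2 * n_per_strand),
                    resno = seq_len(2 * n_per_strand), icode = "",
                    aa = c(a$residues$aa, a$residues$aa),
                    stringsAsFactors = FALSE)
  out <- list(id = "sheetpair", chain = "A",
              experiment = "X-RAY DIFFRACTION", atoms = atoms,
              residues = res,
              segment_types = rep("strand", 2 * n_per_strand))
  class(out) <- "pdb_structure"
  out
}

#' Specification for a synthetic cleavage dataset
#'
#' @param n_substrates number of substrate structures to generate.
#' @param length residues per substrate (>= 20).
#' @param motif pattern planted at P4..P1 of positive sites (up to 8
#'   letters, `.` = wildcard); the default `"DEVD"` is a canonical
#'   caspase-style recognition sequence.
#' @param signal_mode `"sequence_only"` (motif signal only),
#'   `"structure_only"` (positives in coil/loop regions, no motif) or
#'   `"both"`.
#' @param loop_fraction approximate fraction of residues in coil segments.
#' @param seed integer master seed; all randomness derives from it.
#' @param bfactor_model per-segment B-factor distribution, see
#'   [build_backbone()].
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_substrates = 40, length = 40, motif = "DEVD",
                         signal_mode = c("both", "sequence_only",
                                         "structure_only"),
                         loop_fraction = 0.3, seed = 1,
                         bfactor_model = list(core = c(15, 3),
                                              loop = c(40, 8))) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(length >= 20, loop_fraction >= 0, loop_fraction <= 1)
  if (nchar(gsub("\\.", "", motif)) == 0 || nchar(motif) > 8) {
    stop("motif must be 1-8 letters")
  }
  structure(list(n_substrates = n_substrates, length = length,
                 motif = motif, signal_mode = signal_mode,
                 loop_fraction = loop_fraction, seed = seed,
                 bfactor_model = bfactor_model),
            class = "fixture_spec")
}

#' Generate a self-contained synthetic cleavage dataset
#'
#' Emits toy PDB structures, a substrate FASTA, a cleavage-annotation TSV
#' (columns `substrate_id`, `protease`, `p1_position`, `sequence`,
#' `pdb_id`, `chain`) and a JSON manifest recording the generator
#' parameters and ground truth.  One positive site is planted per
#' substrate: under `sequence_only`/`both` the motif occupies P4..P1;
#' under `structure_only`/`both` the site sits at the centre of a coil
#' segment.  Accidental off-site motif matches are mutated away under the
#' sequence modes so negatives violate the planted signal.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created); when `NULL` nothing is written
#'   and only the in-memory dataset is returned.
#' @return invisibly, a list with `structures` (named list of
#'   `pdb_structure`), `annotations` (data frame), `sequences` (named
#'   character), and `manifest` (list).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  L <- spec$length
  motif <- strsplit(spec$motif, "")[[1]]
  need_motif <- spec$signal_mode %in% c("sequence_only", "both")
  need_coil <- spec$signal_mode %in% c("structure_only", "both")

  structures <- list()
  seqs <- character(0)
  ann <- list()
  truth <- list()
  for (k in seq_len(spec$n_substrates)) {
    sid <- sprintf("sub%03d", k)
    lay <- sample_layout(L, spec$loop_fraction)
    # pick the P1 site: coil-segment centre if the structural signal is on,
    # else any interior position
    coil_centres <- lay$centres[lay$centre_type == "coil"]
    p1 <- if (need_coil) {
      coil_centres[sample.int(length(coil_centres), 1)]
    } else {
      cand <- seq(5, L - 5)
      cand[sample.int(length(cand), 1)]
    }
    aa <- sample(names(AA1TO3), L, replace = TRUE)
    if (need_motif) {
      idx <- (p1 - length(motif) + 1):p1  # motif right-aligned at P1
      keep <- motif != "."
      aa[idx[keep]] <- motif[keep]
      aa <- scrub_offsite_motif(aa, motif, p1)
    }
    seqstr <- paste(aa, collapse = "")
    st <- build_backbone(lay$segments, sequence = seqstr,
                         seed = (spec$seed %% 190000L) * 10000L + k,
                         id = sid,
                         bfactor_model = spec$bfactor_model)
    structures[[sid]] <- st
    seqs[sid] <- seqstr
    ann[[sid]] <- data.frame(substrate_id = sid, protease = "synthase-1",
                             p1_position = p1, sequence = seqstr,
                             pdb_id = sid, chain = "A",
                             stringsAsFactors = FALSE)
    truth[[sid]] <- list(p1 = p1, segments = lay$segments)
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL
  manifest <- list(generator = "crfcleave::generate_dataset",
                   n_substrates = spec$n_substrates, length = L,
                   motif = spec$motif, signal_mode = spec$signal_mode,
                   loop_fraction = spec$loop_fraction, seed = spec$seed,
                   truth = lapply(truth, function(t)
                     list(p1 = t$p1,
                          segments = lapply(t$segments, as.character))))
  out <- list(structures = structures, annotations = annotations,
              sequences = seqs, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "structures"), recursive = TRUE,
               showWarnings = FALSE)
    for (sid in names(structures)) {
      write_pdb(structures[[sid]],
                file.path(dir, "structures", paste0(sid, ".pdb")))
    }
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))),
               file.path(dir, "substrates.fasta"))
    utils::write.table(annotations, file.path(dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(out)
}

# strictly alternating helix/coil layout; coil lengths are scaled so the
# overall coil share is close to the requested loop_fraction
sample_layout <- function(L, loop_fraction) {
  f <- max(loop_fraction, 0.1)
  base <- 10 * f / (1 - min(f, 0.9))      # coil length matching helix ~10
  coil_lo <- max(4L, as.integer(round(0.8 * base)))
  coil_hi <- max(coil_lo + 1L, as.integer(round(1.2 * base)))
  segs <- list()
  centres <- integer(0)
  ctype <- character(0)
  pos <- 0
  type <- "helix"
  while (pos < L) {
    len <- if (type == "helix") {
      sample(8:12, 1)
    } else {
      sample(coil_lo:coil_hi, 1)
    }
    len <- min(len, L - pos)
    segs[[length(segs) + 1]] <- c(type, len)
    centre <- pos + ceiling(len / 2)
    if (centre >= 5 && centre <= L - 5) {
      centres <- c(centres, centre)
      ctype <- c(ctype, type)
    }
    pos <- pos + len
    type <- if (type == "helix") "coil" else "helix"
  }
  if (!any(ctype == "coil")) {
    # degenerate draw: convert the middle segment to coil
    mid <- ceiling(length(segs) / 2)
    segs[[mid]][1] <- "coil"
    start <- if (mid == 1) 0 else
      sum(vapply(segs[seq_len(mid - 1)],
                 function(s) as.integer(s[[2]]), integer(1)))
    centre <- min(max(start + ceiling(as.integer(segs[[mid]][[2]]) / 2), 5),
                  L - 5)
    centres <- c(centres, centre)
    ctype <- c(ctype, "coil")
  }
  list(segments = segs, centres = centres, centre_type = ctype)
}

# mutate accidental motif matches away from the planted site
scrub_offsite_motif <- function(aa, motif, p1) {
  m <- length(motif)
  planted_start <- p1 - m + 1
  keep <- motif != "."
  repeat {
    hit <- FALSE
    for (s in seq_len(length(aa) - m + 1)) {
      if (s == planted_start) next
      if (all(aa[s:(s + m - 1)][keep] == motif[keep])) {
        j <- s + which(keep)[1] - 1
        aa[j] <- sample(setdiff(names(AA1TO3), motif[keep]), 1)
        hit <- TRUE
      }
    }
    if (!hit) break
  }
  aa
}
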