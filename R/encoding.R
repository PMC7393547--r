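# Candidate-site windows (P4-P4') and their CRF observation attributes:
# one-hot sequence features, chemical-group features, and discretized
# (optionally smoothed) structural features.
#
# Window convention: P1 is the residue N-terminal to the scissile bond;
# the window covers chain positions p1-3 .. p1+4 (1-based), with
# out-of-chain positions padded with the gap symbol "-".

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# the eight chemical groups of the 20 amino acids
CHEM_GROUPS <- list(
  sulfur     = c("C", "M"),
  aliphatic1 = c("A", "G", "P"),
  aliphatic2 = c("I", "L", "V"),
  acidic     = c("D", "E"),
  basic      = c("H", "K", "R"),
  aromatic   = c("F", "W", "Y"),
  amide      = c("N", "Q"),
  hydroxy    = c("S", "T"))

CHEM_LOOKUP <- local({
  m <- character(0)
  for (g in names(CHEM_GROUPS)) m[CHEM_GROUPS[[g]]] <- g
  m
})

#' Chemical group of an amino acid
#'
#' The 20 amino acids partition into eight chemical groups:
#' sulfur-containing (C, M), aliphatic-1 (A, G, P), aliphatic-2 (I, L,
#' V), acidic (D, E), basic (H, K, R), aromatic (F, W, Y), amide (N, Q)
#' and small hydroxy (S, T).  Gap (`-`) and unknown (`X`) map to the gap
#' category.
#'
#' @param aa character vector of one-letter codes.
#' @return character vector of group names (`"gap"` for `-`/`X`).
#' @export
chemical_group <- function(aa) {
  out <- unname(CHEM_LOOKUP[aa])
  out[is.na(out)] <- "gap"
  out
}

#' Extract all candidate P4-P4' windows from a sequence
#'
#' Every position with a following residue is a candidate P1; windows are
#' padded with `-` where they run off the chain, and labelled positive
#' when the P1 position is in `positive_p1_positions`.
#'
#' @param sequence amino-acid string.
#' @param positive_p1_positions integer vector of 1-based P1 positions of
#'   annotated cleavage sites (may be empty).
#' @param substrate_id,chain_id provenance strings carried on each window.
#' @return data frame of class `site_windows`: one row per candidate with
#'   columns `substrate_id`, `chain_id`, `p1` (1-based), `window`
#'   (8-character string, cleavage between characters 4 and 5) and
#'   `label` (1 positive / 0 negative).
#' @export
#' @examples
#' w <- extract_windows("ACDEFGHIKLM", positive_p1_positions = 6)
#' w$window[w$p1 == 6]  # "DEFGHIKL"
extract_windows <- function(sequence, positive_p1_positions = integer(0),
                            substrate_id = "seq", chain_id = "A") {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  stopifnot(L >= 1)
  bad <- positive_p1_positions[positive_p1_positions < 1 |
                               positive_p1_positions >= L]
  if (length(bad)) {
    stop("P1 position(s) out of range (need 1 <= p1 < sequence length): ",
         paste(bad, collapse = ", "))
  }
  if (L < 2) {
    out <- data.frame(substrate_id = character(0), chain_id = character(0),
                      p1 = integer(0), window = character(0),
                      label = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("site_windows", class(out))
    return(out)
  }
  p1 <- seq_len(L - 1)
  win <- vapply(p1, function(p) {
    idx <- (p - 3):(p + 4)
    chars <- ifelse(idx >= 1 & idx <= L, aa[pmin(pmax(idx, 1), L)], "-")
    paste(chars, collapse = "")
  }, character(1))
  out <- data.frame(substrate_id = substrate_id, chain_id = chain_id,
                    p1 = p1, window = win,
                    label = as.integer(p1 %in% positive_p1_positions),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_windows", class(out))
  out
}

window_chars <- function(window) {
  ch <- strsplit(window, "")[[1]]
  stopifnot(length(ch) == 8)
  ch[!(ch %in% c(AA_ALPHABET, "-"))] <- "-"
  ch
}

#' One-hot sequence encoding of a window
#'
#' Each of the 8 positions contributes a 20-dimensional indicator block
#' (8 x 20 = 160 dimensions); gap or unknown positions contribute an
#' all-zero block.
#'
#' @param window 8-character window string.
#' @return numeric 0/1 vector of length 160.
#' @export
encode_sequence <- function(window) {
  ch <- strsplit(window, "")[[1]]
  stopifnot(length(ch) == 8)
  unknown <- !(ch %in% c(AA_ALPHABET, "-"))
  if (any(unknown)) {
    warning("unknown residue letter(s) treated as gap: ",
            paste(unique(ch[unknown]), collapse = ", "))
    ch[unknown] <- "-"
  }
  v <- numeric(8 * 20)
  for (i in 1:8) {
    k <- match(ch[i], AA_ALPHABET)
    if (!is.na(k)) v[(i - 1) * 20 + k] <- 1
  }
  v
}

#' One-hot chemical-group encoding of a window
#'
#' Each position contributes an 8-dimensional indicator over the chemical
#' groups (8 x 8 = 64 dimensions); gaps contribute zeros.
#'
#' @param window 8-character window string.
#' @return numeric 0/1 vector of length 64.
#' @export
encode_chemical <- function(window) {
  ch <- window_chars(window)
  groups <- chemical_group(ch)
  v <- numeric(8 * 8)
  for (i in 1:8) {
    k <- match(groups[i], names(CHEM_GROUPS))
    if (!is.na(k)) v[(i - 1) * 8 + k] <- 1
  }
  v
}

#' Structural profile of a window
#'
#' Looks up each enabled per-residue descriptor across the 8 window
#' positions, producing one 8-value numeric vector per feature;
#' out-of-chain or missing positions are `NA`.
#'
#' @param p1 1-based P1 residue index in the chain.
#' @param descriptors per-residue table from [residue_descriptors()].
#' @param features descriptor column names to profile.
#' @return named list of numeric length-8 vectors.
#' @export
build_structural_profile <- function(p1, descriptors,
                                     features = STRUCT_FEATURES) {
  missing_cols <- setdiff(features, names(descriptors))
  if (length(missing_cols)) {
    stop("unknown descriptor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  idx <- (p1 - 3):(p1 + 4)
  n <- nrow(descriptors)
  row <- match(idx, descriptors$resi)
  out <- lapply(features, function(f) {
    v <- rep(NA_real_, 8)
    ok <- !is.na(row)
    v[ok] <- descriptors[[f]][row[ok]]
    v
  })
  names(out) <- features
  out
}

#' Smoothing/binning configuration for the structural features
#'
#' Holds, per enabled feature, the LOWESS smoothing range (0 = raw
#' values) and bin count, and - once fitted on training data - the frozen
#' equal-width bin edges used at prediction time.
#'
#' @param features character vector of enabled structural features
#'   (`character(0)` for sequence-only models).
#' @param range integer in 0..5, recycled per feature (0 disables
#'   smoothing).
#' @param bins integer in 1..10, recycled per feature.
#' @return a `smoothing_config` list with elements `features`, `range`,
#'   `bins` (named per feature) and `edges` (empty until
#'   [fit_config()]).
#' @export
smoothing_config <- function(features = STRUCT_FEATURES, range = 2,
                             bins = 5) {
  stopifnot(all(range >= 0 & range <= 5), all(bins >= 1 & bins <= 10))
  n <- length(features)
  cfg <- list(features = features,
              range = stats::setNames(rep_len(range, n), features),
              bins = stats::setNames(rep_len(bins, n), features),
              edges = stats::setNames(vector("list", n), features))
  class(cfg) <- "smoothing_config"
  cfg
}

# smooth one profile under the config; profiles containing NA bypass
# smoothing (their positions carry the explicit NA category downstream)
smooth_profile <- function(profile, cfg) {
  for (f in cfg$features) {
    r <- cfg$range[[f]]
    if (r >= 1 && !anyNA(profile[[f]])) {
      profile[[f]] <- lowess_smooth(profile[[f]], r)
    }
  }
  profile
}

#' Fit bin edges of a configuration on training profiles
#'
#' Applies the configured smoothing to every training profile and fits
#' per-feature equal-width bin edges on the pooled smoothed values.  Bin
#' edges are training-set state: they are frozen into the model and
#' prediction-time values outside the training range are clipped into
#' the extreme bins.
#'
#' @param cfg a [smoothing_config()].
#' @param profiles list of window profiles from
#'   [build_structural_profile()].
#' @return the configuration with `edges` filled in.
#' @export
fit_config <- function(cfg, profiles) {
  for (f in cfg$features) {
    vals <- unlist(lapply(profiles, function(p) {
      v <- p[[f]]
      r <- cfg$range[[f]]
      if (r >= 1 && !anyNA(v)) v <- lowess_smooth(v, r)
      v
    }))
    vals <- vals[is.finite(vals)]
    cfg$edges[[f]] <- if (length(vals)) {
      suppressWarnings(fit_bins(vals, cfg$bins[[f]]))
    } else {
      numeric(0)
    }
  }
  cfg
}

#' Encode a window as a CRF observation chain
#'
#' Produces, for each of the 8 positions, the set of categorical
#' attributes the Boolean feature functions fire on: the residue
#' identity, its chemical group, and one bin id per enabled structural
#' feature (smoothed when the feature's range >= 1; `NA` positions map
#' to an explicit NA category and bypass smoothing).
#'
#' @param window 8-character window string.
#' @param profile structural profile from [build_structural_profile()]
#'   (`NULL` for sequence-only encodings).
#' @param cfg fitted [smoothing_config()] (`NULL` for sequence-only).
#' @param use_sequence,use_chemical enable the residue / chemical-group
#'   attribute families.
#' @return an `encoded_instance`: list of 8 character vectors of
#'   `key=value` attributes.
#' @export
encode_instance <- function(window, profile = NULL, cfg = NULL,
                            use_sequence = TRUE, use_chemical = TRUE) {
  ch <- window_chars(window)
  attrs <- vector("list", 8)
  for (i in 1:8) attrs[[i]] <- character(0)
  if (use_sequence) {
    for (i in 1:8) {
      attrs[[i]] <- c(attrs[[i]], paste0("res=", ch[i]))
    }
  }
  if (use_chemical) {
    g <- chemical_group(ch)
    for (i in 1:8) attrs[[i]] <- c(attrs[[i]], paste0("chem=", g[i]))
  }
  if (!is.null(cfg) && length(cfg$features)) {
    if (is.null(profile)) stop("structural config given without profile")
    profile <- smooth_profile(profile, cfg)
    for (f in cfg$features) {
      v <- profile[[f]]
      ids <- discretize(v, cfg$edges[[f]])
      lab <- ifelse(is.na(ids), "NA", paste0("b", ids))
      for (i in 1:8) {
        attrs[[i]] <- c(attrs[[i]], paste0(f, "=", lab[i]))
      }
    }
  }
  structure(attrs, class = "encoded_instance")
}

# ---- feature-combination presets --------------------------------------

PRESETS <- c("seq", "seq_chem", "seq_chem_real", "seq_chem_smooth",
             "seq_chem_smooth_dssp")

#' Feature-combination preset
#'
#' The five compared feature arms: sequence one-hot only (`seq`);
#' sequence + chemical groups (`seq_chem`); those plus raw (unsmoothed)
#' binned structural features (`seq_chem_real`); plus LOWESS-smoothed
#' structural features (`seq_chem_smooth`); or smoothed
#' secondary-structure-derived features only (`seq_chem_smooth_dssp`).
#'
#' @param preset one of `"seq"`, `"seq_chem"`, `"seq_chem_real"`,
#'   `"seq_chem_smooth"`, `"seq_chem_smooth_dssp"`.
#' @param range,bins smoothing range and bin count applied to the
#'   structural features of the preset (ignored for sequence-only arms;
#'   `seq_chem_real` forces range 0).
#' @return list with `use_sequence`, `use_chemical` flags and a
#'   `smoothing_config` (`NULL` when no structural features are used).
#' @export
preset_config <- function(preset = PRESETS, range = 2, bins = 5) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    seq = NULL,
    seq_chem = NULL,
    seq_chem_real = smoothing_config(STRUCT_FEATURES, range = 0,
                                     bins = bins),
    seq_chem_smooth = smoothing_config(STRUCT_FEATURES, range = range,
                                       bins = bins),
    seq_chem_smooth_dssp = smoothing_config(DSSP_FEATURES, range = range,
                                            bins = bins))
  list(preset = preset,
       use_sequence = TRUE,
       use_chemical = preset != "seq",
       smoothing = cfg)
}
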