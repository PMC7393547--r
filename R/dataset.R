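# Dataset preparation: cleavage-annotation parsing, alignment-based
# mapping of annotated sites onto structure chains, structure filtering,
# equal-count negative sampling and greedy redundancy filtering.

ANNOTATION_COLUMNS <- c("substrate_id", "protease", "p1_position",
                        "sequence", "pdb_id", "chain")

#' Parse a cleavage-annotation TSV
#'
#' Expected columns: `substrate_id`, `protease`, `p1_position` (1-based
#' position of the P1 residue in the substrate sequence), `sequence`,
#' `pdb_id`, `chain`.  Malformed rows (non-integer or out-of-range P1,
#' empty sequence) are rejected with their line numbers; exact duplicate
#' rows are removed with a warning.
#'
#' @param path TSV file path.
#' @return data frame of cleavage records.
#' @export
parse_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("annotation file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  p1 <- suppressWarnings(as.integer(df$p1_position))
  len <- nchar(df$sequence)
  bad <- which(is.na(p1) | p1 < 1 | p1 >= len | len == 0)
  if (length(bad)) {
    warning("rejecting malformed annotation row(s) (file line ",
            paste(bad + 1L, collapse = ", "),
            "): P1 must be an integer in [1, sequence length - 1]")
    df <- df[-bad, , drop = FALSE]
    p1 <- p1[-bad]
  }
  df$p1_position <- p1
  dup <- duplicated(df)
  if (any(dup)) {
    warning("removing ", sum(dup), " duplicate annotation row(s)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Read substrate sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of amino-acid sequences.
#' @export
read_fasta_sequences <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*", "", names(s)))
}

#' Map an annotated cleavage site onto a structure chain
#'
#' Globally aligns the substrate sequence against the chain sequence and
#' accepts the mapping only when the aligned identity reaches
#' `min_identity` and both the P1 and P1' columns align to structure
#' residues (not gaps).
#'
#' @param record one-row cleavage record (see [parse_annotations()]).
#' @param structure a `pdb_structure`.
#' @param min_identity minimum aligned sequence identity (fraction).
#' @return list with `mapped` (logical), `p1_resi` (1-based chain
#'   residue index of P1, or `NA`), `identity`, and `reason` when
#'   unmapped.
#' @export
map_sites_to_chain <- function(record, structure, min_identity = 0.95) {
  sub_seq <- record$sequence
  ch_seq <- chain_sequence(structure)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sub_seq), Biostrings::AAString(ch_seq),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(pat == sbj & pat != "-") / nchar(sub_seq)
  if (ident < min_identity) {
    return(list(mapped = FALSE, p1_resi = NA_integer_, identity = ident,
                reason = sprintf("identity %.3f below threshold %.2f",
                                 ident, min_identity)))
  }
  # walk the alignment to locate the substrate P1 and P1' columns
  sub_pos <- cumsum(pat != "-")
  ch_pos <- cumsum(sbj != "-")
  col_p1 <- which(sub_pos == record$p1_position & pat != "-")[1]
  col_p1p <- which(sub_pos == record$p1_position + 1L & pat != "-")[1]
  if (is.na(col_p1) || is.na(col_p1p) ||
      sbj[col_p1] == "-" || sbj[col_p1p] == "-") {
    return(list(mapped = FALSE, p1_resi = NA_integer_, identity = ident,
                reason = "P1 or P1' aligned opposite a gap"))
  }
  list(mapped = TRUE, p1_resi = ch_pos[col_p1], identity = ident,
       reason = NA_character_)
}

#' Keep only X-ray structures
#'
#' @param structures list of `pdb_structure` objects.
#' @return the X-ray subset; NMR/EM and structures without an EXPDTA
#'   record are dropped (the latter with a warning).
#' @export
filter_xray <- function(structures) {
  keep <- vapply(structures, function(s) {
    if (is.na(s$experiment)) return(NA)
    grepl("X-RAY", toupper(s$experiment), fixed = TRUE)
  }, logical(1))
  if (anyNA(keep)) {
    warning(sum(is.na(keep)),
            " structure(s) without EXPDTA record excluded")
    keep[is.na(keep)] <- FALSE
  }
  structures[keep]
}

#' Sample negative sites, equal in count to the positives
#'
#' Draws a uniform without-replacement sample from the candidate windows
#' that are not annotated positive and do not overlap any positive P1
#' (same substrate, |p1 difference| < 8).
#'
#' @param windows a `site_windows` data frame pooling all candidate
#'   windows of the mapped substrates (with `label` marking positives).
#' @param n number of negatives (default: number of positives).
#' @param seed integer seed making the draw reproducible.
#' @param require_full_window drop candidates whose window runs off the
#'   chain (gap-padded), so negatives have full structural coverage.
#' @return the sampled negative rows of `windows`.
#' @export
sample_negatives <- function(windows, n = NULL, seed = 1,
                             require_full_window = TRUE) {
  pos <- windows[windows$label == 1L, , drop = FALSE]
  if (is.null(n)) n <- nrow(pos)
  cand <- windows[windows$label == 0L, , drop = FALSE]
  if (require_full_window) {
    cand <- cand[!grepl("-", cand$window, fixed = TRUE), , drop = FALSE]
  }
  overlap <- rep(FALSE, nrow(cand))
  for (k in seq_len(nrow(pos))) {
    overlap <- overlap | (cand$substrate_id == pos$substrate_id[k] &
                          abs(cand$p1 - pos$p1[k]) < 8L)
  }
  cand <- cand[!overlap, , drop = FALSE]
  if (nrow(cand) < n) {
    warning("only ", nrow(cand), " negative candidates available; ",
            "taking all")
    n <- nrow(cand)
  }
  set.seed(seed)
  cand[sort(sample.int(nrow(cand), n)), , drop = FALSE]
}

#' Greedy redundancy filter on sequences
#'
#' Longest-first greedy clustering: each sequence joins the first
#' existing cluster whose representative it matches at or above the
#' identity threshold (global alignment identity over the shorter
#' sequence); otherwise it founds a new cluster.  Returns the
#' representatives.
#'
#' @param sequences named character vector of sequences.
#' @param identity_threshold fraction in (0, 1].
#' @return named character vector of representative sequences.
#' @export
redundancy_filter <- function(sequences, identity_threshold = 0.7) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  ord <- order(-nchar(sequences))
  reps <- character(0)
  rep_names <- character(0)
  for (i in ord) {
    s <- sequences[[i]]
    joined <- FALSE
    for (r in reps) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(s), Biostrings::AAString(r),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      pat <- strsplit(as.character(Biostrings::alignedPattern(aln)),
                      "")[[1]]
      sbj <- strsplit(as.character(Biostrings::alignedSubject(aln)),
                      "")[[1]]
      ident <- sum(pat == sbj & pat != "-") /
        min(nchar(s), nchar(r))
      if (ident >= identity_threshold) {
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, s)
      rep_names <- c(rep_names, names(sequences)[i])
    }
  }
  stats::setNames(reps, rep_names)
}

#' Assemble a training dataset from structures and annotations
#'
#' For every annotation record: parse or look up the structure, map the
#' annotated P1 onto the chain by global alignment, extract all candidate
#' windows of the chain sequence, and compute per-residue descriptors.
#' Negatives are then sampled globally, equal in count to the positives.
#'
#' @param annotations data frame from [parse_annotations()].
#' @param structures named list of `pdb_structure` objects keyed by
#'   `pdb_id` (as produced by [generate_dataset()]), or a directory of
#'   `<pdb_id>.pdb` files.
#' @param seed seed for negative sampling.
#' @param min_identity mapping acceptance threshold.
#' @param n_points SASA quadrature points (lower = faster).
#' @return list with `windows` (positives + sampled negatives),
#'   `profiles` (structural profile per window), `unmapped` (data frame
#'   of rejected records).
#' @export
prepare_dataset <- function(annotations, structures, seed = 1,
                            min_identity = 0.95, n_points = 240) {
  get_structure <- function(pdb_id, chain) {
    if (is.list(structures) && !is.null(structures[[pdb_id]])) {
      return(structures[[pdb_id]])
    }
    parse_pdb(file.path(structures, paste0(pdb_id, ".pdb")), chain)
  }
  all_windows <- list()
  descriptors <- list()
  unmapped <- list()
  for (sid in unique(annotations$substrate_id)) {
    rec <- annotations[annotations$substrate_id == sid, , drop = FALSE]
    st <- get_structure(rec$pdb_id[1], rec$chain[1])
    p1s <- integer(0)
    for (k in seq_len(nrow(rec))) {
      m <- map_sites_to_chain(rec[k, ], st, min_identity = min_identity)
      if (m$mapped) {
        p1s <- c(p1s, m$p1_resi)
      } else {
        unmapped[[length(unmapped) + 1]] <-
          cbind(rec[k, ], reason = m$reason)
      }
    }
    w <- extract_windows(chain_sequence(st), p1s, substrate_id = sid,
                         chain_id = rec$chain[1])
    all_windows[[sid]] <- w
    descriptors[[sid]] <- residue_descriptors(st, n_points = n_points)
  }
  windows <- do.call(rbind, all_windows)
  rownames(windows) <- NULL
  pos <- windows[windows$label == 1L, , drop = FALSE]
  neg <- sample_negatives(windows, seed = seed)
  sel <- rbind(pos, neg)
  profiles <- lapply(seq_len(nrow(sel)), function(k) {
    build_structural_profile(sel$p1[k], descriptors[[sel$substrate_id[k]]])
  })
  list(windows = sel, profiles = profiles,
       unmapped = if (length(unmapped)) do.call(rbind, unmapped) else NULL)
}
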