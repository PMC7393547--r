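# Shared fixtures and independent oracles.  Expensive objects are built
# once per test run and memoized here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# minimal structure from an atom table (for analytic-geometry tests)
toy_structure <- function(atoms, aa = NULL) {
  resis <- unique(atoms$resi)
  if (is.null(aa)) aa <- rep("A", length(resis))
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$name)) atoms$name <- "CA"
  if (is.null(atoms$resname)) atoms$resname <- "ALA"
  if (is.null(atoms$aa)) atoms$aa <- "A"
  if (is.null(atoms$resno)) atoms$resno <- atoms$resi
  if (is.null(atoms$icode)) atoms$icode <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 10
  if (is.null(atoms$element)) atoms$element <- "C"
  st <- list(id = "toy", chain = "A", experiment = "X-RAY DIFFRACTION",
             atoms = atoms,
             residues = data.frame(resi = resis, resno = resis,
                                   icode = "", aa = aa,
                                   stringsAsFactors = FALSE))
  class(st) <- "pdb_structure"
  st
}

single_atom_structure <- function(element = "C") {
  toy_structure(data.frame(resi = 1, name = "CA", x = 0, y = 0, z = 0,
                           element = element))
}

# a caged atom: centre atom surrounded by a dense spherical shell
caged_structure <- function(shell_radius = 2.0, n_shell = 80) {
  pts <- crfcleave:::sphere_points(n_shell) * shell_radius
  atoms <- data.frame(
    resi = c(1L, rep(2L, n_shell)),
    name = c("CA", paste0("C", seq_len(n_shell))),
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3]),
    element = "C")
  toy_structure(atoms, aa = c("A", "A"))
}

# medium helix+coil structure reused by several descriptor tests
mixed_structure <- function() {
  cached("mixed30", build_backbone(
    list(c("helix", 12), c("coil", 6), c("helix", 12)), seed = 42))
}

# planted-motif datasets (generation + descriptor computation is the
# expensive part; shared between evaluation, cli and acceptance tests)
both_dataset <- function() {
  cached("both80", {
    ds <- generate_dataset(fixture_spec(n_substrates = 80,
                                        signal_mode = "both", seed = 7))
    prep <- prepare_dataset(ds$annotations, ds$structures, seed = 7)
    list(ds = ds, prep = prep)
  })
}

structure_only_dataset <- function() {
  cached("structonly16", {
    ds <- generate_dataset(fixture_spec(n_substrates = 16,
                                        signal_mode = "structure_only",
                                        seed = 11))
    prep <- prepare_dataset(ds$annotations, ds$structures, seed = 11)
    list(ds = ds, prep = prep)
  })
}

sequence_only_dataset <- function() {
  cached("seqonly10", {
    ds <- generate_dataset(fixture_spec(n_substrates = 10,
                                        signal_mode = "sequence_only",
                                        seed = 19))
    prep <- prepare_dataset(ds$annotations, ds$structures, seed = 19)
    list(ds = ds, prep = prep)
  })
}

# ---- independent oracles ----------------------------------------------

# explicit weighted-least-squares LOWESS oracle: builds the window,
# tricube weights and normal equations directly
wls_lowess_oracle <- function(v, range) {
  len <- length(v)
  out <- numeric(len)
  for (i in seq_len(len)) {
    if (i - range < 1) {
      S <- seq(1, min(2 * range, len)); h <- 2 * range - i + 1
    } else if (i + range > len) {
      S <- seq(max(len - 2 * range, 1), len); h <- i - len + 2 * range + 1
    } else {
      S <- seq(i - range, i + range); h <- 2 * range + 1
    }
    w <- pmin(pmax(1 - (abs(i - S) / h)^3, 0), 1)^3
    X <- cbind(1, S)
    A <- t(X) %*% (w * X)
    b <- t(X) %*% (w * v[S])
    if (abs(det(A)) < 1e-12) {
      out[i] <- sum(w * v[S]) / sum(w)
    } else {
      beta <- solve(A, b)
      out[i] <- beta[1] + beta[2] * i
    }
  }
  out
}

# brute-force CRF distributions by explicit feature summation over all
# 2^8 label sequences
enumerate_crf <- function(model, x) {
  tagged <- crfcleave:::tag_instance(x)
  uni <- function(i, lab) {
    idx <- match(tagged[[i]], model$vocab)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) 0 else sum(model$w_uni[idx, lab + 1])
  }
  n <- length(x)
  ys <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  scores <- apply(ys, 1, function(y) {
    s <- model$w_trans[1, y[1] + 1] + uni(1, y[1])
    for (i in 2:n) {
      s <- s + model$w_trans[y[i - 1] + 2, y[i] + 1] + uni(i, y[i])
    }
    s
  })
  list(ys = ys, scores = scores, logZ = log(sum(exp(scores))))
}

random_instance <- function(n_attr = 3, n_sym = 6) {
  structure(lapply(1:8, function(i)
    paste0("a", sample.int(n_sym, n_attr))), class = "encoded_instance")
}

random_crf_model <- function(instances, scale = 0.8) {
  vocab <- sort(unique(unlist(lapply(instances, function(x)
    unlist(crfcleave:::tag_instance(x))))))
  crfcleave:::crf_model_new(
    vocab,
    matrix(stats::rnorm(length(vocab) * 2, sd = scale),
           ncol = 2),
    matrix(stats::rnorm(6, sd = scale), 3, 2), 1)
}
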