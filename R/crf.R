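# Linear-chain conditional random field with Boolean (indicator) feature
# functions over the length-8 observation chains.
#
#   p(y | x) = exp( sum_i sum_k lambda_k f_k(y_i, y_{i-1}, x_i) ) / Z(x)
#
# Feature templates: one unigram indicator per (position-tagged
# observation attribute, label), plus label-bigram transition indicators
# with a distinguished start state.  Labels are binary: 1 = cleavage,
# 0 = non-cleavage.  Training maximizes the L2-penalized conditional
# log-likelihood from a zero initialization with a deterministic
# quasi-Newton optimizer (L-BFGS-B driven by the analytic gradient
# below); the site-level prediction score is the posterior marginal of
# the cleavage label at the P1 chain position (position 4 of 8).

N_LABELS <- 2L  # internal label indices: 1 = "0" (non-cleavage), 2 = "1"

# position-tag the attributes of an encoded instance so that the same
# observation at P4 and at P1 drives different weights
tag_instance <- function(x) {
  lapply(seq_along(x), function(i) {
    if (length(x[[i]])) paste0("p", i, "|", x[[i]]) else character(0)
  })
}

# integer attribute indices per position; attributes unseen at training
# time are dropped (weight-0 semantics)
instance_indices <- function(vocab, x) {
  tagged <- tag_instance(x)
  lapply(tagged, function(a) {
    i <- match(a, vocab)
    i[!is.na(i)]
  })
}

crf_model_new <- function(vocab, w_uni, w_trans, l2_sigma,
                          config = NULL, use_sequence = TRUE,
                          use_chemical = TRUE, protease = NA_character_,
                          threshold = NA_real_, meta = list()) {
  m <- list(vocab = vocab, w_uni = w_uni, w_trans = w_trans,
            l2_sigma = l2_sigma, config = config,
            use_sequence = use_sequence, use_chemical = use_chemical,
            protease = protease, threshold = threshold, meta = meta)
  class(m) <- "crf_model"
  m
}

#' @export
print.crf_model <- function(x, ...) {
  cat("crf_model:", length(x$vocab), "attributes,",
      length(x$vocab) * N_LABELS + 3 * N_LABELS, "weights;",
      "protease:", x$protease, "\n")
  if (!is.null(x$config)) {
    cat("  structural features:",
        paste(x$config$features, collapse = ", "), "\n")
  }
  invisible(x)
}

# per-position unigram score matrix (8 x 2) for one instance
unigram_scores <- function(model, x) {
  idx <- instance_indices(model$vocab, x)
  U <- matrix(0, length(x), N_LABELS)
  for (i in seq_along(idx)) {
    if (length(idx[[i]])) {
      U[i, ] <- colSums(model$w_uni[idx[[i]], , drop = FALSE])
    }
  }
  U
}

# transition weight matrix rows: 1 = start, 2 = from label 0, 3 = from 1
trans_matrix <- function(model) model$w_trans

#' Unnormalized log-potential of a label sequence
#'
#' @param model a `crf_model`.
#' @param x an `encoded_instance` (list of 8 attribute sets).
#' @param y integer vector of 8 labels in {0, 1}.
#' @return the log-potential (sum of fired feature weights).
#' @export
crf_score <- function(model, x, y) {
  if (length(y) != length(x)) stop("label/observation length mismatch")
  U <- unigram_scores(model, x)
  Tm <- trans_matrix(model)
  yl <- y + 1L
  s <- Tm[1, yl[1]] + U[1, yl[1]]
  for (i in seq_along(y)[-1]) {
    s <- s + Tm[yl[i - 1] + 1L, yl[i]] + U[i, yl[i]]
  }
  s
}

lse2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

forward_matrix <- function(U, Tm) {
  n <- nrow(U)
  alpha <- matrix(0, n, N_LABELS)
  alpha[1, ] <- Tm[1, ] + U[1, ]
  if (n > 1) {
    for (i in 2:n) {
      for (y in 1:N_LABELS) {
        alpha[i, y] <- lse2(alpha[i - 1, 1] + Tm[2, y],
                            alpha[i - 1, 2] + Tm[3, y]) + U[i, y]
      }
    }
  }
  alpha
}

backward_matrix <- function(U, Tm) {
  n <- nrow(U)
  beta <- matrix(0, n, N_LABELS)
  if (n > 1) {
    for (i in (n - 1):1) {
      for (y in 1:N_LABELS) {
        beta[i, y] <- lse2(Tm[y + 1, 1] + U[i + 1, 1] + beta[i + 1, 1],
                           Tm[y + 1, 2] + U[i + 1, 2] + beta[i + 1, 2])
      }
    }
  }
  beta
}

#' Log partition function log Z(x)
#'
#' Computed by the forward recursion in log space.
#'
#' @inheritParams crf_score
#' @return log of the sum of exp(score) over all label sequences.
#' @export
log_partition <- function(model, x) {
  U <- unigram_scores(model, x)
  alpha <- forward_matrix(U, trans_matrix(model))
  lse2(alpha[nrow(U), 1], alpha[nrow(U), 2])
}

#' Per-position posterior label marginals
#'
#' @inheritParams crf_score
#' @return matrix (positions x 2) of posteriors p(y_i = 0), p(y_i = 1);
#'   rows sum to 1.
#' @export
crf_marginals <- function(model, x) {
  U <- unigram_scores(model, x)
  Tm <- trans_matrix(model)
  alpha <- forward_matrix(U, Tm)
  beta <- backward_matrix(U, Tm)
  logz <- lse2(alpha[nrow(U), 1], alpha[nrow(U), 2])
  p <- exp(alpha + beta - logz)
  colnames(p) <- c("0", "1")
  p
}

#' Viterbi decoding
#'
#' Maximum a posteriori label sequence; ties break toward label 0, then
#' lexicographically (the first maximizer in label order is kept at each
#' step).
#'
#' @inheritParams crf_score
#' @return list with `labels` (integer vector in {0, 1}) and `prob`
#'   (posterior probability of that sequence).
#' @export
crf_viterbi <- function(model, x) {
  U <- unigram_scores(model, x)
  Tm <- trans_matrix(model)
  n <- nrow(U)
  delta <- matrix(-Inf, n, N_LABELS)
  back <- matrix(1L, n, N_LABELS)
  delta[1, ] <- Tm[1, ] + U[1, ]
  if (n > 1) {
    for (i in 2:n) {
      for (y in 1:N_LABELS) {
        cand <- delta[i - 1, ] + Tm[2:3, y]
        back[i, y] <- which.max(cand)  # first max -> label 0 on ties
        delta[i, y] <- cand[back[i, y]] + U[i, y]
      }
    }
  }
  yl <- integer(n)
  yl[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) yl[i] <- back[i + 1, yl[i + 1]]
  logz <- log_partition(model, x)
  list(labels = yl - 1L, prob = exp(delta[n, yl[n]] - logz))
}

#' Cleavage probability of a candidate site
#'
#' The posterior marginal of the cleavage label at the P1 chain position
#' (position 4 of the 8-residue window).
#'
#' @inheritParams crf_score
#' @return probability in [0, 1].
#' @export
predict_site <- function(model, x) {
  unname(crf_marginals(model, x)[4, 2])
}

# ---- training ----------------------------------------------------------

# pack a list of encoded instances into the sparse design used by the
# vectorized objective: rows are (instance, position) pairs in
# position-fastest order, columns are vocabulary attributes
pack_instances <- function(instances, vocab) {
  n <- length(instances)
  ii <- jj <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- instance_indices(vocab, instances[[k]])
    rows <- rep((k - 1L) * 8L + seq_len(8L),
                vapply(idx, length, integer(1)))
    ii[[k]] <- rows
    jj[[k]] <- unlist(idx, use.names = FALSE)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                       dims = c(n * 8L, length(vocab)))
}

unpack_par <- function(par, A) {
  list(w_uni = matrix(par[seq_len(2 * A)], A, 2),
       w_trans = matrix(par[2 * A + seq_len(6)], 3, 2))
}

# vectorized penalized NLL and gradient over all instances at once
nll_grad_packed <- function(par, M, Ylab, sigma2) {
  A <- ncol(M)
  n <- nrow(M) / 8L
  w <- unpack_par(par, A)
  Tm <- w$w_trans
  U <- as.matrix(M %*% w$w_uni)             # (n*8) x 2
  rowsel <- function(i) (seq_len(n) - 1L) * 8L + i
  alpha <- vector("list", 8)
  alpha[[1]] <- sweep(U[rowsel(1), , drop = FALSE], 2, Tm[1, ], `+`)
  for (i in 2:8) {
    Ui <- U[rowsel(i), , drop = FALSE]
    prev <- alpha[[i - 1]]
    alpha[[i]] <- cbind(
      lse2(prev[, 1] + Tm[2, 1], prev[, 2] + Tm[3, 1]) + Ui[, 1],
      lse2(prev[, 1] + Tm[2, 2], prev[, 2] + Tm[3, 2]) + Ui[, 2])
  }
  logz <- lse2(alpha[[8]][, 1], alpha[[8]][, 2])
  beta <- vector("list", 8)
  beta[[8]] <- matrix(0, n, 2)
  for (i in 7:1) {
    Un <- U[rowsel(i + 1), , drop = FALSE]
    nxt <- beta[[i + 1]]
    beta[[i]] <- cbind(
      lse2(Tm[2, 1] + Un[, 1] + nxt[, 1], Tm[2, 2] + Un[, 2] + nxt[, 2]),
      lse2(Tm[3, 1] + Un[, 1] + nxt[, 1], Tm[3, 2] + Un[, 2] + nxt[, 2]))
  }
  P <- matrix(0, n * 8L, 2)                  # posterior marginals
  for (i in 1:8) {
    P[rowsel(i), ] <- exp(alpha[[i]] + beta[[i]] - logz)
  }
  # empirical label indicators, same row order
  Yind <- matrix(0, n * 8L, 2)
  for (i in 1:8) {
    Yind[rowsel(i), 1] <- as.numeric(Ylab[, i] == 0L)
    Yind[rowsel(i), 2] <- as.numeric(Ylab[, i] == 1L)
  }
  g_uni <- as.matrix(Matrix::crossprod(M, P - Yind)) + w$w_uni / sigma2

  # transitions: model expectations via pairwise marginals
  g_trans <- matrix(0, 3, 2)
  g_trans[1, ] <- colSums(P[rowsel(1), , drop = FALSE])
  for (i in 2:8) {
    Ui <- U[rowsel(i), , drop = FALSE]
    prev <- alpha[[i - 1]]
    bi <- beta[[i]]
    for (yp in 1:2) {
      for (y in 1:2) {
        pp <- exp(prev[, yp] + Tm[yp + 1, y] + Ui[, y] + bi[, y] - logz)
        g_trans[yp + 1, y] <- g_trans[yp + 1, y] + sum(pp)
      }
    }
  }
  # empirical transition counts
  emp_trans <- matrix(0, 3, 2)
  for (y in 0:1) {
    emp_trans[1, y + 1] <- sum(Ylab[, 1] == y)
  }
  for (i in 2:8) {
    for (yp in 0:1) {
      for (y in 0:1) {
        emp_trans[yp + 2, y + 1] <- emp_trans[yp + 2, y + 1] +
          sum(Ylab[, i - 1] == yp & Ylab[, i] == y)
      }
    }
  }
  g_trans <- g_trans - emp_trans + w$w_trans / sigma2

  # NLL = sum logZ - sum score(observed) + penalty
  obs_uni <- sum(U * Yind)
  obs_trans <- sum(Tm * emp_trans)
  nll <- sum(logz) - obs_uni - obs_trans + sum(par^2) / (2 * sigma2)
  list(value = nll, gradient = c(g_uni, g_trans))
}

#' Penalized negative log-likelihood and gradient
#'
#' NLL = -sum log p(y | x) + ||lambda||^2 / (2 sigma^2); the gradient is
#' the model-minus-empirical feature expectation plus the L2 term.
#' Exposed mainly for optimizer diagnostics and gradient checking.
#'
#' @param model a `crf_model`.
#' @param instances list of `encoded_instance` objects.
#' @param labels integer matrix (instances x 8) of 0/1 labels, or a
#'   vector of per-instance site labels expanded to homogeneous chains.
#' @return list with `value` and `gradient` (gradient ordered as
#'   unigram weights column-major, then transition weights).
#' @export
nll_and_gradient <- function(model, instances, labels) {
  if (!length(instances)) stop("empty instance list")
  Ylab <- expand_labels(labels, length(instances))
  M <- pack_instances(instances, model$vocab)
  nll_grad_packed(c(model$w_uni, model$w_trans), M, Ylab,
                  model$l2_sigma^2)
}

expand_labels <- function(labels, n) {
  if (is.matrix(labels)) {
    stopifnot(nrow(labels) == n, ncol(labels) == 8)
    return(labels)
  }
  stopifnot(length(labels) == n)
  matrix(rep(as.integer(labels), each = 8), n, 8, byrow = TRUE)
}

#' Train a CRF cleavage-site model
#'
#' Builds the attribute vocabulary from the training instances, expands
#' per-site labels to homogeneous length-8 chains (all-1 for cleavage
#' sites, all-0 for non-sites), and maximizes the L2-penalized
#' conditional log-likelihood with L-BFGS-B from a zero initialization.
#' Training is deterministic given identical inputs.
#'
#' @param instances list of `encoded_instance` objects.
#' @param labels per-instance 0/1 site labels (or a full label matrix).
#' @param l2_sigma Gaussian prior scale sigma (penalty
#'   `||w||^2 / (2 sigma^2)`).
#' @param max_iter optimizer iteration cap.
#' @param grad_tol projected-gradient tolerance.
#' @param config fitted `smoothing_config` frozen into the model
#'   (`NULL` for sequence-only models).
#' @param use_sequence,use_chemical attribute families the encoder used.
#' @param protease optional protease name stored in the model.
#' @return a `crf_model`.
#' @export
crf_train <- function(instances, labels, l2_sigma = 1.0, max_iter = 300,
                      grad_tol = 1e-5, config = NULL,
                      use_sequence = TRUE, use_chemical = TRUE,
                      protease = NA_character_) {
  if (!length(instances)) stop("empty instance list")
  lab_site <- if (is.matrix(labels)) labels[, 4] else as.integer(labels)
  if (length(unique(lab_site)) < 2) {
    stop("training requires at least one positive and one negative site")
  }
  vocab <- sort(unique(unlist(lapply(instances, function(x)
    unlist(tag_instance(x))))))
  if (!length(vocab)) stop("degenerate vocabulary: no observation attributes")
  Ylab <- expand_labels(labels, length(instances))
  M <- pack_instances(instances, vocab)
  sigma2 <- l2_sigma^2
  A <- length(vocab)
  fn <- function(par) nll_grad_packed(par, M, Ylab, sigma2)$value
  gr <- function(par) nll_grad_packed(par, M, Ylab, sigma2)$gradient
  opt <- stats::optim(rep(0, 2 * A + 6), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = grad_tol,
                                     factr = 1e7))
  w <- unpack_par(opt$par, A)
  crf_model_new(vocab, w$w_uni, w$w_trans, l2_sigma, config = config,
                use_sequence = use_sequence, use_chemical = use_chemical,
                protease = protease,
                meta = list(n_train = length(instances),
                            n_positive = sum(lab_site == 1),
                            nll = opt$value,
                            convergence = opt$convergence))
}

# ---- serialization -----------------------------------------------------

#' Write a trained model to a JSON file
#'
#' Self-describing single-file serialization of the weights, attribute
#' vocabulary, transition weights, smoothing/bin state and metadata;
#' round-trip stable (read + write reproduces the file byte for byte).
#'
#' @param model a `crf_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_crf_model <- function(model, path) {
  cfg <- model$config
  obj <- list(
    format = "crfcleave-model-v1",
    protease = model$protease,
    l2_sigma = model$l2_sigma,
    threshold = model$threshold,
    use_sequence = model$use_sequence,
    use_chemical = model$use_chemical,
    vocab = model$vocab,
    w_uni = as.numeric(model$w_uni),
    w_trans = as.numeric(model$w_trans),
    config = if (is.null(cfg)) NULL else list(
      features = cfg$features,
      range = as.list(cfg$range),
      bins = as.list(cfg$bins),
      edges = lapply(cfg$edges, as.numeric)),
    meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model written by [write_crf_model()]
#'
#' @param path model file path.
#' @return a `crf_model`.
#' @export
read_crf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "crfcleave-model-v1")) {
    stop("not a crfcleave model file: ", path)
  }
  A <- length(obj$vocab)
  cfg <- NULL
  if (!is.null(obj$config) && length(obj$config$features)) {
    cfg <- smoothing_config(obj$config$features)
    cfg$range <- unlist(obj$config$range)[cfg$features]
    cfg$bins <- unlist(obj$config$bins)[cfg$features]
    edges <- obj$config$edges
    cfg$edges <- stats::setNames(
      lapply(cfg$features, function(f) as.numeric(edges[[f]])),
      cfg$features)
  }
  crf_model_new(obj$vocab, matrix(obj$w_uni, A, 2),
                matrix(obj$w_trans, 3, 2), obj$l2_sigma, config = cfg,
                use_sequence = isTRUE(obj$use_sequence),
                use_chemical = isTRUE(obj$use_chemical),
                protease = obj$protease,
                threshold = if (is.null(obj$threshold)) NA_real_
                            else obj$threshold,
                meta = obj$meta)
}
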