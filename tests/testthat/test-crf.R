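# Linear-chain CRF: scoring, partition function, marginals, Viterbi,
# gradient and training, each against brute-force oracles.

test_that("score is the explicit sum of fired feature weights", {
  set.seed(21)
  x <- random_instance()
  m <- random_crf_model(list(x))
  bf <- enumerate_crf(m, x)
  for (k in sample(nrow(bf$ys), 20)) {
    expect_equal(crf_score(m, x, bf$ys[k, ]), bf$scores[k],
                 tolerance = 1e-10)
  }
  # zero weights: score 0 for any labelling
  m0 <- m
  m0$w_uni[] <- 0
  m0$w_trans[] <- 0
  expect_equal(crf_score(m0, x, rep(1L, 8)), 0)
  # single active unigram feature
  m1 <- m0
  m1$w_uni[1, 2] <- 2
  attr1 <- m1$vocab[1]
  pos <- as.integer(sub("^p(\\d+)\\|.*", "\\1", attr1))
  y <- rep(0L, 8)
  y[pos] <- 1L
  x1 <- x
  expect_equal(crf_score(m1, x1, y),
               sum(crfcleave:::tag_instance(x1)[[pos]] == attr1) * 2)
  expect_error(crf_score(m, x, c(0, 1)), "mismatch")
})

test_that("logZ, marginals and Viterbi agree with enumeration on random models", {
  set.seed(22)
  for (k in 1:200) {
    x <- random_instance()
    m <- random_crf_model(list(x))
    bf <- enumerate_crf(m, x)
    expect_lt(abs(log_partition(m, x) - bf$logZ), 1e-8)
    p <- exp(bf$scores - bf$logZ)
    marg <- crf_marginals(m, x)
    for (i in c(1, 4, 8)) {
      expect_lt(abs(marg[i, 2] - sum(p[bf$ys[, i] == 1])), 1e-8)
    }
    expect_true(all(abs(rowSums(marg) - 1) < 1e-12))
    vit <- crf_viterbi(m, x)
    expect_identical(vit$labels, unname(bf$ys[which.max(bf$scores), ]))
    expect_equal(vit$prob, max(p), tolerance = 1e-8)
    expect_lt(abs(predict_site(m, x) - sum(p[bf$ys[, 4] == 1])), 1e-8)
  }
})

test_that("zero-weight model is uniform: logZ = 8 ln 2, marginals 0.5", {
  x <- random_instance()
  m <- random_crf_model(list(x))
  m$w_uni[] <- 0
  m$w_trans[] <- 0
  expect_equal(log_partition(m, x), 8 * log(2), tolerance = 1e-12)
  expect_true(all(abs(crf_marginals(m, x) - 0.5) < 1e-12))
  expect_equal(predict_site(m, x), 0.5)
  expect_identical(crf_viterbi(m, x)$labels, rep(0L, 8))  # tie-break
})

test_that("a strong (1,1) transition makes adjacent labels co-occur", {
  set.seed(23)
  x <- random_instance()
  m <- random_crf_model(list(x), scale = 0)
  m$w_trans[3, 2] <- 3  # transition 1 -> 1
  bf <- enumerate_crf(m, x)
  p <- exp(bf$scores - bf$logZ)
  p45 <- sum(p[bf$ys[, 4] == 1 & bf$ys[, 5] == 1])
  p4 <- sum(p[bf$ys[, 4] == 1])
  p5 <- sum(p[bf$ys[, 5] == 1])
  expect_gt(p45, p4 * p5)
})

test_that("gradient matches central finite differences", {
  set.seed(24)
  insts <- replicate(6, random_instance(), simplify = FALSE)
  labs <- c(1, 0, 1, 0, 0, 1)
  m <- random_crf_model(insts, scale = 0.3)
  A <- length(m$vocab)
  g <- nll_and_gradient(m, insts, labs)
  par0 <- c(m$w_uni, m$w_trans)
  probe <- sort(sample(length(par0), 25))
  for (i in probe) {
    e <- rep(0, length(par0)); e[i] <- 1e-5
    val <- function(par) {
      w <- crfcleave:::unpack_par(par, A)
      mm <- m; mm$w_uni <- w$w_uni; mm$w_trans <- w$w_trans
      nll_and_gradient(mm, insts, labs)$value
    }
    fd <- (val(par0 + e) - val(par0 - e)) / 2e-5
    expect_lt(abs(fd - g$gradient[i]) / (abs(fd) + 1e-8), 1e-5)
  }
  # at lambda = 0, the gradient's empirical term is the raw feature count
  m0 <- m; m0$w_uni[] <- 0; m0$w_trans[] <- 0
  g0 <- nll_and_gradient(m0, insts, labs)
  M <- crfcleave:::pack_instances(insts, m$vocab)
  counts1 <- as.numeric(
    Matrix::crossprod(M, rep(rep(labs == 1, each = 8), 1)))
  model_term <- 0.5 * Matrix::colSums(M)  # uniform expectations at 0
  expect_equal(g0$gradient[A + seq_len(A)],
               as.numeric(model_term - counts1), tolerance = 1e-10)
})

test_that("training separates a planted pattern and is deterministic", {
  set.seed(25)
  # positives carry a distinctive attribute at position 4
  mk <- function(pos) {
    structure(lapply(1:8, function(i) {
      a <- paste0("bg", sample.int(4, 1))
      if (pos && i == 4) a <- c(a, "sig") else a <- c(a, "nosig")
      a
    }), class = "encoded_instance")
  }
  insts <- c(replicate(30, mk(TRUE), simplify = FALSE),
             replicate(30, mk(FALSE), simplify = FALSE))
  labs <- rep(c(1, 0), each = 30)
  model <- crf_train(insts, labs, max_iter = 100)
  test <- c(replicate(20, mk(TRUE), simplify = FALSE),
            replicate(20, mk(FALSE), simplify = FALSE))
  sc <- vapply(test, function(x) predict_site(model, x), numeric(1))
  expect_gte(roc_auc(sc, rep(c(1, 0), each = 20))$auc, 0.95)

  model2 <- crf_train(insts, labs, max_iter = 100)
  expect_identical(model$w_uni, model2$w_uni)

  # label flip complements predicted probabilities (symmetric vocabulary)
  flip <- crf_train(insts, 1 - labs, max_iter = 100)
  sf <- vapply(test, function(x) predict_site(flip, x), numeric(1))
  expect_equal(sf, 1 - sc, tolerance = 1e-3)

  expect_error(crf_train(insts, rep(1, 60)), "positive and one negative")
  expect_error(crf_train(list(), numeric(0)), "empty")
})

test_that("two optimizer budgets converge to the same NLL neighbourhood", {
  set.seed(26)
  insts <- replicate(20, random_instance(), simplify = FALSE)
  labs <- rep(c(1, 0), 10)
  m1 <- crf_train(insts, labs, max_iter = 60)
  m2 <- crf_train(insts, labs, max_iter = 300)
  expect_lt(abs(m1$meta$nll - m2$meta$nll), 1e-3)
})

test_that("unseen attributes at prediction time contribute nothing", {
  set.seed(27)
  insts <- replicate(8, random_instance(), simplify = FALSE)
  m <- random_crf_model(insts)
  x <- insts[[1]]
  x_aug <- structure(lapply(x, function(a) c(a, "never_seen=1")),
                     class = "encoded_instance")
  expect_equal(predict_site(m, x_aug), predict_site(m, x))
})

test_that("model serialization round-trips byte-stably", {
  set.seed(28)
  s <- mixed_structure()
  d <- residue_descriptors(s, n_points = 240)
  profs <- lapply(5:20, function(p) build_structural_profile(p, d))
  cfg <- fit_config(smoothing_config(c("cn", "rel_all"), 2, 4), profs)
  w <- extract_windows(chain_sequence(s))
  insts <- lapply(5:20, function(p)
    encode_instance(w$window[w$p1 == p], profs[[p - 4]], cfg))
  model <- crf_train(insts, rep(c(1, 0), 8), config = cfg,
                     protease = "synthase-1", max_iter = 50)
  model$threshold <- 0.75
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_crf_model(model, f1)
  m2 <- read_crf_model(f1)
  write_crf_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$w_uni, model$w_uni)
  expect_equal(m2$config$edges, model$config$edges)
  x <- insts[[3]]
  expect_equal(predict_site(m2, x), predict_site(model, x))
})
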