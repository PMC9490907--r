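test_that("attention pooling matches softmax arithmetic on crafted logits", {
  m <- mil_init(4, embed = 4, attn_hidden = 2, seed = 1)
  # single-instance bag: attention is exactly 1
  one <- matrix(rnorm(4), 1, 4)
  expect_equal(attention_pool(one, m)$attention, 1)
  # identical instances: uniform attention by symmetry
  X <- matrix(rep(rnorm(4), each = 4), 4, 4, byrow = FALSE)
  X <- matrix(rep(rnorm(4), times = 4), 4, 4, byrow = TRUE)
  a <- attention_pool(X, m)$attention
  expect_equal(a, rep(0.25, 4))
  expect_equal(sum(a), 1)
  # softmax of known logits via a model stub: e = [ln 2, 0, 0]
  expect_equal(lfbmil:::softmax_vec(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  expect_error(attention_pool(matrix(c(NaN, 1, 1, 1), 1, 4), m), "NaN")
})

test_that("slide prediction gives symmetric probabilities for zero classifiers", {
  m <- mil_init(6, embed = 4, attn_hidden = 3, seed = 2)
  expect_error(predict_slide(matrix(rnorm(12), 2, 6), m), "not been trained")
  m$Wc[] <- 0; m$bc[] <- 0; m$trained <- TRUE
  expect_equal(predict_slide(matrix(rnorm(12), 2, 6), m), 0.5)
  set.seed(4)
  for (i in 1:5) {
    fw <- lfbmil:::mil_forward(m, matrix(rnorm(30), 5, 6))
    expect_equal(sum(fw$p), 1)
    expect_equal(sum(fw$a), 1)
    expect_true(all(fw$a > 0))
  }
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  for (gated in c(TRUE, FALSE)) for (ilw in c(0, 0.3)) {
    m <- mil_init(5, embed = 4, attn_hidden = 3, gated = gated,
                  instance_loss_weight = ilw, B = 2, seed = 5)
    X <- matrix(rnorm(40), 8, 5)
    y <- 1L
    gr <- lfbmil:::mil_bag_grad(m, X, y)
    for (nm in c("W1", "V", "U", "w", "Wc", "b1", "bc", "Wi")) {
      if (!gated && nm == "U") next
      eps <- 1e-6
      m1 <- m; m2 <- m
      m1[[nm]][1] <- m1[[nm]][1] + eps
      m2[[nm]][1] <- m2[[nm]][1] - eps
      num <- (lfbmil:::mil_bag_grad(m1, X, y)$loss -
                lfbmil:::mil_bag_grad(m2, X, y)$loss) / (2 * eps)
      expect_equal(gr$grads[[nm]][1], num, tolerance = 1e-5)
    }
  }
})

test_that("instance loss weight zero reduces to pure bag cross-entropy", {
  m0 <- mil_init(5, embed = 4, attn_hidden = 3, instance_loss_weight = 0, seed = 6)
  m3 <- mil_init(5, embed = 4, attn_hidden = 3, instance_loss_weight = 0.3, seed = 6)
  X <- matrix(rnorm(40), 8, 5)
  l0 <- lfbmil:::mil_bag_grad(m0, X, 1L)$loss
  lb <- lfbmil:::bag_ce(m0, X, 1L)
  expect_equal(l0, lb)
  expect_gte(lfbmil:::mil_bag_grad(m3, X, 1L)$loss, l0)
})

test_that("training reduces loss on separable bags and is deterministic", {
  set.seed(12)
  mk <- function(y) {
    X <- matrix(rnorm(6 * 8), 6, 8)
    if (y == 1) X[1:2, 1] <- X[1:2, 1] + 3
    X
  }
  ys <- rep(c(0L, 1L), each = 12)
  bags <- lapply(ys, mk)
  m <- mil_train(bags, ys, lr = 1e-3, max_epochs = 40, embed = 8,
                 attn_hidden = 4, seed = 3)
  h <- attr(m, "history")$train
  expect_lt(h[length(h)], h[1])
  m2 <- mil_train(bags, ys, lr = 1e-3, max_epochs = 40, embed = 8,
                  attn_hidden = 4, seed = 3)
  expect_identical(m$W1, m2$W1)
  expect_error(mil_train(bags[1:12], ys[1:12]), "single class")
})

test_that("checkpoints round-trip weights and predictions", {
  set.seed(13)
  bags <- lapply(rep(c(0L, 1L), each = 6), function(y)
    matrix(rnorm(32) + 0.8 * y, 4, 8))
  m <- mil_train(bags, rep(c(0L, 1L), each = 6), lr = 1e-3, max_epochs = 10,
                 embed = 6, attn_hidden = 3, seed = 9)
  f <- tempfile(fileext = ".json")
  write_mil_checkpoint(m, f)
  m2 <- read_mil_checkpoint(f)
  X <- matrix(rnorm(24), 3, 8)
  expect_equal(predict_slide(X, m2), predict_slide(X, m), tolerance = 1e-12)
  expect_equal(m2$hyper$embed, m$hyper$embed)
  unlink(f)
})

test_that("Monte Carlo splits are stratified partitions with 80/10/10 sizes", {
  ids <- sprintf("D%03d", 1:100)
  labs <- rep(c(0, 1), each = 50)
  sp <- make_splits(ids, labs, n_folds = 10, seed = 5)
  expect_length(sp$folds, 10L)
  for (fold in sp$folds) {
    expect_length(fold$train, 80L)
    expect_length(fold$val, 10L)
    expect_length(fold$test, 10L)
    expect_length(intersect(fold$train, fold$val), 0L)
    expect_length(intersect(fold$train, fold$test), 0L)
    expect_length(intersect(fold$val, fold$test), 0L)
    expect_setequal(c(fold$train, fold$val, fold$test), ids)
    # stratification: class proportions within 1 donor of overall in each split
    for (part in fold) {
      n1 <- sum(labs[match(part, ids)])
      expect_lte(abs(n1 - length(part) / 2), 1)
    }
  }
  expect_error(make_splits(ids[c(1:2, 51:60)], labs[c(1:2, 51:60)]), "at least 3")
  # uneven sizes: largest remainder keeps the partition exact
  sp2 <- make_splits(ids[1:97], c(rep(0, 47), rep(1, 50)), n_folds = 3, seed = 1)
  for (fold in sp2$folds)
    expect_equal(length(c(fold$train, fold$val, fold$test)), 97L)
})

test_that("AUC equals brute-force pair concordance and responds to ties", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(14)
  for (r in 1:20) {
    s <- sample(seq(0, 1, 0.05), 30, replace = TRUE)  # force ties
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), brute(s, y))
  }
  # constant scores give AUC 0.5 by the tie rule
  expect_equal(auc_score(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(15)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  expect_equal(auc_score(plogis(5 * s - 2), y), auc_score(s, y))
  expect_equal(auc_score(rank(s), y), auc_score(s, y))
})

test_that("balanced accuracy matches confusion-matrix arithmetic", {
  # TP=3 FN=1 TN=2 FP=2 -> (0.75 + 0.5) / 2
  scores <- c(0.9, 0.8, 0.6, 0.2, 0.1, 0.3, 0.7, 0.55)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(balanced_accuracy(scores, labels), 0.625)
  expect_equal(balanced_accuracy(rep(0.7, 10), rep(c(0, 1), 5)), 0.5)
})

test_that("signed-rank aggregation matches the closed form and stats::wilcox.test", {
  aucs <- seq(0.51, 0.60, by = 0.01)
  w <- wilcoxon_signed_rank(aucs, 0.5)
  expect_equal(w$W, 55)
  expect_equal(w$z, 2.752, tolerance = 1e-3)
  expect_equal(w$p.value, 0.0059, tolerance = 1e-2)
  ref <- suppressWarnings(stats::wilcox.test(aucs, mu = 0.5, correct = TRUE,
                                             exact = FALSE))
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-10)
  # symmetric values around the null give p ~ 1
  sym <- 0.5 + c(-0.04, -0.02, -0.01, 0.01, 0.02, 0.04)
  expect_gt(wilcoxon_signed_rank(sym, 0.5)$p.value, 0.8)
})

test_that("fold aggregation averages ROC curves vertically and picks the best fold", {
  r1 <- list(auc = 0.8, balanced_accuracy = 0.7,
             roc = data.frame(fpr = c(0, 0, 1), tpr = c(0, 0.8, 1)))
  r2 <- list(auc = 0.6, balanced_accuracy = 0.6,
             roc = data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 0.5, 1)))
  agg <- aggregate_folds(list(r1, r2))
  expect_equal(agg$mean_auc, 0.7)
  expect_equal(agg$best_fold, 1L)
  # two identical curves average to themselves pointwise
  agg2 <- aggregate_folds(list(r2, r2))
  expect_equal(agg2$avg_roc$tpr, approx(c(0, 0.5, 1), c(0, 0.5, 1),
                                        xout = agg2$avg_roc$fpr)$y)
  expect_equal(agg2$avg_roc$tpr_sd, rep(0, nrow(agg2$avg_roc)))
  expect_error(aggregate_folds(list(r1)), "at least 2")
})

test_that("evaluate_fold agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  set.seed(16)
  for (r in 1:5) {
    s <- runif(30); y <- c(rep(1, 15), rep(0, 15))
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(y, s, levels = c(0, 1), direction = "<"))))
    expect_equal(auc_score(s, y), ref, tolerance = 1e-12)
  }
})
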