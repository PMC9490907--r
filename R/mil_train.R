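#' Stratified Monte Carlo cross-validation splits
#'
#' Draws `n_folds` independent random splits of donors into train/validation/
#' test sets, stratified by label. Within each class the split sizes are
#' rounded by the largest-remainder method so they always sum to the class
#' size.
#'
#' @param donor_ids Character vector of donor identifiers.
#' @param labels Binary labels (0/1 or a two-level factor), one per donor.
#' @param n_folds Number of Monte Carlo folds.
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param seed Seed for the split draws.
#' @return A `split_plan`: list of folds, each with character vectors
#'   `train`, `val`, `test`.
#' @export
make_splits <- function(donor_ids, labels, n_folds = 10,
                        fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(donor_ids) == length(labels),
            abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  labels <- as.integer(factor(labels)) - 1L
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(tab < 3L)) stop("each class needs at least 3 donors", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- lapply(seq_len(n_folds), function(f) {
    parts <- list(train = character(0), val = character(0), test = character(0))
    for (cl in names(tab)) {
      ids <- donor_ids[labels == as.integer(cl)]
      ids <- sample(ids)
      sizes <- largest_remainder(length(ids), fractions)
      # guarantee every part sees each class (class size >= 3 is enforced)
      for (p in c(2L, 3L)) {
        if (sizes[p] == 0L && sizes[1L] > 1L) {
          sizes[1L] <- sizes[1L] - 1L
          sizes[p] <- 1L
        }
      }
      cuts <- cumsum(sizes)
      parts$train <- c(parts$train, ids[seq_len(cuts[1])])
      parts$val <- c(parts$val, ids[seq2(cuts[1] + 1L, cuts[2])])
      parts$test <- c(parts$test, ids[seq2(cuts[2] + 1L, cuts[3])])
    }
    parts
  })
  structure(list(folds = folds, seed = as.integer(seed)), class = "split_plan")
}

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# analytic gradients for one bag; returns the loss and a list of gradients
mil_bag_grad <- function(model, X, y) {
  fw <- mil_forward(model, X)
  K <- nrow(fw$H1)
  hy <- model$hyper
  L <- -log(max(fw$p[y + 1L], 1e-12))
  du <- fw$p; du[y + 1L] <- du[y + 1L] - 1          # d loss / d logits
  gWc <- outer(fw$z, du); gbc <- du
  dz <- drop(model$Wc %*% du)
  da <- drop(fw$H1 %*% dz)
  de <- fw$a * (da - sum(fw$a * da))
  gw <- drop(crossprod(fw$M, de))
  dM <- outer(de, model$w)
  if (hy$gated) {
    dT <- dM * fw$Sg
    dS <- dM * fw$Tm
    dpreU <- dS * fw$Sg * (1 - fw$Sg)
    gU <- crossprod(fw$H1, dpreU); gbu <- colSums(dpreU)
  } else {
    dT <- dM
    dpreU <- NULL
    gU <- 0 * model$U; gbu <- 0 * model$bu
  }
  dpreV <- dT * (1 - fw$Tm^2)
  gV <- crossprod(fw$H1, dpreV); gbv <- colSums(dpreV)
  dH1 <- outer(fw$a, dz) + tcrossprod(dpreV, model$V)
  if (hy$gated) dH1 <- dH1 + tcrossprod(dpreU, model$U)

  gWi <- 0 * model$Wi; gbi <- 0 * model$bi
  if (hy$instance_loss_weight > 0) {
    B <- min(hy$B, max(1L, K %/% 2L))
    ord <- order(fw$a, decreasing = TRUE)
    if (y == 1L) {
      sel <- c(ord[seq_len(B)], rev(ord)[seq_len(B)])
      ylab <- c(rep(1L, B), rep(0L, B))
    } else {
      sel <- ord[seq_len(B)]
      ylab <- rep(0L, B)
    }
    Hs <- fw$H1[sel, , drop = FALSE]
    li <- Hs %*% model$Wi + rep(model$bi, each = length(sel))
    pi1 <- 1 / (1 + exp(li[, 1] - li[, 2]))          # P(class 1)
    Pi <- cbind(1 - pi1, pi1)
    Li <- -mean(log(pmax(Pi[cbind(seq_along(sel), ylab + 1L)], 1e-12)))
    dU2 <- Pi
    dU2[cbind(seq_along(sel), ylab + 1L)] <-
      dU2[cbind(seq_along(sel), ylab + 1L)] - 1
    dU2 <- dU2 * (hy$instance_loss_weight / length(sel))
    gWi <- crossprod(Hs, dU2)
    gbi <- colSums(dU2)
    dH1[sel, ] <- dH1[sel, ] + tcrossprod(dU2, model$Wi)
    L <- L + hy$instance_loss_weight * Li
  }

  dH1pre <- dH1 * (fw$H1 > 0)
  gW1 <- crossprod(fw$Xs, dH1pre); gb1 <- colSums(dH1pre)
  list(loss = L,
       grads = list(W1 = gW1, b1 = gb1, V = gV, bv = gbv, U = gU, bu = gbu,
                    w = gw, Wc = gWc, bc = gbc, Wi = gWi, bi = gbi))
}

bag_ce <- function(model, X, y) {
  p <- mil_forward(model, X)$p
  -log(max(p[y + 1L], 1e-12))
}

#' Train an attention-MIL model on feature bags
#'
#' Minimises the bag-level cross-entropy plus `instance_loss_weight` times the
#' instance-clustering loss with Adam, one bag per update, stopping when the
#' validation bag loss has not improved for `patience` epochs and returning
#' the weights from the best validation epoch. Without validation bags the
#' model trains for `max_epochs` epochs.
#'
#' @param bags List of `feature_bag` objects (or `K x D` matrices).
#' @param labels Binary labels (0/1), one per bag.
#' @param val_bags,val_labels Optional validation bags used for early
#'   stopping.
#' @param lr Adam learning rate.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs.
#' @param embed,attn_hidden,gated,instance_loss_weight,B Model
#'   hyperparameters, see [mil_init()].
#' @param seed Seed controlling initialisation and bag shuffling.
#' @return A trained `mil_model` with attributes `history` (per-epoch train
#'   and validation loss) and `best_epoch`.
#' @export
mil_train <- function(bags, labels, val_bags = NULL, val_labels = NULL,
                      lr = 2e-4, max_epochs = 200, patience = 10,
                      embed = 64, attn_hidden = 48, gated = TRUE,
                      instance_loss_weight = 0.3, B = 8, seed = 1L) {
  Xs <- lapply(bags, function(b) if (inherits(b, "feature_bag")) b$features else b)
  y <- as.integer(labels)
  stopifnot(length(Xs) == length(y), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  d <- ncol(Xs[[1]])
  model <- mil_init(d, embed, attn_hidden, gated, instance_loss_weight, B, seed)
  allX <- do.call(rbind, Xs)
  model$feat_mu <- colMeans(allX)
  sds <- apply(allX, 2, stats::sd)
  model$feat_sd <- ifelse(sds > 1e-8, sds, 1)
  Xv <- if (!is.null(val_bags))
    lapply(val_bags, function(b) if (inherits(b, "feature_bag")) b$features else b)

  pnames <- c("W1", "b1", "V", "bv", "U", "bu", "w", "Wc", "bc", "Wi", "bi")
  m <- lapply(pnames, function(nm) 0 * model[[nm]]); names(m) <- pnames
  v <- m
  b1a <- 0.9; b2a <- 0.999; epsa <- 1e-8; t <- 0

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed + 7L)
  best <- list(loss = Inf, model = model, epoch = 0L)
  wait <- 0L
  hist_tr <- hist_val <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(length(Xs))
    tr_loss <- 0
    for (i in ord) {
      gr <- mil_bag_grad(model, Xs[[i]], y[i])
      tr_loss <- tr_loss + gr$loss
      t <- t + 1
      for (nm in pnames) {
        g <- gr$grads[[nm]]
        m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * g
        v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * g^2
        mhat <- m[[nm]] / (1 - b1a^t)
        vhat <- v[[nm]] / (1 - b2a^t)
        model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + epsa)
      }
    }
    hist_tr <- c(hist_tr, tr_loss / length(Xs))
    if (!is.null(Xv)) {
      vl <- mean(mapply(function(X, yy) bag_ce(model, X, yy), Xv, val_labels))
      hist_val <- c(hist_val, vl)
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, model = model, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  out <- if (!is.null(Xv) && best$epoch > 0L) best$model else model
  out$trained <- TRUE
  attr(out, "history") <- list(train = hist_tr, val = hist_val)
  attr(out, "best_epoch") <- if (!is.null(Xv)) best$epoch else length(hist_tr)
  out
}

#' Serialize model weights to a JSON checkpoint
#'
#' Single-file text checkpoint holding all weights plus hyperparameter
#' metadata.
#'
#' @param model A `mil_model`.
#' @param path Output path.
#' @return `path` invisibly, or the restored model.
#' @export
write_mil_checkpoint <- function(model, path) {
  obj <- unclass(model)
  attr(obj, "history") <- NULL
  attr(obj, "best_epoch") <- NULL
  # store matrices as flat column-major vectors with explicit dimensions
  mats <- c("W1", "V", "U", "Wc", "Wi")
  for (nm in mats) obj[[nm]] <- list(dim = dim(obj[[nm]]),
                                     data = as.vector(obj[[nm]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mil_checkpoint
#' @export
read_mil_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("W1", "V", "U", "Wc", "Wi"))
    obj[[nm]] <- matrix(obj[[nm]]$data, obj[[nm]]$dim[1], obj[[nm]]$dim[2])
  obj$hyper$B <- as.integer(obj$hyper$B)
  structure(obj, class = "mil_model")
}
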