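#' Initialise an attention-MIL model
#'
#' The model embeds standardized tile features through a shared ReLU layer,
#' pools them with (optionally gated) attention, and classifies the pooled
#' slide representation with a two-class linear head:
#' \deqn{e_k = w^T(\tanh(V h_k) \odot \sigma(U h_k)),\quad
#'       a = \mathrm{softmax}(e),\quad z = \sum_k a_k h_k}
#' where \eqn{h_k} is the shared embedding of tile \eqn{k}. With
#' `gated = FALSE` the sigmoid gate is dropped, \eqn{e_k = w^T \tanh(V h_k)}.
#' An auxiliary instance-level head provides the clustering loss used during
#' training (binary pseudo-labels on the top-B and bottom-B attention tiles).
#'
#' @param d Input feature dimension.
#' @param embed Width of the shared embedding layer.
#' @param attn_hidden Width of the attention network hidden layer.
#' @param gated Use the gated attention variant (default).
#' @param instance_loss_weight Weight of the instance-clustering loss term;
#'   0 reduces training to pure bag-level cross-entropy.
#' @param B Number of top/bottom attention tiles given pseudo-labels.
#' @param seed Seed for weight initialisation.
#' @return An object of class `mil_model` (untrained).
#' @export
mil_init <- function(d, embed = 64, attn_hidden = 48, gated = TRUE,
                     instance_loss_weight = 0.3, B = 8, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  structure(list(
    W1 = he(d, embed), b1 = numeric(embed),
    V = he(embed, attn_hidden), bv = numeric(attn_hidden),
    U = he(embed, attn_hidden), bu = numeric(attn_hidden),
    w = stats::rnorm(attn_hidden, 0, sqrt(1 / attn_hidden)),
    Wc = he(embed, 2) * 0.1, bc = numeric(2),
    Wi = he(embed, 2) * 0.1, bi = numeric(2),
    feat_mu = numeric(d), feat_sd = rep(1, d),
    hyper = list(d = d, embed = embed, attn_hidden = attn_hidden,
                 gated = gated, instance_loss_weight = instance_loss_weight,
                 B = as.integer(B)),
    trained = FALSE
  ), class = "mil_model")
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# forward pass through the shared layer and attention network for one bag
mil_forward <- function(model, X) {
  if (any(!is.finite(X))) stop("NaN or non-finite values in bag features", call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$feat_mu), 2, model$feat_sd, "/")
  H1 <- pmax(Xs %*% model$W1 + rep(model$b1, each = nrow(Xs)), 0)
  Tm <- tanh(H1 %*% model$V + rep(model$bv, each = nrow(H1)))
  if (model$hyper$gated) {
    Sg <- stats::plogis(H1 %*% model$U + rep(model$bu, each = nrow(H1)))
    M <- Tm * Sg
  } else {
    Sg <- NULL
    M <- Tm
  }
  e <- drop(M %*% model$w)
  a <- softmax_vec(e)
  z <- drop(crossprod(H1, a))
  logits <- drop(z %*% model$Wc) + model$bc
  p <- softmax_vec(logits)
  list(Xs = Xs, H1 = H1, Tm = Tm, Sg = Sg, M = M, e = e, a = a, z = z,
       logits = logits, p = p)
}

#' Attention pooling for one feature bag
#'
#' Computes per-tile attention weights and the attention-weighted slide
#' representation. Weights are positive and sum to one.
#'
#' @param bag A `feature_bag` (or bare `K x D` matrix).
#' @param model A [mil_init()] model (trained or not).
#' @return List with `attention` (length-K vector) and `z` (slide
#'   representation in embedding space).
#' @export
attention_pool <- function(bag, model) {
  X <- if (inherits(bag, "feature_bag")) bag$features else bag
  if (nrow(X) < 1L) stop("bag is empty", call. = FALSE)
  fw <- mil_forward(model, X)
  list(attention = fw$a, z = fw$z)
}

#' Predict the slide-level probability of cognitive impairment
#'
#' @param bag A `feature_bag` (or bare feature matrix).
#' @param model A trained `mil_model`.
#' @return Probability in `[0, 1]` that the slide is from the impaired class.
#' @export
predict_slide <- function(bag, model) {
  if (!isTRUE(model$trained)) stop("model has not been trained", call. = FALSE)
  X <- if (inherits(bag, "feature_bag")) bag$features else bag
  mil_forward(model, X)$p[2]
}
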