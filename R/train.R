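#' Inverse-frequency loss weights for class-imbalanced training
#'
#' Infrequent classes — including the `O` ("None") class when it happens to
#' be rare — receive a higher weight: `w(c) = (total / count(c))^exponent`,
#' normalised to mean 1 within the label space. Classes never observed get
#' the largest observed weight. `exponent = 0` turns balancing off (all
#' weights 1); `exponent = 1` is full inverse-frequency weighting, the
#' default used in training.
#'
#' @param counts named non-negative numeric vector of class counts for one
#'   label space, or a named list of such vectors (one per label space).
#' @param exponent real in `[0, 1]`.
#' @return numeric vector of positive weights with mean 1 (or a list of
#'   such vectors), named like `counts`.
#' @export
compute_loss_weights <- function(counts, exponent = 1) {
  stopifnot(exponent >= 0, exponent <= 1)
  if (is.list(counts)) {
    return(lapply(counts, compute_loss_weights, exponent = exponent))
  }
  if (all(counts == 0)) stop("all class counts are zero")
  if (any(counts < 0)) stop("negative class count")
  total <- sum(counts)
  w <- rep(NA_real_, length(counts))
  pos <- counts > 0
  w[pos] <- (total / counts[pos])^exponent
  if (any(!pos)) w[!pos] <- max(w[pos])
  w <- w / mean(w)
  names(w) <- names(counts)
  w
}

# Adam with global-norm gradient clipping. The heavy update runs in
# compiled code and modifies theta and the moment buffers in place; the
# training loops own those buffers exclusively, so no copy is needed.
adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  cpp_adam_step(theta, grad, state$m, state$v, state$t, lr, beta1, beta2,
                eps, clip)
  list(theta = theta, state = state)
}

#' Multi-head tagging loss
#'
#' Sum over the five heads of class-weighted token-level cross-entropy:
#' non-negative, and zero iff every prediction is a point mass on the gold
#' class. This is the reference R implementation of the objective the
#' compiled training kernel optimises.
#'
#' @param predictions list of probability matrices (tokens x classes), one
#'   per head.
#' @param gold list of 1-based gold class-id vectors, one per head.
#' @param weights list of per-class weight vectors, one per head (defaults
#'   to unit weights).
#' @return scalar loss (summed over tokens and heads).
#' @export
tagging_loss <- function(predictions, gold, weights = NULL) {
  stopifnot(length(predictions) == length(gold))
  total <- 0
  for (h in seq_along(predictions)) {
    P <- predictions[[h]]
    y <- gold[[h]]
    stopifnot(nrow(P) == length(y))
    w <- if (is.null(weights)) rep(1, ncol(P)) else weights[[h]]
    p_gold <- P[cbind(seq_along(y), y)]
    total <- total + sum(-w[y] * log(pmax(p_gold, 1e-300)))
  }
  total
}

#' Pairwise linking loss
#'
#' Class-weighted binary cross-entropy of the link head plus `lambda` times
#' that of the auxiliary same-tag head; zero iff both heads are perfectly
#' confident and correct. Reference R implementation of the compiled
#' objective.
#'
#' @param pred matrix with columns `link`, `same` of predicted
#'   probabilities (or a vector of link probabilities if the auxiliary head
#'   is unused).
#' @param gold_link,gold_same 0/1 gold bits.
#' @param w_link,w_same per-pair weights (class balancing applied by the
#'   caller; default 1).
#' @param lambda weight of the same-tag objective (default 1).
#' @return scalar loss (summed over pairs).
#' @export
linking_loss <- function(pred, gold_link, gold_same = NULL, w_link = 1,
                         w_same = 1, lambda = 1) {
  bce <- function(p, y, w) sum(-w * (y * log(pmax(p, 1e-300)) +
                                     (1 - y) * log(pmax(1 - p, 1e-300))))
  p_link <- if (is.matrix(pred)) pred[, 1] else pred
  total <- bce(p_link, gold_link, w_link)
  if (lambda != 0 && !is.null(gold_same)) {
    p_same <- if (is.matrix(pred)) pred[, 2] else
      stop("same-tag probabilities required when lambda != 0")
    total <- total + lambda * bce(p_same, gold_same, w_same)
  }
  total
}
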