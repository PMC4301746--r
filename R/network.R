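#' The five graded relevance classes, in increasing order of relevance
#'
#' @format Character vector of length 5.
#' @export
RELEVANCE_LABELS <- c("no relevance", "undecided", "could be of relevance",
                      "minor quality doubts", "fully agree")

#' Map a graded relevance label to a training target
#'
#' The five ordered classes are spaced equally on `[0,1]`:
#' "no relevance" -> 0, "undecided" -> 0.25, "could be of relevance" -> 0.5,
#' "minor quality doubts" -> 0.75, "fully agree" -> 1.
#'
#' @param label One of [RELEVANCE_LABELS].
#' @return A real in `[0,1]`.
#' @export
label_to_target <- function(label) {
  i <- match(label, RELEVANCE_LABELS)
  if (anyNA(i))
    stop("unknown relevance label '", label[which(is.na(i))[1]],
         "'; valid labels: ", paste(RELEVANCE_LABELS, collapse = ", "))
  (i - 1) / 4
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize the relevance ranker network
#'
#' A feed-forward network with 11 input neurons, hidden layers of 16 and 8
#' neurons, one output neuron, and sigmoid activation at every layer. All
#' weights and biases are drawn uniformly from `[-0.5, 0.5]` by a seeded
#' generator, so initialization is deterministic per seed.
#'
#' @param seed Integer RNG seed.
#' @return An object of class `ranker_network` with weight matrices `W1`
#'   (16x11), `W2` (8x16), `W3` (1x8) and bias vectors `b1`, `b2`, `b3`.
#' @export
init_network <- function(seed = 0L) {
  sizes <- c(11L, 16L, 8L, 1L)
  with_seed(seed, {
    W1 <- matrix(stats::runif(16 * 11, -0.5, 0.5), 16, 11)
    b1 <- stats::runif(16, -0.5, 0.5)
    W2 <- matrix(stats::runif(8 * 16, -0.5, 0.5), 8, 16)
    b2 <- stats::runif(8, -0.5, 0.5)
    W3 <- matrix(stats::runif(1 * 8, -0.5, 0.5), 1, 8)
    b3 <- stats::runif(1, -0.5, 0.5)
    structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3,
                   sizes = sizes, seed = as.integer(seed), trained_epochs = 0L),
              class = "ranker_network")
  })
}

#' @export
print.ranker_network <- function(x, ...) {
  cat("<ranker_network> 11-16-8-1, sigmoid; seed", x$seed, ";",
      x$trained_epochs, "training epochs\n")
  invisible(x)
}

# Forward pass on a feature matrix X (n x 11); returns activations per layer.
nn_forward <- function(network, X) {
  A1 <- sigmoid(X %*% t(network$W1) +
                matrix(network$b1, nrow(X), length(network$b1), byrow = TRUE))
  A2 <- sigmoid(A1 %*% t(network$W2) +
                matrix(network$b2, nrow(X), length(network$b2), byrow = TRUE))
  A3 <- sigmoid(A2 %*% t(network$W3) +
                matrix(network$b3, nrow(X), length(network$b3), byrow = TRUE))
  list(A1 = A1, A2 = A2, A3 = A3)
}

#' Predict relevance scores from feature vectors
#'
#' Computes `sigma(W3 sigma(W2 sigma(W1 x + b1) + b2) + b3)`; the output is
#' strictly inside (0,1).
#'
#' @param network A `ranker_network`.
#' @param features A length-11 feature vector, or an `n x 11` matrix of
#'   feature vectors (rows are hits).
#' @return Numeric vector of scores in (0,1).
#' @export
predict_relevance <- function(network, features) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (ncol(X) != 11L)
    stop("feature input must have 11 components, got ", ncol(X))
  as.numeric(nn_forward(network, X)$A3)
}

#' @export
predict.ranker_network <- function(object, features, ...) {
  predict_relevance(object, features)
}

# Mean squared error and its gradients with respect to all parameters.
# Returns list(loss, grads) where grads mirrors the network fields.
nn_loss_grads <- function(network, X, y) {
  n <- nrow(X)
  fwd <- nn_forward(network, X)
  err <- fwd$A3 - y                              # n x 1
  loss <- mean(err^2)

  d3 <- (2 / n) * err * fwd$A3 * (1 - fwd$A3)    # n x 1
  gW3 <- t(d3) %*% fwd$A2                        # 1 x 8
  gb3 <- colSums(d3)
  d2 <- (d3 %*% network$W3) * fwd$A2 * (1 - fwd$A2)   # n x 8
  gW2 <- t(d2) %*% fwd$A1                        # 8 x 16
  gb2 <- colSums(d2)
  d1 <- (d2 %*% network$W2) * fwd$A1 * (1 - fwd$A1)   # n x 16
  gW1 <- t(d1) %*% X                             # 16 x 11
  gb1 <- colSums(d1)

  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3))
}

#' Train the ranker network on graded feedback
#'
#' Full-batch gradient descent on mean squared error with backpropagation.
#' Training is deterministic given the starting network and configuration;
#' there is no stochastic shuffling.
#'
#' @param network A `ranker_network`.
#' @param features An `n x 11` matrix (or data frame) of feature vectors.
#' @param targets Numeric vector of length `n` with values in `[0,1]`
#'   (see [label_to_target()]).
#' @param learning_rate Step size (default 0.5).
#' @param epochs Number of full-batch updates (default 1500).
#' @return The trained `ranker_network`.
#' @export
train_network <- function(network, features, targets,
                          learning_rate = 0.5, epochs = 1500L) {
  if (length(targets) == 0L) return(network)
  X <- as.matrix(features)
  if (ncol(X) != 11L) stop("feature matrix must have 11 columns")
  if (nrow(X) != length(targets))
    stop("features and targets disagree in length")
  if (any(targets < 0 | targets > 1)) stop("targets must lie in [0,1]")
  y <- matrix(targets, ncol = 1)

  initial <- nn_loss_grads(network, X, y)$loss
  for (e in seq_len(epochs)) {
    lg <- nn_loss_grads(network, X, y)
    if (!is.finite(lg$loss)) stop("non-finite training loss at epoch ", e)
    for (p in c("W1", "b1", "W2", "b2", "W3", "b3"))
      network[[p]] <- network[[p]] - learning_rate * lg$grads[[p]]
  }
  final <- nn_loss_grads(network, X, y)$loss
  if (!is.finite(final)) stop("non-finite training loss after training")
  if (final > initial)
    warning("training loss increased (", signif(initial, 4), " -> ",
            signif(final, 4), "); consider a smaller learning_rate")
  network$trained_epochs <- network$trained_epochs + as.integer(epochs)
  network
}

#' Rank hits by predicted relevance
#'
#' @param network A `ranker_network`.
#' @param hits A data frame or list with one feature vector per hit; either
#'   a data frame with a `record_id` column and the 11 feature columns, or
#'   a named list record_id -> feature vector.
#' @return A data frame with columns `record_id`, `score`, and the 11
#'   feature columns, sorted by descending score, ties broken by ascending
#'   `record_id`.
#' @export
rank_hits <- function(network, hits) {
  if (is.data.frame(hits)) {
    ids <- hits$record_id
    X <- as.matrix(hits[, FEATURE_NAMES, drop = FALSE])
  } else {
    ids <- names(hits)
    X <- do.call(rbind, hits)
  }
  if (length(ids) == 0L)
    return(cbind(data.frame(record_id = character(0), score = numeric(0)),
                 as.data.frame(matrix(numeric(0), 0, 11,
                                      dimnames = list(NULL, FEATURE_NAMES)))))
  scores <- predict_relevance(network, X)
  ord <- order(-scores, ids)
  out <- data.frame(record_id = ids[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  feat <- as.data.frame(X[ord, , drop = FALSE])
  names(feat) <- FEATURE_NAMES
  rownames(out) <- rownames(feat) <- NULL
  cbind(out, feat)
}

#' Save network weights as a JSON profile
#'
#' Shapes, row-major weight values, the initialization seed and training
#' metadata are stored in a single JSON document; user profiles are named
#' weight files.
#'
#' @param network A `ranker_network`.
#' @param path Output path.
#' @export
save_network <- function(network, path) {
  # weights are rendered with %.17g so every double round-trips bit-exactly
  num <- function(x) paste0("[", paste(sprintf("%.17g", x), collapse = ","),
                            "]")
  int <- function(x) paste0("[", paste(as.integer(x), collapse = ","), "]")
  doc <- sprintf(paste0(
    '{"format":"bioranker-network","version":1,"sizes":%s,"seed":%d,',
    '"trained_epochs":%d,"W1":%s,"b1":%s,"W2":%s,"b2":%s,"W3":%s,"b3":%s}'),
    int(network$sizes), network$seed, network$trained_epochs,
    num(t(network$W1)), num(network$b1), num(t(network$W2)),
    num(network$b2), num(t(network$W3)), num(network$b3))
  writeLines(doc, path)
  invisible(path)
}

#' Load a network profile saved by [save_network()]
#'
#' @param path Path to a JSON profile.
#' @return A `ranker_network`.
#' @export
load_network <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$format, "bioranker-network"))
    stop("not a network profile: ", path)
  structure(
    list(W1 = matrix(doc$W1, 16, 11, byrow = TRUE), b1 = doc$b1,
         W2 = matrix(doc$W2, 8, 16, byrow = TRUE), b2 = doc$b2,
         W3 = matrix(doc$W3, 1, 8, byrow = TRUE), b3 = doc$b3,
         sizes = as.integer(doc$sizes), seed = as.integer(doc$seed),
         trained_epochs = as.integer(doc$trained_epochs)),
    class = "ranker_network"
  )
}
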