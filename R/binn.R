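#' @keywords internal
"_PACKAGE"

# Canonical class labels of the four-way disease-state problem, in fixed
# index order. Arbitrary label sets are accepted by binn(); this order is
# used whenever the labels are a subset of these four.
BINN_CLASSES <- c("cancer", "CP-CID", "NCP-CID", "normal")

#' Canonical class labels
#'
#' The fixed four-class label order used for the disease-state problem:
#' cancer, CP-CID (cancer-prone chronic inflammatory disease), NCP-CID
#' (non-cancer-prone chronic inflammatory disease), normal.
#'
#' @return Character vector of length 4.
#' @export
binn_classes <- function() BINN_CLASSES

# --- activations -----------------------------------------------------------

.binn_activation <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0),
                df = function(z) (z > 0) * 1),
    tanh = list(f = tanh,
                df = function(z) 1 - tanh(z)^2),
    identity = list(f = identity,
                    df = function(z) array(1, dim = dim(z))),
    stop("Unknown activation: ", name, call. = FALSE)
  )
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- preprocessing ---------------------------------------------------------

#' Fit the expression preprocessing transform
#'
#' Applies \code{log2(v + 1)} to non-negative TPM-like values, then centres
#' and scales each gene using statistics of the supplied (training) matrix.
#' Genes constant across the training samples get a unit scale so they map
#' to zero rather than NaN.
#'
#' @param x Samples-by-genes numeric matrix, values >= 0.
#' @return An object of class \code{binn_preprocess} holding per-gene
#'   \code{center} and \code{scale}; apply it with
#'   [apply_preprocess()].
#' @export
fit_preprocess <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Expression values must be non-negative", call. = FALSE)
  lx <- log2(x + 1)
  center <- colMeans(lx)
  scale <- apply(lx, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale, genes = colnames(x)),
            class = "binn_preprocess")
}

#' Apply a fitted preprocessing transform
#'
#' @param pp A \code{binn_preprocess} from [fit_preprocess()].
#' @param x Samples-by-genes matrix on the raw (TPM-like) scale.
#' @return The transformed matrix: \code{log2(x+1)}, centred and scaled by
#'   the training-fold statistics stored in \code{pp}.
#' @export
apply_preprocess <- function(pp, x) {
  stopifnot(inherits(pp, "binn_preprocess"))
  x <- as.matrix(x)
  if (any(x < 0)) stop("Expression values must be non-negative", call. = FALSE)
  lx <- log2(x + 1)
  out <- sweep(sweep(lx, 2, pp$center, "-"), 2, pp$scale, "/")
  out
}

# --- forward / backward ----------------------------------------------------

# Batched forward pass. X: n x n_genes in network-input space.
# Returns activations H (list, H[[1]] = input), pre-activations Z, logits,
# probabilities.
.binn_forward <- function(object, X, keep = FALSE) {
  act <- .binn_activation(object$activation)
  L <- length(object$W)
  H <- vector("list", L + 1L)
  Z <- vector("list", L)
  H[[1]] <- X
  for (l in seq_len(L)) {
    M <- object$masks$masks[[l]] * object$W[[l]]
    Z[[l]] <- H[[l]] %*% t(M) + matrix(object$b[[l]], nrow(X),
                                       length(object$b[[l]]), byrow = TRUE)
    H[[l + 1L]] <- act$f(Z[[l]])
  }
  logits <- H[[L + 1L]] %*% t(object$W_out) +
    matrix(object$b_out, nrow(X), length(object$b_out), byrow = TRUE)
  shift <- logits - apply(logits, 1, max)
  prob <- exp(shift) / rowSums(exp(shift))
  out <- list(logits = logits, prob = prob)
  if (keep) { out$H <- H; out$Z <- Z }
  out
}

# Gradient of one scalar output per sample w.r.t. the network input.
# X: n x p; class: single class index; target: "logit" or "prob".
# Returns n x p matrix of d target_class / d x.
.binn_input_grad <- function(object, X, class, target = "logit") {
  act <- .binn_activation(object$activation)
  fw <- .binn_forward(object, X, keep = TRUE)
  L <- length(object$W)
  K <- length(object$b_out)
  # seed gradient at the logits
  if (target == "logit") {
    dlogit <- matrix(0, nrow(X), K)
    dlogit[, class] <- 1
  } else {
    p <- fw$prob
    dlogit <- -p * p[, class]           # d p_c / d logit_k = p_c(1[k=c]-p_k)
    dlogit[, class] <- dlogit[, class] + p[, class]
  }
  delta <- dlogit %*% object$W_out      # n x n_last (grad wrt H[[L+1]])
  for (l in rev(seq_len(L))) {
    delta <- (delta * act$df(fw$Z[[l]])) %*% (object$masks$masks[[l]] * object$W[[l]])
  }
  delta
}

#' Construct a masked network from explicit weights
#'
#' Low-level constructor assembling a model object from mask matrices and
#' hand-set (or externally trained) weights, without any preprocessing
#' attached. Mainly useful for small worked examples and for testing
#' attribution methods against closed-form cases.
#'
#' @param masks A \code{mask_stack}.
#' @param W List of weight matrices, one per mask, same shapes.
#' @param b List of bias vectors, one per hidden layer.
#' @param W_out Dense output weight matrix, \code{n_classes} rows.
#' @param b_out Output bias vector.
#' @param activation One of \code{"relu"}, \code{"tanh"}, \code{"identity"}.
#' @param classes Optional class labels (defaults to \code{class1..K}).
#' @return A \code{binn} object.
#' @export
binn_network <- function(masks, W, b, W_out, b_out, activation = "relu",
                         classes = NULL) {
  validate_masks(masks)
  stopifnot(length(W) == length(masks$masks), length(b) == length(masks$masks))
  for (l in seq_along(W)) {
    stopifnot(all(dim(W[[l]]) == dim(masks$masks[[l]])),
              length(b[[l]]) == nrow(masks$masks[[l]]))
  }
  W_out <- as.matrix(W_out)
  stopifnot(ncol(W_out) == nrow(masks$masks[[length(masks$masks)]]),
            length(b_out) == nrow(W_out))
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(W_out)))
  structure(list(masks = masks, W = W, b = b, W_out = W_out, b_out = b_out,
                 activation = activation, classes = classes,
                 genes = colnames(masks$masks[[1]]), preprocess = NULL,
                 loss = numeric(0), config = list(), seed = NULL),
            class = "binn")
}

# Glorot-uniform initialization on unmasked entries, zeros elsewhere.
.binn_init <- function(masks, n_classes) {
  W <- vector("list", length(masks$masks))
  b <- vector("list", length(masks$masks))
  for (l in seq_along(masks$masks)) {
    m <- masks$masks[[l]]
    lim <- sqrt(6 / (nrow(m) + ncol(m)))
    W[[l]] <- matrix(stats::runif(length(m), -lim, lim), nrow(m), ncol(m),
                     dimnames = dimnames(m)) * m
    b[[l]] <- stats::setNames(numeric(nrow(m)), rownames(m))
  }
  last <- nrow(masks$masks[[length(masks$masks)]])
  lim <- sqrt(6 / (n_classes + last))
  W_out <- matrix(stats::runif(n_classes * last, -lim, lim), n_classes, last)
  list(W = W, b = b, W_out = W_out, b_out = numeric(n_classes))
}

.binn_levels <- function(y, class_levels = NULL) {
  y <- as.character(y)
  if (!is.null(class_levels)) {
    bad <- setdiff(unique(y), class_levels)
    if (length(bad)) stop("Labels outside class_levels: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    return(class_levels)
  }
  if (all(unique(y) %in% BINN_CLASSES)) return(BINN_CLASSES)
  sort(unique(y))
}

#' Fit a biologically informed sparse neural network
#'
#' Trains a multi-layer classifier whose hidden connectivity is restricted by
#' binary mask matrices derived from a gene/pathway hierarchy: at every
#' forward pass the effective hidden weights are the Hadamard product of the
#' mask and the free weight matrix, so masked positions can never influence
#' the output, during or after training. Hidden layers use the chosen
#' activation; the output head is dense with a softmax over the classes.
#' Training minimizes mean cross-entropy with the Adam optimizer over
#' shuffled mini-batches.
#'
#' Inputs are expected on a non-negative TPM-like scale; by default they are
#' transformed with \code{log2(v+1)} followed by per-gene standardization
#' using training statistics (stored in the model and reused by
#' [predict.binn()] on new data).
#'
#' @param x Samples-by-genes numeric matrix with gene column names matching
#'   the mask gene layer. Genes absent from the masks are dropped with a
#'   warning; mask genes missing from \code{x} are an error.
#' @param y Class labels, one per row of \code{x}; at least two distinct
#'   classes. Labels drawn from [binn_classes()] use that fixed order.
#' @param masks A \code{mask_stack} from [build_masks()].
#' @param epochs Number of passes over the data (default 500).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Adam learning rate (default 0.001).
#' @param activation Hidden activation: \code{"relu"} (default),
#'   \code{"tanh"}, or \code{"identity"}.
#' @param seed Integer seed controlling initialization and batch shuffling;
#'   identical seed and data give bitwise-identical fits.
#' @param preprocess Apply the log2 + z-scale input transform (default TRUE).
#' @param class_levels Optional explicit class order.
#' @param verbose Print the mean loss every 50 epochs.
#' @return An object of class \code{binn} with the fitted weights, the mask
#'   stack, preprocessing statistics, per-epoch mean training loss
#'   (\code{$loss}), and the training configuration.
#' @seealso [predict.binn()], [binn_cv()], [integrated_gradients()]
#' @export
binn <- function(x, y, masks, epochs = 500, batch_size = 32, lr = 0.001,
                 activation = c("relu", "tanh", "identity"), seed = 1L,
                 preprocess = TRUE, class_levels = NULL, verbose = FALSE) {
  activation <- match.arg(activation)
  validate_masks(masks)
  x <- as.matrix(x)
  genes <- colnames(masks$masks[[1]])
  if (is.null(colnames(x))) {
    if (ncol(x) != length(genes)) stop("x has no gene names and wrong width",
                                       call. = FALSE)
    colnames(x) <- genes
  }
  missing <- setdiff(genes, colnames(x))
  if (length(missing)) stop("Genes required by the masks are missing from x: ",
                            paste(utils::head(missing, 5), collapse = ", "),
                            call. = FALSE)
  extra <- setdiff(colnames(x), genes)
  if (length(extra)) {
    warning(length(extra), " genes in x are absent from the hierarchy and were dropped")
  }
  x <- x[, genes, drop = FALSE]
  if (anyDuplicated(rownames(x))) stop("Duplicate sample identifiers", call. = FALSE)

  levs <- .binn_levels(y, class_levels)
  yf <- factor(as.character(y), levels = levs)
  if (length(yf) != nrow(x)) stop("Length of y does not match rows of x", call. = FALSE)
  present <- levs[levs %in% yf]
  if (length(present) < 2L) stop("Need at least 2 classes present in y", call. = FALSE)
  K <- length(levs)
  yi <- as.integer(yf)
  Y <- matrix(0, nrow(x), K); Y[cbind(seq_len(nrow(x)), yi)] <- 1

  pp <- NULL
  Xn <- x
  if (isTRUE(preprocess)) {
    pp <- fit_preprocess(x)
    Xn <- apply_preprocess(pp, x)
  }

  model <- .with_seed(seed, {
    par <- .binn_init(masks, K)
    obj <- structure(list(masks = masks, W = par$W, b = par$b,
                          W_out = par$W_out, b_out = par$b_out,
                          activation = activation, classes = levs,
                          genes = genes, preprocess = pp,
                          loss = numeric(0),
                          config = list(epochs = epochs, batch_size = batch_size,
                                        lr = lr, activation = activation,
                                        preprocess = isTRUE(preprocess)),
                          seed = seed),
                     class = "binn")
    if (epochs > 0) obj <- .binn_train(obj, Xn, Y, epochs, batch_size, lr, verbose)
    obj
  })
  model
}

# Adam training loop over mini-batches; records per-epoch mean loss.
.binn_train <- function(object, X, Y, epochs, batch_size, lr,
                        verbose = FALSE, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  act <- .binn_activation(object$activation)
  L <- length(object$W)
  n <- nrow(X)
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  par_names <- c(paste0("W", seq_len(L)), paste0("b", seq_len(L)), "W_out", "b_out")
  get_par <- function(nm) {
    if (nm == "W_out") object$W_out
    else if (nm == "b_out") object$b_out
    else if (startsWith(nm, "W")) object$W[[as.integer(substring(nm, 2))]]
    else object$b[[as.integer(substring(nm, 2))]]
  }
  set_par <- function(nm, v) {
    if (nm == "W_out") object$W_out <<- v
    else if (nm == "b_out") object$b_out <<- v
    else if (startsWith(nm, "W")) object$W[[as.integer(substring(nm, 2))]] <<- v
    else object$b[[as.integer(substring(nm, 2))]] <<- v
  }
  m_state <- lapply(par_names, function(nm) zero_like(get_par(nm)))
  v_state <- lapply(par_names, function(nm) zero_like(get_par(nm)))
  names(m_state) <- names(v_state) <- par_names
  step <- 0L
  losses <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      nb <- nrow(Xb)
      fw <- .binn_forward(object, Xb, keep = TRUE)
      p <- pmax(fw$prob, 1e-12)
      loss <- -sum(Yb * log(p)) / nb
      if (!is.finite(loss)) {
        stop("Training diverged: non-finite loss at epoch ", ep,
             " (try a smaller learning rate)", call. = FALSE)
      }
      batch_losses[bi] <- loss

      grads <- list()
      dlogit <- (fw$prob - Yb) / nb            # n x K
      grads$W_out <- t(dlogit) %*% fw$H[[L + 1L]]
      grads$b_out <- colSums(dlogit)
      delta <- dlogit %*% object$W_out          # grad wrt H[[L+1]]
      for (l in rev(seq_len(L))) {
        dz <- delta * act$df(fw$Z[[l]])         # n x n_{l+1}
        grads[[paste0("W", l)]] <- (t(dz) %*% fw$H[[l]]) * object$masks$masks[[l]]
        grads[[paste0("b", l)]] <- colSums(dz)
        delta <- dz %*% (object$masks$masks[[l]] * object$W[[l]])
      }

      step <- step + 1L
      for (nm in par_names) {
        g <- grads[[nm]]
        m_state[[nm]] <- beta1 * m_state[[nm]] + (1 - beta1) * g
        v_state[[nm]] <- beta2 * v_state[[nm]] + (1 - beta2) * g^2
        mhat <- m_state[[nm]] / (1 - beta1^step)
        vhat <- v_state[[nm]] / (1 - beta2^step)
        set_par(nm, get_par(nm) - lr * mhat / (sqrt(vhat) + eps))
      }
    }
    losses[ep] <- mean(batch_losses)
    if (verbose && ep %% 50 == 0) {
      message(sprintf("epoch %d: mean loss %.4f", ep, losses[ep]))
    }
  }
  object$loss <- losses
  object
}

#' Predict from a fitted masked network
#'
#' @param object A \code{binn} model.
#' @param newdata Samples-by-genes matrix on the same (raw) scale as the
#'   training data; the model's stored preprocessing is applied. Columns are
#'   aligned by gene name when present.
#' @param type \code{"class"} (default), \code{"prob"}, or \code{"logit"}.
#' @param ... Unused.
#' @return A factor of predicted classes, or a samples-by-classes numeric
#'   matrix of probabilities / logits. Argmax ties resolve to the lowest
#'   class index.
#' @export
predict.binn <- function(object, newdata, type = c("class", "prob", "logit"),
                         ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$genes, colnames(X))
    if (length(missing)) stop("newdata is missing genes: ",
                              paste(utils::head(missing, 5), collapse = ", "),
                              call. = FALSE)
    X <- X[, object$genes, drop = FALSE]
  } else if (ncol(X) != length(object$genes)) {
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$genes), call. = FALSE)
  }
  if (!is.null(object$preprocess)) X <- apply_preprocess(object$preprocess, X)
  fw <- .binn_forward(object, X)
  out <- switch(type, logit = fw$logits, prob = fw$prob,
                class = factor(object$classes[max.col(fw$prob, ties.method = "first")],
                               levels = object$classes))
  if (type != "class") {
    dimnames(out) <- list(rownames(newdata), object$classes)
  }
  out
}

#' @export
print.binn <- function(x, ...) {
  widths <- c(length(x$genes), vapply(x$masks$masks, nrow, numeric(1)))
  cat("Biologically informed sparse network\n")
  cat("  architecture:", paste(widths, collapse = " -> "), "->",
      length(x$classes), "classes (dense head)\n")
  cat("  activation:", x$activation, "\n")
  cat("  parameters:", parameter_count(x$masks, length(x$classes)),
      sprintf("(dense equivalent: %d)\n",
              parameter_count(.dense_stack(x$masks), length(x$classes))))
  if (length(x$loss)) {
    cat(sprintf("  trained %d epochs; final mean loss %.4f\n",
                length(x$loss), x$loss[length(x$loss)]))
  } else cat("  untrained (initialized weights)\n")
  invisible(x)
}

# All-ones mask stack with the same shapes (for parameter comparisons).
.dense_stack <- function(ms) {
  structure(list(masks = lapply(ms$masks, function(m) {
    array(1, dim = dim(m), dimnames = dimnames(m))
  })), class = "mask_stack")
}

#' @export
summary.binn <- function(object, ...) {
  print(object)
  cat("  config: epochs =", object$config$epochs %||% NA,
      "batch =", object$config$batch_size %||% NA,
      "lr =", object$config$lr %||% NA,
      "seed =", object$seed %||% NA, "\n")
  nnz <- sum(vapply(object$masks$masks, sum, numeric(1)))
  total <- sum(vapply(object$masks$masks, length, numeric(1)))
  cat(sprintf("  hidden connectivity: %d of %d possible edges (%.1f%%)\n",
              nnz, total, 100 * nnz / total))
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract effective model weights
#'
#' Returns the effective (mask-multiplied) hidden weight matrices, the
#' hidden biases, and the dense output head. Masked positions are exactly
#' zero by construction.
#'
#' @param object A \code{binn} model.
#' @param ... Unused.
#' @return A list with \code{hidden} (list of effective weight matrices),
#'   \code{biases}, \code{W_out}, \code{b_out}.
#' @export
coef.binn <- function(object, ...) {
  list(hidden = lapply(seq_along(object$W),
                       function(l) object$masks$masks[[l]] * object$W[[l]]),
       biases = object$b, W_out = object$W_out, b_out = object$b_out)
}
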