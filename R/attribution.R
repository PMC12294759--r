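#' Attribution configuration
#'
#' Bundles the knobs shared by the attribution methods: the baseline input,
#' the path-integral step counts, the surrogate-model query budget for the
#' Shapley approximation, the quadrature scheme, and whether the attributed
#' scalar is the pre-softmax logit (default, numerically stable) or the
#' softmax probability of the target class.
#'
#' @param baseline Baseline input vector in the model's input space
#'   (default: all zeros, matched to the gene count at call time).
#' @param m_ig Integration steps for integrated gradients (default 800).
#' @param m_con Integration steps for conductance (default 800).
#' @param m_shapley Model-query budget for the Shapley approximation
#'   (default 800).
#' @param scheme Path quadrature: \code{"gauss-legendre"} (default) uses
#'   Gauss–Legendre nodes and weights on [0, 1]; \code{"riemann-right"} uses
#'   the right-endpoint Riemann sum.
#' @param target \code{"logit"} (default) or \code{"prob"}.
#' @return A list of class \code{attribution_config}.
#' @export
attribution_config <- function(baseline = NULL, m_ig = 800, m_con = 800,
                               m_shapley = 800,
                               scheme = c("gauss-legendre", "riemann-right"),
                               target = c("logit", "prob")) {
  stopifnot(m_ig >= 1, m_con >= 1, m_shapley >= 1)
  structure(list(baseline = baseline, m_ig = as.integer(m_ig),
                 m_con = as.integer(m_con), m_shapley = as.integer(m_shapley),
                 scheme = match.arg(scheme), target = match.arg(target)),
            class = "attribution_config")
}

# Quadrature nodes/weights on [0,1].
.path_nodes <- function(m, scheme) {
  if (scheme == "gauss-legendre") {
    if (m == 1L) return(list(alpha = 0.5, w = 1))   # degenerate rule: midpoint
    gl <- pracma::gaussLegendre(m, 0, 1)
    list(alpha = gl$x, w = gl$w)
  } else {
    list(alpha = seq_len(m) / m, w = rep(1 / m, m))
  }
}

.class_index <- function(object, class) {
  if (is.character(class) || is.factor(class)) {
    i <- match(as.character(class), object$classes)
    if (is.na(i)) stop("Unknown class: ", class, "; model classes are ",
                       paste(object$classes, collapse = ", "), call. = FALSE)
    return(i)
  }
  ci <- as.integer(class)
  if (ci < 1L || ci > length(object$classes)) stop("Class index out of range",
                                                   call. = FALSE)
  ci
}

.resolve_baseline <- function(cfg, p) {
  b <- cfg$baseline %||% numeric(p)
  if (length(b) != p) stop("Baseline length ", length(b),
                           " does not match input length ", p, call. = FALSE)
  b
}

# Scalar target F evaluated at a batch of network-space inputs.
.binn_target <- function(object, X, class, target) {
  fw <- .binn_forward(object, X)
  if (target == "logit") fw$logits[, class] else fw$prob[, class]
}

#' Integrated gradients attribution
#'
#' Attributes the target-class output of a trained model to each input gene
#' by integrating the gradient of the output along the straight path from
#' the baseline to the input:
#' \deqn{IG_i = (x_i - x'_i) \int_0^1 \partial F(x' + \alpha(x - x')) /
#' \partial x_i \, d\alpha}
#' approximated by \code{m_ig} quadrature points. The right-endpoint Riemann
#' scheme reproduces the classic discrete sum; the default Gauss–Legendre
#' scheme converges faster for smooth models. Both are exact for linear
#' models at any number of steps. Attributions satisfy completeness:
#' their sum converges to \eqn{F(x) - F(x')} as the step count grows.
#'
#' @param object A \code{binn} model.
#' @param x Input vector in the model's network-input space (i.e. already
#'   preprocessed if the model has a preprocessing transform); use
#'   [attribute_dataset()] to go from raw expression.
#' @param class Target class (index or label).
#' @param config An [attribution_config()].
#' @return Named numeric vector of per-gene attributions.
#' @export
integrated_gradients <- function(object, x, class, config = attribution_config()) {
  stopifnot(inherits(object, "binn"))
  class <- .class_index(object, class)
  x <- as.numeric(x)
  p <- length(object$genes)
  if (length(x) != p) stop("Input length ", length(x), " != gene count ", p,
                           call. = FALSE)
  baseline <- .resolve_baseline(config, p)
  diff <- x - baseline
  out <- stats::setNames(numeric(p), object$genes)
  if (all(diff == 0)) return(out)
  nd <- .path_nodes(config$m_ig, config$scheme)
  points <- matrix(baseline, length(nd$alpha), p, byrow = TRUE) +
    outer(nd$alpha, diff)
  G <- .binn_input_grad(object, points, class, config$target)
  out[] <- diff * colSums(G * nd$w)
  out
}

#' Conductance of hidden neurons
#'
#' Extends integrated gradients to hidden neurons: the total conductance of
#' a neuron is the portion of the input-to-output attribution that flows
#' through it,
#' \deqn{Cond^y = \sum_i (x_i - x'_i) \int_0^1 \frac{\partial F}{\partial y}
#' \frac{\partial y}{\partial x_i} d\alpha,}
#' computed here as a quadrature over path points of the output gradient at
#' the neuron times the directional derivative of the neuron along the
#' path. Summed over all neurons of one hidden layer, conductance satisfies
#' the same completeness property as integrated gradients
#' (\eqn{\sum_y Cond^y \approx F(x) - F(x')}), and summing over any named
#' neuron set (e.g. the pathways of one superpathway) gives the set's
#' conductance exactly.
#'
#' @param object A \code{binn} model.
#' @param x Input vector in network-input space.
#' @param layer Hidden layer index (1 = first pathway layer). The output
#'   layer is not a valid target.
#' @param class Target class (index or label).
#' @param config An [attribution_config()] (\code{m_con} steps are used).
#' @param sets Optional named list of neuron-name vectors to aggregate over.
#' @return An object of class \code{conductance_profile}: per-neuron total
#'   conductance (\code{$values}), the layer index, the directly evaluated
#'   output difference \code{$f_diff} = F(x) - F(x'), and \code{$set_values}
#'   when \code{sets} is given.
#' @export
conductance <- function(object, x, layer, class, config = attribution_config(),
                        sets = NULL) {
  stopifnot(inherits(object, "binn"))
  L <- length(object$W)
  if (!(layer %in% seq_len(L))) {
    stop("Conductance is defined for hidden neurons; layer must be in 1..",
         L, " (the output layer is not valid)", call. = FALSE)
  }
  class <- .class_index(object, class)
  x <- as.numeric(x)
  p <- length(object$genes)
  stopifnot(length(x) == p)
  baseline <- .resolve_baseline(config, p)
  diff <- x - baseline
  act <- .binn_activation(object$activation)
  neurons <- rownames(object$masks$masks[[layer]])

  nd <- .path_nodes(config$m_con, config$scheme)
  m <- length(nd$alpha)
  points <- matrix(baseline, m, p, byrow = TRUE) + outer(nd$alpha, diff)
  fw <- .binn_forward(object, points, keep = TRUE)

  # dF/dh_layer by backprop from the logits down to the chosen layer
  K <- length(object$b_out)
  if (config$target == "logit") {
    dlogit <- matrix(0, m, K); dlogit[, class] <- 1
  } else {
    pr <- fw$prob
    dlogit <- -pr * pr[, class]
    dlogit[, class] <- dlogit[, class] + pr[, class]
  }
  delta <- dlogit %*% object$W_out
  if (L > layer) {
    for (l in rev(seq(layer + 1L, L))) {
      delta <- (delta * act$df(fw$Z[[l]])) %*%
        (object$masks$masks[[l]] * object$W[[l]])
    }
  }

  # directional derivative of h_layer along (x - x') at each path point
  U <- matrix(diff, m, p, byrow = TRUE)
  for (l in seq_len(layer)) {
    U <- (U %*% t(object$masks$masks[[l]] * object$W[[l]])) * act$df(fw$Z[[l]])
  }

  vals <- stats::setNames(colSums(delta * U * nd$w), neurons)
  f_diff <- .binn_target(object, matrix(x, 1), class, config$target) -
    .binn_target(object, matrix(baseline, 1), class, config$target)

  set_values <- NULL
  if (!is.null(sets)) {
    set_values <- vapply(sets, function(nm) sum(vals[nm]), numeric(1))
  }
  structure(list(values = vals, layer = layer, class = class,
                 f_diff = as.numeric(f_diff), set_values = set_values),
            class = "conductance_profile")
}

#' @export
print.conductance_profile <- function(x, ...) {
  cat(sprintf("Conductance profile: layer %d, %d neurons\n",
              x$layer, length(x$values)))
  cat(sprintf("  sum of conductances: %.6f; F(x) - F(x'): %.6f\n",
              sum(x$values), x$f_diff))
  top <- utils::head(sort(abs(x$values), decreasing = TRUE), 5)
  cat("  top |conductance|:", paste(names(top), collapse = ", "), "\n")
  invisible(x)
}

# All size-s subsets of 1..M as a binary matrix (rows).
.coalitions_of_size <- function(M, s) {
  cmb <- utils::combn(M, s)
  Z <- matrix(0, ncol(cmb), M)
  for (j in seq_len(ncol(cmb))) Z[j, cmb[, j]] <- 1
  Z
}

#' Shapley-value attribution via weighted linear regression
#'
#' Approximates Shapley values with the kernel method: coalitions of genes
#' are sampled (or fully enumerated when the budget allows), the model is
#' evaluated with off-coalition genes set to the background value, and a
#' linear surrogate is fitted by least squares with the Shapley kernel
#' weights \eqn{(M-1) / (\binom{M}{s} s (M-s))} for coalition size
#' \eqn{s}. The efficiency constraint — attributions sum exactly to
#' \eqn{F(x) - F(background)} — is imposed by eliminating one coefficient,
#' so it holds for every budget. With full enumeration of all \eqn{2^M - 2}
#' proper coalitions the result equals the exact Shapley value.
#'
#' Under sampling, complete size strata are enumerated outside-in while the
#' budget allows (size-1 and size-(M-1) coalitions first), and the remaining
#' budget is filled with paired random coalitions (each sampled coalition
#' together with its complement), drawn with a fixed seed.
#'
#' @param object A \code{binn} model.
#' @param x Input vector in network-input space.
#' @param class Target class (index or label).
#' @param background Background vector (default: the zero baseline of
#'   \code{config}, for comparability with integrated gradients).
#' @param config An [attribution_config()] (\code{m_shapley} is the query
#'   budget).
#' @param seed Seed for coalition sampling.
#' @return Named numeric vector of per-gene Shapley scores.
#' @export
kernel_shap <- function(object, x, class, background = NULL,
                        config = attribution_config(), seed = 1L) {
  stopifnot(inherits(object, "binn"))
  class <- .class_index(object, class)
  x <- as.numeric(x)
  p <- length(object$genes)
  stopifnot(length(x) == p)
  bg <- if (is.null(background)) .resolve_baseline(config, p) else as.numeric(background)
  stopifnot(length(bg) == p)
  f_x <- as.numeric(.binn_target(object, matrix(x, 1), class, config$target))
  f_bg <- as.numeric(.binn_target(object, matrix(bg, 1), class, config$target))
  delta_F <- f_x - f_bg
  out <- stats::setNames(numeric(p), object$genes)
  if (p == 1L) { out[1] <- delta_F; return(out) }

  budget <- config$m_shapley
  full <- p <= 25 && (2^p - 2) <= budget
  if (full) {
    Z <- do.call(rbind, lapply(seq_len(p - 1L), function(s) .coalitions_of_size(p, s)))
  } else {
    Z <- .with_seed(seed, {
      rows <- list()
      used <- 0L
      s <- 1L
      # enumerate complete paired strata outside-in while they fit
      while (s <= (p - 1L) / 2) {
        need <- choose(p, s) * (if (s == p - s) 1L else 2L)
        if (used + need > budget) break
        zs <- .coalitions_of_size(p, s)
        rows[[length(rows) + 1L]] <- zs
        if (s != p - s) rows[[length(rows) + 1L]] <- 1 - zs
        used <- used + need
        s <- s + 1L
      }
      # fill the rest with paired random coalitions from the kernel
      # distribution over the remaining sizes
      sizes <- setdiff(seq_len(p - 1L), c(seq_len(s - 1L), p - seq_len(s - 1L)))
      if (length(sizes) && used < budget) {
        ks <- pmin(sizes, p - sizes)
        pk <- (p - 1) / (ks * (p - ks))     # kernel mass by size (up to choose term aggregated)
        pk <- pk / sum(pk)
        n_draw <- ceiling((budget - used) / 2)
        draw_sizes <- sample(sizes, n_draw, replace = TRUE, prob = pk)
        zr <- matrix(0, 2L * n_draw, p)
        for (j in seq_len(n_draw)) {
          on <- sample.int(p, draw_sizes[j])
          zr[2L * j - 1L, on] <- 1
          zr[2L * j, ] <- 1 - zr[2L * j - 1L, ]
        }
        rows[[length(rows) + 1L]] <- zr
      }
      do.call(rbind, rows)
    })
  }
  if (is.null(Z) || nrow(unique(Z)) < 2L) {
    stop("Degenerate coalition design: all sampled coalitions identical",
         call. = FALSE)
  }

  sz <- rowSums(Z)
  w <- (p - 1) / (choose(p, sz) * sz * (p - sz))
  X_eval <- Z * matrix(x, nrow(Z), p, byrow = TRUE) +
    (1 - Z) * matrix(bg, nrow(Z), p, byrow = TRUE)
  fv <- .binn_target(object, X_eval, class, config$target)

  # efficiency by elimination of the last coefficient
  A <- Z[, -p, drop = FALSE] - Z[, p]
  r <- fv - f_bg - Z[, p] * delta_F
  sw <- sqrt(w)
  fit <- tryCatch(stats::lsfit(A * sw, r * sw, intercept = FALSE),
                  error = function(e) stop("Shapley regression failed: ",
                                           conditionMessage(e), call. = FALSE))
  phi <- fit$coefficients
  out[seq_len(p - 1L)] <- phi
  out[p] <- delta_F - sum(phi)
  out
}

#' Attribute a dataset with a chosen method
#'
#' Applies one attribution method over an expression matrix, following the
#' protocol of restricting to correctly predicted samples and attributing
#' each retained sample to its true class: samples whose predicted class
#' differs from the label are excluded, and for each retained sample the
#' attribution target is the output for its true label.
#'
#' @param object A trained \code{binn} model.
#' @param x Samples-by-genes expression matrix on the raw scale; the model's
#'   preprocessing is applied before attribution, and attributions are
#'   computed in the network-input space with the configured baseline.
#' @param y True class labels, one per row of \code{x}.
#' @param method \code{"ig"}, \code{"shap"}, or \code{"conductance"}.
#' @param config An [attribution_config()].
#' @param layer Hidden layer for \code{method = "conductance"} (default 1,
#'   the pathway layer).
#' @param classes Optional subset of classes to retain (default: all).
#' @param seed Seed for Shapley coalition sampling (one stream per sample,
#'   offset by sample index).
#' @return An object of class \code{attribution_result}: \code{$scores}
#'   (retained samples by entities), \code{$classes} (true class per retained
#'   sample), \code{$entities}, \code{$method}, \code{$retained} (sample
#'   ids), and for conductance the \code{$f_diff} per sample.
#' @export
attribute_dataset <- function(object, x, y, method = c("ig", "shap", "conductance"),
                              config = attribution_config(), layer = 1L,
                              classes = NULL, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(object, "binn"))
  x <- as.matrix(x)
  y <- as.character(y)
  stopifnot(nrow(x) == length(y))
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  pred <- as.character(predict(object, x))
  keep <- pred == y
  if (!is.null(classes)) keep <- keep & y %in% classes
  if (!any(keep)) {
    stop("No correctly predicted samples to attribute", call. = FALSE)
  }
  xs <- x[keep, , drop = FALSE]
  if (!is.null(colnames(xs))) xs <- xs[, object$genes, drop = FALSE]
  ys <- y[keep]
  Xn <- if (!is.null(object$preprocess)) apply_preprocess(object$preprocess, xs) else xs

  entities <- if (method == "conductance")
    rownames(object$masks$masks[[layer]]) else object$genes
  scores <- matrix(NA_real_, nrow(Xn), length(entities),
                   dimnames = list(rownames(xs), entities))
  f_diff <- if (method == "conductance") numeric(nrow(Xn)) else NULL
  for (i in seq_len(nrow(Xn))) {
    ci <- .class_index(object, ys[i])
    scores[i, ] <- switch(method,
      ig = integrated_gradients(object, Xn[i, ], ci, config),
      shap = kernel_shap(object, Xn[i, ], ci, config = config, seed = seed + i),
      conductance = {
        pr <- conductance(object, Xn[i, ], layer, ci, config)
        f_diff[i] <- pr$f_diff
        pr$values
      })
  }
  structure(list(method = method, scores = scores, classes = ys,
                 entities = entities, retained = rownames(xs),
                 layer = if (method == "conductance") layer else 0L,
                 f_diff = f_diff, config = config),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Attribution result: method %s, %d retained samples, %d entities\n",
              toupper(x$method), nrow(x$scores), length(x$entities)))
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$classes)),
                                  table(x$classes)), collapse = ", "), "\n")
  invisible(x)
}
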