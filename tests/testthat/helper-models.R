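# Shared fixtures and independent oracles for the test suite.

# The worked 3-gene / 2-pathway / 1-superpathway hierarchy.
toy_hierarchy <- function() {
  build_hierarchy(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")),
                  data.frame(child = c("P1", "P2"), parent = "SP1"))
}

# A model computing exact linear logits: logit_k = W_lin[k, ] %*% x.
# Identity masks keep the hidden stack a pass-through.
linear_binn <- function(W_lin) {
  W_lin <- as.matrix(W_lin)
  p <- ncol(W_lin)
  genes <- sprintf("x%02d", seq_len(p))
  mask <- diag(p)
  dimnames(mask) <- list(genes, genes)
  ms <- structure(list(masks = list(mask)), class = "mask_stack")
  binn_network(ms, W = list(mask), b = list(numeric(p)),
               W_out = W_lin, b_out = numeric(nrow(W_lin)),
               activation = "identity")
}

# Small trained nonlinear net on a down-scaled synthetic cohort; memoised so
# several test files can share it.
.toy_cache <- new.env(parent = emptyenv())
toy_trained <- function() {
  if (!is.null(.toy_cache$fit)) return(.toy_cache)
  spec <- synthetic_spec(n_genes = 24, n_pathways = 6, genes_per_pathway = 4,
                         n_superpathways = 3, samples_per_class = 25,
                         planted_per_class = 6, effect_size = 2, noise_sd = 0.5,
                         seed = 11)
  ds <- generate_expression(spec)
  ms <- build_masks(ds$hierarchy)
  fit <- binn(ds$expression, ds$labels, ms, epochs = 150, seed = 5,
              activation = "tanh")
  .toy_cache$spec <- spec
  .toy_cache$ds <- ds
  .toy_cache$masks <- ms
  .toy_cache$fit <- fit
  .toy_cache$Xn <- apply_preprocess(fit$preprocess, ds$expression)
  .toy_cache
}

# Target logit evaluated through the public forward contract.
target_logit <- function(fit, x, class) {
  X <- matrix(x, 1, dimnames = list(NULL, fit$genes))
  obj <- fit
  obj$preprocess <- NULL  # x already in network space
  unname(predict(obj, X, type = "logit")[, class])
}

# Independent dense forward reference: plain per-sample loops, no reuse of
# the package's batched matrix code.
dense_forward_reference <- function(W_list, b_list, W_out, b_out, x,
                                    activation = "relu") {
  f <- switch(activation, relu = function(z) pmax(z, 0), tanh = tanh,
              identity = identity)
  h <- x
  for (l in seq_along(W_list)) {
    z <- numeric(nrow(W_list[[l]]))
    for (r in seq_len(nrow(W_list[[l]]))) {
      z[r] <- sum(W_list[[l]][r, ] * h) + b_list[[l]][r]
    }
    h <- f(z)
  }
  logits <- numeric(nrow(W_out))
  for (k in seq_len(nrow(W_out))) logits[k] <- sum(W_out[k, ] * h) + b_out[k]
  logits
}

# Brute-force Shapley values: average marginal contribution over all
# feature orderings, with off-coalition features at the background value.
shapley_brute <- function(f, x, bg) {
  p <- length(x)
  perms <- gtools_permutations(p)
  phi <- numeric(p)
  for (r in seq_len(nrow(perms))) {
    on <- logical(p)
    prev <- f(ifelse(on, x, bg))
    for (j in perms[r, ]) {
      on[j] <- TRUE
      cur <- f(ifelse(on, x, bg))
      phi[j] <- phi[j] + (cur - prev)
      prev <- cur
    }
  }
  phi / nrow(perms)
}

# All permutations of 1..n as rows (tiny n only).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}
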