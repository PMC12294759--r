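test_that("preprocessing handles zeros, constant genes and all-zero input", {
  x <- rbind(c(0, 2, 5), c(3, 2, 1), c(1, 2, 7))
  colnames(x) <- c("a", "b", "c")
  pp <- fit_preprocess(x)
  out <- apply_preprocess(pp, x)
  expect_equal(pp$scale[["b"]], 1)            # constant gene -> unit scale
  expect_equal(out[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  z <- matrix(0, 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(apply_preprocess(fit_preprocess(z), z)),
               matrix(0, 3, 2))
  expect_error(fit_preprocess(matrix(-1, 2, 2)), "non-negative")
})

test_that("zero-weight network outputs uniform class probabilities", {
  ms <- build_masks(toy_hierarchy())
  m0 <- binn_network(ms, W = lapply(ms$masks, function(m) m * 0),
                     b = list(numeric(2), numeric(1)),
                     W_out = matrix(0, 4, 1), b_out = numeric(4))
  p <- predict(m0, matrix(rnorm(3)^2, 1, dimnames = list(NULL, c("g1", "g2", "g3"))),
               type = "prob")
  expect_equal(unname(p[1, ]), rep(0.25, 4))
})

test_that("forward pass matches hand matrix arithmetic on the toy net", {
  ms <- build_masks(toy_hierarchy())
  W1 <- matrix(c(1, 0, 2, -1, 0, 3), 2, 3, dimnames = dimnames(ms$masks[[1]]))
  W2 <- matrix(c(0.5, -2), 1, 2, dimnames = dimnames(ms$masks[[2]]))
  W_out <- matrix(c(1, -1, 2, 0), 4, 1)
  net <- binn_network(ms, W = list(W1, W2), b = list(c(0.1, -0.2), 0.3),
                      W_out = W_out, b_out = c(0, 0.5, 0, 0),
                      activation = "identity")
  x <- c(g1 = 1, g2 = 2, g3 = 3)
  h1 <- (ms$masks[[1]] * W1) %*% x + c(0.1, -0.2)        # hand layer 1
  h2 <- (ms$masks[[2]] * W2) %*% h1 + 0.3                # hand layer 2
  expect_equal(unname(predict(net, matrix(x, 1, dimnames = list(NULL, names(x))),
                              type = "logit")[1, ]),
               as.numeric(W_out %*% h2 + c(0, 0.5, 0, 0)))
})

test_that("perturbing a masked weight never changes the output", {
  tc <- toy_trained()
  fit <- tc$fit
  masked_pos <- which(fit$masks$masks[[1]] == 0, arr.ind = TRUE)[1, ]
  before <- predict(fit, tc$ds$expression[1:5, ], type = "logit")
  fit2 <- fit
  fit2$W[[1]][masked_pos[1], masked_pos[2]] <- 1e6
  expect_identical(before, predict(fit2, tc$ds$expression[1:5, ], type = "logit"))
  eff <- coef(fit2)$hidden[[1]]
  expect_equal(eff[fit$masks$masks[[1]] == 0], numeric(sum(fit$masks$masks[[1]] == 0)))
})

test_that("all-ones masks reproduce an independent dense reference network", {
  genes <- paste0("g", 1:4)
  mask1 <- matrix(1, 3, 4, dimnames = list(paste0("P", 1:3), genes))
  mask2 <- matrix(1, 2, 3, dimnames = list(c("S1", "S2"), paste0("P", 1:3)))
  ms <- structure(list(masks = list(mask1, mask2)), class = "mask_stack")
  set.seed(42)
  W1 <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(6), 2, 3)
  W_out <- matrix(rnorm(8), 4, 2); b_out <- rnorm(4)
  b <- list(rnorm(3), rnorm(2))
  net <- binn_network(ms, W = list(W1, W2), b = b, W_out = W_out,
                      b_out = b_out, activation = "relu")
  x <- rnorm(4)
  ref <- dense_forward_reference(list(W1, W2), b, W_out, b_out, x, "relu")
  got <- predict(net, matrix(x, 1, dimnames = list(NULL, genes)), type = "logit")
  expect_equal(unname(got[1, ]), ref, tolerance = 1e-12)
})

test_that("probability rows always sum to one", {
  tc <- toy_trained()
  p <- predict(tc$fit, tc$ds$expression, type = "prob")
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("training is deterministic given the seed and loss decreases", {
  tc <- toy_trained()
  fit1 <- binn(tc$ds$expression, tc$ds$labels, tc$masks, epochs = 30, seed = 9)
  fit2 <- binn(tc$ds$expression, tc$ds$labels, tc$masks, epochs = 30, seed = 9)
  expect_identical(fit1$W, fit2$W)
  expect_identical(fit1$loss, fit2$loss)
  fit3 <- binn(tc$ds$expression, tc$ds$labels, tc$masks, epochs = 30, seed = 10)
  expect_false(identical(fit1$W, fit3$W))
  expect_lt(tc$fit$loss[length(tc$fit$loss)], tc$fit$loss[1])
})

test_that("epochs = 0 returns an initialized model with empty loss trace", {
  tc <- toy_trained()
  fit0 <- binn(tc$ds$expression, tc$ds$labels, tc$masks, epochs = 0, seed = 1)
  expect_length(fit0$loss, 0)
  expect_s3_class(fit0, "binn")
  # initialization respects the mask
  expect_true(all(fit0$W[[1]][tc$masks$masks[[1]] == 0] == 0))
})

test_that("a separable cohort is fit to perfect training F1", {
  # independent oracle: a multinomial linear classifier separates the data
  spec <- synthetic_spec(n_genes = 24, n_pathways = 6, genes_per_pathway = 4,
                         n_superpathways = 3, samples_per_class = 25,
                         planted_per_class = 6, effect_size = 4, noise_sd = 0.3,
                         seed = 21)
  ds <- generate_expression(spec)
  lx <- log2(ds$expression + 1)
  oracle <- nnet::multinom(y ~ ., data = data.frame(y = ds$labels, lx),
                           trace = FALSE, maxit = 200)
  expect_equal(mean(predict(oracle) == ds$labels), 1)  # separability confirmed
  fit <- binn(ds$expression, ds$labels, build_masks(ds$hierarchy),
              epochs = 200, seed = 2, activation = "tanh")
  m <- weighted_metrics(ds$labels, predict(fit, ds$expression))
  expect_equal(unname(m["f1"]), 1.0)
})

test_that("invalid training inputs error clearly", {
  tc <- toy_trained()
  one_class <- rep("cancer", nrow(tc$ds$expression))
  expect_error(binn(tc$ds$expression, one_class, tc$masks, epochs = 1),
               "2 classes")
  xm <- tc$ds$expression[, -1]
  expect_error(binn(xm, tc$ds$labels, tc$masks, epochs = 1), "missing")
  expect_error(predict(tc$fit, tc$ds$expression[, 1:3]), "missing genes")
})

test_that("argmax ties resolve to the lowest class index", {
  ms <- build_masks(toy_hierarchy())
  m0 <- binn_network(ms, W = lapply(ms$masks, function(m) m * 0),
                     b = list(numeric(2), numeric(1)),
                     W_out = matrix(0, 4, 1), b_out = numeric(4),
                     classes = binn_classes())
  p <- predict(m0, matrix(1, 1, 3, dimnames = list(NULL, c("g1", "g2", "g3"))))
  expect_equal(as.character(p), "cancer")
})
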