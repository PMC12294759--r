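test_that("input gradients agree with central finite differences", {
  tc <- toy_trained()
  x <- tc$Xn[3, ]
  g <- frbinn:::.binn_input_grad(tc$fit, matrix(x, 1), 2, "logit")[1, ]
  eps <- 1e-5
  fd <- vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    (target_logit(tc$fit, xp, 2) - target_logit(tc$fit, xm, 2)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(g), fd, tolerance = 1e-6)
})

test_that("integrated gradients are exact on linear models at any step count", {
  net <- linear_binn(rbind(c(3, 2), c(0, 0)))
  x <- c(1, 1)
  for (scheme in c("riemann-right", "gauss-legendre")) {
    for (m in c(1, 5, 800)) {
      ig <- integrated_gradients(net, x, 1,
                                 attribution_config(m_ig = m, scheme = scheme))
      expect_equal(unname(ig), c(3, 2), tolerance = 1e-12)
    }
  }
  # input equal to the baseline attributes exactly zero
  ig0 <- integrated_gradients(net, c(0, 0), 1)
  expect_equal(unname(ig0), c(0, 0))
})

test_that("IG at m = 800 matches a high-resolution Riemann path integral", {
  tc <- toy_trained()
  x <- tc$Xn[10, ]
  cls <- 1L
  # oracle: independent right-endpoint Riemann loop at 100,000 steps over
  # finite-difference-validated gradients
  m_hi <- 100000L
  alpha <- seq_len(m_hi) / m_hi
  pts <- outer(alpha, x)                       # zero baseline
  G <- frbinn:::.binn_input_grad(tc$fit, pts, cls, "logit")
  oracle <- x * colSums(G) / m_hi
  ig <- integrated_gradients(tc$fit, x, cls, attribution_config(m_ig = 800))
  expect_lt(max(abs(ig - oracle)), 1e-3)
  ig_r <- integrated_gradients(tc$fit, x, cls,
                               attribution_config(m_ig = 800,
                                                  scheme = "riemann-right"))
  expect_lt(max(abs(ig_r - oracle)), 1e-2)     # slower scheme, looser bound
})

test_that("IG completeness holds on the toy net at m = 800", {
  tc <- toy_trained()
  for (i in c(2, 30, 60)) {
    x <- tc$Xn[i, ]
    cls <- as.integer(tc$ds$labels[i])
    ig <- integrated_gradients(tc$fit, x, cls, attribution_config(m_ig = 800))
    fdiff <- target_logit(tc$fit, x, cls) -
      target_logit(tc$fit, numeric(length(x)), cls)
    expect_lt(abs(sum(ig) - fdiff) / max(abs(fdiff), 1), 1e-3)
  }
})

test_that("conductance on a single-path linear chain equals the chain product", {
  mask <- matrix(1, 1, 1, dimnames = list("P1", "g1"))
  ms <- structure(list(masks = list(mask)), class = "mask_stack")
  w1 <- 1.7; w2 <- -0.8
  net <- binn_network(ms, W = list(mask * w1), b = list(0),
                      W_out = matrix(c(w2, 0), 2, 1), b_out = c(0, 0),
                      activation = "identity")
  x <- 2.5
  pr <- conductance(net, x, layer = 1, class = 1,
                    attribution_config(m_con = 10))
  expect_equal(unname(pr$values), w2 * w1 * x, tolerance = 1e-12)
  expect_equal(unname(pr$values), pr$f_diff, tolerance = 1e-12)
})

test_that("per-layer conductance sums to the output difference", {
  tc <- toy_trained()
  for (i in c(5, 40)) {
    x <- tc$Xn[i, ]
    cls <- as.integer(tc$ds$labels[i])
    fdiff <- target_logit(tc$fit, x, cls) -
      target_logit(tc$fit, numeric(length(x)), cls)
    for (layer in 1:2) {
      pr <- conductance(tc$fit, x, layer, cls, attribution_config(m_con = 800))
      expect_lt(abs(sum(pr$values) - fdiff) / max(abs(fdiff), 1), 1e-3)
      expect_equal(pr$f_diff, fdiff, tolerance = 1e-10)
    }
  }
})

test_that("set aggregation is the exact sum of member conductances", {
  tc <- toy_trained()
  sp_mask <- tc$masks$masks[[2]]
  sets <- lapply(rownames(sp_mask), function(sp)
    colnames(sp_mask)[sp_mask[sp, ] == 1])
  names(sets) <- rownames(sp_mask)
  pr <- conductance(tc$fit, tc$Xn[7, ], 1, 1,
                    attribution_config(m_con = 50), sets = sets)
  for (sp in names(sets)) {
    expect_identical(unname(pr$set_values[sp]), sum(pr$values[sets[[sp]]]))
  }
})

test_that("a neuron with zero effective incoming weights has zero conductance", {
  tc <- toy_trained()
  fit <- tc$fit
  fit$W[[1]]["P01", ] <- 0
  pr <- conductance(fit, tc$Xn[1, ], 1, 1, attribution_config(m_con = 20))
  expect_equal(unname(pr$values["P01"]), 0)
  # likewise a gene with zero effective outgoing weights gets zero IG
  fit2 <- tc$fit
  fit2$W[[1]][, "g001"] <- 0
  ig <- integrated_gradients(fit2, tc$Xn[1, ], 1, attribution_config(m_ig = 20))
  expect_equal(unname(ig["g001"]), 0)
})

test_that("conductance rejects the output layer", {
  tc <- toy_trained()
  expect_error(conductance(tc$fit, tc$Xn[1, ], 3, 1), "hidden")
  expect_error(conductance(tc$fit, tc$Xn[1, ], 0, 1), "hidden")
})

test_that("kernel SHAP recovers the linear closed form under full enumeration", {
  w <- c(3, -2, 0.5, 1, -1)
  net <- linear_binn(rbind(w, 0 * w))
  x <- c(1, 2, -1, 0.5, 3); bg <- c(0.2, 0, -0.5, 0, 1)
  phi <- kernel_shap(net, x, 1, background = bg,
                     config = attribution_config(m_shapley = 2^5))
  expect_equal(unname(phi), w * (x - bg), tolerance = 1e-9)
})

test_that("full-enumeration kernel SHAP equals brute-force Shapley", {
  # 3-gene ReLU net with genuine feature interactions
  genes <- c("g1", "g2", "g3")
  mask <- matrix(1, 2, 3, dimnames = list(c("P1", "P2"), genes))
  ms <- structure(list(masks = list(mask)), class = "mask_stack")
  set.seed(13)
  W <- matrix(rnorm(6), 2, 3); b <- rnorm(2)
  W_out <- matrix(rnorm(4), 2, 2); b_out <- rnorm(2)
  net <- binn_network(ms, W = list(W), b = list(b), W_out = W_out,
                      b_out = b_out, activation = "relu")
  x <- c(1.2, -0.7, 0.9); bg <- c(0, 0, 0)
  f <- function(v) target_logit(net, v, 1)
  oracle <- shapley_brute(f, x, bg)
  phi <- kernel_shap(net, x, 1, background = bg,
                     config = attribution_config(m_shapley = 8))
  expect_equal(unname(phi), oracle, tolerance = 1e-9)
})

test_that("exchangeable features receive equal Shapley scores", {
  net <- linear_binn(rbind(c(2, 2, 1), c(0, 0, 0)))
  phi <- kernel_shap(net, c(1, 1, 3), 1,
                     config = attribution_config(m_shapley = 8))
  expect_equal(unname(phi[1]), unname(phi[2]), tolerance = 1e-10)
})

test_that("Shapley efficiency holds exactly under a sampling budget", {
  tc <- toy_trained()
  x <- tc$Xn[12, ]
  cls <- as.integer(tc$ds$labels[12])
  phi <- kernel_shap(tc$fit, x, cls,
                     config = attribution_config(m_shapley = 200), seed = 2)
  fdiff <- target_logit(tc$fit, x, cls) -
    target_logit(tc$fit, numeric(length(x)), cls)
  expect_equal(sum(phi), fdiff, tolerance = 1e-8)
  # deterministic under its seed
  phi2 <- kernel_shap(tc$fit, x, cls,
                      config = attribution_config(m_shapley = 200), seed = 2)
  expect_identical(phi, phi2)
})

test_that("dataset attribution keeps only correctly predicted samples", {
  tc <- toy_trained()
  pred <- as.character(predict(tc$fit, tc$ds$expression))
  truth <- as.character(tc$ds$labels)
  cfg <- attribution_config(m_ig = 30)
  a <- attribute_dataset(tc$fit, tc$ds$expression, truth, "ig", cfg)
  expect_setequal(a$retained, rownames(tc$ds$expression)[pred == truth])
  # a forced misclassification is absent from the result
  y_bad <- truth
  y_bad[1] <- setdiff(binn_classes(), truth[1])[1]
  a2 <- attribute_dataset(tc$fit, tc$ds$expression, y_bad, "ig", cfg)
  expect_false(rownames(tc$ds$expression)[1] %in% a2$retained)
  # impossible labels leave nothing to attribute
  y_none <- ifelse(pred == "cancer", "normal", "cancer")
  expect_error(attribute_dataset(tc$fit, tc$ds$expression, y_none, "ig", cfg),
               "No correctly predicted")
})

test_that("batched dataset attribution equals single-sample calls", {
  tc <- toy_trained()
  cfg <- attribution_config(m_ig = 30)
  a <- attribute_dataset(tc$fit, tc$ds$expression, tc$ds$labels, "ig", cfg,
                         classes = "CP-CID")
  sid <- a$retained[1]
  x1 <- tc$Xn[sid, ]
  single <- integrated_gradients(tc$fit, x1, "CP-CID", cfg)
  expect_equal(a$scores[sid, ], single)
})
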