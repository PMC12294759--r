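test_that("spec validation enforces the generator's invariants", {
  expect_s3_class(strong_effect_preset(), "synthetic_spec")
  expect_error(synthetic_spec(n_genes = 10, n_pathways = 2,
                              genes_per_pathway = 20), "exceeds n_genes")
  expect_error(synthetic_spec(n_genes = 12, n_pathways = 2,
                              genes_per_pathway = 5), "partition|equal")
  expect_error(synthetic_spec(planted_per_class = 100), "exceeds")
  expect_error(synthetic_spec(effect_size = -1), "effect_size")
})

test_that("generated hierarchy deals genes round-robin", {
  spec <- synthetic_spec(n_genes = 6, n_pathways = 2, genes_per_pathway = 3,
                         n_superpathways = 1, samples_per_class = 5,
                         planted_per_class = 2)
  ms <- build_masks(generate_hierarchy(spec))
  expect_equal(unname(rowSums(ms$masks[[1]])), c(3, 3))
  # zero overlap -> partition: each gene in exactly one pathway
  expect_equal(unname(colSums(ms$masks[[1]])), rep(1, 6))
  # overlapping memberships when requested
  spec2 <- synthetic_spec(n_genes = 6, n_pathways = 3, genes_per_pathway = 2,
                          n_superpathways = 1, samples_per_class = 5,
                          planted_per_class = 2, pathway_overlap = 1)
  ms2 <- build_masks(generate_hierarchy(spec2))
  expect_equal(unname(colSums(ms2$masks[[1]])), rep(2, 6))
})

test_that("identical specs generate identical datasets", {
  spec <- synthetic_spec(n_genes = 20, n_pathways = 4, genes_per_pathway = 5,
                         n_superpathways = 2, samples_per_class = 10,
                         planted_per_class = 4, seed = 33)
  d1 <- generate_expression(spec)
  d2 <- generate_expression(spec)
  expect_identical(d1$expression, d2$expression)
  expect_identical(d1$labels, d2$labels)
  expect_identical(generate_hierarchy(spec), generate_hierarchy(spec))
  d3 <- generate_expression(synthetic_spec(n_genes = 20, n_pathways = 4,
                                           genes_per_pathway = 5,
                                           n_superpathways = 2,
                                           samples_per_class = 10,
                                           planted_per_class = 4, seed = 34))
  expect_false(identical(d1$expression, d3$expression))
})

test_that("planted gene sets are pairwise disjoint and recorded", {
  ds <- generate_expression(strong_effect_preset())
  pl <- ds$planted
  expect_length(intersect(pl[["cancer"]], pl[["CP-CID"]]), 0)
  expect_length(intersect(pl[["cancer"]], pl[["NCP-CID"]]), 0)
  expect_length(intersect(pl[["CP-CID"]], pl[["NCP-CID"]]), 0)
  expect_true(all(unlist(pl) %in% colnames(ds$expression)))
  expect_equal(lengths(pl), c(cancer = 20L, `CP-CID` = 20L, `NCP-CID` = 20L))
})

test_that("noise-free generation shifts planted genes by exactly the effect", {
  spec <- synthetic_spec(n_genes = 12, n_pathways = 3, genes_per_pathway = 4,
                         n_superpathways = 1, samples_per_class = 4,
                         planted_per_class = 3, effect_size = 2, noise_sd = 0,
                         seed = 5)
  ds <- generate_expression(spec)
  lmat <- log2(ds$expression)
  cp <- ds$labels == "CP-CID"
  g <- ds$planted[["CP-CID"]][1]
  expect_equal(unname(lmat[cp, g] - ds$baseline[g]), rep(2, 4))
  # non-planted genes sit at baseline for every class
  other <- setdiff(colnames(ds$expression), unlist(ds$planted))[1]
  expect_equal(unname(lmat[, other]), rep(unname(ds$baseline[other]), 16))
})

test_that("null generation (effect 0) leaves no class signal", {
  spec <- synthetic_spec(n_genes = 20, n_pathways = 4, genes_per_pathway = 5,
                         n_superpathways = 2, samples_per_class = 50,
                         planted_per_class = 4, effect_size = 0,
                         noise_sd = 0.5, seed = 17)
  ds <- generate_expression(spec)
  lmat <- log2(ds$expression)
  g <- ds$planted[["CP-CID"]][1]
  tt <- t.test(lmat[ds$labels == "CP-CID", g], lmat[ds$labels == "normal", g])
  expect_gt(tt$p.value, 0.001)   # no planted shift to detect
})

test_that("planted genes carry larger two-sample t statistics than background", {
  spec <- synthetic_spec(n_genes = 40, n_pathways = 8, genes_per_pathway = 5,
                         n_superpathways = 2, samples_per_class = 200,
                         planted_per_class = 8, effect_size = 2, noise_sd = 0.5,
                         seed = 23)
  ds <- generate_expression(spec)
  lmat <- log2(ds$expression)
  cp <- ds$labels == "CP-CID"; nm <- ds$labels == "normal"
  tstat <- vapply(colnames(lmat), function(g)
    abs(t.test(lmat[cp, g], lmat[nm, g])$statistic), numeric(1))
  planted <- colnames(lmat) %in% ds$planted[["CP-CID"]]
  expect_gt(mean(tstat[planted]), mean(tstat[!planted]))
  expect_gt(mean(tstat[planted]), 10)  # effect 2 at sd 0.5, n = 200/class
})

test_that("synthetic files round-trip through the writers", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_genes = 12, n_pathways = 3, genes_per_pathway = 4,
                         n_superpathways = 1, samples_per_class = 3,
                         planted_per_class = 3, seed = 2)
  ds <- generate_expression(spec)
  paths <- write_synthetic(ds, dir)
  x <- read_expression(paths["expression"])
  expect_equal(dim(x), dim(ds$expression))
  expect_equal(x, ds$expression, tolerance = 1e-5)
  y <- read_labels(paths["labels"])
  expect_equal(as.character(y[rownames(x)]), as.character(ds$labels))
  h <- build_hierarchy(read_gmt(paths["gmt"]),
                       read_pathway_edges(paths["edges"]))
  expect_identical(build_masks(h), build_masks(ds$hierarchy))
})
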