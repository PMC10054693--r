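# The synthetic benchmark uses the built-in Nussinov engine at modest sizes:
# fast, deterministic, and exercising exactly the same downstream code paths
# as Vienna-folded data.

test_that("feature datasets have the five canonical columns and no missing values", {
  d <- generate_pseudo_natural(pseudo_natural_spec(L = 60, n = 20),
                               folding_engine("nussinov"), seed = 1)
  expect_equal(nrow(d), 40L)
  expect_setequal(unique(d$class), c("random", "pseudo-natural"))
  f <- make_feature_dataset(d)
  expect_identical(names(f),
                   c("bulges", "loops", "junctions", "helices", "bonds", "label"))
  expect_false(anyNA(f))
  expect_equal(sum(f$label), 20L)

  hairpin <- tibble::tibble(db = "(((...)))", class = "pseudo-natural")
  row <- make_feature_dataset(hairpin)
  expect_equal(unlist(row[1, 1:5], use.names = FALSE), c(0L, 1L, 0L, 1L, 3L))
})

test_that("generation is reproducible from the seed", {
  spec <- pseudo_natural_spec(L = 50, n = 15)
  eng <- folding_engine("nussinov")
  expect_identical(generate_pseudo_natural(spec, eng, seed = 5),
                   generate_pseudo_natural(spec, eng, seed = 5))
})

test_that("mean motif shifts move in the direction of the effect vector", {
  eng <- folding_engine("nussinov")
  spec <- pseudo_natural_spec(L = 120, n = 120,
                              shift = c(bulges = -2, loops = 2, junctions = 0,
                                        helices = 0, bonds = 0),
                              candidates_per_accept = 4)
  d <- generate_pseudo_natural(spec, eng, seed = 11)
  f <- make_feature_dataset(d)
  mu1 <- colMeans(f[f$label == 1, 1:5])
  mu0 <- colMeans(f[f$label == 0, 1:5])
  expect_lt(mu1[["bulges"]], mu0[["bulges"]])
  expect_gt(mu1[["loops"]], mu0[["loops"]])
})

test_that("classes are exchangeable at zero effect and AUC grows with effect size", {
  eng <- folding_engine("nussinov")
  zero <- pseudo_natural_spec(L = 80, n = 80, gc_alpha = 1e6, gc_beta = 1e6,
                              shift = c(bulges = 0, loops = 0, junctions = 0,
                                        helices = 0, bonds = 0),
                              candidates_per_accept = 1)
  d0 <- generate_pseudo_natural(zero, eng, seed = 21)
  f0 <- make_feature_dataset(d0)
  r0 <- knn_cv(f0[1:5], f0$label, B = 150, seed = 3)
  null_auc <- vapply(seq_len(200), function(b) {
    set.seed(3000 + b)
    roc_auc(r0$scores, sample(r0$labels))
  }, numeric(1))
  band <- quantile(null_auc, c(0.025, 0.975))
  expect_gte(r0$auc, band[1])
  expect_lte(r0$auc, band[2])

  auc_at <- function(mult, seed) {
    spec <- pseudo_natural_spec(L = 80, n = 80,
                                shift = mult * c(bulges = -1, loops = 1,
                                                 junctions = 0, helices = 0,
                                                 bonds = -0.5),
                                candidates_per_accept = 4)
    d <- generate_pseudo_natural(spec, eng, seed = seed)
    f <- make_feature_dataset(d)
    knn_cv(f[1:5], f$label, B = 150, seed = 3)$auc
  }
  aucs <- c(r0$auc, auc_at(1, 21), auc_at(4, 21))
  expect_true(all(diff(aucs) > -0.02))  # non-decreasing up to CV noise
  expect_gt(aucs[3], band[2])           # clear signal beats the null band
})
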