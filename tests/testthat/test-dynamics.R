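test_that("rand_index matches hand-derived and brute-force values", {
  expect_identical(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_identical(rand_index(c(1, 1), c(1, 2)), 0)
  expect_identical(rand_index(rep(1, 5), rep(2, 5)), 1)
  expect_identical(rand_index(letters[c(1, 1, 2, 3)], c(9, 9, 4, 7)), 1)
  # invariance to label renaming and symmetry
  a <- c(1, 1, 2, 2, 3)
  b <- c(2, 1, 1, 3, 3)
  expect_identical(rand_index(a, b), rand_index(b, a))
  expect_identical(rand_index(a, b), rand_index(c("x", "x", "y", "y", "z"), b))
  set.seed(1)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    p <- sample.int(5, n, replace = TRUE)
    q <- sample.int(5, n, replace = TRUE)
    expect_equal(rand_index(p, q), ri_brute(p, q), tolerance = 1e-12)
  }
  expect_error(rand_index(1:3, 1:4), "equal length")
  expect_error(rand_index(1, 1), "at least 2")
})

test_that("label transfer is deterministic, validated, and accurate on separable data", {
  tc <- make_course(seed = 4)
  n1 <- normalize_counts(tc[[1]]$counts)
  n2 <- normalize_counts(tc[[2]]$counts)
  hv <- select_hvgs(n1)
  spec <- classifier_spec("gradient_boosting", seed = 123)
  tr1 <- transfer_labels(n1, tc[[1]]$annotation, n2, tc[[2]]$annotation, spec, hv)
  tr2 <- transfer_labels(n1, tc[[1]]$annotation, n2, tc[[2]]$annotation, spec, hv)
  expect_identical(tr1$predicted, tr2$predicted)
  expect_identical(sum(tr1$confusion), nrow(tc[[2]]$annotation))
  expect_true(all(tr1$predicted %in% unique(tc[[1]]$annotation$subtype)))

  # stable, well-separated subtypes: every classifier kind transfers accurately
  for (kind in c("gradient_boosting", "multinomial_logistic", "nearest_centroid")) {
    tr <- transfer_labels(n1, tc[[1]]$annotation, n2, tc[[2]]$annotation,
                          classifier_spec(kind, seed = 1), hv)
    expect_gte(mean(tr$predicted == tr$true), 0.95)
  }

  one <- tc[[1]]$annotation
  one$subtype <- "only"
  expect_error(transfer_labels(n1, one, n2, tc[[2]]$annotation, spec, hv),
               "single subtype")
  few <- classifier_spec("gradient_boosting", cv_folds = 50)
  expect_error(transfer_labels(n1, tc[[1]]$annotation, n2, tc[[2]]$annotation,
                               few, hv), "fewer folds")
  expect_warning(transfer_labels(n1, tc[[1]]$annotation, n2, tc[[2]]$annotation,
                                 classifier_spec("nearest_centroid"),
                                 c(hv[1:20], "not_a_gene")), "absent")
})

test_that("dynamic scores are partition-based: zero on identity, rename-invariant", {
  true <- rep(c("s1", "s2", "s3"), each = 10)
  cm <- stats::setNames(rep("C", 3), c("s1", "s2", "s3"))
  perfect <- fake_transfer(true, true)
  dyn <- dynamic_scores(perfect, cm)
  expect_identical(dyn$pairs$dynamic_score, 0)
  expect_identical(dyn$pairs$rand_index, 1)

  # renaming target subtypes (immature -> mature style) must not change scores
  pred <- sample(c("s1", "s2", "s3"), 30, replace = TRUE)
  renamed <- stats::setNames(c("Im s1", "Im s2", "Im s3"), c("s1", "s2", "s3"))
  cm2 <- stats::setNames(rep("C", 3), renamed)
  d1 <- dynamic_scores(fake_transfer(true, pred), cm)
  d2 <- dynamic_scores(fake_transfer(unname(renamed[true]), pred), cm2)
  expect_identical(d1$pairs$dynamic_score, d2$pairs$dynamic_score)
  expect_true(all(d1$pairs$dynamic_score >= 0 & d1$pairs$dynamic_score <= 1))
  expect_identical(d1$pairs$dynamic_score, 1 - d1$pairs$rand_index)
})

test_that("per-class restriction, summaries, and missing classes behave as defined", {
  true <- c(rep("a1", 6), rep("a2", 6), rep("b1", 6), "c1")
  pred <- c(rep("a1", 3), rep("a2", 3), rep("a2", 6), rep("b1", 6), "b1")
  cm <- stats::setNames(c("A", "A", "B", "C"), c("a1", "a2", "b1", "c1"))
  tr <- fake_transfer(true, pred, source_levels = c("a1", "a2", "b1"))
  dyn <- dynamic_scores(tr, cm)
  p <- dyn$pairs
  # class B is perfectly transferred, class A is not, class C has < 2 cells
  expect_identical(p$dynamic_score[p$class == "B"], 0)
  expect_gt(p$dynamic_score[p$class == "A"], 0)
  expect_true(p$missing[p$class == "C"])
  expect_true(is.na(p$dynamic_score[p$class == "C"]))
  # class A score matches a direct computation on its own cells only
  ri_a <- rand_index(true[1:12], pred[1:12])
  expect_identical(p$rand_index[p$class == "A"], ri_a)

  # equal scores across pairs: mean is the score, sd is 0
  t1 <- fake_transfer(true[1:12], pred[1:12], "P1", "P4")
  t2 <- fake_transfer(true[1:12], pred[1:12], "P4", "P10")
  dyn2 <- dynamic_scores(list(t1, t2), cm)
  expect_equal(dyn2$summary$mean_score, 1 - ri_a)
  expect_identical(dyn2$summary$sd_score, 0)
  expect_true(dyn2$summary$mean_score >= min(dyn2$pairs$dynamic_score) &&
              dyn2$summary$mean_score <= max(dyn2$pairs$dynamic_score))
})

test_that("class comparison p-values come from the configured test", {
  mk <- function(err, src, tgt) {
    true <- rep(c("a1", "a2", "b1", "b2"), each = 20)
    pred <- true
    flip <- seq_len(err)
    pred[flip] <- "a2"           # corrupt only class A
    fake_transfer(true, pred, src, tgt, source_levels = c("a1", "a2", "b1", "b2"))
  }
  cm <- stats::setNames(c("A", "A", "B", "B"), c("a1", "a2", "b1", "b2"))
  trs <- list(mk(6, "P1", "P4"), mk(8, "P4", "P10"), mk(10, "P10", "Adult"))
  dw <- dynamic_scores(trs, cm, comparison = "welch")
  expect_true(dw$comparisons$p_value > 0 && dw$comparisons$p_value < 0.05)
  dp <- dynamic_scores(trs, cm, comparison = "permutation", n_perm = 500, seed = 1)
  expect_true(dp$comparisons$p_value > 0 && dp$comparisons$p_value <= 1)
  expect_identical(dw$comparisons$mean_a, dp$comparisons$mean_a)
})

test_that("sankey edges are row-normalized confusion with a similarity floor", {
  true <- rep(c("s1", "s2"), each = 10)
  perfect <- fake_transfer(true, true)
  e <- sankey_edges(perfect)
  expect_identical(nrow(e), 2L)
  expect_identical(e$similarity, c(1, 1))
  expect_identical(e$source_subtype, e$target_subtype)

  # a target subtype split 50/50 between two source subtypes
  split <- fake_transfer(rep("t1", 10), rep(c("s1", "s2"), 5),
                         source_levels = c("s1", "s2"))
  es <- sankey_edges(split)
  expect_identical(nrow(es), 2L)
  expect_identical(es$similarity, c(0.5, 0.5))
  expect_identical(es$weight, c(5L, 5L))

  # floor 0: similarities per target subtype sum to 1 on random confusions
  set.seed(7)
  for (i in 1:10) {
    true <- sample(paste0("t", 1:4), 60, replace = TRUE)
    pred <- sample(paste0("s", 1:3), 60, replace = TRUE)
    e0 <- sankey_edges(fake_transfer(true, pred, source_levels = paste0("s", 1:3)),
                       floor = 0)
    sums <- tapply(e0$similarity, e0$target_subtype, sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
  # default floor drops weak edges
  ef <- sankey_edges(fake_transfer(rep("t1", 100),
                                   c(rep("s1", 99), "s2"),
                                   source_levels = c("s1", "s2")))
  expect_identical(ef$source_subtype, "s1")
})
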