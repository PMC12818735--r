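test_that("knn excludes self, breaks ties by cell id, and matches brute force", {
  collinear <- data.frame(cell_id = c("c1", "c2", "c3"),
                          x = c(0, 1, 2), y = 0)
  nb <- knn_neighbors(collinear, k = 1)
  expect_identical(rownames(nb)[nb["c2", 1]], "c1")  # equidistant: first by id
  expect_identical(rownames(nb)[nb["c1", 1]], "c2")

  set.seed(3)
  field <- data.frame(cell_id = sprintf("c%03d", 1:40),
                      x = runif(40), y = runif(40))
  nb_all <- knn_neighbors(field, k = 39)
  expect_true(all(apply(nb_all, 1, function(r) length(unique(r)) == 39)))
  expect_true(all(vapply(seq_len(40), function(i) !(i %in% nb_all[i, ]), TRUE)))

  d <- as.matrix(dist(field[, c("x", "y")]))
  nb5 <- knn_neighbors(field, k = 5)
  for (i in seq_len(40)) {
    want <- setdiff(order(d[i, ]), i)[1:5]
    expect_identical(unname(nb5[i, ]), want)
  }
  expect_error(knn_neighbors(collinear, k = 3), "more than 3 cells")
})

test_that("lr_score follows the pairwise product rule and its degenerate cases", {
  # 2-cell field: the only interaction is 2 * 3 = 6 under the raw product rule
  two <- data.frame(cell_id = c("c1", "c2"), x = c(0, 1), y = 0,
                    ligand = c(2, 0), receptor = c(0, 3))
  f <- lr_score(two, k = 1, normalize = FALSE)
  expect_equal(f$score, c(6, 6))

  # zero ligand everywhere: every score is 0
  z <- data.frame(cell_id = paste0("c", 1:10), x = runif(10), y = runif(10),
                  ligand = 0, receptor = runif(10))
  expect_true(all(lr_score(z, k = 3)$score == 0))
  expect_error(lr_score(z[, -4], k = 3), "`ligand` not present")

  # six-cell layout vs exhaustive enumeration
  set.seed(11)
  six <- data.frame(cell_id = paste0("c", 1:6), x = runif(6), y = runif(6),
                    ligand = rexp(6), receptor = rexp(6))
  expect_equal(lr_score(six, k = 3)$score, lr_oracle(six, k = 3))
  expect_equal(lr_score(six, k = 3, normalize = FALSE)$score,
               lr_oracle(six, k = 3, normalize = FALSE))
})

test_that("lr_score is scale-equivariant on raw values and rigid-motion invariant", {
  set.seed(5)
  field <- data.frame(cell_id = sprintf("c%03d", 1:60), x = runif(60, 0, 10),
                      y = runif(60, 0, 10), ligand = rexp(60), receptor = rexp(60))
  base <- lr_score(field, k = 5, normalize = FALSE)$score
  scaled <- field
  scaled$ligand <- scaled$ligand * 3.7
  expect_equal(lr_score(scaled, k = 5, normalize = FALSE)$score, 3.7 * base)

  th <- 0.83
  rot <- field
  rot$x <- cos(th) * field$x - sin(th) * field$y + 12
  rot$y <- sin(th) * field$x + cos(th) * field$y - 4
  expect_equal(lr_score(rot, k = 5, normalize = FALSE)$score, base)
  expect_identical(knn_neighbors(rot, k = 5), knn_neighbors(field, k = 5))
})

test_that("field comparison is symmetric and null on identical fields", {
  set.seed(8)
  f1 <- lr_score(generate_spatial(spatial_config(n_cells = 150, seed = 1)))
  f2 <- lr_score(generate_spatial(spatial_config(n_cells = 150, seed = 2,
                                                 ligand_high = 2, receptor_high = 2)))
  expect_gte(compare_fields(f1, f1)$p_value, 0.99)
  ab <- compare_fields(f1, f2)
  ba <- compare_fields(f2, f1)
  expect_equal(ab$p_value, ba$p_value)
  expect_identical(ab$median_a, ba$median_b)
  expect_error(compare_fields(list(score = numeric(0)), f1), "empty")
})

test_that("spot labels are the argmax over non-excluded subtypes", {
  ab <- rbind(s1 = c(A = 0.7, B = 0.2, C = 0.1),
              s2 = c(A = 0.5, B = 0.5, C = 0),
              s3 = c(A = 0, B = 0, C = 0),
              s4 = c(A = 0.9, B = 0.1, C = 0))
  expect_identical(assign_spot_labels(ab),
                   c(s1 = "A", s2 = "A", s3 = "unassigned", s4 = "A"))
  expect_identical(unname(assign_spot_labels(ab, exclude = "A")["s4"]), "B")
  expect_error(assign_spot_labels(ab, exclude = c("A", "B", "C")), "excluded")
})
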