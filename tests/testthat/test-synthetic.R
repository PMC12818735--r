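test_that("generator is deterministic and validates its configuration", {
  cfg <- timecourse_config(ages = c("P1", "P4"),
                           subtypes = list(subtype_spec("S1", proportion_schedule = 1)),
                           n_cells_per_age = 50, n_genes = 100, seed = 7)
  tc1 <- generate_timecourse(cfg)
  tc2 <- generate_timecourse(cfg)
  expect_identical(tc1[[1]]$counts, tc2[[1]]$counts)
  expect_identical(tc1[[2]]$counts, tc2[[2]]$counts)
  expect_identical(tc1[[1]]$annotation, tc2[[1]]$annotation)

  expect_error(timecourse_config(ages = "P1",
                                 subtypes = list(subtype_spec("S1")),
                                 n_cells_per_age = 10), "ages")
  expect_error(timecourse_config(ages = c("P1", "P1"),
                                 subtypes = list(subtype_spec("S1")),
                                 n_cells_per_age = 10), "ages")
  expect_error(timecourse_config(
    ages = c("P1", "P4"),
    subtypes = list(subtype_spec("S1", proportion_schedule = 0.6)),
    n_cells_per_age = 10), "proportion_schedule")
  expect_error(subtype_spec("S1", drift = 1.2), "drift")
  expect_error(subtype_spec("S1", dispersion = 0), "dispersion")
  expect_error(subtype_spec("S1", mito_fraction = 1), "mito_fraction")
})

test_that("cells carry true labels and per-age subtype counts follow the schedule", {
  subs <- list(subtype_spec("S1", proportion_schedule = c(0.5, 0.2)),
               subtype_spec("S2", proportion_schedule = c(0.3, 0.3)),
               subtype_spec("S3", proportion_schedule = c(0.2, 0.5)))
  cfg <- timecourse_config(ages = c("P1", "P4"), subtypes = subs,
                           n_cells_per_age = 103, n_genes = 120, seed = 3)
  tc <- generate_timecourse(cfg)
  for (a in 1:2) {
    ann <- tc[[a]]$annotation
    expect_identical(colnames(tc[[a]]$counts), ann$cell_id)
    expect_true(all(ann$age == c("P1", "P4")[a]))
    got <- as.vector(table(factor(ann$subtype, c("S1", "S2", "S3"))))
    want <- celldyn:::apportion_cells(vapply(subs, function(s)
      s$proportion_schedule[a], numeric(1)), 103)
    expect_identical(got, want)
    expect_identical(sum(got), 103L)
  }
  # largest-remainder apportionment: hand-checked case with a tie
  expect_identical(celldyn:::apportion_cells(c(0.5, 0.25, 0.25), 101),
                   c(51L, 25L, 25L))
  expect_identical(celldyn:::apportion_cells(c(1, 1, 1) / 3, 10), c(4L, 3L, 3L))
})

test_that("counts are overdispersed: per-gene variance >= mean on 10k cells", {
  cfg <- timecourse_config(
    ages = c("P1", "P4"),
    subtypes = list(subtype_spec("S1", dispersion = 0.5, proportion_schedule = 1)),
    n_cells_per_age = 5000, n_genes = 60, n_program_genes = 10,
    n_mito_genes = 5, n_ribo_genes = 4, artifact_fraction = 0, seed = 11)
  tc <- generate_timecourse(cfg)
  x <- cbind(as.matrix(tc[[1]]$counts), as.matrix(tc[[2]]$counts))
  expect_gte(ncol(x), 10000)
  mu <- rowMeans(x)
  v <- apply(x, 1, var)
  expect_true(all(v >= mu))
})

test_that("a drift-0 subtype has the same mean program at first and last age", {
  cfg <- timecourse_config(
    ages = c("P1", "P4", "P10"),
    subtypes = list(subtype_spec("S1", drift = 0, proportion_schedule = 1)),
    n_cells_per_age = 500, n_genes = 100, artifact_fraction = 0, seed = 5)
  tc <- generate_timecourse(cfg)
  a <- as.matrix(tc[[1]]$counts)
  b <- as.matrix(tc[[3]]$counts)
  # per-gene mean differences on library-size-free proportions are centered
  # at zero (raw means share per-cell library noise across genes)
  pa <- sweep(a, 2, colSums(a), "/")
  pb <- sweep(b, 2, colSums(b), "/")
  se <- sqrt(apply(pa, 1, var) / ncol(pa) + apply(pb, 1, var) / ncol(pb))
  z <- (rowMeans(pa) - rowMeans(pb)) / se
  expect_lt(abs(mean(z)), 0.3)
  expect_lt(mean(abs(z) > 3), 0.02)
})

test_that("spatial generator is deterministic, validated, and patch-structured", {
  cfg <- spatial_config(n_cells = 300, seed = 9)
  s1 <- generate_spatial(cfg)
  s2 <- generate_spatial(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$x >= 0 & s1$x <= 100 & s1$y >= 0 & s1$y <= 100))

  # degenerate field: no patch and zero low mean => ligand identically zero
  flat <- generate_spatial(spatial_config(n_cells = 100, coloc_fraction = 0,
                                          ligand_low = 0, seed = 2))
  expect_true(all(flat$ligand == 0))
  expect_false(any(flat$in_patch))

  expect_error(spatial_config(n_cells = 5, k_neighbors = 5), "k_neighbors")
  expect_error(spatial_config(ligand_high = 1, ligand_low = 2), "ligand_high")
})
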