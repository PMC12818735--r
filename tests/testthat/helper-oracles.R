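# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive: pair-by-pair counting, exhaustive enumeration, dense
# arithmetic. The package code must agree with it, never the other way round.

# All set partitions of n items as restricted-growth label strings (0-based).
enumerate_partitions <- function(n) {
  res <- list()
  rec <- function(pref, mx) {
    if (length(pref) == n) {
      res[[length(res) + 1L]] <<- pref
      return(invisible())
    }
    for (l in 0:(mx + 1L)) rec(c(pref, l), max(mx, l))
  }
  rec(integer(0), -1L)
  do.call(rbind, res)
}

# Rand index by explicit counting over all element pairs.
ri_brute <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# Co-membership indicator over the upper triangle, one row per partition.
comembership <- function(parts) {
  n <- ncol(parts)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- apply(parts, 1L, function(p) as.numeric(p[ut[, 1]] == p[ut[, 2]]))
  if (is.null(dim(out))) matrix(out, ncol = 1L) else t(out)
}

# Colocalization score by exhaustive enumeration (ties in distance assumed
# absent, which holds almost surely for the random fields used).
lr_oracle <- function(spatial, k, normalize = TRUE, include_self = TRUE) {
  mm <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else if (r[2] > 0) v / r[2] else v
  }
  L <- if (normalize) mm(spatial$ligand) else spatial$ligand
  R <- if (normalize) mm(spatial$receptor) else spatial$receptor
  n <- nrow(spatial)
  vapply(seq_len(n), function(i) {
    d <- sqrt((spatial$x - spatial$x[i])^2 + (spatial$y - spatial$y[i])^2)
    nb <- setdiff(order(d), i)[seq_len(k)]
    cand <- if (include_self) c(nb, i) else nb
    max(vapply(cand, function(j) max(L[i] * R[j], L[j] * R[i]), numeric(1)))
  }, numeric(1))
}

# 5-cell QC toy: totals {2000, 999, 1500, 1200, 3000}, mitochondrial
# fractions {0.05, 0, 0.20, 0.10, 0.149}; every cell except the 999-count one
# detects >= 1000 genes.
make_qc_toy <- function() {
  totals <- c(2000, 999, 1500, 1200, 3000)
  mito_frac <- c(0.05, 0, 0.20, 0.10, 0.149)
  n_reg <- 1200
  genes <- c(sprintf("mt-g%02d", 1:10), sprintf("g%04d", seq_len(n_reg)))
  m <- matrix(0, length(genes), 5,
              dimnames = list(genes, sprintf("cell%d", 1:5)))
  for (c in 1:5) {
    mt <- round(mito_frac[c] * totals[c])
    body <- totals[c] - mt
    ones <- min(1050, body)
    m[10 + seq_len(ones), c] <- 1
    m[11, c] <- m[11, c] + (body - ones)
    m[1, c] <- mt
  }
  stopifnot(colSums(m) == totals,
            abs(colSums(m[1:10, ]) / totals - mito_frac) < 1e-12)
  methods::as(m, "CsparseMatrix")
}

# Compact drifting-vs-stable course used by several dynamics tests.
make_course <- function(ages = c("P1", "P4"), drift_a = 0, drift_b = 0,
                        n_cells = 120, n_genes = 200, seed = 1, ...) {
  subs <- c(lapply(sprintf("A%d", 1:2), function(s)
              subtype_spec(s, "A", drift = drift_a, proportion_schedule = 0.25)),
            lapply(sprintf("B%d", 1:2), function(s)
              subtype_spec(s, "B", drift = drift_b, proportion_schedule = 0.25)))
  generate_timecourse(timecourse_config(ages = ages, subtypes = subs,
                                        n_cells_per_age = n_cells,
                                        n_genes = n_genes, seed = seed, ...))
}

course_class_map <- function() {
  stats::setNames(rep(c("A", "B"), each = 2), sprintf("%s%d", rep(c("A", "B"), each = 2), rep(1:2, 2)))
}

# A fake transfer result built directly from label vectors, for partition-
# level tests that need no classifier.
fake_transfer <- function(true, predicted, source_age = "P1", target_age = "P4",
                          source_levels = sort(unique(predicted))) {
  ids <- sprintf("c%03d", seq_along(true))
  structure(list(source_age = source_age, target_age = target_age,
                 predicted = stats::setNames(predicted, ids),
                 true = stats::setNames(true, ids),
                 confusion = table(true = factor(true),
                                   predicted = factor(predicted, levels = source_levels))),
            class = "transfer_result")
}
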