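#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon (Mann-Whitney) rank-sum test between two cell
#' groups on normalized expression, with normal approximation, tie
#' correction, and continuity correction. Fold changes are computed on the
#' de-logged (`expm1`) normalized means with a pseudocount of 1:
#' `log2((mean_a + 1) / (mean_b + 1))`. Genes at or below the absolute
#' log2 fold-change threshold are not tested (reported with `tested =
#' FALSE`); p-values of tested genes are Bonferroni-adjusted by default.
#' For groups with fewer than 3 cells a warning is issued and the exact
#' small-sample distribution is used where ties permit.
#'
#' @param norm Normalized gene x cell expression matrix (see
#'   [normalize_counts()]).
#' @param groups Factor (or character) of length `ncol(norm)` with exactly
#'   two levels; the first level is group A, whose higher expression gives
#'   positive fold changes.
#' @param lfc_threshold Absolute log2 fold-change below or at which genes
#'   are skipped (default 0.25).
#' @param adjust Multiple-testing adjustment over tested genes
#'   (`"bonferroni"` default, or any [stats::p.adjust()] method).
#' @param pseudocount Added inside the fold-change log.
#' @return A `de_result` data.frame with one row per gene: `gene`,
#'   `log2_fold_change`, `mean_a`, `mean_b`, `p_value`, `adjusted_p`,
#'   `direction` (`"up"`/`"down"` relative to group A), `tested`.
#' @export
wilcoxon_de <- function(norm, groups, lfc_threshold = 0.25,
                        adjust = "bonferroni", pseudocount = 1) {
  assert_count_matrix(norm, "norm")
  groups <- factor(groups)
  if (nlevels(groups) != 2L)
    stop("`groups` must have exactly two levels", call. = FALSE)
  if (length(groups) != ncol(norm))
    stop("`groups` must have one entry per cell", call. = FALSE)
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  if (!length(ia) || !length(ib))
    stop("both groups must be non-empty", call. = FALSE)
  small <- min(length(ia), length(ib)) < 3L
  if (small)
    warning("a group has fewer than 3 cells; using exact p-values where ties permit",
            call. = FALSE)
  e <- as.matrix(norm)
  ea <- expm1(e[, ia, drop = FALSE])
  eb <- expm1(e[, ib, drop = FALSE])
  mean_a <- rowMeans(ea)
  mean_b <- rowMeans(eb)
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  tested <- abs(lfc) > lfc_threshold
  p <- rep(NA_real_, nrow(e))
  if (any(tested)) {
    xa <- e[tested, ia, drop = FALSE]
    xb <- e[tested, ib, drop = FALSE]
    p[tested] <- if (small)
      vapply(seq_len(nrow(xa)), function(g)
        suppressWarnings(stats::wilcox.test(xa[g, ], xb[g, ])$p.value),
        numeric(1))
    else
      rank_sum_p(xa, xb)
  }
  adj <- rep(NA_real_, nrow(e))
  adj[tested] <- stats::p.adjust(p[tested], method = adjust)
  out <- data.frame(gene = rownames(e), log2_fold_change = lfc,
                    mean_a = mean_a, mean_b = mean_b, p_value = p,
                    adjusted_p = adj,
                    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
                    tested = tested, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  attr(out, "lfc_threshold") <- lfc_threshold
  out
}

# Row-wise two-sided Mann-Whitney with normal approximation, tie and
# continuity correction (matches stats::wilcox.test(exact = FALSE)).
rank_sum_p <- function(xa, xb) {
  na <- ncol(xa)
  nb <- ncol(xb)
  n <- na + nb
  vapply(seq_len(nrow(xa)), function(g) {
    v <- c(xa[g, ], xb[g, ])
    r <- rank(v)
    U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - na * nb / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))
}

#' Subtype proportion time course and coefficient of variation
#'
#' Per age, the fraction of cells belonging to each subtype; per subtype,
#' the coefficient of variation (population standard deviation / mean) of
#' its fractions across ages. Optionally the CV is computed on the
#' consecutive-age changes (deltas) of the fractions instead.
#'
#' @param annotation Data.frame with `cell_id`, `age`, `subtype` covering
#'   at least two ages.
#' @param age_order Ordered age labels; every age must have cells.
#' @param cv_of `"proportions"` (default) or `"deltas"`.
#' @return A `proportion_table` list: `fractions` (subtype x age matrix,
#'   columns summing to 1) and `cv` (named per-subtype vector).
#' @export
subtype_proportions <- function(annotation, age_order,
                                cv_of = c("proportions", "deltas")) {
  cv_of <- match.arg(cv_of)
  ages <- factor(annotation$age, levels = age_order)
  if (anyNA(ages))
    stop("annotation contains ages outside `age_order`", call. = FALSE)
  if (length(age_order) < 2L)
    stop("need at least two ages", call. = FALSE)
  tab <- table(subtype = annotation$subtype, age = ages)
  totals <- colSums(tab)
  if (any(totals == 0))
    stop(sprintf("age `%s` has no cells", age_order[which(totals == 0)[1]]),
         call. = FALSE)
  frac <- sweep(unclass(tab), 2, totals, "/")
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  cv <- apply(frac, 1, function(x) {
    v <- if (cv_of == "deltas") diff(x) else x
    m <- mean(v)
    if (m == 0) 0 else pop_sd(v) / abs(m)
  })
  structure(list(fractions = frac, cv = cv, cv_of = cv_of),
            class = "proportion_table")
}
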