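#' Spatial k-nearest neighbors
#'
#' Euclidean nearest neighbors over cell centroids, self excluded. Distance
#' ties are broken by cell identifier order, so the result is deterministic.
#'
#' @param spatial Data.frame with columns `cell_id`, `x`, `y` (e.g. from
#'   [read_spatial()] or [generate_spatial()]).
#' @param k Number of neighbors; must be < number of cells.
#' @return An integer matrix (cells x k) of neighbor row indices, with cell
#'   ids as rownames.
#' @export
knn_neighbors <- function(spatial, k = 5) {
  n <- nrow(spatial)
  if (n <= k) stop(sprintf("k = %d requires more than %d cells", k, n),
                   call. = FALSE)
  d <- as.matrix(stats::dist(spatial[, c("x", "y")]))
  id_rank <- rank(spatial$cell_id, ties.method = "first")
  nb <- matrix(0L, n, k, dimnames = list(spatial$cell_id, NULL))
  for (i in seq_len(n)) {
    cand <- setdiff(order(d[i, ], id_rank), i)
    nb[i, ] <- cand[seq_len(k)]
  }
  nb
}

minmax_scale <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
  else if (rng[2] > 0) v / rng[2]
  else v
}

#' Ligand-receptor spatial colocalization score
#'
#' For every cell, the strongest ligand-receptor interaction between the cell
#' and its `k` spatial nearest neighbors: the pair strength between cells
#' `i` and `j` is `max(L_i * R_j, L_j * R_i)` (the stronger of the two
#' directional ligand->receptor products; switchable to the single direction
#' `L_i * R_j` via `rule`), and the cell's score is the maximum pair strength
#' over its neighborhood. The cell itself is part of its neighborhood by
#' default (a cell co-expressing ligand and receptor colocalizes trivially).
#' Intensities are min-max scaled to `[0, 1]` per gene by default, since
#' fluorescence units are arbitrary; disable with `normalize = FALSE` to
#' score on raw values (under which the score is exactly scale-equivariant).
#'
#' @param spatial Data.frame with columns `cell_id`, `x`, `y` and the two
#'   expression columns.
#' @param ligand,receptor Names of the ligand and receptor columns.
#' @param k Spatial nearest neighbors per cell (default 5).
#' @param normalize Min-max scale each gene before scoring (default TRUE).
#' @param include_self Include the cell in its own candidate pair set.
#' @param rule `"strongest"` (both directions, take the max) or
#'   `"directional"` (`L_i * R_j` only, cell as ligand sender).
#' @return A `lr_score_field` data.frame with columns `cell_id`, `x`, `y`,
#'   `score`; neighbor ids are attached as `attr(, "neighbors")`.
#' @export
lr_score <- function(spatial, ligand = "ligand", receptor = "receptor", k = 5,
                     normalize = TRUE, include_self = TRUE,
                     rule = c("strongest", "directional")) {
  rule <- match.arg(rule)
  for (g in c(ligand, receptor))
    if (!g %in% names(spatial))
      stop(sprintf("gene column `%s` not present", g), call. = FALSE)
  L <- spatial[[ligand]]
  R <- spatial[[receptor]]
  if (normalize) {
    L <- minmax_scale(L)
    R <- minmax_scale(R)
  }
  nb <- knn_neighbors(spatial, k)
  n <- nrow(spatial)
  score <- numeric(n)
  for (i in seq_len(n)) {
    j <- nb[i, ]
    s <- if (rule == "strongest") pmax(L[i] * R[j], L[j] * R[i]) else L[i] * R[j]
    if (include_self) s <- c(s, L[i] * R[i])
    score[i] <- max(s)
  }
  out <- data.frame(cell_id = spatial$cell_id, x = spatial$x, y = spatial$y,
                    score = score, stringsAsFactors = FALSE)
  attr(out, "neighbors") <- matrix(spatial$cell_id[nb], n, k,
                                   dimnames = list(spatial$cell_id, NULL))
  class(out) <- c("lr_score_field", "data.frame")
  out
}

#' Compare two colocalization score fields
#'
#' Two-sided Wilcoxon rank-sum test on the per-cell scores, reporting
#' medians and effect direction.
#'
#' @param field_a,field_b `lr_score_field` data.frames (or anything with a
#'   `score` column), e.g. the same ligand-receptor pair scored at two ages.
#' @return A list with `median_a`, `median_b`, `direction` (`"a>b"`,
#'   `"a<b"`, or `"a=b"` on medians), and `p_value`.
#' @export
compare_fields <- function(field_a, field_b) {
  a <- field_a$score
  b <- field_b$score
  if (!length(a) || !length(b))
    stop("empty score field", call. = FALSE)
  p <- stats::wilcox.test(a, b, exact = FALSE)$p.value
  ma <- stats::median(a)
  mb <- stats::median(b)
  list(median_a = ma, median_b = mb,
       direction = if (ma > mb) "a>b" else if (ma < mb) "a<b" else "a=b",
       p_value = p, n_a = length(a), n_b = length(b))
}

#' Assign spot identities from deconvolution abundances
#'
#' Each spot is labelled with the non-excluded subtype of highest abundance;
#' ties are broken by subtype name order, and spots whose non-excluded
#' abundances are all zero are labelled `"unassigned"`.
#'
#' @param ab Abundance matrix (spots x subtypes) with dimnames, e.g. from
#'   [read_abundance()].
#' @param exclude Subtype names excluded before the argmax (e.g. an
#'   artifact-prone subtype).
#' @return Named character vector of per-spot labels.
#' @export
assign_spot_labels <- function(ab, exclude = character()) {
  keep <- setdiff(colnames(ab), exclude)
  if (!length(keep)) stop("all subtypes excluded", call. = FALSE)
  ab <- ab[, sort(keep), drop = FALSE]      # name order makes ties deterministic
  lab <- colnames(ab)[max.col(ab, ties.method = "first")]
  lab[rowSums(ab) == 0] <- "unassigned"
  stats::setNames(lab, rownames(ab))
}
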