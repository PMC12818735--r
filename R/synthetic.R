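#' Describe one simulated cell subtype
#'
#' A subtype is defined by a sparse expression program drawn at the first age
#' (`P_start`) and an independently drawn program at the last age (`P_end`).
#' `drift` controls how far the subtype's mean program interpolates from
#' `P_start` toward `P_end` across the age axis: at age index `a` of `A` ages
#' the mean program is `(1 - drift * a/(A-1)) * P_start + drift * a/(A-1) *
#' P_end`, so `drift = 0` is a transcriptomically stable subtype and
#' `drift = 1` full program replacement, mimicking immature-to-mature
#' maturation of cortical neurons.
#'
#' @param name Subtype label.
#' @param class_name Class label grouping subtypes (e.g. all IT subtypes
#'   share class `"IT"`). Defaults to `name`.
#' @param drift Real in `[0, 1]`; program replacement across the course.
#' @param proportion_schedule Per-age fraction of cells belonging to this
#'   subtype; either one value per age or a single value recycled.
#' @param mean_library_size Expected total UMI counts per cell.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`);
#'   must be > 0.
#' @param mito_fraction Expected mitochondrial fraction of each cell's
#'   library, in `[0, 1)`.
#' @return A `subtype_spec` list.
#' @export
subtype_spec <- function(name, class_name = name, drift = 0,
                         proportion_schedule = 1, mean_library_size = 5000,
                         dispersion = 0.5, mito_fraction = 0.05) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    config_error("name", "must be a non-empty string")
  if (!is.numeric(drift) || length(drift) != 1L || drift < 0 || drift > 1)
    config_error("drift", "must be a single value in [0, 1]")
  if (!is.numeric(dispersion) || dispersion <= 0)
    config_error("dispersion", "must be > 0")
  if (mito_fraction < 0 || mito_fraction >= 1)
    config_error("mito_fraction", "must be in [0, 1)")
  if (any(proportion_schedule < 0) || any(proportion_schedule > 1))
    config_error("proportion_schedule", "fractions must be in [0, 1]")
  if (mean_library_size <= 0)
    config_error("mean_library_size", "must be positive")
  structure(list(name = name, class_name = class_name, drift = drift,
                 proportion_schedule = proportion_schedule,
                 mean_library_size = mean_library_size,
                 dispersion = dispersion, mito_fraction = mito_fraction),
            class = "subtype_spec")
}

#' Configure a multi-age simulated time course
#'
#' @param ages Ordered character vector of unique age labels (>= 2).
#' @param subtypes List of [subtype_spec()] objects.
#' @param n_cells_per_age Cells simulated at each age (single value or one
#'   per age).
#' @param n_genes Total genes, including mitochondrial/ribosomal ones.
#' @param n_program_genes Program genes per subtype signature; default 10% of
#'   `n_genes`.
#' @param program_strength Multiplicative up-weighting of program genes over
#'   the flat baseline.
#' @param n_mito_genes,n_ribo_genes Genes carrying the `mt-` and `Rps`/`Rpl`
#'   prefixes so quality-control recognizes them.
#' @param artifact_fraction Fraction of cells injected as low-quality
#'   artifacts (elevated mitochondrial content, reduced library size), giving
#'   the QC thresholds true positives.
#' @param artifact_mito_fraction Expected mitochondrial fraction of artifact
#'   cells.
#' @param library_sdlog Log-normal sd of per-cell library sizes.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `timecourse_config` list, validated.
#' @export
timecourse_config <- function(ages, subtypes, n_cells_per_age, n_genes = 500,
                              n_program_genes = NULL, program_strength = 4,
                              n_mito_genes = 10, n_ribo_genes = 10,
                              artifact_fraction = 0.02,
                              artifact_mito_fraction = 0.35,
                              library_sdlog = 0.3, seed = 1) {
  if (length(ages) < 2L) config_error("ages", "need at least two ages")
  if (anyDuplicated(ages)) config_error("ages", "age labels must be unique")
  if (!length(subtypes) || !all(vapply(subtypes, inherits, TRUE, "subtype_spec")))
    config_error("subtypes", "must be a non-empty list of subtype_spec objects")
  A <- length(ages)
  n_cells_per_age <- rep_len(as.integer(n_cells_per_age), A)
  if (any(n_cells_per_age <= 0L))
    config_error("n_cells_per_age", "must be positive")
  if (is.null(n_program_genes)) n_program_genes <- max(5L, round(0.1 * n_genes))
  if (n_genes < n_program_genes + n_mito_genes + n_ribo_genes)
    config_error("n_genes",
                 "must be at least n_program_genes + n_mito_genes + n_ribo_genes")
  sched <- vapply(subtypes, function(s) rep_len(s$proportion_schedule, A),
                  numeric(A))
  sums <- if (A == 1L) sum(sched) else rowSums(sched)
  if (any(abs(sums - 1) > 1e-9))
    config_error("proportion_schedule",
                 sprintf("per-age proportions must sum to 1 (age %s sums to %.12g)",
                         ages[which.max(abs(sums - 1))], sums[which.max(abs(sums - 1))]))
  if (artifact_fraction < 0 || artifact_fraction >= 1)
    config_error("artifact_fraction", "must be in [0, 1)")
  structure(list(ages = as.character(ages), subtypes = subtypes,
                 n_cells_per_age = n_cells_per_age, n_genes = as.integer(n_genes),
                 n_program_genes = as.integer(n_program_genes),
                 program_strength = program_strength,
                 n_mito_genes = as.integer(n_mito_genes),
                 n_ribo_genes = as.integer(n_ribo_genes),
                 artifact_fraction = artifact_fraction,
                 artifact_mito_fraction = artifact_mito_fraction,
                 library_sdlog = library_sdlog, seed = as.integer(seed),
                 schedule = sched),
            class = "timecourse_config")
}

# Largest-remainder apportionment of n cells to proportions; ties broken by
# subtype order.
apportion_cells <- function(props, n) {
  raw <- props * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    ord <- order(-(raw - counts), seq_along(props))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Simulate a multi-age single-cell count time course
#'
#' Counts are negative-binomial around subtype-and-age mean programs with
#' log-normal per-cell library sizes; a configurable fraction of cells is
#' injected as mitochondrial/low-count artifacts. Every cell carries its true
#' subtype, class, and age in the per-age annotation table.
#'
#' @param config A [timecourse_config()].
#' @return A list of class `timecourse_data` with one element per age, each a
#'   list with `age`, `counts` (sparse gene x cell matrix with gene rownames
#'   and cell colnames), and `annotation` (data.frame with columns `cell_id`,
#'   `age`, `subtype`, `class`, `artifact`).
#' @export
generate_timecourse <- function(config) {
  if (!inherits(config, "timecourse_config"))
    config <- do.call(timecourse_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  G <- config$n_genes
  n_mt <- config$n_mito_genes
  n_rb <- config$n_ribo_genes
  gene_ids <- c(sprintf("mt-g%02d", seq_len(n_mt)),
                sprintf("Rps%02d", seq_len(ceiling(n_rb / 2))),
                sprintf("Rpl%02d", seq_len(floor(n_rb / 2))),
                sprintf("gene%04d", seq_len(G - n_mt - n_rb)))
  is_mito <- startsWith(gene_ids, "mt-")
  n_body <- G - n_mt                       # program space: all non-mito genes

  draw_program <- function() {
    p <- rep(1, n_body)
    idx <- sample.int(n_body, config$n_program_genes)
    p[idx] <- p[idx] + config$program_strength * runif(config$n_program_genes, 0.5, 1.5)
    p
  }
  programs <- lapply(config$subtypes, function(s)
    list(start = draw_program(), end = draw_program()))

  A <- length(config$ages)
  out <- vector("list", A)
  for (a in seq_len(A)) {
    n_cells <- config$n_cells_per_age[a]
    per_sub <- apportion_cells(config$schedule[a, ], n_cells)
    counts_blocks <- vector("list", length(config$subtypes))
    ann_blocks <- vector("list", length(config$subtypes))
    cell0 <- 0L
    for (s in seq_along(config$subtypes)) {
      ns <- per_sub[s]
      if (ns == 0L) next
      sub <- config$subtypes[[s]]
      w <- if (A == 1L) 0 else sub$drift * (a - 1) / (A - 1)
      prog <- (1 - w) * programs[[s]]$start + w * programs[[s]]$end
      lib <- rlnorm(ns, log(sub$mean_library_size) - config$library_sdlog^2 / 2,
                    config$library_sdlog)
      artifact <- runif(ns) < config$artifact_fraction
      mito_frac <- ifelse(artifact, config$artifact_mito_fraction, sub$mito_fraction)
      lib <- ifelse(artifact, lib * 0.3, lib)
      # per-gene mean: non-mito genes share (1 - mito_frac) by program weight,
      # mito genes split mito_frac evenly
      p_body <- prog / sum(prog)
      mu <- matrix(0, G, ns)
      mu[!is_mito, ] <- outer(p_body, lib * (1 - mito_frac))
      if (n_mt > 0)
        mu[is_mito, ] <- matrix(rep(lib * mito_frac / n_mt, each = n_mt), n_mt, ns)
      x <- rnbinom(length(mu), mu = as.vector(mu), size = 1 / sub$dispersion)
      counts_blocks[[s]] <- matrix(x, G, ns)
      ann_blocks[[s]] <- data.frame(
        cell_id = sprintf("%s_c%05d", config$ages[a], cell0 + seq_len(ns)),
        age = config$ages[a], subtype = sub$name, class = sub$class_name,
        artifact = artifact, stringsAsFactors = FALSE)
      cell0 <- cell0 + ns
    }
    counts <- do.call(cbind, counts_blocks[!vapply(counts_blocks, is.null, TRUE)])
    ann <- do.call(rbind, ann_blocks[!vapply(ann_blocks, is.null, TRUE)])
    rownames(ann) <- NULL
    dimnames(counts) <- list(gene_ids, ann$cell_id)
    out[[a]] <- list(age = config$ages[a],
                     counts = methods::as(methods::as(counts, "CsparseMatrix"), "dMatrix"),
                     annotation = ann)
  }
  names(out) <- config$ages
  structure(out, class = "timecourse_data", config = config)
}

#' Configure a simulated 2D spatial ligand/receptor field
#'
#' Cells are placed uniformly on a rectangle; cells falling inside a central
#' disc covering `coloc_fraction` of the domain area express both the ligand
#' and the receptor at the high means, cells outside at the low means, giving
#' a spatially structured co-expression patch.
#'
#' @param n_cells Number of cells.
#' @param width,height Domain size in arbitrary spatial units.
#' @param k_neighbors Spatial nearest neighbors used downstream (default 5,
#'   the neighborhood size of the colocalization score).
#' @param coloc_fraction Fraction of the domain (hence, in expectation, of
#'   cells) inside the high-colocalization patch, in `[0, 1]`.
#' @param ligand_high,ligand_low,receptor_high,receptor_low Nonnegative
#'   expression means; `high >= low` for both genes.
#' @param noise_sdlog Log-normal multiplicative noise sd on intensities.
#' @param seed Integer seed.
#' @return A `spatial_config` list.
#' @export
spatial_config <- function(n_cells = 1000, width = 100, height = 100,
                           k_neighbors = 5, coloc_fraction = 0.3,
                           ligand_high = 10, ligand_low = 1,
                           receptor_high = 10, receptor_low = 1,
                           noise_sdlog = 0.3, seed = 1) {
  if (n_cells <= 0) config_error("n_cells", "must be positive")
  if (k_neighbors >= n_cells)
    config_error("k_neighbors", "must be smaller than n_cells")
  if (coloc_fraction < 0 || coloc_fraction > 1)
    config_error("coloc_fraction", "must be in [0, 1]")
  if (ligand_high < ligand_low)
    config_error("ligand_high", "must be >= ligand_low")
  if (receptor_high < receptor_low)
    config_error("receptor_high", "must be >= receptor_low")
  if (min(ligand_low, receptor_low) < 0)
    config_error("ligand_low", "expression means must be nonnegative")
  structure(list(n_cells = as.integer(n_cells), width = width, height = height,
                 k_neighbors = as.integer(k_neighbors),
                 coloc_fraction = coloc_fraction,
                 ligand_high = ligand_high, ligand_low = ligand_low,
                 receptor_high = receptor_high, receptor_low = receptor_low,
                 noise_sdlog = noise_sdlog, seed = as.integer(seed)),
            class = "spatial_config")
}

#' Simulate a segmented-cell spatial field with a co-expression patch
#'
#' @param config A [spatial_config()].
#' @return A data.frame with columns `cell_id`, `x`, `y`, `ligand`,
#'   `receptor`, and the ground-truth flag `in_patch`.
#' @export
generate_spatial <- function(config) {
  if (!inherits(config, "spatial_config"))
    config <- do.call(spatial_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n_cells
  x <- runif(n, 0, config$width)
  y <- runif(n, 0, config$height)
  radius <- sqrt(config$coloc_fraction * config$width * config$height / pi)
  in_patch <- (x - config$width / 2)^2 + (y - config$height / 2)^2 <= radius^2
  noise <- function(n) rlnorm(n, -config$noise_sdlog^2 / 2, config$noise_sdlog)
  ligand <- ifelse(in_patch, config$ligand_high, config$ligand_low) * noise(n)
  receptor <- ifelse(in_patch, config$receptor_high, config$receptor_low) * noise(n)
  data.frame(cell_id = sprintf("cell%05d", seq_len(n)), x = x, y = y,
             ligand = ligand, receptor = receptor, in_patch = in_patch,
             stringsAsFactors = FALSE)
}
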