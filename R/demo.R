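#' Configuration of the end-to-end demonstration pipeline
#'
#' Assembles the stage configurations of the full pipeline: simulate a
#' multi-age course with one drifting and one stable class plus a spatial
#' co-expression field, run QC and normalization, transfer labels across
#' consecutive ages, score per-class dynamics, call differential expression,
#' and score spatial colocalization. A single global seed is fanned out to
#' every stochastic stage via stage-name-salted sub-seeds, so stages are
#' reproducible independently.
#'
#' @param out_dir Output directory (created if needed); all reports are
#'   written inside it.
#' @param seed Global integer seed.
#' @param ages Ordered age labels.
#' @param n_cells_per_age,n_genes Scale of the simulated course.
#' @param drift_high Drift of the reorganizing class (the stable class has
#'   drift 0).
#' @param classifier A [classifier_spec()].
#' @param qc A [qc_config()]; defaults are rescaled to the simulated library
#'   sizes.
#' @param spatial A [spatial_config()] for the patch field.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 0,
                            ages = c("P1", "P4", "P10", "Adult"),
                            n_cells_per_age = 250, n_genes = 400,
                            drift_high = 0.8,
                            classifier = classifier_spec(seed = seed),
                            qc = qc_config(min_counts_per_cell = 500,
                                           min_genes_per_cell = 50),
                            spatial = spatial_config(seed = seed)) {
  problems <- character()
  if (missing(out_dir) || is.null(out_dir) || !nzchar(out_dir))
    problems <- c(problems, "`out_dir` is required")
  if (is.null(ages) || length(ages) < 2L)
    problems <- c(problems, "`ages` must list at least two ordered age labels")
  if (!is.numeric(seed) || length(seed) != 1L)
    problems <- c(problems, "`seed` must be a single integer")
  if (!is.numeric(n_cells_per_age) || any(n_cells_per_age <= 0))
    problems <- c(problems, "`n_cells_per_age` must be positive")
  if (!is.numeric(n_genes) || n_genes < 50)
    problems <- c(problems, "`n_genes` must be at least 50")
  if (!inherits(classifier, "classifier_spec"))
    problems <- c(problems, "`classifier` must be a classifier_spec")
  if (!inherits(qc, "qc_config"))
    problems <- c(problems, "`qc` must be a qc_config")
  if (!inherits(spatial, "spatial_config"))
    problems <- c(problems, "`spatial` must be a spatial_config")
  if (length(problems))
    stop(paste0("invalid pipeline configuration:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), ages = ages,
                 n_cells_per_age = n_cells_per_age, n_genes = n_genes,
                 drift_high = drift_high, classifier = classifier, qc = qc,
                 spatial = spatial),
            class = "pipeline_config")
}

#' Run the end-to-end demonstration pipeline
#'
#' Generator -> QC -> cross-age dynamics -> differential expression ->
#' spatial colocalization, writing `dynamics.json`, `sankey.csv`, `de.csv`,
#' `lr_scores.csv`, `proportions.csv` and a human-readable `demo.log` into
#' the output directory. Deterministic given the global seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_demo <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "demo.log")
  log_lines <- character()
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    say(stage, "done in %.2fs", proc.time()[["elapsed"]] - t0)
    r
  }

  # simulate: one drifting class (3 subtypes) vs one stable class (2 subtypes)
  drifting <- paste0("IT.", 1:3)
  stable <- paste0("PT.", 1:2)
  subtypes <- c(
    lapply(drifting, function(s)
      subtype_spec(s, class_name = "IT", drift = config$drift_high,
                   proportion_schedule = 0.6 / 3)),
    lapply(stable, function(s)
      subtype_spec(s, class_name = "PT", drift = 0,
                   proportion_schedule = 0.4 / 2)))
  tc_cfg <- timecourse_config(ages = config$ages, subtypes = subtypes,
                              n_cells_per_age = config$n_cells_per_age,
                              n_genes = config$n_genes,
                              seed = stage_seed(config$seed, "simulate"))
  course <- timed("simulate", generate_timecourse(tc_cfg))
  sp_cfg <- config$spatial
  sp_cfg$seed <- stage_seed(config$seed, "spatial")
  patch <- generate_spatial(sp_cfg)
  flat_cfg <- sp_cfg
  flat_cfg$coloc_fraction <- 0
  flat_cfg$seed <- stage_seed(config$seed, "spatial_flat")
  flat <- generate_spatial(flat_cfg)

  # qc + normalization per age
  prep <- timed("qc", lapply(course, function(stage) {
    fc <- filter_cells(stage$counts, config$qc)
    kept <- filter_genes(fc$counts, config$qc)
    ann <- stage$annotation[match(colnames(kept), stage$annotation$cell_id), ]
    list(age = stage$age, norm = normalize_counts(kept, config$qc),
         annotation = ann, report = fc$report)
  }))

  # dynamics across consecutive pairs
  spec <- config$classifier
  transfers <- timed("dynamics", lapply(seq_len(length(prep) - 1L), function(i) {
    src <- prep[[i]]
    tgt <- prep[[i + 1L]]
    hvgs <- select_hvgs(src$norm, config$qc)
    transfer_labels(src$norm, src$annotation, tgt$norm, tgt$annotation,
                    spec = spec, hvgs = hvgs)
  }))
  class_map <- stats::setNames(
    vapply(subtypes, `[[`, character(1), "class_name"),
    vapply(subtypes, `[[`, character(1), "name"))
  dyn <- dynamic_scores(transfers, class_map)
  edges <- sankey_edges(transfers)

  # differential expression: drifting subtype, first vs last age
  first <- prep[[1L]]
  last <- prep[[length(prep)]]
  sub <- drifting[1L]
  genes <- intersect(rownames(first$norm), rownames(last$norm))
  a <- first$norm[genes, first$annotation$subtype == sub, drop = FALSE]
  b <- last$norm[genes, last$annotation$subtype == sub, drop = FALSE]
  de <- timed("de", wilcoxon_de(
    cbind(a, b),
    factor(rep(c("first", "last"), c(ncol(a), ncol(b))), c("first", "last"))))

  # proportions across the course
  ann_all <- do.call(rbind, lapply(course, `[[`, "annotation"))
  props <- subtype_proportions(ann_all, config$ages)

  # spatial colocalization: patch field vs uniform field
  lr_patch <- timed("lrscore", lr_score(patch, k = sp_cfg$k_neighbors))
  lr_flat <- lr_score(flat, k = sp_cfg$k_neighbors)
  field_cmp <- compare_fields(lr_patch, lr_flat)

  # reports
  paths <- list(
    dynamics = file.path(config$out_dir, "dynamics.json"),
    sankey = file.path(config$out_dir, "sankey.csv"),
    de = file.path(config$out_dir, "de.csv"),
    lr = file.path(config$out_dir, "lr_scores.csv"),
    proportions = file.path(config$out_dir, "proportions.csv"),
    log = log_path)
  jsonlite::write_json(list(
    pairs = dyn$pairs, summary = dyn$summary, comparisons = dyn$comparisons,
    field_comparison = field_cmp,
    qc = lapply(prep, `[[`, "report")),
    paths$dynamics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(edges, paths$sankey, row.names = FALSE, quote = FALSE)
  write.csv(de, paths$de, row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(lr_patch), paths$lr, row.names = FALSE, quote = FALSE)
  fr <- data.frame(subtype = rownames(props$fractions), props$fractions,
                   cv = props$cv, check.names = FALSE)
  write.csv(fr, paths$proportions, row.names = FALSE, quote = FALSE)
  ranking <- dyn$summary[order(-dyn$summary$mean_score), "class"]
  say("report", "class ranking by mean dynamic score: %s",
      paste(ranking, collapse = " > "))
  writeLines(log_lines, log_path)
  invisible(list(dynamics = dyn, sankey = edges, de = de,
                 proportions = props, lr_patch = lr_patch, lr_flat = lr_flat,
                 field_comparison = field_cmp, transfers = transfers,
                 paths = paths))
}
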