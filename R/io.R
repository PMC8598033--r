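# File formats and the end-to-end pipeline. All writes are atomic
# (temp file in the target directory, then rename); CSV schemas are
# validated on read; TIFF stacks are 16-bit grayscale, one page per
# timepoint.

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

#' Write / read a multi-page 16-bit grayscale TIFF stack
#'
#' @param frames list of integer matrices (0..65535), one per page.
#' @param path output file.
#' @return `path` invisibly; `read_stack_tiff` returns the list of
#'   integer matrices.
#' @export
write_stack_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  pages <- lapply(frames, function(m) {
    stopifnot(is.matrix(m), all(m >= 0), all(m <= 65535))
    m / 65535
  })
  atomic_write(path, function(p)
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, compression = "none"))
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) matrix(as.integer(round(m * 65535)),
                                   nrow(m), ncol(m)))
}

#' Write / read a feature table CSV (manifest schema)
#'
#' Columns: `cell_id`, `time_min`, the 169 manifest features, and any
#' extra metadata columns (e.g. `label`). The schema is validated on both
#' ends; a missing manifest column is an error naming it.
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @export
write_feature_csv <- function(table, path) {
  validate_feature_table(table)
  atomic_write(path, function(p)
    utils::write.csv(table, p, row.names = FALSE))
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  validate_feature_table(out)
  out
}

#' Write a JSON report (atomic, unboxed scalars)
#' @param x list to serialize.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  atomic_write(path, function(p)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
}

#' Run the full pipeline from a configuration
#'
#' simulate -> segment -> extract -> classify and/or cluster. Each stage
#' writes its artifact under `out_dir` and logs row counts; a
#' `manifest.json` listing every produced file with its md5 checksum is
#' written last. Stage configs mirror the constructor arguments of
#' [scene_plan()], [phenotype_spec()], [experiment_plan()] and
#' [cluster_subphenotypes()].
#'
#' @param config a named list (or path to a YAML file) with elements
#'   `scene` (scene_plan args), `phenotypes` (named list of
#'   phenotype_spec args), optional `mix`, optional `classify`
#'   (experiment_plan args), optional `cluster` (list with
#'   `purity_threshold`, `k_min`, `k_max`, `truth_col`), and `seed`.
#' @param out_dir output directory (created if needed).
#' @return invisible list with the stage results and the file manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$scene), !is.null(config$phenotypes))
  seed <- if (!is.null(config$seed)) config$seed else 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  log_line <- function(...) message(sprintf(...))

  plan <- do.call(scene_plan, c(config$scene, list(seed = seed)))
  phenos <- lapply(names(config$phenotypes), function(nm)
    do.call(phenotype_spec, c(list(name = nm), config$phenotypes[[nm]])))
  names(phenos) <- names(config$phenotypes)
  mix <- if (!is.null(config$mix)) unlist(config$mix) else NULL
  scene <- simulate_timelapse(plan, phenos, mix, seed = seed)
  stack_path <- file.path(out_dir, "stack.tif")
  via_path <- file.path(out_dir, "stack_viability.tif")
  truth_path <- file.path(out_dir, "truth.csv")
  write_stack_tiff(scene$frames, stack_path)
  write_stack_tiff(scene$viability, via_path)
  atomic_write(truth_path, function(p)
    utils::write.csv(scene$truth, p, row.names = FALSE))
  artifacts <- c(artifacts, stack_path, via_path, truth_path)
  log_line("simulate: %d wells, %d frames", nrow(scene$truth), plan$frames)

  cells <- segment_timelapse(scene$frames, plan, scene$times_min)
  cells <- filter_viability(cells, scene$viability, plan)
  retained_path <- file.path(out_dir, "cells_retained.csv")
  retained <- data.frame(
    cell_id = vapply(cells, function(cc) as.character(cc$cell_id), ""),
    n_frames = vapply(cells, function(cc) length(cc$masks), 0L))
  atomic_write(retained_path, function(p)
    utils::write.csv(retained, p, row.names = FALSE))
  artifacts <- c(artifacts, retained_path)
  log_line("segment: %d wells in, %d single live cells retained",
           nrow(scene$truth), length(cells))
  if (length(cells) == 0L) stop("pipeline: no cells retained after filtering")

  feats <- extract_table(cells, pixel_size = plan$pixel_size_um)
  feats_path <- file.path(out_dir, "features.csv")
  write_feature_csv(feats, feats_path)
  man_path <- file.path(out_dir, "feature_manifest.json")
  write_report_json(list(version = "1", features = feature_manifest()),
                    man_path)
  artifacts <- c(artifacts, feats_path, man_path)
  log_line("extract: %d rows x %d feature columns", nrow(feats), 169L)

  truth_by_cell <- scene$truth[match(retained$cell_id, scene$truth$well_id), ]
  labels <- data.frame(cell_id = retained$cell_id,
                       class = truth_by_cell$class_label,
                       subphenotype_id = truth_by_cell$subphenotype_id,
                       stringsAsFactors = FALSE)

  report <- list()
  if (!is.null(config$classify)) {
    eplan <- do.call(experiment_plan,
                     c(config$classify, list(seed = substream_seed(seed, "classify"))))
    rep_cls <- run_experiment(feats, labels, eplan)
    cls_path <- file.path(out_dir, "classification.json")
    write_report_json(list(summary = rep_cls$summary,
                           per_repeat = rep_cls$per_repeat), cls_path)
    artifacts <- c(artifacts, cls_path)
    report$classification <- rep_cls
    log_line("classify: %d repeats", eplan$repeats)
  }
  if (!is.null(config$cluster)) {
    cc <- config$cluster
    truth_col <- if (!is.null(cc$truth_col)) cc$truth_col else "class"
    if (is.null(labels[[truth_col]]) || anyNA(labels[[truth_col]])) {
      stop("clustering requested but truth labels ('", truth_col,
           "') are unavailable")
    }
    res <- cluster_subphenotypes(
      feats, labels, truth_col = truth_col,
      n_components = if (!is.null(cc$n_components)) cc$n_components else 14L,
      k_range = (if (!is.null(cc$k_min)) cc$k_min else 2):(if (!is.null(cc$k_max)) cc$k_max else 15),
      purity_threshold = if (!is.null(cc$purity_threshold)) cc$purity_threshold else 0.95,
      seed = substream_seed(seed, "cluster"))
    asg_path <- file.path(out_dir, "assignments.csv")
    atomic_write(asg_path, function(p)
      utils::write.csv(data.frame(cell_id = res$cell_id,
                                  cluster_id = res$assignments), p,
                       row.names = FALSE))
    clu_path <- file.path(out_dir, "cluster.json")
    write_report_json(list(
      k_selected = res$k, constraint_met = res$constraint_met,
      homogeneity = res$homogeneity, min_purity = res$min_purity,
      per_cluster_purity = as.list(res$per_cluster_purity)), clu_path)
    artifacts <- c(artifacts, asg_path, clu_path)
    report$cluster <- res
    log_line("cluster: selected k = %d (constraint %s)", res$k,
             if (res$constraint_met) "met" else "NOT met")
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)))
  write_report_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(scene = scene, cells = cells, features = feats,
                 labels = labels, report = report, manifest = manifest))
}
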