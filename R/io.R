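## Plain-text cohort serialisation: one delimited matrix per subject per
## modality (tab-separated, header row of region labels), a cohort-level
## seed-voxel table, a CSV of cognitive scores, a JSON ground-truth record
## and a JSON manifest tying subjects to files. Output is byte-identical on
## re-run for a fixed config.

write_matrix_tsv <- function(M, path, digits = 10) {
  df <- as.data.frame(signif(M, digits))
  colnames(df) <- colnames(M) %||% region_labels_for(ncol(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  M <- as.matrix(df)
  rownames(M) <- colnames(M)
  M
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' @param cohort a `connectome_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest (invisibly).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    n_subjects = length(cohort$subjects),
    n_regions = cohort$config$n_regions,
    samples_per_voxel = cohort$config$samples_per_voxel,
    region_labels = region_labels_for(cohort$config$n_regions),
    seed_voxels_file = "seed_voxels.tsv",
    scores_file = "scores.csv",
    ground_truth_file = "ground_truth.json",
    subjects = list()
  )
  N <- cohort$subjects[[1L]]$sc_counts$N
  utils::write.table(
    data.frame(region = manifest$region_labels, seed_voxels = N),
    file.path(dir, "seed_voxels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (s in cohort$subjects) {
    scf <- paste0(s$id, "_sc-counts.tsv")
    fcf <- paste0(s$id, "_fc-z.tsv")
    M <- s$sc_counts$M
    dimnames(M) <- list(manifest$region_labels, manifest$region_labels)
    write_matrix_tsv(M, file.path(dir, scf))
    write_matrix_tsv(s$fc_z, file.path(dir, fcf))
    manifest$subjects[[s$id]] <- list(sc_counts = scf, fc_z = fcf)
  }
  utils::write.csv(
    data.frame(subject = rownames(cohort$scores$values),
               cohort$scores$values, check.names = FALSE),
    file.path(dir, "scores.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  for (d in seq_along(gt$domains))
    gt$domains[[d]]$features <- as.list(gt$domains[[d]]$features)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `connectome_cohort` (without generator config).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  N <- utils::read.table(file.path(dir, manifest$seed_voxels_file),
                         sep = "\t", header = TRUE)$seed_voxels
  spv <- manifest$samples_per_voxel
  subjects <- lapply(names(manifest$subjects), function(id) {
    files <- manifest$subjects[[id]]
    M <- read_matrix_tsv(file.path(dir, files$sc_counts))
    list(id = id,
         sc_counts = structure(
           list(M = M, N = N, samples_per_voxel = spv,
                region_labels = colnames(M)),
           class = "streamline_counts"),
         fc_z = read_matrix_tsv(file.path(dir, files$fc_z)))
  })
  sc <- utils::read.csv(file.path(dir, manifest$scores_file),
                        check.names = FALSE)
  values <- as.matrix(sc[, -1L, drop = FALSE])
  rownames(values) <- sc[[1L]]
  gt_path <- file.path(dir, manifest$ground_truth_file)
  gt <- if (file.exists(gt_path)) jsonlite::read_json(gt_path) else NULL
  structure(list(subjects = subjects,
                 scores = cognitive_scores(values, colnames(values), gt),
                 ground_truth = gt, config = NULL),
            class = "connectome_cohort")
}
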