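#' Write a graded image set to a directory of PNGs with a manifest
#'
#' The manifest (`manifest.tsv`, columns `relative_path` and `grade`) is the
#' same dialect the trainer (which ignores grades) and the evaluator read.
#'
#' @param set a `graded_image_set`, or a list of images when `grades` is
#'   given.
#' @param dir output directory (created if missing).
#' @param grades grades aligned to `set` when `set` is a plain image list.
#' @return invisibly, the manifest data frame.
#' @export
write_image_dir <- function(set, dir, grades = NULL) {
  if (inherits(set, "graded_image_set")) {
    images <- set$images
    grades <- set$grades
  } else {
    images <- set
    if (is.null(grades)) stop("grades required when writing a plain image list")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("img_%04d.png", seq_along(images))
  for (i in seq_along(images)) {
    png::writePNG(images[[i]], file.path(dir, paths[i]))
  }
  manifest <- data.frame(relative_path = paths, grade = as.integer(grades))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Read a directory of images, optionally with a manifest
#'
#' Without a manifest, all `.png` files are read in lexicographic order and
#' grades are `NULL`. With one, images are read in manifest order and grades
#' come from its `grade` column.
#'
#' @param dir directory of PNG images.
#' @param manifest optional path to a TSV manifest (`relative_path`,
#'   `grade`).
#' @return list with `images`, `grades` (or `NULL`), `paths`.
#' @export
read_image_dir <- function(dir, manifest = NULL) {
  if (!is.null(manifest)) {
    man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    if (!all(c("relative_path", "grade") %in% names(man))) {
      stop("manifest must have columns relative_path and grade")
    }
    paths <- man$relative_path
    grades <- as.integer(man$grade)
  } else {
    paths <- sort(list.files(dir, pattern = "\\.png$"))
    if (length(paths) == 0) stop("no PNG images found in ", dir)
    grades <- NULL
  }
  images <- lapply(paths, function(p) {
    im <- png::readPNG(file.path(dir, p))
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    if (dim(im)[3] == 4) im <- im[, , 1:3, drop = FALSE]
    im
  })
  list(images = images, grades = grades, paths = paths)
}

write_predictions_tsv <- function(preds, query_paths, gallery_paths, path) {
  out <- data.frame(
    query_path = query_paths,
    predicted_grade = preds$predicted_grade,
    match_distance = preds$match_distance,
    matched_gallery_path = gallery_paths[preds$matched_id]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

write_metrics_json <- function(ev, path) {
  m <- ev$metrics
  payload <- list(
    multiclass_accuracy = m$multiclass_accuracy,
    accuracy = m$accuracy, accuracy_ci = m$accuracy_ci,
    sensitivity = m$sensitivity, sensitivity_ci = m$sensitivity_ci,
    specificity = m$specificity, specificity_ci = m$specificity_ci,
    auc = ev$roc$auc,
    confusion = as.data.frame(ev$confusion)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
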