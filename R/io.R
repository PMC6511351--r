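#' NIfTI and table input/output
#'
#' Thin wrappers around [RNifti] for the volumes the pipeline exchanges
#' (BOLD runs, gray-matter maps, atlas labels) and base-R TSV/JSON for
#' motion traces, network assignments and cohort manifests.
#'
#' @param x Object to write.
#' @param path Destination file.
#' @name visionet-io
NULL

as_nifti_with_affine <- function(arr, affine, tr = NULL) {
  img <- RNifti::asNifti(arr)
  vs <- abs(diag(affine)[1:3])
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4) c(vs, tr) else vs
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

affine_of <- function(img) {
  x <- RNifti::xform(img)
  matrix(as.numeric(x), 4, 4, dimnames = NULL)
}

#' @rdname visionet-io
#' @export
write_bold <- function(x, path) {
  stopifnot(inherits(x, "bold4d"))
  RNifti::writeNifti(as_nifti_with_affine(x$data, x$affine, x$tr), path)
  invisible(path)
}

#' @rdname visionet-io
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  bold4d(as.array(img), affine_of(img), RNifti::pixdim(img)[4])
}

#' @rdname visionet-io
#' @export
write_gm <- function(x, path) {
  stopifnot(inherits(x, "gm_map"))
  RNifti::writeNifti(as_nifti_with_affine(x$data, x$affine), path)
  invisible(path)
}

#' @rdname visionet-io
#' @export
read_gm <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(data = as.array(img), affine = affine_of(img)),
            class = "gm_map")
}

#' @rdname visionet-io
#' @param assignment_path TSV with columns `roi_id`, `network`.
#' @export
write_atlas <- function(x, path, assignment_path) {
  stopifnot(inherits(x, "atlas_networks"))
  RNifti::writeNifti(as_nifti_with_affine(x$labels, x$affine), path)
  write.table(data.frame(roi_id = as.integer(names(x$assignment)),
                         network = unname(x$assignment)),
              assignment_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname visionet-io
#' @export
read_atlas <- function(path, assignment_path) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.array(img))), dim(img))
  tab <- read.table(assignment_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  assignment <- setNames(tab$network, as.character(tab$roi_id))
  present <- sort(unique(labels[labels > 0L]))
  missing <- setdiff(as.character(present), names(assignment))
  if (length(missing))
    stop("label volume contains ROI(s) without assignment: ",
         paste(missing, collapse = ", "))
  affine <- affine_of(img)
  structure(list(labels = labels, assignment = assignment, affine = affine,
                 voxel_size_mm = abs(affine[1, 1])),
            class = "atlas_networks")
}

#' @rdname visionet-io
#' @export
write_motion <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname visionet-io
#' @export
read_motion <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

# Cohort manifest: subject table + paths + ground-truth block (synthetic
# cohorts only), as JSON.
write_manifest <- function(cohort, out_dir) {
  subj <- lapply(cohort$subjects, function(s) {
    list(id = s$id, group = s$group,
         bold = if (is.character(s$bold)) basename(s$bold) else NULL,
         gm = if (is.character(s$gm)) basename(s$gm) else NULL,
         motion = if (is.character(s$motion)) basename(s$motion) else NULL)
  })
  truth <- list(
    target_z = lapply(cohort$config$target_z, function(m) unclass(m)),
    gm_effect_d = cohort$config$gm_effect_d,
    gm_effect_voxels = gm_effect_voxels(cohort$atlas, cohort$config),
    motion_exclude = vapply(cohort$subjects,
                            function(s) isTRUE(s$exclude_truth), TRUE),
    seed = cohort$config$seed)
  manifest <- list(atlas = "atlas.nii.gz", assignment = "networks.tsv",
                   clinical = "clinical.tsv", tr = cohort$config$tr,
                   subjects = unname(subj), ground_truth = truth)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Load a cohort written by [simulate_cohort()]
#'
#' Reads the manifest and reattaches file paths; volumes are loaded
#' lazily by the pipeline, one subject at a time.
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `cohort_on_disk` object.
#' @export
read_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  atlas <- read_atlas(file.path(dir, manifest$atlas),
                      file.path(dir, manifest$assignment))
  clinical <- read.table(file.path(dir, manifest$clinical), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  subjects <- lapply(manifest$subjects, function(s) {
    list(id = s$id, group = s$group,
         bold = if (!is.null(s$bold)) file.path(dir, s$bold),
         gm = if (!is.null(s$gm)) file.path(dir, s$gm),
         motion = if (!is.null(s$motion)) file.path(dir, s$motion))
  })
  names(subjects) <- vapply(subjects, `[[`, "", "id")
  structure(list(dir = dir, atlas = atlas, clinical = clinical,
                 subjects = subjects, tr = manifest$tr,
                 ground_truth = manifest$ground_truth),
            class = "cohort_on_disk")
}
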