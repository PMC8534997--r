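# Artifact IO: numbered 8-bit image files for frames/masks/representations,
# OpenPose-convention JSON pose documents (one per frame), CSV manifests,
# YAML configs and JSON reports. Round-trips are lossless at the stated bit
# depths.

#' Read a single-frame OpenPose pose document
#'
#' Parses the body keypoints of one frame: a JSON document with a `people`
#' list whose entries hold a flat 75-number `pose_keypoints_2d` array
#' (x1, y1, c1, ..., x25, y25, c25). With several detected people, the one
#' with the highest total confidence is taken. Zero-confidence triplets are
#' preserved.
#'
#' @param path path to the JSON file.
#' @return 25 x 3 matrix of (x, y, confidence), or `NULL` when the `people`
#'   list is empty (empty-pose signal).
#' @export
read_pose_file <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  people <- doc$people
  if (is.null(people) || length(people) == 0L) return(NULL)
  arrays <- lapply(people, function(p) {
    v <- as.numeric(unlist(p$pose_keypoints_2d))
    if (length(v) != 75L)
      stop("malformed pose document: expected 75 body-keypoint numbers, got ",
           length(v), call. = FALSE)
    matrix(v, ncol = 3L, byrow = TRUE)
  })
  conf <- vapply(arrays, function(m) sum(m[, 3L]), numeric(1))
  arrays[[which.max(conf)]]
}

#' Write a single-frame OpenPose pose document
#'
#' @param keypoints 25 x 3 matrix of (x, y, confidence).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(keypoints, path) {
  stopifnot(is.matrix(keypoints), nrow(keypoints) == 25L, ncol(keypoints) == 3L)
  flat <- as.vector(t(keypoints))
  doc <- list(version = 1.3,
              people = list(list(person_id = list(-1L),
                                 pose_keypoints_2d = flat)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Read all numbered pose files of a sequence directory into a pose_sequence.
read_pose_dir <- function(dir, width, height, fps = 10) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) stop("no pose files in ", dir, call. = FALSE)
  kps <- array(0, c(25L, 3L, length(files)))
  for (i in seq_along(files)) {
    kp <- read_pose_file(files[i])
    if (!is.null(kp)) kps[, , i] <- kp
  }
  structure(list(keypoints = kps, width = width, height = height, fps = fps),
            class = "pose_sequence")
}

#' Write / read a binary mask as an 8-bit image file
#'
#' Masks are stored 0/255; reading thresholds at mid-gray.
#'
#' @param mask binary matrix (foreground > 0).
#' @param path image file path (`.png`).
#' @return `write_mask` returns `path` invisibly; `read_mask` the 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(as_ebimage((mask > 0) * 1), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  (from_ebimage(EBImage::readImage(path)) > 0.5) * 1L
}

#' Write / read an RGB frame as an 8-bit image file
#' @param frame h x w x 3 array in \[0,1\].
#' @param path image file path (`.png`).
#' @return `write_frame` returns `path` invisibly; `read_frame` the array.
#' @export
write_frame <- function(frame, path) {
  img <- EBImage::Image(aperm(frame, c(2L, 1L, 3L)), colormode = "Color")
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  aperm(EBImage::imageData(img), c(2L, 1L, 3L))
}

#' Write / read a gait representation as an 8-bit grayscale image
#'
#' Intensities are stored as `round(255 * value)`; reading restores values
#' in \[0,1\] at 8-bit precision.
#'
#' @param rep a `gait_representation`.
#' @param path image file path (`.png`).
#' @param kind,scope tags restored on read (the file itself carries only
#'   pixels).
#' @return `write_representation` returns `path` invisibly;
#'   `read_representation` a `gait_representation`.
#' @export
write_representation <- function(rep, path) {
  stopifnot(inherits(rep, "gait_representation"))
  px <- round(255 * rep$pixels) / 255
  EBImage::writeImage(as_ebimage(px), path, type = "png", bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_representation
#' @export
read_representation <- function(path, kind = "GEI", scope = "whole_sequence") {
  px <- from_ebimage(EBImage::readImage(path))
  structure(list(kind = kind, pixels = px, scope = scope, cycle = NULL,
                 n_frames = NA_integer_), class = "gait_representation")
}

#' Write / read a dataset manifest as CSV
#' @param manifest manifest data frame.
#' @param path CSV path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an evaluation report as JSON plus a CSV confusion matrix
#'
#' @param report an `evaluation_report`.
#' @param json_path path for the JSON report.
#' @param csv_path optional path for the confusion-matrix CSV.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(list(
    accuracy = report$accuracy,
    per_class_accuracy = as.list(report$per_class_accuracy),
    fold_accuracies = report$fold_accuracies,
    fold_accuracy_mean = report$fold_accuracy_mean,
    n = report$n,
    confusion = as.data.frame(report$confusion)),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$confusion, csv_path)
  invisible(json_path)
}
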