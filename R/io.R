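#' Read a frame stack from disk
#'
#' Accepts either a multi-page TIFF (page order = frame order) or a
#' directory of equally shaped grayscale PNGs read in lexicographic name
#' order (`frame_0000.png`, `frame_0001.png`, ...). Pixel values are
#' returned on the 8-bit scale (0-255) as numeric matrices.
#'
#' @param path TIFF file or PNG directory.
#' @param expected_frames If given, the frame count is validated against
#'   it and a mismatch is a hard error (the manifest schedule defines the
#'   expected count).
#' @return A list of numeric matrices.
#' @export
read_image_sequence <- function(path, expected_frames = NULL) {
  if (dir.exists(path)) {
    files <- sort(dir(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop_input("no PNG frames in ", path)
    frames <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img * 255
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, function(img) {
      if (length(dim(img)) == 3) img <- img[, , 1]
      storage.mode(img) <- "double"
      img
    })
  } else {
    stop_input("no such file or directory: ", path)
  }
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop_input("mixed frame shapes in ", path)
  }
  if (!is.null(expected_frames) && length(frames) != expected_frames) {
    stop_input(sprintf("%s: %d frames found, schedule expects %d",
                       path, length(frames), expected_frames))
  }
  frames
}

#' Read an experiment manifest
#'
#' Manifests are plain text, either YAML or JSON (decided by file
#' extension). See [run_pipeline()] for the expected fields.
#'
#' @param path Manifest file.
#' @return The manifest as a list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_input("no such manifest: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

#' Write a manifest as JSON
#'
#' @param manifest Manifest list.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
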