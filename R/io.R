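# File I/O: 16-bit multi-page TIFF image stacks, CSV tables, JSON records.

#' Write an image stack as 16-bit multi-page TIFF
#'
#' ADU frames are rounded and clamped to the 16-bit unsigned range before
#' writing (the digitisation step of a real camera).
#'
#' @param frames A matrix or list of matrices (ADU).
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_stack_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(f) {
    f <- pmin(pmax(round(f), 0), 65535)
    matrix(f / 65535, nrow = nrow(f), ncol = ncol(f))
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF stack as ADU matrices
#'
#' @param path TIFF file path.
#' @return List of numeric matrices on the original ADU scale.
#' @export
read_stack_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) {
    storage.mode(m) <- "double"
    m
  })
}

#' Write a results record as JSON
#'
#' Full-precision, unboxed JSON so that identical results serialize to
#' byte-identical files.
#'
#' @param x A list.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# md5 of the canonical JSON serialization of a config list; used to stamp
# every artifact of a run.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
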