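#' Read a grayscale image
#'
#' Reads 8-bit grayscale PNG, TIFF, or PGM (ASCII `P2` or binary `P5`)
#' by file extension. Multi-channel images are rejected rather than
#' converted, since the segmentation model is defined on single-channel
#' 8-bit data.
#'
#' @param path file path ending in `.png`, `.tif(f)`, or `.pgm`.
#' @return grayscale integer matrix in `[0, 255]`.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    pgm = return(read_pgm(path)),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  if (length(dim(img)) == 3L) {
    stop(sprintf("'%s' has %d channels; only single-channel images are supported",
                 path, dim(img)[3L]), call. = FALSE)
  }
  quantize8(img * 255)
}

#' Write a grayscale image
#'
#' Writes 8-bit grayscale PNG, TIFF, or ASCII PGM by file extension.
#'
#' @param image grayscale matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image / 255, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::writeTIFF(image / 255, path)
    },
    pgm = write_pgm(image, path),
    stop(sprintf("unsupported image format: .%s", ext), call. = FALSE))
  invisible(path)
}

read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a PGM file", call. = FALSE)
  if (magic == "P2") {
    tokens <- scan(text = rawToChar(raw), what = character(),
                   comment.char = "#", quiet = TRUE)
    nums <- as.integer(tokens[-1])  # drop the magic
    w <- nums[1]; h <- nums[2]; maxval <- nums[3]
    if (maxval > 255) stop("only 8-bit PGM supported", call. = FALSE)
    vals <- nums[3 + seq_len(w * h)]
  } else {
    # parse header byte-wise: three numeric tokens, '#' starts a comment
    tokens <- integer(0); buf <- character(0); i <- 3L
    while (length(tokens) < 3L) {
      if (i > length(raw)) stop("truncated PGM header", call. = FALSE)
      ch <- rawToChar(raw[i]); i <- i + 1L
      if (ch == "#") {
        while (i <= length(raw) && rawToChar(raw[i]) != "\n") i <- i + 1L
      } else if (grepl("[0-9]", ch)) {
        buf <- c(buf, ch)
      } else if (length(buf)) {
        tokens <- c(tokens, as.integer(paste(buf, collapse = "")))
        buf <- character(0)
      }
    }
    w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
    if (maxval > 255) stop("only 8-bit PGM supported", call. = FALSE)
    vals <- as.integer(raw[i - 1L + seq_len(w * h)])
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  writeLines(apply(image, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Write a label image with a JSON sidecar
#'
#' Stores labels `1..k` as `k` evenly spaced gray levels in a PNG (or
#' PGM), plus a JSON sidecar recording the label-to-gray mapping, the
#' centroids (if given), and any extra metadata, so the label image is
#' recoverable exactly.
#'
#' @param labels integer label matrix (`1..k`).
#' @param path output image path; the sidecar is `paste0(path, ".json")`.
#' @param centroids optional centroid intensities to record.
#' @param extra optional named list of additional metadata.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, centroids = NULL, extra = NULL) {
  k <- max(labels)
  stopifnot(min(labels) >= 1L)
  gray <- round_half_away(seq_len(k) * 255 / k)
  img <- matrix(gray[as.vector(labels)], nrow(labels), ncol(labels))
  write_gray(quantize8(img), path)
  meta <- c(list(k = k, gray_levels = gray),
            if (!is.null(centroids)) list(centroids = as.numeric(centroids)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a label image written by [write_labels()]
#'
#' @param path the label image path (sidecar `paste0(path, ".json")`
#'   must exist).
#' @return integer label matrix; centroids, if recorded, are attached
#'   as attribute `"centroids"`.
#' @export
read_labels <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- read_gray(path)
  lut <- integer(256)
  lut[meta$gray_levels + 1L] <- seq_len(meta$k)
  labels <- matrix(lut[as.vector(img) + 1L], nrow(img), ncol(img))
  if (any(labels == 0L)) stop("image does not match its sidecar gray levels",
                              call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!is.null(meta$centroids)) {
    attr(labels, "centroids") <- as.numeric(meta$centroids)
  }
  labels
}
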