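# Tile and report I/O. Images are handled internally in [-1, 1]; files are
# 8- or 16-bit PNG/TIFF mapped affinely onto that range.

#' Write an image tile to PNG or TIFF
#'
#' @param img (H,W,3) array in `range` units.
#' @param path Output path; format chosen by extension (.png/.tif/.tiff).
#' @param range Value range of `img` (default taken from the tile attribute,
#'   else `c(0,1)`).
#' @export
write_tile <- function(img, path, range = NULL) {
  if (is.null(range)) range <- attr(img, "range", exact = TRUE)
  if (is.null(range)) range <- c(0, 1)
  v <- clamp((unclass(img) - range[1]) / (range[2] - range[1]), 0, 1)
  attributes(v) <- list(dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(v, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(v, path, bits.per.sample = 16L)
  else vs_stop(paste0("unsupported image format: .", ext), "vs_io_error")
  invisible(path)
}

read_one_tile <- function(path) {
  if (!file.exists(path))
    vs_stop(paste0("cannot read image file: ", path), "vs_io_error")
  ext <- tolower(tools::file_ext(path))
  v <- tryCatch(
    if (ext == "png") png::readPNG(path)
    else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else vs_stop(paste0("unsupported image format: ", path), "vs_io_error"),
    error = function(e) vs_stop(paste0("cannot read image file: ", path,
                                       " (", conditionMessage(e), ")"),
                                "vs_io_error"))
  if (length(dim(v)) == 2L) v <- array(rep(v, 3L), c(dim(v), 3L))
  if (dim(v)[3] > 3L) v <- v[, , 1:3, drop = FALSE]
  v * 2 - 1  # [0,1] file range -> model range [-1,1]
}

#' Read image tiles from a directory or manifest
#'
#' Directory mode lists `*.png`/`*.tif(f)` files in lexicographic order;
#' manifest mode (a `manifest.json` written by [make_dataset()]) reads the
#' listed files, keeping their domain tags. Pixel values are rescaled
#' affinely to the model range \eqn{[-1,1]} (8-bit 0 -> -1, 255 -> +1).
#'
#' @param src A directory or a manifest JSON path.
#' @param domain Optional filter (`"stained"`/`"unstained"`) in manifest mode.
#' @param strict If `TRUE` (default), mixed tile sizes raise an error.
#' @return A list of (H,W,3) arrays in `[-1,1]`, with `domain` attributes
#'   when known; manifest mode also attaches the manifest as an attribute.
#' @export
read_tiles <- function(src, domain = NULL, strict = TRUE) {
  if (dir.exists(src)) {
    files <- sort(list.files(src, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    man <- NULL
  } else if (file.exists(src)) {
    man <- jsonlite::read_json(src, simplifyVector = TRUE)
    if (!is.null(domain)) man <- man[man$domain == domain, , drop = FALSE]
    files <- file.path(dirname(src), man$path)
  } else vs_stop(paste0("no such directory or manifest: ", src), "vs_io_error")
  tiles <- lapply(files, read_one_tile)
  if (strict && length(tiles) > 1L) {
    ds <- vapply(tiles, function(t) paste(dim(t), collapse = "x"), "")
    if (length(unique(ds)) > 1L)
      vs_stop("tiles have mixed sizes in strict mode", "vs_io_error")
  }
  if (!is.null(man) && length(tiles)) {
    for (i in seq_along(tiles)) {
      attr(tiles[[i]], "domain") <- man$domain[i]
      attr(tiles[[i]], "class_label") <- man$class[i]
    }
    attr(tiles, "manifest") <- man
  }
  tiles
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a metric report or training log
#'
#' Metric reports (lists) are written as schema-versioned JSON; training
#' logs (data.frames) as JSONL, one record per line, with a leading
#' schema-version record.
#'
#' @param x A metric report list or a training-log data.frame.
#' @param path Output file.
#' @export
write_report <- function(x, path) {
  ok <- tryCatch({
    if (is.data.frame(x)) {
      con <- file(path, "w"); on.exit(close(con), add = TRUE)
      writeLines(as.character(jsonlite::toJSON(
        list(schema_version = REPORT_SCHEMA_VERSION), auto_unbox = TRUE)), con)
      for (i in seq_len(nrow(x)))
        writeLines(as.character(jsonlite::toJSON(as.list(x[i, , drop = FALSE]),
                                                 auto_unbox = TRUE, digits = NA)), con)
    } else {
      x <- unclass(x)
      x$schema_version <- REPORT_SCHEMA_VERSION
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    vs_stop(paste0("cannot write report to ", path, " (",
                   conditionMessage(ok), ")"), "vs_io_error")
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path Report path; `.jsonl` logs return a data.frame, JSON reports
#'   a list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) vs_stop(paste0("no such report: ", path), "vs_io_error")
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE)
    recs <- lapply(lines, function(l) jsonlite::fromJSON(l))
    recs <- recs[vapply(recs, function(r) is.null(r$schema_version), TRUE)]
    if (!length(recs)) return(data.frame())
    return(do.call(rbind, lapply(recs, as.data.frame)))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
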