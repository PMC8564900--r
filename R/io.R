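#' Read and write images as plain-text rasters
#'
#' Images are stored as tab-separated matrices preceded by `#`-comment
#' header lines carrying the physical metadata (nm per pixel, origin,
#' view). A plain-text raster keeps every artifact of a run
#' human-inspectable and diff-able; the pixel-size metadata plays the
#' role of TIFF resolution tags, which viewers disagree about anyway.
#'
#' @param img an [image2d].
#' @param path output file path.
#' @return `write_image_txt` returns `path` invisibly; `read_image_txt`
#'   returns an [image2d].
#' @export
write_image_txt <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ciliaquant image2d v1",
    sprintf("# pixel_size_nm: %.10g", pixel_size(img)),
    sprintf("# origin_nm: %.10g %.10g", image_origin(img)[1],
            image_origin(img)[2]),
    sprintf("# view: %s", attr(img, "view"))), con)
  utils::write.table(unclass(img), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image_txt
#' @param path file written by `write_image_txt`.
#' @export
read_image_txt <- function(path) {
  hdr <- readLines(path, n = 4)
  if (!startsWith(hdr[1], "# ciliaquant image2d"))
    stop("not a ciliaquant image file: ", path)
  px <- as.numeric(sub("# pixel_size_nm: ", "", hdr[2]))
  origin <- as.numeric(strsplit(sub("# origin_nm: ", "", hdr[3]), " ")[[1]])
  view <- sub("# view: ", "", hdr[4])
  m <- as.matrix(utils::read.table(path, sep = "\t", comment.char = "#"))
  dimnames(m) <- NULL
  image2d(m, pixel_size_nm = px, origin_nm = origin, view = view)
}

#' Read and write frame stacks as plain text
#'
#' One file per stack: a metadata header, then each frame as a
#' tab-separated matrix preceded by a `# frame: i` marker.
#'
#' @param stack a `frame_stack`.
#' @param path file path.
#' @return `write_stack_txt` returns `path` invisibly;
#'   `read_stack_txt` a `frame_stack` (without ground-truth events).
#' @export
write_stack_txt <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ciliaquant frame_stack v1",
    sprintf("# pixel_size_nm: %.10g", stack$pixel_size_nm),
    sprintf("# origin_nm: %.10g %.10g", stack$origin_nm[1], stack$origin_nm[2]),
    sprintf("# view: %s", stack$view),
    sprintf("# frames: %d", d[3])), con)
  for (f in seq_len(d[3])) {
    writeLines(sprintf("# frame: %d", f), con)
    utils::write.table(stack$frames[, , f], con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_stack_txt
#' @export
read_stack_txt <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ciliaquant frame_stack"))
    stop("not a ciliaquant frame stack file: ", path)
  px <- as.numeric(sub("# pixel_size_nm: ", "", lines[2]))
  origin <- as.numeric(strsplit(sub("# origin_nm: ", "", lines[3]), " ")[[1]])
  view <- sub("# view: ", "", lines[4])
  nfr <- as.integer(sub("# frames: ", "", lines[5]))
  starts <- grep("^# frame: ", lines)
  stopifnot(length(starts) == nfr)
  ends <- c(starts[-1] - 1L, length(lines))
  mats <- lapply(seq_len(nfr), function(i) {
    block <- lines[(starts[i] + 1L):ends[i]]
    do.call(rbind, lapply(strsplit(block, "\t"), as.numeric))
  })
  stack <- array(0, dim = c(nrow(mats[[1]]), ncol(mats[[1]]), nfr))
  for (i in seq_len(nfr)) stack[, , i] <- mats[[i]]
  structure(list(frames = stack, pixel_size_nm = px, origin_nm = origin,
                 view = view,
                 events = data.frame(frame = integer(0), row_nm = numeric(0),
                                     col_nm = numeric(0), photons = numeric(0),
                                     emitter = integer(0))),
            class = "frame_stack")
}

#' CSV round trips for the pipeline's tables
#'
#' Emitters, ground-truth events, localization tables and measurement
#' records travel as ordinary CSV files.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return the path (write) or the data.frame (read).
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a run configuration / provenance block as YAML
#'
#' Every pipeline run drops a provenance YAML next to its outputs:
#' the configuration, the package version and every seed used.
#'
#' @param config named list.
#' @param path file path.
#' @return path invisibly (write) or named list (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

# provenance block shared by the run_* drivers
.provenance <- function(stage, config, seed) {
  c(list(stage = stage,
         package = "ciliaquant",
         version = as.character(utils::packageVersion("ciliaquant")),
         seed = seed),
    config)
}
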