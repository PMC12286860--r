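## File interchange.
##
## Arrays and fitted objects are stored as RDS; metric tables as tidy CSV;
## bootstrap summaries and run manifests as JSON; stimuli as PNG files with
## a metadata CSV. All raster I/O converts pixels to [0, 1] on read.

#' Write an image as PNG
#' @param image Array `[height, width, channels]`, pixels in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), target = path)
  invisible(path)
}

#' Read a PNG image
#' @param path PNG file path.
#' @return Array `[height, width, channels]` with pixels in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' Export a stimulus set as a PNG directory plus metadata CSV
#'
#' @param world A [make_stimulus_world()] object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_stimulus_set <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(world$stimulus_ids)) {
    write_image_png(array(world$images[i, , , ], dim = dim(world$images)[-1]),
                    file.path(dir, paste0(world$stimulus_ids[i], ".png")))
  }
  utils::write.csv(data.frame(stimulus_id = world$stimulus_ids,
                              category = world$category,
                              split = world$split),
                   file.path(dir, "stimuli.csv"), row.names = FALSE)
  invisible(dir)
}

#' Save / load package objects
#'
#' Response datasets, feature stacks, decoders and converters are saved as
#' RDS with a format tag so that loads can be validated.
#'
#' @param object The object to save.
#' @param path File path.
#' @export
save_object <- function(object, path) {
  saveRDS(list(format = class(object)[1], object = object,
               package = "ncconvert"), path)
  invisible(path)
}

#' @rdname save_object
#' @param expect Optional class name the loaded object must have.
#' @export
load_object <- function(path, expect = NULL) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$object)) stop("not an ncconvert object file")
  if (!is.null(expect) && !inherits(x$object, expect)) {
    stop("expected a '", expect, "' object but found '", x$format, "'")
  }
  x$object
}

#' Write a metric table as tidy CSV
#' @param metrics A metric table data frame.
#' @param path Output CSV path.
#' @export
write_metric_table <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Write a bootstrap CI as JSON
#' @param ci A [dyadic_bootstrap()] result.
#' @param path Output JSON path.
#' @export
write_bootstrap_ci <- function(ci, path) {
  jsonlite::write_json(list(mean = ci$mean, lower = ci$lower,
                            upper = ci$upper, confidence = ci$confidence,
                            n_replicates = ci$n_replicates, seed = ci$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, outputs, the configuration and a config hash for
#' provenance.
#'
#' @param path Output JSON path.
#' @param inputs,outputs Character vectors of file paths.
#' @param config A configuration list.
#' @export
write_manifest <- function(path, inputs, outputs, config) {
  hash <- sum(utf8ToInt(paste(utils::capture.output(utils::str(config)),
                              collapse = ""))) %% 1e9
  jsonlite::write_json(list(inputs = inputs, outputs = outputs,
                            config = config, config_hash = hash,
                            r_version = as.character(getRversion()),
                            timestamp = format(Sys.time(), tz = "UTC")),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
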