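# Readers/writers for the exchange formats at the package boundary.
# Internally everything is a boxes_df() with 0-based half-open corners;
# COCO's [x, y, width, height] and VOC's 1-based inclusive corners are
# converted on ingest and restored on write.

#' Read COCO-style detections
#'
#' Expects a JSON array of records
#' `{image_id (or frame_index), category, bbox = [x, y, w, h], score}`;
#' an optional `provenance` field is preserved (default `"detector"`).
#'
#' @param path JSON file.
#' @return a [boxes_df()] data frame (possibly 0-row).
#' @export
read_coco_detections <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  recs <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                   error = function(e) {
                     stop("malformed JSON in ", path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (length(recs) == 0L) return(empty_boxes())
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    frame <- r$image_id
    if (is.null(frame)) frame <- r$frame_index
    bad <- function(why) stop("record ", i, " in ", path, ": ", why,
                              call. = FALSE)
    if (is.null(frame)) bad("missing image_id/frame_index")
    if (is.null(r$bbox) || length(r$bbox) != 4L) bad("bbox must have 4 values")
    bbox <- as.numeric(r$bbox)
    if (bbox[3L] <= 0 || bbox[4L] <= 0) bad("bbox width/height must be > 0")
    score <- if (is.null(r$score)) 1 else as.numeric(r$score)
    if (is.na(score) || score < 0 || score > 1) bad("score must be in [0, 1]")
    boxes_df(frame = as.integer(frame),
             x_min = bbox[1L], y_min = bbox[2L],
             x_max = bbox[1L] + bbox[3L], y_max = bbox[2L] + bbox[4L],
             label = if (is.null(r$category)) "polyp" else as.character(r$category),
             confidence = score,
             provenance = if (is.null(r$provenance)) "detector"
                          else as.character(r$provenance))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write COCO-style detections
#'
#' Inverse of [read_coco_detections()]; corner boxes are converted back to
#' `[x, y, w, h]` and the per-box `provenance` flag is carried along.
#'
#' @param detections a [boxes_df()] data frame.
#' @param path output JSON file.
#' @export
write_coco_detections <- function(detections, path) {
  detections <- validate_boxes(detections)
  recs <- lapply(seq_len(nrow(detections)), function(i) {
    b <- detections[i, ]
    list(image_id = b$frame,
         category = b$label,
         bbox = c(b$x_min, b$y_min, b$x_max - b$x_min, b$y_max - b$y_min),
         score = b$confidence,
         provenance = b$provenance)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read one Pascal VOC XML annotation file
#'
#' VOC's 1-based inclusive corners become 0-based half-open:
#' `x_min = xmin - 1`, `x_max = xmax`.
#'
#' @param path XML file.
#' @param frame 0-based frame index to record in the result.
#' @return a [boxes_df()] data frame, provenance `"ground_truth"`.
#' @export
read_voc_annotation <- function(path, frame = 0L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0L) return(empty_boxes())
  num <- function(node, tag) {
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, paste0(".//", tag))))
  }
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    boxes_df(frame = as.integer(frame),
             x_min = num(o, "xmin") - 1, y_min = num(o, "ymin") - 1,
             x_max = num(o, "xmax"), y_max = num(o, "ymax"),
             label = xml2::xml_text(xml2::xml_find_first(o, ".//name")),
             confidence = 1, provenance = "ground_truth")
  })
  do.call(rbind, rows)
}

#' Read a directory of Pascal VOC XML annotations as one video
#'
#' Files are ordered by natural sort of their names (`frame_2` before
#' `frame_10`) and assigned 0-based frame indices in that order.
#'
#' @param dir directory containing `.xml` files, one per frame.
#' @return a [boxes_df()] data frame.
#' @export
read_voc_annotations <- function(dir) {
  files <- list.files(dir, pattern = "\\.xml$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .xml annotation files in ", dir, call. = FALSE)
  }
  files <- files[natural_order(basename(files))]
  out <- do.call(rbind, lapply(seq_along(files), function(i) {
    read_voc_annotation(files[i], frame = i - 1L)
  }))
  rownames(out) <- NULL
  out
}

#' Write one Pascal VOC XML annotation file
#'
#' @param boxes a [boxes_df()] data frame (one frame's boxes).
#' @param path output XML file.
#' @param image_size `c(height, width)` of the annotated frame.
#' @param filename image filename recorded in the annotation.
#' @export
write_voc_annotation <- function(boxes, path, image_size,
                                 filename = basename(path)) {
  boxes <- validate_boxes(boxes)
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "filename", filename)
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(image_size[2L]))
  xml2::xml_add_child(size, "height", as.character(image_size[1L]))
  xml2::xml_add_child(size, "depth", "3")
  for (i in seq_len(nrow(boxes))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", boxes$label[i])
    bb <- xml2::xml_add_child(o, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(boxes$x_min[i] + 1))
    xml2::xml_add_child(bb, "ymin", as.character(boxes$y_min[i] + 1))
    xml2::xml_add_child(bb, "xmax", as.character(boxes$x_max[i]))
    xml2::xml_add_child(bb, "ymax", as.character(boxes$y_max[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read ordered frames from a directory of PNG images
#'
#' Frames are ordered by natural sort of their filenames. RGBA images are
#' reduced to RGB.
#'
#' @param dir directory of `.png` frames.
#' @param resize optional target side in pixels (e.g. 640): every frame is
#'   bilinearly resized to `resize x resize`.
#' @return list of `[H, W]` / `[H, W, 3]` arrays in `[0, 1]`.
#' @export
read_frames <- function(dir, resize = NULL) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .png frames found in ", dir, call. = FALSE)
  }
  files <- files[natural_order(basename(files))]
  lapply(seq_along(files), function(i) {
    img <- tryCatch(png::readPNG(files[i]), error = function(e) {
      stop("unreadable frame ", i, " (", files[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
      img <- img[, , 1:3]
    }
    if (!is.null(resize)) img <- resize_image(img, resize, resize)
    img
  })
}

#' Write frames as numbered PNG files
#'
#' @param frames list of image arrays in `[0, 1]`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are `prefix_000.png`, ...
#' @export
write_frames <- function(frames, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.png", prefix,
                                  seq_along(frames) - 1L))
  for (i in seq_along(frames)) {
    png::writePNG(clamp01(frames[[i]]), paths[i])
  }
  invisible(paths)
}

#' Read a YAML or JSON configuration file
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", path, " (use .yaml or .json)",
         call. = FALSE)
  }
}

# natural sort order: numeric substrings compare by value, so frame_2
# precedes frame_10
natural_order <- function(x) {
  padded <- vapply(x, function(s) {
    m <- gregexpr("[0-9]+", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(v) {
      sprintf("%020d", as.integer(v))
    })
    s
  }, character(1L), USE.NAMES = FALSE)
  order(padded)
}
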