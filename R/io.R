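# file formats: images (PNG/JPEG/TIFF via EBImage, PGM natively),
# annotation dialects (generic CSV, BioID .eye sidecars, JSON),
# detection records and evaluation reports
#
# Internal coordinates are 0-based everywhere; 1-based dialects are
# converted at the boundary and the convention is recorded per record, so
# off-by-one drift cannot creep in.

#' Read an image as a greyscale 0-255 intensity matrix
#'
#' PGM (P2/P5) is parsed natively; PNG/JPEG/TIFF go through
#' [EBImage::readImage()]. Colour images are converted with
#' [to_greyscale()] luma weights.
#'
#' @param path image file path.
#' @return intensity matrix (rows = y, columns = x).
#' @export
read_image_grey <- function(path) {
  if (!file.exists(path))
    pupilloc_error(paste("no such image:", path), "pupilloc_io_error")
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) return(read_pgm(path))
  img <- EBImage::imageData(EBImage::readImage(path))  # dim1 = x, in [0,1]
  if (length(dim(img)) == 2) return(t(img) * 255)
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    arr <- array(0, c(dim(img)[2], dim(img)[1], 3))
    for (ch in 1:3) arr[, , ch] <- t(img[, , ch]) * 255
    return(to_greyscale(arr))
  }
  pupilloc_error("unsupported channel layout", "pupilloc_format_error")
}

#' Write a greyscale matrix as PNG
#'
#' @param m intensity matrix, 0-255.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_png_grey <- function(m, path) {
  stopifnot(is_intensity_matrix(m))
  EBImage::writeImage(EBImage::Image(t(clamp(m, 0, 255) / 255)), path)
  invisible(path)
}

#' Read / write PGM images
#'
#' Supports both the ASCII (P2) and binary (P5) variants with maxval up to
#' 255; writing uses P2 so outputs remain inspectable as text.
#'
#' @param path file path.
#' @param m intensity matrix, 0-255 (rounded on write).
#' @return `read_pgm`: intensity matrix; `write_pgm`: `path`, invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "")
        pupilloc_error(paste("truncated PGM header:", path),
                       "pupilloc_parse_error")
      if (ch == "#") {                       # comment to end of line
        repeat {
          ch <- readChar(con, 1, useBytes = TRUE)
          if (length(ch) == 0 || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok)
      } else tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5"))
    pupilloc_error(paste("not a PGM file:", path), "pupilloc_parse_error")
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1 || maxval > 255)
    pupilloc_error(paste("bad PGM header:", path), "pupilloc_parse_error")
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  if (length(vals) != w * h)
    pupilloc_error(paste("truncated PGM data:", path), "pupilloc_parse_error")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(m, path) {
  stopifnot(is_intensity_matrix(m))
  v <- round_half_up(clamp(m, 0, 255))
  lines <- c("P2", paste(ncol(m), nrow(m)), "255",
             apply(v, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read eye-centre annotations
#'
#' Dialects:
#' \describe{
#'   \item{`generic_csv`}{one CSV with header
#'     `image,left_x,left_y,right_x,right_y`, 0-based pixel coordinates.}
#'   \item{`bioid_eye`}{one `.eye` sidecar file per image: `#`-prefixed
#'     header lines, then a data line of four whitespace-separated
#'     integers `LX LY RX RY` (0-based). `path` may be a single file or a
#'     directory of `.eye` files.}
#'   \item{`json`}{an array of objects with fields `image`, `left` (x, y)
#'     and `right` (x, y).}
#' }
#'
#' @param path annotation file (or directory for `bioid_eye`).
#' @param dialect one of `"generic_csv"`, `"bioid_eye"`, `"json"`.
#' @return data.frame with columns `image`, `left_x`, `left_y`, `right_x`,
#'   `right_y`, `convention` (always `"0-based"` after normalisation).
#' @export
read_annotations <- function(path, dialect = c("generic_csv", "bioid_eye",
                                               "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "generic_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("image", "left_x", "left_y", "right_x", "right_y")
    if (!all(need %in% names(df)))
      pupilloc_error(paste("missing annotation columns in", path),
                     "pupilloc_parse_error")
    df <- df[, need]
  } else if (dialect == "json") {
    js <- jsonlite::read_json(path, simplifyVector = FALSE)
    df <- do.call(rbind, lapply(js, function(r) data.frame(
      image = r$image,
      left_x = r$left[[1]], left_y = r$left[[2]],
      right_x = r$right[[1]], right_y = r$right[[2]])))
  } else {
    files <- if (dir.exists(path))
      list.files(path, pattern = "\\.eye$", full.names = TRUE) else path
    if (length(files) == 0)
      pupilloc_error(paste("no .eye files under", path), "pupilloc_io_error")
    df <- do.call(rbind, lapply(files, read_bioid_eye_file))
  }
  if (any(df$left_x < 0 | df$left_y < 0 | df$right_x < 0 | df$right_y < 0,
          na.rm = TRUE))
    pupilloc_error("negative annotation coordinates after normalisation",
                   "pupilloc_parse_error")
  df$convention <- "0-based"
  df
}

read_bioid_eye_file <- function(file) {
  lines <- readLines(file, warn = FALSE)
  data_lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  if (length(data_lines) != 1)
    pupilloc_error(sprintf("%s: expected one data line, found %d",
                           file, length(data_lines)),
                   "pupilloc_parse_error")
  vals <- suppressWarnings(as.numeric(strsplit(data_lines, "\\s+")[[1]]))
  if (length(vals) != 4 || anyNA(vals))
    pupilloc_error(sprintf("%s: malformed data line '%s'", file, data_lines),
                   "pupilloc_parse_error")
  data.frame(image = sub("\\.eye$", "", basename(file)),
             left_x = vals[1], left_y = vals[2],
             right_x = vals[3], right_y = vals[4])
}

#' Write annotations in a chosen dialect
#'
#' Inverse of [read_annotations()] for every dialect: a write followed by
#' a read recovers the records exactly.
#'
#' @param annotations data.frame with the generic columns.
#' @param path output file (or directory for `bioid_eye`).
#' @param dialect as in [read_annotations()].
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              dialect = c("generic_csv", "bioid_eye",
                                          "json")) {
  dialect <- match.arg(dialect)
  need <- c("image", "left_x", "left_y", "right_x", "right_y")
  stopifnot(all(need %in% names(annotations)))
  ann <- annotations[, need]
  if (dialect == "generic_csv") {
    utils::write.csv(ann, path, row.names = FALSE, quote = FALSE)
  } else if (dialect == "json") {
    recs <- lapply(seq_len(nrow(ann)), function(i) list(
      image = ann$image[i],
      left = c(ann$left_x[i], ann$left_y[i]),
      right = c(ann$right_x[i], ann$right_y[i])))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nrow(ann)))
      writeLines(c("#LX LY RX RY",
                   paste(ann$left_x[i], ann$left_y[i],
                         ann$right_x[i], ann$right_y[i])),
                 file.path(path, paste0(ann$image[i], ".eye")))
  }
  invisible(path)
}

#' Write / read detection records
#'
#' Detection records hold one row per image: the validity flag with its
#' reason, and per-eye estimated centres in parent-image coordinates
#' (empty for invalid frames). Column order is fixed, so identical inputs
#' produce byte-identical files.
#'
#' @param records data.frame with columns `image`, `valid`, `reason`,
#'   `left_x`, `left_y`, `right_x`, `right_y`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `write_detections`: `path` invisibly; `read_detections`: the
#'   records data.frame.
#' @export
write_detections <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("image", "valid", "reason", "left_x", "left_y", "right_x",
            "right_y")
  if (nrow(records) == 0)
    records <- data.frame(image = character(0), valid = logical(0),
                          reason = character(0), left_x = numeric(0),
                          left_y = numeric(0), right_x = numeric(0),
                          right_y = numeric(0))
  stopifnot(all(cols %in% names(records)))
  recs <- records[, cols]
  if (format == "csv") {
    utils::write.csv(recs, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
    df$valid <- as.logical(df$valid)
    if (is.null(df$reason)) df$reason <- NA_character_
    df$reason <- as.character(df$reason)
  } else {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  df
}

#' Write an evaluation report
#'
#' @param report an `eval_report` from [evaluate_detections()].
#' @param path output path without extension; writes `<path>.json` (full
#'   report) and `<path>_curve.csv` (accuracy-vs-threshold table).
#' @return the JSON path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  json_path <- paste0(path, ".json")
  jsonlite::write_json(
    list(aggregates = report$aggregates, curve = report$curve,
         per_frame = report$per_frame),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(report$curve, paste0(path, "_curve.csv"),
                   row.names = FALSE)
  invisible(json_path)
}

#' Read facial landmarks from a JSON file
#'
#' Layout: an object (or array of objects, one per image) with fields
#' `image`, `face_rect` (x, y, w, h) and per-eye point arrays `left_eye`,
#' `right_eye` (each an array of `[x, y]` pairs, 0-based).
#'
#' @param path JSON file path.
#' @return named list (by image) of landmark lists as accepted by
#'   [crop_eye_frames()].
#' @export
read_landmarks <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(js$image)) js <- list(js)
  out <- lapply(js, function(r) list(
    face_rect = as.numeric(unlist(r$face_rect)),
    left_eye = do.call(rbind, lapply(r$left_eye, as.numeric)),
    right_eye = do.call(rbind, lapply(r$right_eye, as.numeric))))
  names(out) <- vapply(js, function(r) r$image, "")
  out
}

#' Write facial landmarks to JSON
#'
#' Inverse of [read_landmarks()].
#'
#' @param landmarks named list (by image) of landmark lists.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  recs <- lapply(names(landmarks), function(id) {
    l <- landmarks[[id]]
    list(image = id, face_rect = l$face_rect,
         left_eye = lapply(seq_len(nrow(l$left_eye)),
                           function(i) l$left_eye[i, ]),
         right_eye = lapply(seq_len(nrow(l$right_eye)),
                            function(i) l$right_eye[i, ]))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
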