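## Landmark file IO.
##
## Two encodings are supported: TPS (the geometric-morphometrics standard;
## "LM=19" records with an ID line, bottom-left origin) and CSV (columns
## image_id, point_name, x, y; top-left origin, bit-exact round trip).
## Internal coordinates are always top-left-origin with y increasing
## downward, so TPS y values are flipped against a canvas height.

validate_landmark_set <- function(m, where = "landmark set") {
  if (!is.matrix(m) || ncol(m) != 2)
    stopf("%s: expected a 19 x 2 coordinate matrix", where)
  if (nrow(m) != 19)
    stopf("%s: expected 19 landmarks, found %d", where, nrow(m))
  if (is.null(rownames(m)) || !setequal(rownames(m), LANDMARK_NAMES))
    stopf("%s: landmarks must be named %s", where,
          paste(LANDMARK_NAMES, collapse = ", "))
  if (any(!is.finite(m))) stopf("%s: non-finite coordinates", where)
  m[LANDMARK_NAMES, , drop = FALSE]
}

#' Read landmarks from TPS or CSV
#'
#' TPS records are mapped to named points by the canonical point order
#' (A, B, C, D, E1, E2, G1, G2, F, H, I, J, K, L, M, N, O1, O2, P) and their
#' y axis is flipped (`y = height - y_tps`) so internal coordinates are
#' top-left-origin. CSV files carry explicit point names and are read as-is.
#'
#' @param path file path.
#' @param format "tps" or "csv"; guessed from the extension by default.
#' @param height canvas height for the TPS y-flip (default 540).
#' @return named list of 19 x 2 landmark matrices, keyed by image id.
#' @export
load_landmarks <- function(path, format = c("auto", "tps", "csv"), height = 540) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "tps") "tps" else "csv"
  if (!file.exists(path)) stopf("landmark file not found: %s", path)
  if (format == "tps") read_landmarks_tps(path, height) else read_landmarks_csv(path)
}

read_landmarks_tps <- function(path, height = 540) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (!length(starts)) stopf("%s: no LM= records found", path)
  out <- list()
  for (k in seq_along(starts)) {
    i <- starts[k]
    n_lm <- as.integer(sub("^LM\\s*=\\s*", "", lines[i]))
    end <- if (k < length(starts)) starts[k + 1] - 1 else length(lines)
    rec <- lines[(i + 1):end]
    id_line <- grep("^ID\\s*=", rec, value = TRUE)
    id <- if (length(id_line)) sub("^ID\\s*=\\s*", "", id_line[1]) else paste0("record", k)
    coords <- rec[!grepl("^[A-Z]+\\s*=", rec)]
    if (n_lm != 19)
      stopf("%s, record '%s': expected LM=19, found LM=%d", path, id, n_lm)
    if (length(coords) != n_lm)
      stopf("%s, record '%s': %d coordinate lines for LM=%d", path, id,
            length(coords), n_lm)
    m <- do.call(rbind, lapply(strsplit(coords, "\\s+"), as.numeric))
    m[, 2] <- height - m[, 2]
    rownames(m) <- LANDMARK_NAMES
    colnames(m) <- c("x", "y")
    out[[id]] <- validate_landmark_set(m, sprintf("%s record '%s'", path, id))
  }
  out
}

read_landmarks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("point_name", "x", "y")
  if (!all(need %in% names(df)))
    stopf("%s: landmark CSV needs columns point_name, x, y", path)
  if (!"image_id" %in% names(df)) df$image_id <- "image1"
  out <- lapply(split(df, df$image_id), function(d) {
    if (nrow(d) != 19)
      stopf("%s, image '%s': expected 19 landmarks, found %d", path,
            d$image_id[1], nrow(d))
    m <- as.matrix(d[, c("x", "y")])
    rownames(m) <- d$point_name
    validate_landmark_set(m, sprintf("%s image '%s'", path, d$image_id[1]))
  })
  out[unique(df$image_id)]
}

#' Write landmarks to TPS
#'
#' @param landmarks named list of 19 x 2 landmark matrices.
#' @param path output file.
#' @param height canvas height for the y-flip (must match the reader's).
#' @export
write_landmarks_tps <- function(landmarks, path, height = 540) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(landmarks)) {
    m <- validate_landmark_set(landmarks[[id]], id)
    writeLines(sprintf("LM=%d", nrow(m)), con)
    writeLines(sprintf("%.6f %.6f", m[, 1], height - m[, 2]), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

#' Write landmarks to CSV (bit-exact round trip)
#'
#' @inheritParams write_landmarks_tps
#' @export
write_landmarks_csv <- function(landmarks, path) {
  rows <- lapply(names(landmarks), function(id) {
    m <- validate_landmark_set(landmarks[[id]], id)
    data.frame(image_id = id, point_name = rownames(m),
               x = m[, 1], y = m[, 2], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rating matrix from CSV
#'
#' Expects rows = raters with columns `rater_id`, `gender`, `age` and one
#' integer column per stimulus.
#'
#' @param path CSV file.
#' @return a [rating_matrix()].
#' @export
read_ratings_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("rater_id", "gender", "age"), names(df))
  score_cols <- setdiff(names(df), meta_cols)
  scores <- as.matrix(df[, score_cols, drop = FALSE])
  storage.mode(scores) <- "integer"
  rownames(scores) <- df$rater_id %||% paste0("rater", seq_len(nrow(df)))
  meta <- if (length(meta_cols)) df[, meta_cols, drop = FALSE] else NULL
  rating_matrix(scores, rater_meta = meta)
}

#' Write a rating matrix to CSV
#'
#' @param m a `rating_matrix`.
#' @param path output file.
#' @export
write_ratings_csv <- function(m, path) {
  df <- data.frame(rater_id = m$rater_meta$rater_id,
                   gender = m$rater_meta$gender, age = m$rater_meta$age,
                   m$scores, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
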