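# TPS input/output. TPS files (as written by tpsDig and relatives) are
# blocks of the form
#   LM=<k>
#   <x> <y>          (k lines)
#   IMAGE=<...>      (optional)
#   ID=<...>         (optional)
#   SCALE=<...>      (optional, units per pixel)
# TPS carries no structured replicate fields, so specimen / side / image /
# digitizing are recovered from the ID (or IMAGE) string by a pluggable
# parser.

#' Default TPS identifier parser
#'
#' Parses identifiers of the form `"<specimen>_<side>_i<image>_d<digit>"`,
#' e.g. `"MN1234_L_i1_d2"`. Side tokens `L`/`R`/`left`/`right` are accepted
#' case-insensitively. Returns `NULL` when the string does not conform, so
#' callers can report the offending record.
#'
#' @param id character scalar (the TPS `ID=` or `IMAGE=` field).
#' @return list with `specimen`, `side`, `image_rep`, `digit_rep`, or
#'   `NULL` on failure.
#' @export
parse_landmark_id <- function(id) {
  low <- tolower(id)
  m <- regmatches(low, regexec(
    "^(.+)_(left|right|l|r)_i([0-9]+)_d([0-9]+)$", low))[[1]]
  if (length(m) == 0L) return(NULL)
  # recover original-case specimen id by position
  spec <- substr(id, 1L, nchar(m[2]))
  side <- if (m[3] %in% c("l", "left")) "left" else "right"
  list(specimen = spec, side = side,
       image_rep = as.integer(m[4]), digit_rep = as.integer(m[5]))
}

#' Read a TPS landmark file
#'
#' @param path file path.
#' @param id_parser function mapping the record identifier to a list with
#'   `specimen`, `side`, `image_rep`, `digit_rep` (see
#'   [parse_landmark_id()]); may also return a `population` element.
#' @param invert_y flip the y axis on read (for files digitized in image
#'   coordinates, where y grows downwards).
#' @return a [landmark_dataset()]. When `SCALE=` is present, coordinates are
#'   multiplied by it (converting pixels to physical units).
#' @export
read_tps <- function(path, id_parser = parse_landmark_id,
                     invert_y = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM=", lines, ignore.case = TRUE)
  assert_that(length(starts) > 0L, "no LM= records found")
  ends <- c(starts[-1] - 1L, length(lines))

  configs <- vector("list", length(starts))
  infos <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    k <- as.integer(sub("^LM=", "", block[1], ignore.case = TRUE))
    coord_lines <- block[-1][!grepl("=", block[-1])]
    if (length(coord_lines) != k) {
      stop(sprintf(
        "TPS record %d: LM=%d but %d coordinate line(s) found",
        r, k, length(coord_lines)), call. = FALSE)
    }
    xy <- do.call(rbind, lapply(strsplit(coord_lines, "[[:space:]]+"),
                                function(v) as.numeric(v[1:2])))
    if (any(!is.finite(xy))) {
      stop(sprintf("TPS record %d: non-numeric coordinates", r),
           call. = FALSE)
    }
    get_field <- function(name) {
      hit <- grep(paste0("^", name, "="), block, ignore.case = TRUE,
                  value = TRUE)
      if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
    }
    scale <- suppressWarnings(as.numeric(get_field("SCALE")))
    if (is.finite(scale)) xy <- xy * scale
    if (invert_y) xy[, 2] <- -xy[, 2]
    id <- get_field("ID")
    if (is.na(id)) id <- get_field("IMAGE")
    if (is.na(id)) {
      stop(sprintf("TPS record %d: no ID= or IMAGE= field", r),
           call. = FALSE)
    }
    meta <- id_parser(id)
    if (is.null(meta)) {
      stop(sprintf("TPS record %d: unparseable identifier '%s'", r, id),
           call. = FALSE)
    }
    configs[[r]] <- xy
    infos[[r]] <- data.frame(
      specimen = meta$specimen,
      population = meta$population %||% NA_character_,
      side = meta$side, image_rep = meta$image_rep,
      digit_rep = meta$digit_rep, stringsAsFactors = FALSE)
  }
  ks <- vapply(configs, nrow, integer(1))
  if (length(unique(ks)) != 1L) {
    stop("mixed landmark counts across records: ",
         paste(unique(ks), collapse = ", "), call. = FALSE)
  }
  landmark_dataset(configs, do.call(rbind, infos))
}

#' Write a landmark dataset to a TPS file
#'
#' Identifiers are written as `"<specimen>_<side>_i<image>_d<digit>"` (the
#' dialect [parse_landmark_id()] reads back), with side abbreviated to
#' `L`/`R`. Coordinates are written with 12 significant digits so that a
#' read/write cycle round-trips to well below 1e-9.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  info <- dataset$info
  out <- character(0)
  for (i in seq_len(nrow(info))) {
    xy <- dataset$coords[, , i]
    id <- sprintf("%s_%s_i%d_d%d", info$specimen[i],
                  ifelse(info$side[i] == "left", "L", "R"),
                  info$image_rep[i], info$digit_rep[i])
    out <- c(out,
             sprintf("LM=%d", dataset$k),
             sprintf("%.12g %.12g", xy[, 1], xy[, 2]),
             sprintf("ID=%s", id))
  }
  writeLines(out, path)
  invisible(path)
}
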