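#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by `nrows` rows
#' of values, first file row = northernmost. The matrix is flipped on read so
#' row 1 of the returned grid is the southernmost row.
#'
#' @param path file path.
#' @return a [scape_grid].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed header line ", i, ": '", lines[i], "'")
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val))
      stop("malformed header line ", i, ": '", lines[i], "'")
    hdr[[tolower(parts[1])]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed header: missing ", paste(miss, collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- paste(lines[i:length(lines)], collapse = " ")
  vals <- scan(text = body, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]  # file is north-first; store south-first
  scape_grid(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param g a [scape_grid].
#' @param path output path.
#' @param digits significant digits written (default 15, round-trip safe).
#' @export
write_grid <- function(g, path, digits = 15) {
  stopifnot(is.scape_grid(g))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  nr <- nrow(g$values); nc <- ncol(g$values)
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(g$xll, digits = digits)),
    paste("yllcorner", format(g$yll, digits = digits)),
    paste("cellsize", format(g$cellsize, digits = digits)),
    paste("NODATA_value", format(g$nodata, digits = digits))), con)
  m <- g$values[nr:1, , drop = FALSE]  # back to north-first
  for (r in seq_len(nr))
    writeLines(paste(format(m[r, ], digits = digits, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

.point_roles <- c("presence", "pseudo_absence", "telemetry", "disperser",
                  "available")

#' Point set constructor
#'
#' Point records used throughout: sightings, telemetry fixes, pseudo-absence
#' and availability samples, candidate dispersers. A plain data.frame with
#' required columns `id`, `x`, `y`, `role` and optional `individual_id`,
#' `sex`, `study_area`, `timestamp`.
#'
#' @param id unique point ids.
#' @param x,y projected coordinates in meters (finite).
#' @param role one of `presence`, `pseudo_absence`, `telemetry`, `disperser`,
#'   `available`.
#' @param ... optional extra columns (recycled by data.frame rules).
#' @return data.frame of class `scape_points`.
#' @export
scape_points <- function(id, x, y, role, ...) {
  if (anyDuplicated(id)) stop("point ids must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  role <- as.character(role)
  bad <- setdiff(unique(role), .point_roles)
  if (length(bad))
    stop("unknown point role(s): ", paste(bad, collapse = ", "))
  out <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y),
                    role = role, ..., stringsAsFactors = FALSE)
  class(out) <- c("scape_points", "data.frame")
  out
}

#' Read points from CSV
#'
#' Requires `id`, `x`, `y`, `role` columns; all other columns are carried
#' through. Rows with missing/blank coordinates are rejected and reported by
#' id (mirroring removal of records with missing geospatial data), with the
#' retained count attached as attribute `n_dropped`.
#'
#' @param path CSV path.
#' @return `scape_points` data.frame; attribute `n_dropped` gives the number
#'   of rows removed for missing coordinates, `dropped_ids` their ids.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "role")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("points CSV missing column(s): ", paste(miss, collapse = ", "))
  df$x <- suppressWarnings(as.numeric(df$x))
  df$y <- suppressWarnings(as.numeric(df$y))
  bad <- !is.finite(df$x) | !is.finite(df$y)
  dropped <- df$id[bad]
  if (any(bad)) {
    message(sum(bad), " row(s) with missing coordinates removed: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (sum(bad) > 10) ", ..." else "")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("no rows with valid coordinates in ", path)
  extra <- df[setdiff(names(df), need)]
  out <- do.call(scape_points,
                 c(list(id = df$id, x = df$x, y = df$y, role = df$role),
                   as.list(extra)))
  attr(out, "n_dropped") <- sum(bad)
  attr(out, "dropped_ids") <- dropped
  out
}

#' Write points to CSV
#'
#' @param pts a `scape_points` data.frame.
#' @param path output path.
#' @export
write_points <- function(pts, path) {
  utils::write.csv(as.data.frame(pts), path, row.names = FALSE)
  invisible(path)
}

.line_classes <- c("high_traffic", "other_road", "stream")

#' Line set constructor
#'
#' Polyline features (roads, streams) as a list of features, each a list with
#' a two-column `coords` vertex matrix (map units) and a `class` from
#' `high_traffic`, `other_road`, `stream`.
#'
#' @param features list of `list(coords = <n x 2 matrix>, class = <chr>)`.
#' @return object of class `scape_lines`.
#' @export
scape_lines <- function(features) {
  for (f in features) {
    if (is.null(f$coords) || nrow(f$coords) < 2)
      stop("each line feature needs >= 2 vertices")
    if (!f$class %in% .line_classes)
      stop("unknown line class: ", f$class)
  }
  structure(list(features = features), class = "scape_lines")
}

#' @export
print.scape_lines <- function(x, ...) {
  cls <- vapply(x$features, function(f) f$class, "")
  cat("<scape_lines>", length(x$features), "features:",
      paste(sprintf("%s=%d", names(table(cls)), table(cls)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write lines as GeoJSON LineStrings
#'
#' @param lines a `scape_lines` object.
#' @param path output path.
#' @export
write_lines <- function(lines, path) {
  feats <- lapply(lines$features, function(f) {
    list(type = "Feature",
         properties = list(class = f$class),
         geometry = list(type = "LineString",
                         coordinates = unname(split(f$coords,
                                                    seq_len(nrow(f$coords))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON LineStrings
#'
#' @param path GeoJSON path.
#' @return a `scape_lines` object.
#' @export
read_lines_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- lapply(j$features, function(f) {
    cc <- do.call(rbind, lapply(f$geometry$coordinates,
                                function(p) unlist(p)))
    list(coords = cc, class = f$properties$class)
  })
  scape_lines(feats)
}
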