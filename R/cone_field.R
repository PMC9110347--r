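#' Labelled 2-D cone centroid field
#'
#' A `cone_field` holds the digitized centroids of cone photoreceptors in a
#' rectangular sampling window, one point per morphological cone unit (a
#' double or triple cone contributes a single centroid with its class label).
#' Coordinates are continuous Cartesian positions in micrometres with the
#' origin at the lower-left window corner.
#'
#' @param x,y Numeric vectors of equal length, centroid coordinates in um.
#' @param label Character or factor vector of cone classes, one per point;
#'   values must be among `"single"`, `"double"`, `"triple"`.
#' @param window Numeric length-2 vector, window width and height in um.
#'   Defaults to the 52 x 52 um^2 micrograph field.
#' @param meta Optional named list of free-form tags (region, stage,
#'   generator parameters, seed).
#'
#' @return An object of class `cone_field`: a list with elements `x`, `y`,
#'   `label` (factor with levels single/double/triple), `window`, `meta`.
#' @examples
#' f <- cone_field(c(10, 20, 30), c(10, 20, 30),
#'                 c("single", "double", "triple"))
#' f
#' @export
cone_field <- function(x, y, label, window = c(52, 52), meta = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length")
  if (length(label) != length(x))
    stop("`label` must have one entry per point")
  label <- as.character(label)
  bad <- setdiff(unique(label), CONE_CLASSES)
  if (length(bad))
    stop("unknown cone class label(s): ", paste(bad, collapse = ", "))
  window <- as.numeric(window)
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    stop("`window` must be two positive numbers (width, height) in um")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  if (length(x) && (any(x < 0 | x > window[1]) || any(y < 0 | y > window[2])))
    stop("all points must lie inside the window [0,", window[1],
         "] x [0,", window[2], "]")
  structure(
    list(x = x, y = y,
         label = factor(label, levels = CONE_CLASSES),
         window = window, meta = meta),
    class = "cone_field")
}

#' Cone class labels recognised throughout the package
#' @keywords internal
CONE_CLASSES <- c("single", "double", "triple")

#' Soma size constraints per cone class
#'
#' Hard-core (centre-to-centre) exclusion distances used when simulating
#' random fields constrained by soma size. Defaults are the measured mean
#' single-cone diameter, double-cone short-axis, and triple-cone median
#' chord, in micrometres.
#'
#' @param single,double,triple Positive sizes in um.
#' @return Named numeric vector of class `soma_sizes`.
#' @examples
#' soma_sizes()
#' @export
soma_sizes <- function(single = 2.2, double = 3.0, triple = 4.1) {
  s <- c(single = single, double = double, triple = triple)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all soma sizes must be strictly positive")
  structure(s, class = "soma_sizes")
}

#' @export
print.cone_field <- function(x, ...) {
  n <- length(x$x)
  cat("Cone centroid field:", n, "points in",
      paste0(x$window[1], " x ", x$window[2], " um window\n"))
  if (n) {
    tab <- table(x$label)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cone_field <- function(x, pch = NULL, col = NULL, asp = 1, ...) {
  cls <- as.integer(x$label)
  if (is.null(pch)) pch <- c(16, 17, 15)[cls]
  if (is.null(col)) col <- c("goldenrod", "firebrick", "forestgreen")[cls]
  graphics::plot(x$x, x$y, pch = pch, col = col, asp = asp,
                 xlim = c(0, x$window[1]), ylim = c(0, x$window[2]),
                 xlab = "x (um)", ylab = "y (um)", ...)
  graphics::rect(0, 0, x$window[1], x$window[2], border = "grey40")
  invisible(x)
}

#' Number of points of a class in a field
#' @param field A [cone_field()].
#' @param cone_class One of `"single"`, `"double"`, `"triple"`, or `"all"`.
#' @return Integer count.
#' @keywords internal
class_index <- function(field, cone_class) {
  stopifnot(inherits(field, "cone_field"))
  if (identical(cone_class, "all")) return(seq_along(field$x))
  cone_class <- match.arg(cone_class, CONE_CLASSES)
  which(field$label == cone_class)
}

#' Read a cone centroid field from CSV
#'
#' The file must have a header `x_um,y_um,cone_class`. The window can be
#' supplied in a comment line `# window_um=52,52` before the header, or via
#' the `window` argument (the argument wins if both are given).
#'
#' @param path Path to the CSV file.
#' @param window Optional numeric length-2 window (um); overrides any
#'   window recorded in the file.
#' @return A [cone_field()].
#' @export
read_cone_field <- function(path, window = NULL) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  file_window <- NULL
  wline <- grep("window_um\\s*=", comments, value = TRUE)
  if (length(wline)) {
    val <- sub(".*window_um\\s*=\\s*", "", wline[1])
    file_window <- as.numeric(strsplit(trimws(val), ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "cone_class")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  for (cc in c("x_um", "y_um")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v))
      stop("non-numeric value in column ", cc, " at data row ",
           which(is.na(v))[1])
    df[[cc]] <- v
  }
  bad <- which(!(df$cone_class %in% CONE_CLASSES))
  if (length(bad))
    stop("unknown cone class '", df$cone_class[bad[1]], "' at data row ",
         bad[1])
  win <- if (!is.null(window)) window else
    if (!is.null(file_window)) file_window else c(52, 52)
  out_x <- which(df$x_um < 0 | df$x_um > win[1] |
                 df$y_um < 0 | df$y_um > win[2])
  if (length(out_x))
    stop("point outside window at data row ", out_x[1], " (",
         df$x_um[out_x[1]], ", ", df$y_um[out_x[1]], ")")
  cone_field(df$x_um, df$y_um, df$cone_class, window = win,
             meta = list(source = path))
}

#' Write a cone centroid field to CSV
#'
#' Writes the schema read by [read_cone_field()], including the
#' `# window_um=` comment header, at full double precision.
#'
#' @param field A [cone_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cone_field <- function(field, path) {
  stopifnot(inherits(field, "cone_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_um=%.17g,%.17g",
                     field$window[1], field$window[2]), con)
  writeLines("x_um,y_um,cone_class", con)
  if (length(field$x))
    writeLines(sprintf("%.17g,%.17g,%s", field$x, field$y,
                       as.character(field$label)), con)
  invisible(path)
}
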