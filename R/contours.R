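# Conversion between 3-class label masks and epicardial/endocardial
# contour polylines, plus the CON-TXT v1 plain-text contour file dialect.
#
# Coordinate convention (fixed for all round trips and documented in the
# file header): 1-based pixel indices, x = column, y = row, with contour
# vertices at pixel-center coordinates. Boundaries are traced as the 0.5
# iso-contour of the binary region indicator, so vertices sit on half-pixel
# positions between foreground and background pixel centers.

# Trace the outer boundary of a binary region as a closed polyline.
# Holes are filled beforehand (papillary muscles belong to the blood pool)
# and, when several connected components exist, the largest by area is
# traced and the event is reported via a message.
trace_boundary <- function(region, what = "region") {
  if (!any(region)) return(NULL)
  m <- matrix(as.numeric(region), nrow(region), ncol(region))
  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp > 1) {
    areas <- tabulate(lab[lab > 0], nbins = ncomp)
    keep <- which.max(areas)
    message(sprintf("%s has %d connected components; tracing the largest",
                    what, ncomp))
    m <- matrix(as.numeric(lab == keep), nrow(m), ncol(m))
  }
  m <- EBImage::fillHull(m)
  H <- nrow(m); W <- ncol(m)
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- m
  cl <- grDevices::contourLines(x = 0:(H + 1), y = 0:(W + 1), z = z,
                                levels = 0.5)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(ct) length(ct$x), integer(1))
  ct <- cl[[which.max(lens)]]
  # contourLines' x follows rows, y follows columns; emit (x=col, y=row)
  poly <- cbind(x = ct$y, y = ct$x)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

#' Extract endocardial and epicardial contours from a label mask
#'
#' The endocardial contour is the boundary of the cavity region (label 1,
#' holes filled); the epicardial contour is the outer boundary of the
#' union of cavity and myocardium (labels 1 and 2). An empty region yields
#' an absent (`NULL`) contour; when a region has several connected
#' components the largest is traced and a message is emitted.
#'
#' @param mask 2D integer matrix with labels in `{0, 1, 2}`.
#' @param slice_index,phase_index Optional indices stored on the result.
#' @return A `contour_pair` list with elements `endo`, `epi` (two-column
#'   matrices of (x = column, y = row) vertices of an implicitly closed
#'   polyline, or `NULL`), `slice_index` and `phase_index`.
#' @export
mask_to_contours <- function(mask, slice_index = NA_integer_,
                             phase_index = NA_integer_) {
  if (!all(mask %in% 0:2))
    stop("mask labels must lie in {0, 1, 2}", call. = FALSE)
  endo <- trace_boundary(mask == 1L, "cavity")
  epi <- trace_boundary(mask == 1L | mask == 2L, "epicardial region")
  structure(list(endo = endo, epi = epi,
                 slice_index = as.integer(slice_index),
                 phase_index = as.integer(phase_index)),
            class = "contour_pair")
}

point_in_poly <- function(px, py, poly, boundary = FALSE) {
  pracma::inpolygon(px, py, poly[, 1], poly[, 2], boundary = boundary)
}

#' Rasterize a contour pair into a 3-class label mask
#'
#' Pixels whose centers lie strictly inside the endocardial polygon get
#' label 1; inside the epicardial but not the endocardial polygon, label 2;
#' all others 0. Absent contours yield an all-background mask.
#'
#' @param cp A `contour_pair` (see [mask_to_contours()]).
#' @param shape Integer vector `c(rows, cols)` of the target grid.
#' @return Integer label matrix.
#' @export
contours_to_mask <- function(cp, shape) {
  H <- shape[1]; W <- shape[2]
  out <- matrix(0L, H, W)
  if (is.null(cp$endo) && is.null(cp$epi)) return(out)
  if (!is.null(cp$endo) && !is.null(cp$epi) &&
      !all(point_in_poly(cp$endo[, 1], cp$endo[, 2], cp$epi, boundary = TRUE)))
    stop("endocardial contour must lie inside the epicardial contour",
         call. = FALSE)
  px <- rep(seq_len(W), each = H)   # x = column
  py <- rep(seq_len(H), times = W)  # y = row
  inside_endo <- if (is.null(cp$endo)) rep(FALSE, H * W) else
    point_in_poly(px, py, cp$endo)
  inside_epi <- if (is.null(cp$epi)) inside_endo else
    point_in_poly(px, py, cp$epi)
  out[matrix(inside_epi, H, W)] <- 2L
  out[matrix(inside_endo, H, W)] <- 1L
  out
}

#' Contour file container
#'
#' @param scan_id Character scan identifier (no whitespace).
#' @param spacing Numeric `c(dx, dy, dz)`: pixel spacing and slice
#'   thickness in mm.
#' @param contours List of `contour_pair` objects.
#' @return A `contour_file` list.
#' @export
contour_file <- function(scan_id, spacing, contours = list()) {
  if (grepl("\\s", scan_id)) stop("`scan_id` must not contain whitespace",
                                  call. = FALSE)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("`spacing` must be three positive numbers", call. = FALSE)
  structure(list(scan_id = as.character(scan_id),
                 spacing = as.numeric(spacing),
                 contours = contours),
            class = "contour_file")
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a contour file in the CON-TXT v1 dialect
#'
#' CON-TXT v1 is a plain-text (UTF-8, LF) stand-in for proprietary binary
#' contour files: a header (`#CONTXT 1`, `scan <id>`,
#' `spacing <dx> <dy> <dz>`) followed by blocks
#' `contour <slice> <phase> <endo|epi> <n>` and `n` lines `x y`.
#' Contours are emitted ordered by slice, then phase, with endo before
#' epi; coordinates are printed with 17 significant digits so that
#' `read_contour_file(write_contour_file(x))` is bit-exact.
#'
#' @param cf A [contour_file()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_contour_file <- function(cf, path) {
  stopifnot(inherits(cf, "contour_file"))
  lines <- c("#CONTXT 1",
             paste("scan", cf$scan_id),
             paste("spacing", paste(fmt_num(cf$spacing), collapse = " ")))
  ord <- order(vapply(cf$contours, `[[`, integer(1), "slice_index"),
               vapply(cf$contours, `[[`, integer(1), "phase_index"))
  for (cp in cf$contours[ord]) {
    for (kind in c("endo", "epi")) {
      poly <- cp[[kind]]
      if (is.null(poly)) next
      lines <- c(lines,
                 sprintf("contour %d %d %s %d", cp$slice_index,
                         cp$phase_index, kind, nrow(poly)),
                 paste(fmt_num(poly[, 1]), fmt_num(poly[, 2])))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a CON-TXT v1 contour file
#'
#' @param path Path to a file written by [write_contour_file()].
#' @return A [contour_file()] object.
#' @export
read_contour_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fail <- function(i, msg) stop(sprintf("parse error at line %d: %s", i, msg),
                                call. = FALSE)
  if (length(lines) < 3) fail(length(lines), "truncated header")
  if (lines[1] != "#CONTXT 1") fail(1L, "unknown header or version")
  sc <- strsplit(lines[2], " ", fixed = TRUE)[[1]]
  if (length(sc) != 2 || sc[1] != "scan") fail(2L, "expected `scan <id>`")
  sp <- strsplit(lines[3], " ", fixed = TRUE)[[1]]
  if (length(sp) != 4 || sp[1] != "spacing")
    fail(3L, "expected `spacing <dx> <dy> <dz>`")
  spacing <- suppressWarnings(as.numeric(sp[-1]))
  if (anyNA(spacing)) fail(3L, "non-numeric spacing")

  pairs <- list()
  key_of <- function(s, p) paste(s, p, sep = "/")
  i <- 4L
  while (i <= length(lines)) {
    if (lines[i] == "") { i <- i + 1L; next }
    tok <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (length(tok) != 5 || tok[1] != "contour")
      fail(i, "expected `contour <slice> <phase> <endo|epi> <n>`")
    s <- suppressWarnings(as.integer(tok[2]))
    p <- suppressWarnings(as.integer(tok[3]))
    kind <- tok[4]
    n <- suppressWarnings(as.integer(tok[5]))
    if (is.na(s) || is.na(p) || is.na(n)) fail(i, "non-integer field")
    if (!kind %in% c("endo", "epi")) fail(i, "boundary type must be endo|epi")
    if (i + n > length(lines)) fail(length(lines), "truncated vertex list")
    verts <- matrix(NA_real_, n, 2)
    for (j in seq_len(n)) {
      vt <- strsplit(lines[i + j], " ", fixed = TRUE)[[1]]
      if (length(vt) != 2) fail(i + j, "expected `x y`")
      verts[j, ] <- suppressWarnings(as.numeric(vt))
      if (anyNA(verts[j, ])) fail(i + j, "non-numeric vertex")
    }
    colnames(verts) <- c("x", "y")
    key <- key_of(s, p)
    if (is.null(pairs[[key]]))
      pairs[[key]] <- structure(list(endo = NULL, epi = NULL,
                                     slice_index = s, phase_index = p),
                                class = "contour_pair")
    pairs[[key]][[kind]] <- verts
    i <- i + n + 1L
  }
  contour_file(sc[2], spacing, unname(pairs))
}
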