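# Gridded bathymetry: analytic generators, point lookup, ESRI ASCII I/O.
# Depth is stored positive-down in meters on a regular node grid; x/y are
# node (cell-center) coordinates in the local ENU frame.

#' Construct a bathymetry grid
#'
#' @param x,y Strictly increasing, regularly spaced node coordinates (m).
#' @param depth Matrix of depths (m, positive down), `length(x)` rows by
#'   `length(y)` columns.
#' @return An object of class `bathymetry`.
#' @export
bathymetry <- function(x, y, depth) {
  x <- as.numeric(x); y <- as.numeric(y); depth <- as.matrix(depth)
  check_axis <- function(a, nm) {
    if (length(a) < 2L) stop(nm, " axis needs at least 2 nodes")
    d <- diff(a)
    if (any(d <= 0)) stop(nm, " axis must be strictly increasing")
    if (diff(range(d)) > 1e-6 * mean(d)) stop(nm, " axis must be regular")
    mean(d)
  }
  dx <- check_axis(x, "x"); dy <- check_axis(y, "y")
  if (abs(dx - dy) > 1e-6 * dx) stop("grid cells must be square")
  if (!all(dim(depth) == c(length(x), length(y))))
    stop("depth must be length(x) x length(y)")
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("all depths must be finite and positive (meters, positive down)")
  structure(list(x = x, y = y, depth = depth, cell_size = dx),
            class = "bathymetry")
}

#' Generate an analytic bathymetry surface
#'
#' Three surface families stand in for the monitored sites: a flat plain, a
#' uniform slope, and a plain incised by a Gaussian-profile canyon channel.
#'
#' @param kind One of `"flat"`, `"slope"`, `"canyon"`.
#' @param params Named list of surface parameters:
#'   * flat: `depth` (m, default 1300).
#'   * slope: `depth` (at the grid origin), `gradient_x`, `gradient_y`
#'     (m depth per m horizontal, default 0).
#'   * canyon: `depth` (base plain), `excess` (extra channel depth, m),
#'     `width` (Gaussian sigma of the channel, m), `axis_x` (east coordinate
#'     of the north-south channel axis, default 0).
#' @param extent Numeric length-4 `c(xmin, xmax, ymin, ymax)` in meters.
#' @param cell_size Node spacing in meters.
#' @return A [bathymetry()] grid whose nodes sample the analytic surface
#'   exactly.
#' @export
generate_bathymetry <- function(kind = c("flat", "slope", "canyon"),
                                params = list(), extent = c(-4000, 4000, -4000, 4000),
                                cell_size = 100) {
  kind <- match.arg(kind)
  stopifnot(length(extent) == 4L)
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  if (extent[2] - extent[1] < cell_size || extent[4] - extent[3] < cell_size)
    stop("extent must span at least one cell in each direction")
  x <- seq(extent[1], extent[2], by = cell_size)
  y <- seq(extent[3], extent[4], by = cell_size)
  f <- switch(kind,
    flat = {
      d0 <- params$depth %||% 1300
      function(px, py) rep(d0, length(px))
    },
    slope = {
      d0 <- params$depth %||% 1300
      gx <- params$gradient_x %||% 0
      gy <- params$gradient_y %||% 0
      function(px, py) d0 + gx * px + gy * py
    },
    canyon = {
      d0 <- params$depth %||% 1300
      ex <- params$excess %||% 150
      w <- params$width %||% 500
      ax <- params$axis_x %||% 0
      function(px, py) d0 + ex * exp(-0.5 * ((px - ax) / w)^2)
    })
  g <- expand.grid(x = x, y = y)
  bathymetry(x, y, matrix(f(g$x, g$y), length(x), length(y)))
}

#' Seafloor depth at arbitrary points
#'
#' @param bathy A [bathymetry()] grid.
#' @param x,y Query coordinates (m); recycled to a common length.
#' @param method `"nearest"` (closest grid node, the default) or
#'   `"bilinear"`.
#' @return Depths in meters, positive down.
#' @export
bathy_depth_at <- function(bathy, x, y, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  rx <- range(bathy$x); ry <- range(bathy$y)
  if (any(x < rx[1] | x > rx[2] | y < ry[1] | y > ry[2]))
    stop("query point outside bathymetry extent")
  if (method == "nearest") {
    ix <- pmin(pmax(round((x - bathy$x[1]) / bathy$cell_size) + 1, 1), length(bathy$x))
    iy <- pmin(pmax(round((y - bathy$y[1]) / bathy$cell_size) + 1, 1), length(bathy$y))
    bathy$depth[cbind(ix, iy)]
  } else {
    cs <- bathy$cell_size
    fx <- (x - bathy$x[1]) / cs
    fy <- (y - bathy$y[1]) / cs
    i0 <- pmin(pmax(floor(fx) + 1, 1), length(bathy$x) - 1)
    j0 <- pmin(pmax(floor(fy) + 1, 1), length(bathy$y) - 1)
    tx <- fx - (i0 - 1); ty <- fy - (j0 - 1)
    d00 <- bathy$depth[cbind(i0, j0)]
    d10 <- bathy$depth[cbind(i0 + 1, j0)]
    d01 <- bathy$depth[cbind(i0, j0 + 1)]
    d11 <- bathy$depth[cbind(i0 + 1, j0 + 1)]
    (1 - tx) * (1 - ty) * d00 + tx * (1 - ty) * d10 +
      (1 - tx) * ty * d01 + tx * ty * d11
  }
}

#' Write a grid as ESRI ASCII raster
#'
#' Node coordinates are treated as cell centers; rows are written north to
#' south per the format. Works for [bathymetry()] grids and for any count or
#' probability grid shaped the same way.
#'
#' @param bathy A [bathymetry()] object (or list with `x`, `y`, square-celled
#'   `depth` matrix).
#' @param path Output file path.
#' @param nodata NODATA sentinel written for non-finite cells.
#' @export
write_esri_ascii <- function(bathy, path, nodata = -9999) {
  z <- bathy$depth
  cs <- bathy$cell_size %||% mean(diff(bathy$x))
  hdr <- c(sprintf("ncols %d", length(bathy$x)),
           sprintf("nrows %d", length(bathy$y)),
           sprintf("xllcorner %.10g", bathy$x[1] - cs / 2),
           sprintf("yllcorner %.10g", bathy$y[1] - cs / 2),
           sprintf("cellsize %.10g", cs),
           sprintf("NODATA_value %.10g", nodata))
  z[!is.finite(z)] <- nodata
  rows <- vapply(rev(seq_along(bathy$y)),
                 function(j) paste(format(z[, j], trim = TRUE, digits = 15),
                                   collapse = " "),
                 character(1))
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII raster as a bathymetry grid
#'
#' @param path File path.
#' @return A [bathymetry()] object (NODATA cells become `NA` and are rejected
#'   by the constructor; grids with NODATA should be read with
#'   `validate = FALSE`).
#' @param validate If `FALSE`, skip the positive-depth check and return the
#'   raw grid structure.
#' @export
read_esri_ascii <- function(path, validate = TRUE) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- hdr$ncols; nr <- hdr$nrows; cs <- hdr$cellsize
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr) stop("ESRI ASCII grid has wrong cell count")
  m <- matrix(vals, nrow = nc)          # columns are raster rows, north first
  m <- m[, rev(seq_len(nr)), drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  x <- hdr$xllcorner + cs / 2 + (seq_len(nc) - 1) * cs
  y <- hdr$yllcorner + cs / 2 + (seq_len(nr) - 1) * cs
  if (validate) bathymetry(x, y, m)
  else structure(list(x = x, y = y, depth = m, cell_size = cs),
                 class = "bathymetry")
}
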