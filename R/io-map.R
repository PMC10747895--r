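#' 3-D density map
#'
#' A scalar grid with physical metadata: voxel size, origin (position of the
#' first voxel, Angstrom) and a stated nominal resolution. The grid is held
#' in canonical X, Y, Z axis order (X fastest); [read_map] re-orders
#' whatever axis order the file declares into this convention. Voxel
#' `(i, j, k)` (1-based) sits at `origin + (c(i, j, k) - 1) * voxel_size`.
#'
#' @param grid 3-D numeric array.
#' @param voxel_size length-3 (or scalar) voxel edge lengths, Angstrom.
#' @param origin length-3 position of voxel (1,1,1), Angstrom.
#' @param resolution stated resolution in Angstrom (NA if unknown).
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        resolution = NA_real_) {
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  if (any(dim(grid) < 2L)) stop("map grid must be at least 2 voxels per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  structure(list(grid = grid, voxel_size = voxel_size,
                 origin = as.numeric(origin), resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "density_map: %d x %d x %d voxels, voxel %.3g x %.3g x %.3g A, origin (%.1f, %.1f, %.1f)\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  density min %.4g max %.4g mean %.4g", min(x$grid),
              max(x$grid), mean(x$grid)))
  if (is.finite(x$resolution)) cat(sprintf(", stated resolution %.1f A", x$resolution))
  cat("\n")
  invisible(x)
}

#' Read an MRC/CCP4 2014 density map
#'
#' Minimal MRC2014 reader (modes 0, 1, 2 and 6). The MAPC/MAPR/MAPS axis
#' order words are honored and the grid re-ordered into canonical X, Y, Z;
#' the origin is taken from the ORIGIN header fields when set, otherwise
#' from NXSTART/NYSTART/NZSTART times the voxel size. EMDB entries vary in
#' both conventions.
#'
#' @param path file path.
#' @param resolution optional stated resolution to attach (Angstrom).
#' @return A [density_map].
#' @export
read_map <- function(path, resolution = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 1024L)
  stamp <- hdr_raw[213:214]  # word 54
  endian <- if (as.integer(stamp[1]) == 0x11) "big" else "little"
  ints <- readBin(hdr_raw, "integer", 256L, size = 4L, endian = endian)
  flts <- readBin(hdr_raw, "numeric", 256L, size = 4L, endian = endian)
  nc <- ints[1]; nr <- ints[2]; ns <- ints[3]; mode <- ints[4]
  nstart <- ints[5:7]
  m <- ints[8:10]
  cella <- flts[11:13]
  axis_map <- ints[17:19]            # MAPC, MAPR, MAPS: physical axis per slot
  if (!all(sort(axis_map) == 1:3))
    stop("invalid MAPC/MAPR/MAPS axis words: ", paste(axis_map, collapse = ","))
  nvox <- as.double(nc) * nr * ns
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", nvox, size = 1L, signed = TRUE, endian = endian)),
    "1" = as.numeric(readBin(con, "integer", nvox, size = 2L, signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", nvox, size = 4L, endian = endian),
    "6" = as.numeric(readBin(con, "integer", nvox, size = 2L, signed = FALSE, endian = endian)),
    stop("unsupported MRC mode word: ", mode))
  if (length(data) < nvox) stop("truncated MRC data block in ", path)
  A <- array(data, dim = c(nc, nr, ns))
  perm <- match(1:3, axis_map)       # storage slot holding each physical axis
  grid <- aperm(A, perm)
  # MX/MY/MZ and CELLA are along physical X,Y,Z; N*START follows storage order
  voxel <- ifelse(m > 0, cella / pmax(m, 1L), 1)
  nstart_phys <- nstart; nstart_phys[axis_map] <- nstart
  origin_field <- flts[50:52]
  origin <- if (any(origin_field != 0)) origin_field else nstart_phys * voxel
  density_map(grid, voxel_size = voxel, origin = origin, resolution = resolution)
}

#' Write a density map as MRC2014 (mode 2)
#'
#' Written in canonical axis order with the physical origin in the ORIGIN
#' header fields; round-trips through [read_map].
#'
#' @param map a [density_map].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  g <- as.numeric(map$grid)
  wi(d); wi(2L)                       # NX NY NZ, MODE 2
  wi(c(0L, 0L, 0L))                   # NXSTART..
  wi(d)                               # MX MY MZ
  wf(d * map$voxel_size)              # CELLA
  wf(c(90, 90, 90))                   # CELLB
  wi(1:3)                             # MAPC MAPR MAPS canonical
  wf(c(min(g), max(g), mean(g)))      # DMIN DMAX DMEAN
  wi(c(1L, 0L))                       # ISPG, NSYMBT
  wi(rep(0L, 25L))                    # EXTRA, words 25-49
  wf(map$origin)                      # ORIGIN
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(stats::sd(g))                    # RMS
  wi(0L)                              # NLABL
  wi(rep(0L, 200L))                   # labels
  wf(g)
  invisible(path)
}

#' Physical coordinates of every voxel
#' @param map a [density_map].
#' @return N x 3 matrix in grid linear order (X fastest).
#' @export
map_voxel_coords <- function(map) {
  d <- dim(map$grid)
  ix <- (seq_len(d[1]) - 1) * map$voxel_size[1] + map$origin[1]
  iy <- (seq_len(d[2]) - 1) * map$voxel_size[2] + map$origin[2]
  iz <- (seq_len(d[3]) - 1) * map$voxel_size[3] + map$origin[3]
  cbind(rep(ix, times = d[2] * d[3]),
        rep(rep(iy, each = d[1]), times = d[3]),
        rep(iz, each = d[1] * d[2]))
}

#' Trilinear interpolation of a map at arbitrary points
#'
#' Points outside the grid evaluate to 0.
#'
#' @param map a [density_map].
#' @param points N x 3 matrix of physical coordinates (Angstrom).
#' @return numeric vector of interpolated densities.
#' @export
map_interpolate <- function(map, points) {
  d <- dim(map$grid)
  p <- sweep(sweep(as.matrix(points), 2, map$origin, "-"), 2,
             map$voxel_size, "/") + 1  # continuous 1-based voxel index
  eps <- 1e-9
  inside <- p[, 1] >= 1 - eps & p[, 1] <= d[1] + eps &
            p[, 2] >= 1 - eps & p[, 2] <= d[2] + eps &
            p[, 3] >= 1 - eps & p[, 3] <= d[3] + eps
  p <- pmin(pmax(p, 1), matrix(d, nrow(p), 3, byrow = TRUE))
  i0 <- pmin(floor(p), matrix(d - 1L, nrow(p), 3, byrow = TRUE))
  fr <- p - i0
  out <- numeric(nrow(p))
  if (!any(inside)) return(out)
  i0 <- i0[inside, , drop = FALSE]
  fr <- fr[inside, , drop = FALSE]
  g <- map$grid
  lin <- function(dx, dy, dz)
    g[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  v <-
    lin(0, 0, 0) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    lin(1, 0, 0) * fr[, 1]       * (1 - fr[, 2]) * (1 - fr[, 3]) +
    lin(0, 1, 0) * (1 - fr[, 1]) * fr[, 2]       * (1 - fr[, 3]) +
    lin(1, 1, 0) * fr[, 1]       * fr[, 2]       * (1 - fr[, 3]) +
    lin(0, 0, 1) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    lin(1, 0, 1) * fr[, 1]       * (1 - fr[, 2]) * fr[, 3] +
    lin(0, 1, 1) * (1 - fr[, 1]) * fr[, 2]       * fr[, 3] +
    lin(1, 1, 1) * fr[, 1]       * fr[, 2]       * fr[, 3]
  out[inside] <- v
  out
}

#' Resample a map onto another map's grid
#' @param map the map to resample.
#' @param onto the map whose grid defines the target sampling.
#' @return A [density_map] on `onto`'s grid.
#' @export
resample_map <- function(map, onto) {
  vals <- map_interpolate(map, map_voxel_coords(onto))
  density_map(array(vals, dim(onto$grid)), onto$voxel_size, onto$origin,
              resolution = map$resolution)
}
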