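#' Voxel volume constructor
#'
#' A voxel volume is a 3D binary occupancy grid; the voxel size is carried
#' as metadata only (box counting works in voxel units).
#'
#' @param grid a 3D logical (or 0/1) array.
#' @param voxel_size_mm positive length-3 numeric.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_size_mm = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  if (is.numeric(grid)) {
    if (!all(grid %in% c(0, 1)))
      stop("occupancy must be strictly binary")
    grid <- array(grid != 0, dim = dim(grid))
  }
  if (!is.logical(grid))
    stop("grid must be logical or 0/1")
  if (any(dim(grid) < 1L))
    stop("all three extents must be >= 1")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 3L ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive numbers")
  structure(list(grid = grid, shape = dim(grid),
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(x$shape, collapse = " x "),
      " grid, ", sum(x$grid), " filled voxels\n", sep = "")
  invisible(x)
}

#' Solid cube phantom
#'
#' A fully filled `side`^3 grid; its box-counting dimension is 3, the
#' topological dimension of a solid.
#'
#' @param side positive integer edge length in voxels.
#' @return A `voxel_volume` with all `side`^3 voxels filled.
#' @export
make_solid_cube <- function(side) {
  side <- check_count(side, "side")
  voxel_volume(array(TRUE, dim = c(side, side, side)))
}

#' Slab phantom
#'
#' A `side` x `side` x `thickness` filled block inside a `side`^3 grid.
#' For thickness 1 this is a plane, with box-counting dimension 2.
#'
#' @param side positive integer edge length of the grid.
#' @param thickness positive integer slab thickness, at most `side`.
#' @return A `voxel_volume`.
#' @export
make_slab <- function(side, thickness = 1L) {
  side <- check_count(side, "side")
  thickness <- check_count(thickness, "thickness")
  if (thickness > side)
    stop("thickness must not exceed side")
  grid <- array(FALSE, dim = c(side, side, side))
  grid[, , seq_len(thickness)] <- TRUE
  voxel_volume(grid)
}

#' Menger sponge phantom
#'
#' Standard Menger construction: a cube of side 3^level where at each
#' recursion 20 of the 27 subcubes are kept (face centers and the body
#' center removed). The level-k sponge has exactly 20^k filled voxels and
#' Hausdorff dimension log(20)/log(3) ~ 2.7268.
#'
#' @param level nonnegative integer, at most 4 (level 4 is an 81^3 grid).
#' @return A `voxel_volume` of side 3^level.
#' @export
make_menger_sponge <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || level != round(level) ||
      level < 0)
    stop("level must be a nonnegative integer")
  if (level > 4)
    stop("level must be <= 4 (level 4 is already an 81^3 grid)")
  side <- 3L^level
  ax <- 0:(side - 1L)
  # voxel kept iff at every ternary digit position at most one coordinate
  # digit equals 1
  keep <- array(TRUE, dim = c(side, side, side))
  for (p in seq_len(level)) {
    d <- (ax %/% 3L^(p - 1L)) %% 3L == 1L
    mid <- outer(outer(d, d, "+"), d, "+") # count of middle digits per voxel
    keep <- keep & (mid < 2L)
  }
  voxel_volume(keep)
}

#' Block-grid phantom parcellation
#'
#' Lays the 68 atlas regions out as disjoint solid cubes on a 3D grid,
#' giving a parcellation where every region is non-empty and has a known
#' simple shape. Useful as a synthetic stand-in for a real labeled
#' parcellation when exercising the per-region FD pipeline.
#'
#' @param block_side positive integer edge of each region block, in voxels.
#' @param gap nonnegative integer spacing between blocks.
#' @param region_table a region table.
#' @return A `parcellation` with labels 1..68.
#' @export
make_block_parcellation <- function(block_side = 4L, gap = 1L,
                                    region_table = dk_region_table()) {
  block_side <- check_count(block_side, "block_side")
  if (gap < 0 || gap != round(gap)) stop("gap must be a nonnegative integer")
  n <- nrow(region_table)
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  pitch <- block_side + gap
  dims <- c(nx * pitch + gap, ny * pitch + gap, block_side + 2L * gap)
  labels <- array(0L, dim = dims)
  for (k in seq_len(n)) {
    ix <- (k - 1L) %% nx
    iy <- (k - 1L) %/% nx
    x0 <- gap + ix * pitch
    y0 <- gap + iy * pitch
    labels[x0 + seq_len(block_side), y0 + seq_len(block_side),
           gap + seq_len(block_side)] <- region_table$id[k]
  }
  parcellation(labels, region_table = region_table)
}

#' Write a voxel volume as a NIfTI mask
#'
#' @param volume a `voxel_volume`.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  img <- RNifti::asNifti(array(as.integer(volume$grid), dim = volume$shape))
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# shared argument check: strictly positive integer scalar
check_count <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || x != round(x) || x < 1)
    stop(what, " must be a positive integer")
  as.integer(x)
}
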