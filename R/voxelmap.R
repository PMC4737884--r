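# Spherical-voxel density mapping of 3D cell centroids.
#
# The analysis "voxel" is a sphere (default 100 um diameter) centred on a
# regular grid whose spacing (default 50 um, the radius) makes neighbouring
# spheres overlap, so one cell can contribute to several voxels. Counts per
# sphere give the density map; per-voxel paired NB tests plus BH-FDR give
# the voxelwise q map.

#' Define an overlapping-sphere voxel grid
#'
#' @param origin grid origin in micrometres (first sphere centre), length 3.
#' @param extent grid extent in micrometres along each axis; centres are laid
#'   at `origin + k * spacing` while within `origin + extent`.
#' @param sphere_diameter sphere diameter in micrometres (default 100).
#' @param center_spacing centre-to-centre spacing in micrometres, scalar or
#'   length 3 (default 50, the radius, so neighbouring spheres overlap).
#' @return a `voxel_grid` object with per-axis centre coordinates.
#' @export
voxel_grid <- function(origin = c(0, 0, 0), extent,
                       sphere_diameter = 100, center_spacing = 50) {
  origin <- rep_len(as.numeric(origin), 3)
  extent <- rep_len(as.numeric(extent), 3)
  center_spacing <- rep_len(as.numeric(center_spacing), 3)
  if (sphere_diameter <= 0) stop("sphere_diameter must be > 0")
  if (any(center_spacing <= 0)) stop("center_spacing must be > 0")
  if (any(extent <= 0)) stop("grid extent must be positive along every axis")
  axes <- lapply(1:3, function(a)
    origin[a] + center_spacing[a] * seq(0, floor(extent[a] / center_spacing[a])))
  structure(list(origin = origin, extent = extent,
                 sphere_diameter = sphere_diameter,
                 center_spacing = center_spacing, axes = axes,
                 dim = lengths(axes)),
            class = "voxel_grid")
}

#' Count cells inside each spherical voxel
#'
#' For every grid centre, counts the centroids whose Euclidean distance to
#' the centre is at most `sphere_diameter / 2` (boundary inclusive). Points
#' in the overlap of neighbouring spheres are counted in each.
#'
#' Candidate voxels for each point are found by index arithmetic on the
#' regular grid (only centres within the sphere radius along every axis are
#' examined), so cost scales with points, not with points times voxels.
#'
#' @param points matrix or data.frame of centroid coordinates in
#'   micrometres; first three columns are x, y, z.
#' @param grid a [voxel_grid()].
#' @return 3D integer array of counts, `dim = grid$dim`.
#' @export
voxel_density <- function(points, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  p <- as.matrix(as.data.frame(points)[, 1:3])
  storage.mode(p) <- "double"
  if (nrow(p) && any(!is.finite(p))) stop("centroid coordinates must be finite")
  counts <- array(0L, dim = grid$dim)
  if (!nrow(p)) return(counts)
  r <- grid$sphere_diameter / 2
  sp <- grid$center_spacing
  o <- grid$origin
  nd <- grid$dim
  for (i in seq_len(nrow(p))) {
    idx <- vector("list", 3)
    for (a in 1:3) {
      lo <- ceiling((p[i, a] - r - o[a]) / sp[a])
      hi <- floor((p[i, a] + r - o[a]) / sp[a])
      k <- max(0, lo):min(nd[a] - 1, hi)
      if (lo > hi || !length(k) || max(0, lo) > min(nd[a] - 1, hi)) {
        idx <- NULL; break
      }
      idx[[a]] <- k + 1L
    }
    if (is.null(idx)) next
    cand <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
    cx <- o[1] + (cand[, 1] - 1) * sp[1]
    cy <- o[2] + (cand[, 2] - 1) * sp[2]
    cz <- o[3] + (cand[, 3] - 1) * sp[3]
    d2 <- (cx - p[i, 1])^2 + (cy - p[i, 2])^2 + (cz - p[i, 3])^2
    hit <- d2 <= r^2 + 1e-9
    if (any(hit)) counts[cand[hit, , drop = FALSE]] <-
        counts[cand[hit, , drop = FALSE]] + 1L
  }
  counts
}

#' Construct a label atlas
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param spacing micrometres per voxel, scalar or length 3.
#' @param label_map optional named character vector, label id to acronym.
#' @return a `label_atlas` object.
#' @export
label_atlas <- function(labels, spacing, label_map = NULL) {
  stopifnot(length(dim(labels)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (any(labels < 0)) stop("labels must be non-negative (0 = background)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing, label_map = label_map),
            class = "label_atlas")
}

#' Tally cell centroids per atlas region
#'
#' Each point is assigned the label of the atlas voxel containing it, using
#' the half-open convention `[i * spacing, (i + 1) * spacing)` (coordinates
#' are 0-based micrometres in the atlas frame). Background (label 0) points
#' and points outside the volume are tallied separately, so the region
#' counts plus those two bins always sum to the cloud size.
#'
#' @param points centroid coordinates in micrometres (x, y, z columns).
#' @param atlas a [label_atlas()].
#' @return list: `counts` (named integer vector per region label),
#'   `background` and `out_of_volume` counts.
#' @export
region_counts <- function(points, atlas) {
  stopifnot(inherits(atlas, "label_atlas"))
  p <- as.matrix(as.data.frame(points)[, 1:3])
  dims <- dim(atlas$labels)
  ijk <- floor(sweep(p, 2, atlas$spacing, "/"))
  inside <- ijk[, 1] >= 0 & ijk[, 1] < dims[1] &
    ijk[, 2] >= 0 & ijk[, 2] < dims[2] &
    ijk[, 3] >= 0 & ijk[, 3] < dims[3]
  if (any(!inside)) warning(sum(!inside), " point(s) outside the atlas volume")
  labs_all <- sort(unique(as.vector(atlas$labels)))
  labs_all <- labs_all[labs_all > 0]
  lab <- atlas$labels[ijk[inside, , drop = FALSE] + 1L]
  tab <- table(factor(lab, levels = labs_all))
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       background = sum(lab == 0),
       out_of_volume = sum(!inside))
}

#' Per-voxel paired screen of density maps
#'
#' Runs the paired NB group test ([fit_paired_nb()]) on the integer counts
#' of every voxel across animals, then adjusts across all voxels with
#' [bh_fdr()].
#'
#' @param maps named list of per-animal density arrays (all from one grid);
#'   names are animal ids matching `design$animal_id`.
#' @param design pair design data.frame.
#' @param dispersion as in [region_screen()]: `"common"` (default, shared
#'   across voxels), `"per_region"`, or a fixed number.
#' @return list with `p` and `q` arrays shaped like the input maps.
#' @export
voxel_screen <- function(maps, design, dispersion = "common") {
  validate_pair_design(design)
  dims <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), dims), logical(1))))
    stop("all density maps must share one grid")
  if (!setequal(names(maps), design$animal_id))
    stop("animal mismatch between maps and design")
  y <- vapply(design$animal_id, function(id) as.vector(maps[[id]]),
              numeric(prod(dims)))
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)   # single-voxel grid
  colnames(y) <- design$animal_id
  counts <- t(y)
  colnames(counts) <- sprintf("v%06d", seq_len(ncol(counts)))
  res <- region_screen(counts, design, dispersion = dispersion)
  list(p = array(res$p_value, dims), q = array(res$q_value, dims))
}
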