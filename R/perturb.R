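## Systematic ROI perturbation by binary dilation/erosion, emulating
## inter-observer segmentation variability.

#' Discrete Euclidean-ball structuring element of radius 1
#'
#' The set of integer offsets with Euclidean norm <= 1: a 5-voxel cross in
#' 2D (circular element) and a 7-voxel octahedron in 3D (spherical element).
#'
#' @param dim 2 or 3.
#' @param radius only radius 1 is supported.
#' @return integer matrix of offsets, one row per neighbour (incl. centre).
#' @export
structuringElement <- function(dim, radius = 1) {
  if (!dim %in% c(2, 3)) stop("structuringElement: dim must be 2 or 3")
  if (radius != 1) stop("structuringElement: only radius 1 is supported")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1,
                             dz = if (dim == 3) -1:1 else 0))
  g[rowSums(g^2) <= 1, , drop = FALSE]
}

## shift-combine morphology; out-of-volume voxels count as background
.morph <- function(values, se, op) {
  d <- dim(values)
  P <- array(0, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- values
  out <- array(if (op == "dilate") 0 else 1, d)
  comb <- if (op == "dilate") pmax else pmin
  for (k in seq_len(nrow(se))) {
    o <- se[k, ]
    sh <- P[(2 + o[1]):(d[1] + 1 + o[1]),
            (2 + o[2]):(d[2] + 1 + o[2]),
            (2 + o[3]):(d[3] + 1 + o[3]), drop = FALSE]
    out <- comb(out, sh)
  }
  array(out, d)
}

#' Binary dilation of a mask
#'
#' @param mask a [VoxelMask-class].
#' @param iterations 1 or 2.
#' @param se structuring element; default radius-1 ball matched to the mask
#'   dimensionality (2D cross for depth-1 masks, 3D octahedron otherwise).
#' @return dilated [VoxelMask-class].
#' @export
dilateMask <- function(mask, iterations = 1, se = NULL) {
  stopifnot(iterations %in% c(1, 2))
  if (is.null(se))
    se <- structuringElement(if (dim(mask@values)[3] == 1) 2 else 3)
  v <- mask@values
  for (it in seq_len(iterations)) v <- .morph(v, se, "dilate")
  voxelMask(v, mask@spacing)
}

#' Binary erosion of a mask
#'
#' @inheritParams dilateMask
#' @param minVoxels minimum surviving foreground voxels.
#' @return eroded [VoxelMask-class]; error if fewer than `minVoxels` remain.
#' @export
erodeMask <- function(mask, iterations = 1, se = NULL, minVoxels = 1) {
  stopifnot(iterations %in% c(1, 2))
  if (is.null(se))
    se <- structuringElement(if (dim(mask@values)[3] == 1) 2 else 3)
  v <- mask@values
  for (it in seq_len(iterations)) v <- .morph(v, se, "erode")
  if (sum(v) < minVoxels)
    stop(sprintf("erodeMask: %d voxels remain, need >= %d (insufficient ROI)",
                 as.integer(sum(v)), minVoxels))
  voxelMask(v, mask@spacing)
}

#' Generate the perturbation variant set for a mask
#'
#' Variant ladders follow the analysis policy: single-slice uses erosions of
#' 1-2 and dilations of 1-2 iterations (5 variants incl. the original);
#' multi-slice keeps only one erosion so enough voxels survive (4 variants);
#' under resegmentation no erosion is performed at all (3 variants).
#'
#' @param mask a [VoxelMask-class].
#' @param policy "single_slice", "multi_slice" or "resegmented".
#' @param minVoxels minimum surviving voxels for eroded variants.
#' @return named list of [VoxelMask-class] objects, ordered from most eroded
#'   to most dilated; names from "erode2", "erode1", "original", "dilate1",
#'   "dilate2".
#' @export
generateVariants <- function(mask,
                             policy = c("single_slice", "multi_slice",
                                        "resegmented"),
                             minVoxels = 10) {
  policy <- match.arg(policy)
  ids <- switch(policy,
    single_slice = c("erode2", "erode1", "original", "dilate1", "dilate2"),
    multi_slice = c("erode1", "original", "dilate1", "dilate2"),
    resegmented = c("original", "dilate1", "dilate2"))
  out <- lapply(ids, function(id) {
    switch(id,
           erode2 = erodeMask(mask, 2, minVoxels = minVoxels),
           erode1 = erodeMask(mask, 1, minVoxels = minVoxels),
           original = mask,
           dilate1 = dilateMask(mask, 1),
           dilate2 = dilateMask(mask, 2))
  })
  names(out) <- ids
  out
}
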