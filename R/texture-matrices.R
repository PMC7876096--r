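## Grey-level texture matrices (GLCM, GLRLM, GLSZM, GLDM, NGTDM) computed on
## the level array of a QuantisedROI (NA outside the mask). All matrices use
## chessboard distance 1; GLCM/GLRLM are direction-resolved (4 in-plane
## directions in 2D, 13 in 3D), GLSZM/GLDM/NGTDM use the full 8/26
## neighbourhood.

## unique direction offsets (one per +/- pair)
.directions <- function(mode) {
  if (mode == "2d") {
    list(c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L), c(-1L, 1L, 0L))
  } else {
    out <- list()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      o <- c(dx, dy, dz)
      if (all(o == 0)) next
      nz <- o[o != 0]
      if (nz[1] > 0) out[[length(out) + 1L]] <- as.integer(o)
    }
    out   # 13 offsets
  }
}

## full neighbourhood (both signs)
.neighbourhood <- function(mode) {
  dirs <- .directions(mode)
  c(dirs, lapply(dirs, function(o) -o))
}

## extract aligned voxel pairs for an offset; returns list(a, b) of levels
## (NA where outside mask)
.offset_pairs <- function(L, o) {
  d <- dim(L)
  lo <- pmax(1L, 1L - o)
  hi <- pmin(d, d - o)
  if (any(lo > hi)) return(list(a = integer(0), b = integer(0)))
  r <- lapply(1:3, function(ax) seq.int(lo[ax], hi[ax]))
  a <- L[r[[1]], r[[2]], r[[3]], drop = FALSE]
  b <- L[r[[1]] + o[1], r[[2]] + o[2], r[[3]] + o[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Grey-level co-occurrence matrices
#'
#' One symmetric, normalised Ng x Ng co-occurrence matrix per direction at
#' chessboard distance 1. Directions with no in-mask voxel pair are omitted.
#'
#' @param roi a [QuantisedROI-class].
#' @param mode "2d" (4 in-plane directions) or "3d" (13 directions).
#' @return list of normalised matrices (possibly empty).
#' @export
glcmMatrices <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  L <- roi@levels; Ng <- roi@Ng
  out <- list()
  for (o in .directions(mode)) {
    p <- .offset_pairs(L, o)
    if (length(p$a) == 0) next
    cnt <- tabulate((p$a - 1L) * Ng + p$b, nbins = Ng * Ng)
    m <- matrix(cnt, Ng, Ng, byrow = TRUE)
    m <- m + t(m)                       # symmetrise
    out[[length(out) + 1L]] <- m / sum(m)
  }
  out
}

#' Grey-level run-length matrices
#'
#' One Ng x maxRunLength matrix of run counts per direction; runs are
#' maximal straight segments of equal grey level, broken by voxels outside
#' the mask.
#'
#' @inheritParams glcmMatrices
#' @return list of count matrices.
#' @export
glrlmMatrices <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  L <- roi@levels; Ng <- roi@Ng
  d <- dim(L)
  co <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  lv <- as.integer(L); lv[is.na(lv)] <- 0L
  out <- list()
  for (o in .directions(mode)) {
    ## line id = cross product (constant along a line), position = projection
    k1 <- co$x * o[2] - co$y * o[1]
    k2 <- co$y * o[3] - co$z * o[2]
    k3 <- co$x * o[3] - co$z * o[1]
    tt <- co$x * o[1] + co$y * o[2] + co$z * o[3]
    key <- paste(k1, k2, k3)
    ord <- order(key, tt, method = "radix")
    lo <- lv[ord]; ko <- key[ord]
    new_run <- c(TRUE, ko[-1] != ko[-length(ko)] | lo[-1] != lo[-length(lo)])
    run_id <- cumsum(new_run)
    len <- tabulate(run_id)
    g <- lo[new_run]
    keep <- g > 0L
    len <- len[keep]; g <- g[keep]
    if (length(len) == 0) next
    m <- matrix(0, Ng, max(len))
    cnt <- tabulate((g - 1L) * max(len) + len, nbins = Ng * max(len))
    m <- matrix(cnt, Ng, max(len), byrow = TRUE)
    out[[length(out) + 1L]] <- m
  }
  out
}

## linear-index neighbour offsets in a padded array
.lin_offsets <- function(dpad, mode) {
  vapply(.neighbourhood(mode),
         function(o) o[1] + o[2] * dpad[1] + o[3] * dpad[1] * dpad[2], 0)
}

.pad_levels <- function(L) {
  d <- dim(L)
  P <- array(NA_integer_, d + 2L)
  P[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- L
  P
}

#' Grey-level size-zone counts
#'
#' Connected zones of equal grey level under 8-connectivity (2D) or
#' 26-connectivity (3D).
#'
#' @inheritParams glcmMatrices
#' @return data.frame with columns `level` and `size`, one row per zone.
#' @export
glszmZones <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  P <- .pad_levels(roi@levels)
  noff <- .lin_offsets(dim(P), mode)
  lev <- integer(0); siz <- integer(0)
  for (g in sort(unique(P[!is.na(P)]))) {
    rem <- !is.na(P) & P == g
    while (any(rem)) {
      frontier <- which(rem)[1]
      size <- 0L
      while (length(frontier)) {
        rem[frontier] <- FALSE
        size <- size + length(frontier)
        nb <- unique(as.vector(outer(frontier, noff, "+")))
        frontier <- nb[rem[nb]]
      }
      lev <- c(lev, g); siz <- c(siz, size)
    }
  }
  data.frame(level = lev, size = siz)
}

#' Grey-level dependence matrix
#'
#' For each in-mask voxel the dependence size j counts the voxel itself plus
#' its neighbours (chessboard distance 1) whose grey level differs by at
#' most `alpha`. Returns the Ng x maxJ count matrix.
#'
#' @inheritParams glcmMatrices
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return count matrix, columns indexed by dependence size j = 1, 2, ...
#' @export
gldmMatrix <- function(roi, mode = c("2d", "3d"), alpha = 0) {
  mode <- match.arg(mode)
  P <- .pad_levels(roi@levels)
  d <- dim(P)
  inm <- which(!is.na(P))
  dep <- rep(1L, length(inm))   # centre voxel counts itself
  for (o in .lin_offsets(d, mode)) {
    nb <- P[inm + o]
    dep <- dep + as.integer(!is.na(nb) & abs(nb - P[inm]) <= alpha)
  }
  g <- P[inm]
  Ng <- roi@Ng; mj <- max(dep)
  cnt <- tabulate((g - 1L) * mj + dep, nbins = Ng * mj)
  matrix(cnt, Ng, mj, byrow = TRUE)
}

#' Neighbouring grey tone difference vector
#'
#' Per grey level i: `n_i` = number of in-mask voxels of level i that have at
#' least one in-mask neighbour, and `s_i` = the summed absolute difference
#' between i and the mean level of each such voxel's in-mask neighbours.
#'
#' @inheritParams glcmMatrices
#' @return data.frame with columns `level`, `n`, `s` for levels 1..Ng.
#' @export
ngtdmVector <- function(roi, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  P <- .pad_levels(roi@levels)
  d <- dim(P)
  inm <- which(!is.na(P))
  ssum <- numeric(length(inm)); cnt <- numeric(length(inm))
  for (o in .lin_offsets(d, mode)) {
    nb <- P[inm + o]
    ok <- !is.na(nb)
    ssum[ok] <- ssum[ok] + nb[ok]
    cnt <- cnt + ok
  }
  valid <- cnt > 0
  g <- P[inm]
  absdiff <- abs(g[valid] - ssum[valid] / cnt[valid])
  Ng <- roi@Ng
  n_i <- tabulate(g[valid], nbins = Ng)
  s_i <- vapply(seq_len(Ng), function(i) sum(absdiff[g[valid] == i]), 0)
  data.frame(level = seq_len(Ng), n = n_i, s = s_i)
}
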