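#' Number of 3D Zernike invariants up to a given order
#'
#' Counts the (n, l) index pairs with `0 <= l <= n`, `n - l` even and
#' `n <= order`.  One rotation invariant `F_nl` exists per pair, so this is
#' the length of the descriptor vector.  At the default order 15 the
#' descriptor has 72 components.
#'
#' @param order Maximum expansion order `n` (nonnegative integer).
#' @return Integer count of (n, l) pairs.
#' @examples
#' descriptor_length(15)  # 72
#' @export
descriptor_length <- function(order) {
  if (!is.numeric(order) || length(order) != 1L || is.na(order) ||
      order != floor(order) || order < 0) {
    stop("`order` must be a single nonnegative integer")
  }
  as.integer(sum(floor(0:order / 2) + 1L))
}

#' Construct a cubic voxel grid
#'
#' @param values Numeric 3D array, cubic.
#' @param spacing Physical edge length of one voxel (Angstrom).
#' @param origin Physical coordinates of the grid corner (length 3).
#' @return A `voxel_grid` object.
#' @export
voxel_grid <- function(values, spacing = 1, origin = c(0, 0, 0)) {
  d <- dim(values)
  if (length(d) != 3L || length(unique(d)) != 1L) {
    stop("`values` must be a cubic 3D array")
  }
  if (!all(is.finite(values))) stop("voxel values must all be finite")
  structure(list(dim = d[1L], spacing = spacing, origin = origin,
                 values = values),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d^3, spacing %.3g, %d nonzero voxels>\n",
              x$dim, x$spacing, sum(x$values != 0)))
  invisible(x)
}

# Voxel-center coordinates along one axis in unit-ball units: the grid cube
# spans [-1, 1] on every axis.
.grid_axis <- function(dim) {
  (seq_len(dim) - (dim + 1) / 2) * (2 / dim)
}

#' Map weighted points onto a cubic grid normalized to the unit ball
#'
#' Centers the grid on the point centroid and scales coordinates so the
#' farthest point sits at radius `ball_fill` (default 0.7, keeping mass away
#' from the numerically unstable rim of the unit ball).  Each point is
#' assigned to its nearest voxel; when several points share a voxel their
#' values are averaged, which removes any dependence on point order.
#'
#' With the default `sigma = 0` each point is assigned to its nearest voxel
#' and co-located point values are averaged.  With `sigma > 0` (Angstrom)
#' every point is splatted as a Gaussian footprint and the grid carries the
#' value-weighted surface density `f(x) = sum_p v_p exp(-|x - x_p|^2 /
#' (2 sigma^2))`; this smooth representation is far more stable under small
#' coordinate perturbations than single-voxel marking, which matters when
#' descriptors of noisy copies of one patch are compared.
#'
#' An explicit `center` and `scale_radius` pin the grid frame to an
#' external anchor (e.g. a ligand atom) and a fixed physical radius, so
#' that all channels and all perturbed copies of a patch share one frame.
#'
#' @param points Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param values Scalar per point (default 1, the shape channel).
#' @param dim Voxels per axis (cubic grid), at least 8.
#' @param ball_fill Radius of the farthest point after scaling, in (0, 1].
#' @param sigma Gaussian footprint width in Angstrom (0 = nearest-voxel
#'   marking).
#' @param center Optional fixed grid center (length 3, Angstrom); default
#'   is the point centroid.
#' @param scale_radius Optional fixed physical radius mapped to
#'   `ball_fill`; default is the farthest point distance.  Points outside
#'   it are dropped.
#' @return A `voxel_grid` whose nonzero voxels all lie inside the unit ball.
#' @export
voxelize_points <- function(points, values = NULL, dim = 64L,
                            ball_fill = 0.7, sigma = 0, center = NULL,
                            scale_radius = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("at least one point is required")
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (dim < 8L) stop("`dim` must be at least 8")
  if (ball_fill <= 0 || ball_fill > 1) stop("`ball_fill` must be in (0, 1]")
  if (is.null(values)) values <- rep(1, nrow(points))
  if (length(values) != nrow(points)) {
    stop("`values` must have one entry per point")
  }
  ctr <- if (is.null(center)) colMeans(points) else as.numeric(center)
  centered <- sweep(points, 2L, ctr)
  rmax <- if (is.null(scale_radius)) {
    sqrt(max(rowSums(centered^2)))
  } else {
    keep <- rowSums(centered^2) <= scale_radius^2
    centered <- centered[keep, , drop = FALSE]
    values <- values[keep]
    if (nrow(centered) == 0L) stop("no points inside `scale_radius`")
    scale_radius
  }
  scale <- if (rmax > 0) ball_fill / rmax else 1
  unit <- centered * scale
  vals <- array(0, dim = rep(dim, 3L))
  if (sigma <= 0) {
    # nearest voxel: coordinate u maps to index round((u + 1) * dim/2 + 0.5)
    idx <- round((unit + 1) * dim / 2 + 0.5)
    idx[idx < 1L] <- 1L
    idx[idx > dim] <- dim
    lin <- (idx[, 3L] - 1L) * dim * dim + (idx[, 2L] - 1L) * dim + idx[, 1L]
    sums <- rowsum(values, lin)
    cnts <- rowsum(rep(1, length(lin)), lin)
    vals[as.integer(rownames(sums))] <- sums / cnts
  } else {
    # deposit values on nearest voxels, then smooth with a separable
    # Gaussian kernel of width sigma: f approximates
    # sum_p v_p exp(-|x - x_p|^2 / (2 sigma^2)) up to half-voxel binning
    ax <- .grid_axis(dim)
    sg <- max(sigma * scale, 1.2 * (2 / dim))  # at least ~1 voxel wide
    idx <- round((unit + 1) * dim / 2 + 0.5)
    idx[idx < 1L] <- 1L
    idx[idx > dim] <- dim
    lin <- (idx[, 3L] - 1L) * dim * dim + (idx[, 2L] - 1L) * dim + idx[, 1L]
    sums <- rowsum(values, lin)
    vals[as.integer(rownames(sums))] <- sums
    kr <- ceiling(3 * sg / (2 / dim))
    kern <- exp(-((-kr:kr) * (2 / dim))^2 / (2 * sg^2))
    K <- matrix(0, dim, dim)
    for (o in -kr:kr) {
      rows <- seq_len(dim)
      cols <- rows + o
      ok <- cols >= 1L & cols <= dim
      K[cbind(rows[ok], cols[ok])] <- kern[o + kr + 1L]
    }
    conv_axis <- function(a) {
      # convolve along the first axis, then rotate axes forward
      out <- array(K %*% matrix(a, nrow = dim), dim = rep(dim, 3L))
      aperm(out, c(2L, 3L, 1L))
    }
    vals <- conv_axis(conv_axis(conv_axis(vals)))
    # spherical support mask keeps Gaussian tails inside the unit ball;
    # the mask is rotation-invariant so invariance is preserved
    r2 <- array(outer(outer(ax^2, ax^2, "+"), ax^2, "+"), dim = rep(dim, 3L))
    vals[r2 > (1 - 1 / dim)^2] <- 0
  }
  voxel_grid(vals, spacing = (2 / dim) / scale, origin = ctr - (1 / scale))
}

# check that every nonzero voxel of a unit-normalized grid lies inside the
# unit ball (with half-voxel slack for the voxel footprint)
.check_unit_ball <- function(grid) {
  ax <- .grid_axis(grid$dim)
  nz <- which(grid$values != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(invisible(TRUE))
  r2 <- ax[nz[, 1L]]^2 + ax[nz[, 2L]]^2 + ax[nz[, 3L]]^2
  lim <- (1 + 1 / grid$dim)^2
  if (any(r2 > lim)) {
    stop("grid is not normalized: nonzero voxels lie outside the unit ball")
  }
  invisible(TRUE)
}

# Geometric moments M_abc = sum_v f(v) u^a v^b w^c dV for all a+b+c <= order,
# computed by successive tensor contractions along each axis.
.geometric_moments <- function(grid, order) {
  d <- grid$dim
  ax <- .grid_axis(d)
  k <- order + 1L
  P <- outer(ax, 0:order, "^")                       # d x k
  f <- grid$values
  # contract x: A[a, y, z]
  A <- array(crossprod(P, matrix(f, nrow = d)), dim = c(k, d, d))
  # contract y: B[a, c?, ...] -- permute y forward, multiply, permute back
  A <- aperm(A, c(2L, 1L, 3L))                       # [y, a, z]
  B <- array(crossprod(P, matrix(A, nrow = d)), dim = c(k, k, d))  # [b, a, z]
  B <- aperm(B, c(3L, 2L, 1L))                       # [z, a, b]
  M <- array(crossprod(P, matrix(B, nrow = d)), dim = c(k, k, k))  # [c, a, b]
  aperm(M, c(2L, 3L, 1L)) * (2 / d)^3
}

#' 3D Zernike moments of a unit-ball-normalized voxel grid
#'
#' Computes `Omega_nlm = (3 / 4 pi) * Int_{|x| <= 1} f(x) conj(Z_nlm(x)) dx`
#' as a voxel sum, going through geometric moments and the monomial
#' expansion of the Zernike-Canterakis basis.  Moments for negative `m` are
#' filled in through the conjugate symmetry
#' `Omega_{n,l,-m} = (-1)^m * conj(Omega_{n,l,m})`.
#'
#' @param grid A `voxel_grid` normalized to the unit ball
#'   (see [voxelize_points()]).
#' @param order Maximum expansion order, at most 20.
#' @return A `zernike_moments` object: a data frame of (n, l, m) triples with
#'   complex moment values, plus the order as an attribute.
#' @export
zernike_moments <- function(grid, order = 15L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (order > 20L) stop("orders above 20 are not supported")
  .check_unit_ball(grid)
  M <- .geometric_moments(grid, order)
  op <- .zernike_operator(order)
  om_pos <- as.vector(op$C %*% as.vector(M))
  tri <- op$triples
  # fill m < 0 through conjugate symmetry
  neg <- tri[, "m"] > 0L
  n <- c(tri[, "n"], tri[neg, "n"])
  l <- c(tri[, "l"], tri[neg, "l"])
  m <- c(tri[, "m"], -tri[neg, "m"])
  om <- c(om_pos, (-1)^tri[neg, "m"] * Conj(om_pos[neg]))
  ord <- order(n, l, m)
  out <- data.frame(n = n[ord], l = l[ord], m = m[ord])
  out$omega <- om[ord]
  structure(out, order = order, class = c("zernike_moments", "data.frame"))
}

#' Rotation-invariant 3D Zernike descriptor from moments
#'
#' Collapses the moments to the invariants
#' `F_nl = sqrt( sum_{m=-l..l} |Omega_nlm|^2 )`, one per valid (n, l) pair in
#' fixed (n ascending, l ascending) order.  Taking the norm over `m` is what
#' removes the orientation dependence.
#'
#' @param moments A `zernike_moments` object.
#' @return A `zernike_descriptor`: numeric vector of length
#'   `descriptor_length(order)` with the order stored as an attribute.
#' @export
zernike_invariants <- function(moments) {
  stopifnot(inherits(moments, "zernike_moments"))
  ord <- attr(moments, "order")
  pairs <- .nl_pairs(ord)
  vals <- numeric(nrow(pairs))
  key <- paste(moments$n, moments$l)
  mag2 <- Mod(moments$omega)^2
  agg <- rowsum(mag2, key)
  vals <- sqrt(agg[paste(pairs[, "n"], pairs[, "l"]), 1L])
  names(vals) <- paste0("F", pairs[, "n"], ".", pairs[, "l"])
  structure(vals, order = ord, class = "zernike_descriptor")
}

#' @export
print.zernike_descriptor <- function(x, ...) {
  cat(sprintf("<zernike_descriptor order %d, length %d>\n",
              attr(x, "order"), length(x)))
  print(unclass(x)[seq_len(min(8L, length(x)))])
  invisible(x)
}

#' Compute a 3D Zernike descriptor directly from a voxel grid
#'
#' Convenience wrapper chaining [zernike_moments()] and
#' [zernike_invariants()].
#'
#' @inheritParams zernike_moments
#' @return A `zernike_descriptor`.
#' @export
zernike_descriptor <- function(grid, order = 15L) {
  zernike_invariants(zernike_moments(grid, order))
}

#' Write descriptors to a file
#'
#' One descriptor per row.  The text format stores doubles with 17
#' significant digits, which round-trips IEEE doubles bit-exactly; the
#' binary format stores raw doubles.  A header records the expansion order
#' and the channel labels.
#'
#' @param x Numeric matrix (rows = descriptors) or a single descriptor.
#' @param path Output file.
#' @param order Expansion order recorded in the header.
#' @param channels Character vector of row labels (recycled).
#' @param format `"text"` or `"binary"`.
#' @export
write_descriptors <- function(x, path, order = 15L, channels = "shape",
                              format = c("text", "binary")) {
  format <- match.arg(format)
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
  channels <- rep_len(channels, nrow(x))
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# zernike descriptors v1"), con)
    writeLines(sprintf("# order: %d", order), con)
    writeLines(sprintf("# length: %d", ncol(x)), con)
    for (i in seq_len(nrow(x))) {
      writeLines(paste(c(channels[i], sprintf("%.17g", x[i, ])),
                       collapse = "\t"), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(as.integer(order), nrow(x), ncol(x)), con, size = 4L)
    writeBin(paste(channels, collapse = ","), con)
    writeBin(as.numeric(t(x)), con, size = 8L)
  }
  invisible(path)
}

#' Read descriptors written by [write_descriptors()]
#'
#' @param path Input file.
#' @param format `"text"` or `"binary"`.
#' @return Numeric matrix with `order` attribute and channel row names.
#' @export
read_descriptors <- function(path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path)
    hdr <- grepl("^#", lines)
    ord <- as.integer(sub("# order: ", "", lines[hdr][2L]))
    body <- lines[!hdr]
    parts <- strsplit(body, "\t", fixed = TRUE)
    channels <- vapply(parts, `[[`, "", 1L)
    vals <- t(vapply(parts, function(p) as.numeric(p[-1L]),
                     numeric(length(parts[[1L]]) - 1L)))
    rownames(vals) <- channels
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, integer(), n = 3L, size = 4L)
    ord <- hdr[1L]
    channels <- strsplit(readBin(con, character()), ",", fixed = TRUE)[[1L]]
    vals <- matrix(readBin(con, numeric(), n = hdr[2L] * hdr[3L], size = 8L),
                   nrow = hdr[2L], byrow = TRUE)
    rownames(vals) <- channels
  }
  attr(vals, "order") <- ord
  vals
}
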