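#' Fit a batch self-organizing map on a hexagonal lattice
#'
#' Trains a self-organizing map over gene expression profiles using the
#' batch algorithm: each epoch assigns every profile to its best-matching
#' unit (BMU, the codebook vector nearest in Euclidean distance) and then
#' replaces each codebook by the neighborhood-weighted mean of all
#' profiles, with a Gaussian neighborhood kernel on the hexagonal lattice
#' whose radius decays linearly from `max(grid)/2` to 0.5 over the epochs.
#' Codebooks are initialized on the plane spanned by the first two
#' principal components of the data, laid out along the lattice
#' coordinates, which makes training deterministic given the data (no RNG
#' is consumed).
#'
#' @param x numeric matrix, observations (genes) x variables (time
#'   points). Typically the `normalized` slot of a `profile_matrix`.
#' @param grid integer vector `c(rows, cols)` of the hexagonal lattice;
#'   the default 26 x 17 gives 442 units.
#' @param epochs number of batch epochs.
#' @return An object of class `som_map`: list with `codebook` (units x
#'   variables), `grid`, `grid_coords` (unit positions in the plane),
#'   `bmu` (named unit index per observation), `qerror` (mean distance of
#'   each observation to its BMU, per epoch, measured before each update),
#'   and `data_colnames`.
#' @export
som_map <- function(x, grid = c(26, 17), epochs = 40) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty input")
  if (any(!is.finite(x))) stop("input contains non-finite values")
  n_units <- prod(grid)
  if (nrow(x) < n_units)
    warning("fewer observations than SOM units; map will be sparse")

  coords <- hex_coords(grid[1], grid[2])
  ud <- as.matrix(stats::dist(coords))          # unit-unit lattice distances

  # PCA initialization: codebooks span the first two principal components
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(min(2, ncol(pc$rotation))), drop = FALSE]
  # fix eigenvector sign for cross-run stability
  for (j in seq_len(ncol(rot)))
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  sdev <- pc$sdev[seq_len(ncol(rot))]
  u <- scale(coords)            # lattice coordinates, standardized
  codebook <- matrix(rep(colMeans(x), each = n_units), n_units)
  for (j in seq_len(ncol(rot)))
    codebook <- codebook + (u[, j] * 2 * sdev[j]) %*% t(rot[, j])

  sigma <- seq(max(grid) / 2, 0.5, length.out = epochs)
  qerr <- numeric(epochs)
  bmu <- integer(nrow(x))
  x_sq <- rowSums(x^2)
  for (e in seq_len(epochs)) {
    d2 <- outer(x_sq, rowSums(codebook^2), `+`) - 2 * x %*% t(codebook)
    bmu <- max.col(-d2, ties.method = "first")
    qerr[e] <- mean(sqrt(pmax(d2[cbind(seq_len(nrow(x)), bmu)], 0)))
    h <- exp(-ud^2 / (2 * sigma[e]^2))          # units x units
    cnt <- tabulate(bmu, n_units)
    sums <- rowsum_safe(x, bmu, n_units)
    denom <- as.vector(h %*% cnt)
    num <- h %*% sums
    upd <- denom > 1e-12
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }
  d2 <- outer(x_sq, rowSums(codebook^2), `+`) - 2 * x %*% t(codebook)
  bmu <- max.col(-d2, ties.method = "first")
  structure(list(codebook = codebook, grid = grid, grid_coords = coords,
                 bmu = stats::setNames(bmu, rownames(x)), qerror = qerr,
                 data_colnames = colnames(x)),
            class = "som_map")
}

# planar coordinates of an r x c hexagonal lattice (odd rows offset)
hex_coords <- function(rows, cols) {
  g <- expand.grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  cbind(x = g$col + 0.5 * (g$row %% 2), y = g$row * sqrt(3) / 2)
}

# rowsum that always returns one row per group 1..n_groups
rowsum_safe <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  s <- rowsum(x, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

#' @export
print.som_map <- function(x, ...) {
  cat(sprintf("som_map: %d x %d hexagonal grid (%d units), %d profiles\n",
              x$grid[1], x$grid[2], prod(x$grid), length(x$bmu)))
  cat(sprintf("  final quantization error: %.4f after %d epochs\n",
              x$qerror[length(x$qerror)], length(x$qerror)))
  invisible(x)
}

#' @export
summary.som_map <- function(object, ...) {
  occ <- tabulate(object$bmu, prod(object$grid))
  structure(list(grid = object$grid, n_profiles = length(object$bmu),
                 occupied_units = sum(occ > 0), max_unit_load = max(occ),
                 qerror = object$qerror),
            class = "summary.som_map")
}

#' @export
print.summary.som_map <- function(x, ...) {
  cat(sprintf("SOM %d x %d: %d profiles, %d/%d units occupied (max load %d)\n",
              x$grid[1], x$grid[2], x$n_profiles, x$occupied_units,
              prod(x$grid), x$max_unit_load))
  cat(sprintf("  quantization error: %.4f -> %.4f\n",
              x$qerror[1], x$qerror[length(x$qerror)]))
  invisible(x)
}

#' Map new profiles to their best-matching units
#'
#' @param object a fitted [som_map()].
#' @param newdata matrix of profiles with the same variables as the
#'   training data.
#' @param ... unused.
#' @return Integer vector of unit indices (named by rownames of
#'   `newdata`).
#' @export
predict.som_map <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$codebook))
    stop("newdata has the wrong number of variables")
  d2 <- outer(rowSums(newdata^2), rowSums(object$codebook^2), `+`) -
    2 * newdata %*% t(object$codebook)
  stats::setNames(max.col(-d2, ties.method = "first"), rownames(newdata))
}

#' Plot SOM training diagnostics
#'
#' Left panel: quantization error per batch epoch. Right panel: unit
#' occupancy (profiles per unit) on the hexagonal lattice.
#'
#' @param x a [som_map()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.som_map <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$qerror), x$qerror, type = "b", pch = 16,
                 xlab = "epoch", ylab = "quantization error",
                 main = "SOM training", ...)
  occ <- tabulate(x$bmu, prod(x$grid))
  graphics::plot(x$grid_coords, asp = 1, pch = 16,
                 cex = 0.4 + 1.6 * occ / max(occ, 1),
                 col = grDevices::gray(1 - occ / max(occ, 1)),
                 xlab = "", ylab = "", main = "unit occupancy")
  invisible(x)
}
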