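#' Build a knot grid over a rectangular spatial domain
#'
#' Knots are the support points of the latent Gaussian fields; every haul is
#' mapped to its nearest knot, so fields are piecewise constant at the knot
#' resolution. `layout = "regular"` places knots at the cell centres of an
#' `nx` x `ny` partition with `nx * ny == n_knots` (the factorization chosen
#' to best match the domain's aspect ratio), each knot representing its cell
#' area. `layout = "random"` draws knot locations uniformly and approximates
#' the represented (Voronoi) areas by nearest-knot assignment of a fine
#' regular lattice.
#'
#' @param n_knots Number of knots, `>= 4`.
#' @param extent Bounding box `c(xmin, xmax, ymin, ymax)` in planar km.
#' @param layout `"regular"` (default) or `"random"`.
#' @param seed Integer seed (random layout only).
#' @return Data frame of class `sdfa_knots` with columns `knot_id` (0-based,
#'   contiguous), `x_km`, `y_km`, `area_km2`; areas sum to the extent area.
#' @export
make_knot_grid <- function(n_knots, extent, layout = c("regular", "random"),
                           seed = NULL) {
  layout <- match.arg(layout)
  stopifnot(n_knots >= 4, length(extent) == 4, all(is.finite(extent)))
  wx <- extent[2] - extent[1]
  wy <- extent[4] - extent[3]
  if (wx <= 0 || wy <= 0) stop("degenerate extent: requires xmax > xmin and ymax > ymin")
  total_area <- wx * wy

  if (layout == "regular") {
    divs <- which(n_knots %% seq_len(n_knots) == 0)
    nx <- divs[which.min(abs(log((divs^2 / n_knots) / (wx / wy))))]
    ny <- n_knots / nx
    xs <- extent[1] + (seq_len(nx) - 0.5) * wx / nx
    ys <- extent[3] + (seq_len(ny) - 0.5) * wy / ny
    g <- expand.grid(x_km = xs, y_km = ys)
    out <- data.frame(knot_id = seq_len(nrow(g)) - 1L,
                      x_km = g$x_km, y_km = g$y_km,
                      area_km2 = total_area / n_knots)
  } else {
    if (!is.null(seed)) set.seed(seed)
    x <- runif(n_knots, extent[1], extent[2])
    y <- runif(n_knots, extent[3], extent[4])
    # Voronoi areas approximated on a ~120x120 lattice
    m <- 120
    lx <- extent[1] + (seq_len(m) - 0.5) * wx / m
    ly <- extent[3] + (seq_len(m) - 0.5) * wy / m
    lat <- expand.grid(x = lx, y = ly)
    nn <- nearest_knot(lat$x, lat$y, x, y)
    counts <- tabulate(nn, nbins = n_knots)
    out <- data.frame(knot_id = seq_len(n_knots) - 1L, x_km = x, y_km = y,
                      area_km2 = total_area * counts / length(nn))
  }
  class(out) <- c("sdfa_knots", "data.frame")
  out
}

# Index (1-based) of the nearest knot for each point.
nearest_knot <- function(px, py, kx, ky) {
  vapply(seq_along(px), function(i) {
    which.min((kx - px[i])^2 + (ky - py[i])^2)
  }, integer(1))
}

#' @export
print.sdfa_knots <- function(x, ...) {
  cat(sprintf("Knot grid: %d knots, total area %.1f km^2\n",
              nrow(x), sum(x$area_km2)))
  NextMethod()
}
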