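#' Discretize the reference membrane sphere along a meridian
#'
#' Builds the axisymmetric discretization of the undeformed plasma membrane,
#' a sphere of radius `r0`. Nodes are polar angles `theta` on `[0, pi]`
#' (`theta = pi` is the pole facing the slide); each node carries the exact
#' area of the spherical zone between the midpoints to its neighbours, so the
#' weights always sum to the full sphere area `4*pi*r0^2` regardless of the
#' number of nodes.
#'
#' @param r0 Cell radius in micrometres.
#' @param n_nodes Number of meridian nodes (at least 3).
#' @return An object of class `"sphere_mesh"`: a list with `r0`, `theta`
#'   (increasing node angles), `weights` (reference area per node, µm²),
#'   `elements` (two-column matrix of adjacent-node segments), `n`, and the
#'   total reference `area`.
#' @examples
#' mesh <- build_meridian_mesh(10, 200)
#' sum(mesh$weights)  # 4 * pi * 100 = 1256.64 µm²
#' @export
build_meridian_mesh <- function(r0, n_nodes) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("`r0` must be a single positive length [µm]", call. = FALSE)
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 3)
    stop("`n_nodes` must be at least 3", call. = FALSE)
  n <- as.integer(n_nodes)
  theta <- seq(0, pi, length.out = n)
  # Voronoi interval boundaries on the meridian
  mid <- c(0, (theta[-n] + theta[-1]) / 2, pi)
  # spherical zone area between consecutive boundaries: 2 pi r0^2 (cos a - cos b)
  weights <- 2 * pi * r0^2 * (cos(mid[-(n + 1L)]) - cos(mid[-1L]))
  structure(
    list(r0 = r0, theta = theta, weights = weights,
         elements = cbind(seq_len(n - 1L), seq.int(2L, n)),
         n = n, area = 4 * pi * r0^2),
    class = "sphere_mesh")
}

#' @export
print.sphere_mesh <- function(x, ...) {
  cat("Reference sphere mesh: r0 =", x$r0, "µm,", x$n, "meridian nodes\n")
  cat("  total reference area", format(sum(x$weights), digits = 10), "µm²\n")
  invisible(x)
}
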