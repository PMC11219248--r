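# Sub-vertex landmark refinement.  A raw extreme-vertex detection on a
# jittered surface is biased outward (the argmax selects favourable noise);
# fitting a quadratic height field over the local vertex patch and taking
# its stationary point averages the noise away and restores the smooth
# surface's tangent point.  On noise-free surfaces the fit reproduces the
# analytic extremum to second order.

#' Refine a detected extreme landmark by local quadric fit
#'
#' Around a detected extreme vertex, vertices within `radius` are expressed
#' in a local frame (height along the detection direction, two transverse
#' coordinates); a full quadratic is least-squares fitted to the height and
#' its stationary point is returned as the refined landmark.  Falls back to
#' the input vertex when the patch is too small, the fit is not concave, or
#' the stationary point leaves the patch.
#'
#' @param mesh A [femur_mesh()].
#' @param point Detected extreme vertex (length-3, mm).
#' @param direction Outward detection direction (unit): the landmark
#'   maximizes the projection onto it.
#' @param radius Patch radius in mm (default 3).  Choose it of the order of
#'   the noise-competition length `sqrt(2 * R * sigma)` for local curvature
#'   radius `R`: small for sharp prominences, larger for flat extremes.
#' @param passes Number of fit passes (default 2); after each pass the patch
#'   is re-centred on the fitted extremum, which recovers extrema that the
#'   noisy argmax placed near the patch boundary.
#' @return Refined landmark position (length-3, mm).
#' @export
refine_landmark <- function(mesh, point, direction, radius = 3, passes = 2) {
  d <- unitize(direction)
  e1 <- unitize(if (abs(d[1]) < 0.9) cross3(d, c(1, 0, 0)) else cross3(d, c(0, 1, 0)))
  e2 <- cross3(d, e1)
  v <- mesh$vertices
  centre <- point
  for (p in seq_len(passes)) {
    rel <- sweep(v, 2, centre)
    sel <- rowSums(rel^2) <= radius^2
    if (sum(sel) < 8L) return(centre)
    rel <- rel[sel, , drop = FALSE]
    xi <- as.numeric(rel %*% e1)
    eta <- as.numeric(rel %*% e2)
    h <- as.numeric(rel %*% d)
    X <- cbind(1, xi, eta, xi^2, xi * eta, eta^2)
    beta <- tryCatch(qr.solve(X, h), error = function(e) NULL)
    if (is.null(beta)) return(centre)
    hess <- matrix(c(2 * beta[4], beta[5], beta[5], 2 * beta[6]), 2)
    ev <- eigen(hess, symmetric = TRUE, only.values = TRUE)$values
    if (max(ev) >= -1e-9) return(centre)  # not a strict maximum
    st <- -solve(hess, c(beta[2], beta[3]))
    if (sqrt(sum(st^2)) > radius) return(centre)
    h_st <- sum(beta * c(1, st[1], st[2], st[1]^2, st[1] * st[2], st[2]^2))
    centre <- centre + st[1] * e1 + st[2] * e2 + h_st * d
  }
  centre
}
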