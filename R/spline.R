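# Low-rank radial (thin-plate-style) spline basis over day of the year.
#
# The seasonal transition trend f(day) = sum_k b_k Z[day, k] is given a
# random-effects interpretation: with Z = |day - knot|^3 post-multiplied by
# Omega^{-1/2} (Omega[k,l] = |knot_k - knot_l|^3, square root via SVD),
# iid-normal coefficients b ~ N(0, sigma) induce the usual penalized-spline
# prior. Columns are additionally rescaled to unit sample SD so sigma's prior
# lives on a sane scale; the curve family is unchanged.

#' Equally spaced spline knots
#'
#' @param K Number of knots (>= 2).
#' @param lo,hi Interval endpoints (`lo < hi`), both included as knots.
#' @return Numeric vector of `K` equally spaced knots.
#' @examples
#' make_knots(5, 1, 365)   # 1, 92, 183, 274, 365
#' @export
make_knots <- function(K, lo = 1, hi = 365) {
  if (K < 2L) stop("need at least 2 knots")
  if (!(lo < hi)) stop("lo must be < hi")
  seq(lo, hi, length.out = K)
}

#' Build the seasonal spline basis
#'
#' @param knots Strictly increasing knot vector (see [make_knots()]).
#' @param days Day grid the basis is evaluated on (default 1..365).
#' @param type `"radial"` (default) for the low-rank radial construction, or
#'   `"bspline"` for a cubic B-spline basis with iid-normal coefficients; all
#'   downstream code is basis-agnostic.
#' @param scale_columns Center columns and rescale them to unit sample SD
#'   (default TRUE). This changes only the parameterization, not the family
#'   of seasonal curves: the column means move into the intercept, and the
#'   coefficient SD prior then acts on a common scale.
#' @return A `spline_basis`: list with `knots`, `Z` (days x K matrix), `days`,
#'   `scale` (per-column divisors), `sqrt_omega` (radial only, for round
#'   trips) and `formulation_tag`.
#' @export
build_basis <- function(knots, days = 1:365,
                        type = c("radial", "bspline"), scale_columns = TRUE) {
  type <- match.arg(type)
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  K <- length(knots)
  if (type == "radial") {
    Z_raw <- abs(outer(days, knots, "-"))^3
    Omega <- abs(outer(knots, knots, "-"))^3
    sv <- svd(Omega)
    if (min(sv$d) < max(sv$d) * 1e-12)
      stop("knot cross-distance matrix is numerically singular")
    inv_sqrt <- sv$v %*% (t(sv$u) / sqrt(sv$d))
    sqrt_omega <- sv$u %*% (t(sv$v) * sqrt(sv$d))
    Z <- Z_raw %*% inv_sqrt
    tag <- "lowrank_radial_svd"
  } else {
    Z <- splines::bs(days, knots = knots[-c(1L, K)],
                     Boundary.knots = knots[c(1L, K)], intercept = FALSE)
    Z <- unclass(Z)[, , drop = FALSE]
    sqrt_omega <- NULL
    tag <- "cubic_bspline"
  }
  scl <- rep(1, ncol(Z))
  ctr <- rep(0, ncol(Z))
  if (scale_columns) {
    ctr <- colMeans(Z)
    scl <- apply(Z, 2, stats::sd)
    if (any(scl == 0)) stop("constant basis column; bad knot placement")
    Z <- sweep(sweep(Z, 2, ctr, "-"), 2, scl, "/")
    tag <- paste0(tag, "_centered_unitsd")
  }
  dimnames(Z) <- NULL
  structure(list(knots = knots, Z = Z, days = as.integer(days), scale = scl,
                 center = ctr, sqrt_omega = sqrt_omega, formulation_tag = tag),
            class = "spline_basis")
}

#' Evaluate the seasonal effect f(day) = sum_k b_k Z[day, k]
#'
#' @param day Integer day(s) within the basis grid (1..365 by default).
#' @param b Coefficient vector of length `ncol(basis$Z)`.
#' @param basis A `spline_basis`.
#' @return Numeric vector, one value per `day`.
#' @export
seasonal_effect <- function(day, b, basis) {
  idx <- match(day, basis$days)
  if (anyNA(idx)) stop("day out of basis range")
  if (length(b) != ncol(basis$Z)) stop("coefficient length mismatch")
  drop(basis$Z[idx, , drop = FALSE] %*% b)
}

#' Export a basis as a day-by-knot CSV for inspection
#' @param basis A `spline_basis`.
#' @param path Output path.
#' @export
write_basis <- function(basis, path) {
  tab <- data.frame(day = basis$days, basis$Z)
  names(tab) <- c("day", paste0("Z", seq_len(ncol(basis$Z))))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
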