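# Analytical real-root solvers for the cubic and quartic polynomials arising in
# ray-torus intersection.  All guard constants are artifact choices and are
# documented next to their use; the solvers never touch complex arithmetic.

#' Largest positive real root of a monic cubic
#'
#' Solves \eqn{x^3 + p_2 x^2 + p_1 x + p_0 = 0} by Cardano's method in the
#' trigonometric / real-cube-root form, avoiding complex arithmetic and
#' divisions by quantities that may underflow, and returns the largest real
#' root that is strictly positive (or `NULL` when none exists).  This is the
#' resolvent-cubic step of the quartic solver.
#'
#' @param p2,p1,p0 Real coefficients of the monic cubic.
#' @return The largest positive real root, or `NULL`.
#' @export
#' @examples
#' solve_cubic_largest_positive(-6, 11, -6) # roots 1, 2, 3 -> 3
solve_cubic_largest_positive <- function(p2, p1, p0) {
  if (!all(is.finite(c(p2, p1, p0))))
    stop("cubic coefficients must be finite")
  roots <- .cubic_real_roots(p2, p1, p0)
  pos <- roots[roots > 0]
  if (length(pos) == 0L) return(NULL)
  max(pos)
}

# All real roots of the monic cubic x^3 + p2 x^2 + p1 x + p0, Numerical-Recipes
# style: trigonometric branch for three real roots, real cube roots otherwise.
.cubic_real_roots <- function(p2, p1, p0) {
  Q <- (p2 * p2 - 3 * p1) / 9
  R <- (2 * p2^3 - 9 * p2 * p1 + 27 * p0) / 54
  roots <- if (R * R < Q^3) {
    theta <- acos(max(-1, min(1, R / sqrt(Q^3))))
    -2 * sqrt(Q) * cos((theta + c(0, 2, -2) * pi) / 3) - p2 / 3
  } else {
    A <- -sign(R) * (abs(R) + sqrt(max(0, R * R - Q^3)))^(1 / 3)
    B <- if (A != 0) Q / A else 0
    (A + B) - p2 / 3
  }
  # one Newton step per root guards the acos/cbrt rounding
  for (k in 1:2) {
    f  <- ((roots + p2) * roots + p1) * roots + p0
    df <- (3 * roots + 2 * p2) * roots + p1
    step <- ifelse(df != 0, f / df, 0)
    roots <- roots - ifelse(abs(step) < 1 + abs(roots), step, 0)
  }
  sort(roots)
}

#' Construct a monic quartic
#'
#' Container for \eqn{x^4 + b x^3 + c x^2 + d x + e}; the discriminant is
#' derived on construction.
#'
#' @param b,c,d,e Real coefficients.
#' @return An object of class `quartic`.
#' @export
quartic <- function(b, c, d, e) {
  if (!all(is.finite(c(b, c, d, e))))
    stop("quartic coefficients must be finite")
  structure(list(b = b, c = c, d = d, e = e,
                 discriminant = .quartic_discriminant(b, c, d, e)),
            class = "quartic")
}

.quartic_discriminant <- function(b, c, d, e) {
  256 * e^3 - 192 * b * d * e^2 - 128 * c^2 * e^2 + 144 * c * d^2 * e -
    27 * d^4 + 144 * b^2 * c * e^2 - 6 * b^2 * d^2 * e - 80 * b * c^2 * d * e +
    18 * b * c * d^3 + 16 * c^4 * e - 4 * c^3 * d^2 - 27 * b^4 * e^2 +
    18 * b^3 * c * d * e - 4 * b^3 * d^3 - 4 * b^2 * c^3 * e + b^2 * c^2 * d^2
}

#' Real roots of a monic quartic (Ferrari's method)
#'
#' Returns the real roots of \eqn{x^4 + b x^3 + c x^2 + d x + e = 0} in
#' ascending order, 0, 2 or 4 of them counting multiplicity.  The procedure
#' follows Ferrari: depress the quartic, take the largest positive root
#' \eqn{m} of the resolvent cubic via [solve_cubic_largest_positive()], and
#' split into two quadratics.  The sign of the quartic discriminant decides
#' the real-root count and is used to clamp quadratic discriminants that
#' rounding pushed barely negative.  When the quadratic/linear coefficients
#' or the discriminant are exceedingly large (trigger:
#' `max(|c|,|d|,|discriminant|) > 1e8` with `|e| > 1e-300`; the magnitude is
#' an artifact choice) the equation is solved in the rescaled unknown
#' \eqn{\hat x = 4e(x - d)} and mapped back.  A resolvent root with
#' \eqn{|m| \le 10^{-12}\max(1,|p|)} is treated as zero (biquadratic branch).
#' Each root receives two Newton polish steps on the original quartic.
#'
#' @param q A [quartic()] object.
#' @return Numeric vector of real roots, ascending (length 0, 2 or 4).
#' @export
#' @examples
#' solve_quartic(quartic(0, -5, 0, 4)) # (x^2-1)(x^2-4): -2 -1 1 2
solve_quartic <- function(q) {
  stopifnot(inherits(q, "quartic"))
  .solve_quartic(q$b, q$c, q$d, q$e, rescale_ok = TRUE)
}

.solve_quartic <- function(b, c, d, e, rescale_ok = TRUE) {
  disc <- .quartic_discriminant(b, c, d, e)
  plain <- .solve_quartic_plain(b, c, d, e, disc)

  # Rescaled-unknown branch: xhat = 4e(x - d), engaged when the quadratic or
  # linear coefficients or the discriminant are exceedingly large (threshold
  # artifact-defined); the candidate with the smaller polished residual wins,
  # so the rescue can never make a well-conditioned case worse.
  if (rescale_ok && abs(e) > 1e-300 &&
      max(abs(c), abs(d), abs(disc)) > 1e8) {
    s <- 4 * e
    # substitute x = xhat/s + d into the quartic and renormalise to monic
    B <- b + 4 * d
    C <- c + 3 * b * d + 6 * d^2
    D <- d + 2 * c * d + 3 * b * d^2 + 4 * d^3
    E <- e + d * d + c * d^2 + b * d^3 + d^4
    r <- .solve_quartic(B * s, C * s^2, D * s^3, E * s^4, rescale_ok = FALSE)
    resc <- .polish_roots(sort(r / s + d), b, c, d, e)
    if (length(resc) != length(plain))
      return(if (length(resc) > length(plain)) resc else plain)
    if (length(plain) == 0L) return(plain)
    res_of <- function(x)
      max(abs((((x + b) * x + c) * x + d) * x + e) / pmax(1, x^4))
    return(if (res_of(resc) < res_of(plain)) resc else plain)
  }
  plain
}

.solve_quartic_plain <- function(b, c, d, e, disc) {
  # depressed quartic y^4 + p y^2 + qq y + r, x = y - b/4
  p  <- c - 3 * b^2 / 8
  qq <- d - b * c / 2 + b^3 / 8
  r  <- e - b * d / 4 + b^2 * c / 16 - 3 * b^4 / 256

  roots_y <- if (abs(qq) < 1e-13 * max(1, abs(p), abs(r))) {
    .biquadratic_roots(p, r)
  } else {
    m <- solve_cubic_largest_positive(p, p^2 / 4 - r, -qq^2 / 8)
    if (is.null(m) || m <= 1e-12 * max(1, abs(p))) {
      # "m close to zero": the split degenerates, fall back to biquadratic
      .biquadratic_roots(p, r)
    } else {
      s2 <- sqrt(2 * m)
      t  <- qq / (2 * s2)
      clamp <- disc >= 0   # discriminant sign governs borderline real counts
      y1 <- .quadratic_roots(-s2, p / 2 + m + t, clamp)
      y2 <- .quadratic_roots(s2, p / 2 + m - t, clamp)
      c(y1, y2)
    }
  }
  if (length(roots_y) == 0L) return(numeric(0))
  .polish_roots(sort(roots_y - b / 4), b, c, d, e)
}

# real roots of y^2 + B y + C; clamp slightly-negative discriminants when the
# quartic discriminant says a real pair must exist there
.quadratic_roots <- function(B, C, clamp = FALSE) {
  D <- B * B - 4 * C
  if (D < 0) {
    if (clamp && D > -1e-10 * max(1, B * B, abs(C))) D <- 0 else return(numeric(0))
  }
  # stable form: avoid cancellation between -B and sqrt(D)
  sq <- sqrt(D)
  q <- -(B + sign(ifelse(B == 0, 1, B)) * sq) / 2
  if (q == 0) c(-B / 2, -B / 2) else c(q, C / q)
}

.biquadratic_roots <- function(p, r) {
  z <- .quadratic_roots(p, r, clamp = TRUE)
  z <- z[z >= -1e-12 * max(1, abs(p))]
  if (length(z) == 0L) return(numeric(0))
  z[z < 0] <- 0
  unlist(lapply(z, function(v) c(-sqrt(v), sqrt(v))))
}

# Newton polish on the original quartic (up to six steps, each applied only
# if it shrinks the residual, so multiple roots are left untouched)
.polish_roots <- function(x, b, c, d, e) {
  for (k in 1:6) {
    f  <- (((x + b) * x + c) * x + d) * x + e
    df <- ((4 * x + 3 * b) * x + 2 * c) * x + d
    step <- ifelse(df != 0 & is.finite(f / df), f / df, 0)
    x2 <- x - step
    f2 <- (((x2 + b) * x2 + c) * x2 + d) * x2 + e
    x  <- ifelse(abs(f2) <= abs(f), x2, x)
  }
  sort(x)
}

#' Torus geometry
#'
#' A torus with ring (major) radius `R`, tube (minor) radius `r`, arbitrary
#' `center` and unit `axis`.  Spindle tori (`R < r`), which arise as SES
#' patches for close atom pairs, are permitted.
#'
#' @param center Numeric length-3 centre (Angstrom).
#' @param axis Numeric length-3 axis; normalised internally.
#' @param ring_radius,tube_radius Positive radii (Angstrom).
#' @return An object of class `torus`.
#' @export
torus <- function(center, axis, ring_radius, tube_radius) {
  stopifnot(length(center) == 3, length(axis) == 3,
            ring_radius > 0, tube_radius > 0)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("torus axis must be nonzero")
  structure(list(center = as.numeric(center), axis = as.numeric(axis) / n,
                 ring_radius = ring_radius, tube_radius = tube_radius),
            class = "torus")
}

#' Monic quartic of a ray-torus intersection
#'
#' Substitutes the parametric ray \eqn{p(t) = o + t\,\hat d} into the torus
#' implicit equation
#' \eqn{(\|p\|^2 + R^2 - r^2)^2 = 4R^2\|p_\perp\|^2}
#' (coordinates relative to the torus centre, \eqn{p_\perp} the component
#' normal to the axis) and returns the monic [quartic()] in `t`.
#'
#' @param origin Ray origin (length 3).
#' @param direction Unit ray direction (length 3).
#' @param tor A [torus()].
#' @return A [quartic()] object.
#' @export
ray_torus_quartic <- function(origin, direction, tor) {
  stopifnot(inherits(tor, "torus"))
  if (abs(sum(direction^2) - 1) > 1e-9)
    stop("ray direction must be a unit vector")
  o <- as.numeric(origin) - tor$center
  dd <- as.numeric(direction)
  a <- tor$axis
  R2 <- tor$ring_radius^2
  K <- R2 - tor$tube_radius^2
  beta <- 2 * sum(o * dd)
  gam <- sum(o * o)
  da <- sum(dd * a)
  oa <- sum(o * a)
  u <- 2 * K - 4 * R2
  quartic(b = 2 * beta,
          c = beta^2 + 2 * gam + u + 4 * R2 * da^2,
          d = 2 * beta * gam + u * beta + 8 * R2 * da * oa,
          e = gam^2 + u * gam + K * K + 4 * R2 * oa^2)
}

#' Ray-torus intersection parameters
#'
#' Analytical intersection of a ray with a torus: forms the monic quartic via
#' [ray_torus_quartic()] and solves it with [solve_quartic()].  Tangential
#' grazings may come back as a coincident pair of parameters.
#'
#' @inheritParams ray_torus_quartic
#' @return Ascending numeric vector of ray parameters `t` (possibly empty).
#' @export
ray_torus_intersect <- function(origin, direction, tor) {
  solve_quartic(ray_torus_quartic(origin, direction, tor))
}
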