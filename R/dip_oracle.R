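#' Exhaustive small-sample oracle for the dip statistic
#'
#' Independent re-derivation of the dip from first principles, used to
#' validate [dip_statistic()]. A continuous cdf G stays within sup-distance
#' `d` of the empirical cdf iff at every unique sample value `z_i` it passes
#' through the band `[c_i - d, c_(i-1) + d]`, where `c_i` is the empirical
#' cdf at `z_i`. The dip is the smallest `d` for which a *unimodal* G
#' (convex up to its mode, concave after) threads all bands. This routine
#' finds that `d` by bisection, checking feasibility exhaustively over every
#' candidate modal knot: for each knot `j` it tests whether a nondecreasing
#' convex function can thread the bands on knots `1..j` and a nondecreasing
#' concave one the bands on knots `j..k`, with an admissible junction at the
#' mode (a unimodal cdf may jump there, so the left limit need only stay
#' below the post-jump value; each half-problem projects onto an interval of
#' admissible junction values, found by inner bisection).
#'
#' Runs in time exponential-free but heavily iterative; intended for
#' samples of at most a few dozen observations.
#'
#' @param x numeric vector, `length(x) >= 2`, finite.
#' @param tol bisection tolerance on the returned statistic.
#' @return the dip statistic.
#' @export
dip_statistic_exhaustive <- function(x, tol = 1e-14) {
  n <- length(x)
  gd_check(n >= 2, "dip requires n >= 2", class = "gutdrift_underpowered")
  gd_check(all(is.finite(x)), "non-finite values", class = "gutdrift_bad_input")
  x <- sort(x)
  z <- unique(x)
  k <- length(z)
  if (k == 1) return(1 / (2 * n))
  cc <- cumsum(tabulate(match(x, z), k)) / n  # empirical cdf at z
  cp <- c(0, cc[-k])                          # left limits

  lo <- 1 / (2 * n)
  hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.dip_band_feasible(z, cc, cp, mid)) hi <- mid else lo <- mid
  }
  hi
}

# Feasibility of a unimodal G within bands [cc - d, cp + d] at knots z.
# G may carry an atom at its mode (a unimodal cdf is continuous everywhere
# except possibly at the mode): with mode at knot j the left convex part ends
# at the left limit a with |a - cp_j| <= d, the right concave part starts at
# the post-jump value v with |v - cc_j| <= d, and a <= v. The continuous case
# is the sub-case a = v.
.dip_band_feasible <- function(z, cc, cp, d) {
  k <- length(z)
  L <- pmax(0, cc - d)
  U <- pmin(1, cp + d)
  if (any(pmin(1, cc + d) < pmax(0, cp - d))) return(FALSE)
  for (j in seq_len(k)) {
    Lj <- L[seq_len(j)]; Uj <- U[seq_len(j)]
    Lj[j] <- max(0, cp[j] - d); Uj[j] <- min(1, cp[j] + d)
    left <- .convex_interval(z[seq_len(j)], Lj, Uj)
    if (is.null(left)) next
    Lk <- L[j:k]; Uk <- U[j:k]
    Lk[1] <- max(0, cc[j] - d); Uk[1] <- min(1, cc[j] + d)
    right <- .concave_interval(z[j:k], Lk, Uk)
    if (is.null(right)) next
    # need left limit <= post-jump value: min attainable a <= max attainable v
    if (left[1] <= right[2] + 1e-15) return(TRUE)
  }
  FALSE
}

# greatest convex minorant (lower convex hull) of points (z, y)
.gcm <- function(z, y) {
  k <- length(z)
  if (k <= 2) return(y)
  h <- c(1L, 2L)
  for (j in 3:k) {
    while (length(h) >= 2) {
      b <- h[length(h)]; a <- h[length(h) - 1]
      if ((y[b] - y[a]) * (z[j] - z[b]) < (y[j] - y[b]) * (z[b] - z[a])) break
      h <- h[-length(h)]
    }
    h <- c(h, j)
  }
  approx(z[h], y[h], xout = z)$y
}

.lcm <- function(z, y) -.gcm(z, -y)

# interval of values attainable at the LAST knot by a nondecreasing convex
# function threading boxes [L, U]; NULL if infeasible. U, L nondecreasing.
.convex_interval <- function(z, L, U, tol = 1e-15) {
  k <- length(z)
  if (k == 1) return(c(L[1], U[1]))
  feas <- function(a) {
    # pin the last value to a; monotonicity caps earlier values at a
    Ua <- pmin(U, a)
    Ua[k] <- a
    if (a < L[k] - tol) return(FALSE)
    h <- cummax(.gcm(z, Ua))   # maximal nondecreasing convex fit under Ua
    all(h >= L - tol)
  }
  if (!feas(U[k])) return(NULL)     # U[k] is the maximal candidate
  lo <- L[k]; hi <- U[k]
  if (feas(lo)) return(c(lo, hi))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (feas(mid)) hi <- mid else lo <- mid
  }
  c(hi, U[k])
}

# interval attainable at the FIRST knot by a nondecreasing concave function
# threading boxes [L, U]
.concave_interval <- function(z, L, U, tol = 1e-15) {
  k <- length(z)
  if (k == 1) return(c(L[1], U[1]))
  feas <- function(b) {
    La <- pmax(L, b)
    La[1] <- b
    if (b > U[1] + tol) return(FALSE)
    h <- .lcm(z, La)           # least concave majorant of the floor
    h <- pmin(h, h[k])         # minimal nondecreasing concave fit over La
    all(h <= U + tol)
  }
  if (!feas(L[1])) return(NULL)     # L[1] is the minimal candidate
  lo <- L[1]; hi <- U[1]
  if (feas(hi)) return(c(lo, hi))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (feas(mid)) lo <- mid else hi <- mid
  }
  c(L[1], lo)
}
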