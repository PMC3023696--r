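# Small planar-geometry helpers shared by the layout and junction solvers.
# Internal coordinates are y-up mathematical; the SVG writer flips to y-down.

unit_vec <- function(a) c(cos(a), sin(a))
angle_of <- function(v) atan2(v[2], v[1])
rot90 <- function(v) c(-v[2], v[1])                 # counterclockwise
rotate_vec <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                               sin(a) * v[1] + cos(a) * v[2])
vnorm <- function(v) sqrt(sum(v^2))

# normalize angle to (-pi, pi]
ang_norm <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  ifelse(a <= -pi, a + 2 * pi, a)
}

# Intersection points of two circles; NULL when they do not intersect.
circle_intersect <- function(c1, r1, c2, r2) {
  d <- vnorm(c2 - c1)
  if (d > r1 + r2 || d < abs(r1 - r2) || d == 0) return(NULL)
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  h <- sqrt(max(h2, 0))
  m <- c1 + a * (c2 - c1) / d
  perp <- rot90((c2 - c1) / d)
  list(m + h * perp, m - h * perp)
}

# Sweep sign s in {+1,-1} such that from + s*total lands on to (mod 2pi).
choose_sweep <- function(from, to, total, tol = 1e-6) {
  if (abs(ang_norm(from + total - to)) < tol) return(1)
  if (abs(ang_norm(from - total - to)) < tol) return(-1)
  stop("internal geometry error: no sweep direction closes the arc (residual ",
       signif(min(abs(ang_norm(from + total - to)),
                  abs(ang_norm(from - total - to))), 3), ")", call. = FALSE)
}

# Distance from point p to segment a-b.
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(vnorm(p - a))
  t <- max(0, min(1, sum((p - a) * ab) / L2))
  vnorm(p - (a + t * ab))
}
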