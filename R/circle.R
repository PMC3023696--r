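# Circle fitting for loops: constant chord lengths on a common circle.

#' Angle subtended by a chord on a circle
#'
#' The apex angle of the isosceles triangle with sides `r`, `r` and `d`:
#' `2 * asin(d / (2 r))`.
#'
#' @param d Chord length (distance between consecutive or base-paired
#'   nucleotides), `0 < d`.
#' @param r Circle radius.
#' @return Angle in radians. `d > 2 r` is an infeasible radius and signals a
#'   condition of class `infeasible_radius` (used to drive the bisection).
#' @export
step_angle <- function(d, r) {
  if (any(d > 2 * r))
    stop(structure(class = c("infeasible_radius", "error", "condition"),
                   list(message = paste0("chord ", max(d), " exceeds diameter ",
                                         2 * r),
                        call = NULL)))
  2 * asin(d / (2 * r))
}

#' Solve the loop circle radius by binary search
#'
#' Finds the radius `r*` at which the chord step angles sum to the requested
#' total: `2 * pi` for a full loop, `pi` for a bulge or one side of an
#' internal loop. The angle sum decreases monotonically in `r` (smaller
#' radii give sums above the total), so bisection applies: the lower bracket
#' is `max(d)/2`, the upper bracket is doubled until the sum drops below the
#' total.
#'
#' @param chords Numeric vector of chord lengths (at least one).
#' @param total Target angle sum in radians, `2 * pi` or `pi`.
#' @param tol Bisection tolerance on the angle sum (default `1e-9`).
#' @param max_iter Maximum bisection iterations.
#' @return List of class `circle_fit`: `radius`, `angles` (per-chord
#'   subtended angles summing to `total` within `tol`), `total`.
#' @examples
#' solve_loop_radius(rep(1, 6), 2 * pi)$radius  # regular hexagon: 1
#' @export
solve_loop_radius <- function(chords, total = 2 * pi, tol = 1e-9,
                              max_iter = 200L) {
  stopifnot(length(chords) >= 1, all(chords > 0), total > 0)
  f <- function(r) sum(step_angle(chords, r)) - total
  lo <- max(chords) / 2
  if (f(lo) < 0)
    stop("infeasible loop: angle sum at minimum radius is below the target (",
         length(chords), " chord(s), total ", round(total * 180 / pi),
         " degrees)", call. = FALSE)
  hi <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol) break
    if (v > 0) lo <- mid else hi <- mid
  }
  r <- mid
  structure(list(radius = r, angles = step_angle(chords, r), total = total),
            class = "circle_fit")
}
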