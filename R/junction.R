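# Multistem-junction layout as a constrained non-linear program.
#
# The junction's elements (stem closing pairs with user-fixed directions,
# unpaired segments, variable-length regions) should approximately follow a
# circle. Three formulations express "approximately": (1) unpaired
# nucleotides exactly on a common circle, pair chords intersecting it,
# objective = sudden radial changes at paired nucleotides; (2) nothing
# pinned to the main circle, each segment on its own circle, objective =
# radial deviation of sample points from the main circle; (3) like 2 but
# penalizing slope deviations via the cosine between center vectors.
# Problems are solved by SLSQP (sequential quadratic programming) with
# finite-difference gradients and seeded Gaussian restarts.

#' Junction specification
#'
#' Describes one multistem junction in backbone (counterclockwise) order:
#' stem `i` (its closing pair chord) is followed by segment `i`; segment `k`
#' leads back to stem 1, which is conventionally the enclosing stem.
#'
#' @param dirs_deg Outward direction of each stem, degrees (0 = +x,
#'   counterclockwise); at least two stems, user-supplied.
#' @param seg_n Unpaired nucleotide count of each segment (same length as
#'   `dirs_deg`).
#' @param seg_var Number of variable-length regions per segment (default 0).
#' @param d_nt,d_bp Backbone and pair chord lengths.
#' @param seg_kinds Optional explicit item order per segment: list of
#'   character vectors over `"nt"`/`"var"`; overrides `seg_n`/`seg_var`.
#' @param aligns,centroids Alignment constraints; lists of
#'   `list(stems=, angle_deg=)` and `list(group=, target=, angle_deg=)`
#'   where stems are indices into `dirs_deg`.
#' @return Object of class `junction_spec`.
#' @export
junction_spec <- function(dirs_deg, seg_n, seg_var = 0L, d_nt = 1, d_bp = 1.6,
                          seg_kinds = NULL, aligns = list(),
                          centroids = list()) {
  k <- length(dirs_deg)
  if (k < 2) stop("a junction needs at least two stems", call. = FALSE)
  seg_var <- rep_len(seg_var, k)
  seg_n <- rep_len(seg_n, k)
  if (is.null(seg_kinds))
    seg_kinds <- lapply(seq_len(k), function(i)
      c(rep("nt", seg_n[i]), rep("var", seg_var[i])))
  structure(list(k = k, dirs = dirs_deg * pi / 180,
                 seg_kinds = seg_kinds, d_nt = d_nt, d_bp = d_bp,
                 aligns = aligns, centroids = centroids),
            class = "junction_spec")
}

seg_nt_count <- function(kinds) sum(kinds == "nt")
seg_var_count <- function(kinds) sum(kinds == "var")

# chord direction of stem i for a counterclockwise walk
stem_chord_dir <- function(spec, i) rot90(unit_vec(spec$dirs[i]))

# ---- formulation construction ----------------------------------------------

#' Build the junction NLP
#'
#' @param spec A [junction_spec()].
#' @param formulation 1, 2 or 3 (default 2, which usually produces an
#'   acceptable layout).
#' @return Object of class `junction_nlp`: variables with bounds (`x0`,
#'   `lower`, `upper`, `var_names`), `objective(x)`, equality constraints
#'   `heq(x)`, a `decode(x)` closure returning positions, and for
#'   formulations 2/3 the per-segment objective sample counts
#'   (`sample_counts`, N+2+3V per segment).
#' @export
junction_nlp <- function(spec, formulation = 2L) {
  formulation <- as.integer(formulation)
  stopifnot(formulation %in% 1:3)
  if (formulation == 1L) nlp_formulation1(spec)
  else nlp_formulation23(spec, formulation)
}

n_var_regions <- function(spec) sum(vapply(spec$seg_kinds, seg_var_count,
                                           integer(1)))

# one-slot cache: objective, heq and hin all decode the same x per iteration
memoize_decode <- function(f) {
  last_x <- NULL; last_d <- NULL
  function(x) {
    if (!is.null(last_x) && identical(last_x, x)) return(last_d)
    d <- f(x)
    last_x <<- x; last_d <<- d
    d
  }
}

# warm start: plain circular layout ignoring the direction constraints
warm_circle <- function(spec, var_len0) {
  steps <- vapply(spec$seg_kinds, function(kinds)
    seg_nt_count(kinds) + 1 + seg_var_count(kinds) * var_len0 / spec$d_nt,
    numeric(1))
  chords <- c(rep(spec$d_bp, spec$k), rep(spec$d_nt, ceiling(sum(steps))))
  solve_loop_radius(chords, 2 * pi)$radius
}

nlp_formulation1 <- function(spec) {
  k <- spec$k
  V <- n_var_regions(spec)
  var_len0 <- 3 * spec$d_nt
  r0 <- warm_circle(spec, var_len0)
  x0 <- c(r0, spec$dirs[1], rep(0.5, k), rep(var_len0, V))
  lower <- c(max(spec$d_nt, spec$d_bp) / 2 * 1.0001, spec$dirs[1] - 2 * pi,
             rep(0, k), rep(0.5 * spec$d_nt, V))
  upper <- c(r0 * 20, spec$dirs[1] + 2 * pi, rep(1, k),
             rep(10 * spec$d_nt, V))
  var_names <- c("r", "theta0", paste0("t", seq_len(k)),
                 if (V) paste0("L", seq_len(V)))
  decode <- memoize_decode(function(x) decode_formulation1(spec, x))
  env <- new.env(parent = emptyenv())
  env$extra_heq <- list()
  problem <- list(formulation = 1L, spec = spec, x0 = x0, lower = lower,
                  upper = upper, var_names = var_names, env = env)
  problem$decode <- decode
  problem$objective <- function(x) {
    d <- decode(x)
    sum((d$paired_dn - d$paired_da)^2)
  }
  problem$heq <- function(x) {
    d <- decode(x)
    c(d$total_sweep - 2 * pi, d$defects, extra_heq_values(env, d))
  }
  class(problem) <- "junction_nlp"
  problem
}

# Closed-form walk for formulation 1: everything follows from
# (r, theta0, t_i, L_v) by two-circle intersections, so the on-circle and
# chord-intersection constraints hold by construction; what remains is the
# 360-degree closure (plus reach defects when an intersection fails).
decode_formulation1 <- function(spec, x) {
  k <- spec$k
  r <- x[1]; theta0 <- x[2]
  tt <- x[3:(2 + k)]
  Ls <- if (length(x) > 2 + k) x[-(1:(2 + k))] else numeric(0)
  a_nt <- if (spec$d_nt <= 2 * r) 2 * asin(spec$d_nt / (2 * r)) else pi
  defects <- numeric(0)
  Lidx <- 0L

  q <- r * unit_vec(theta0)
  u1 <- stem_chord_dir(spec, 1)
  p5 <- q - tt[1] * spec$d_bp * u1
  p3 <- q + (1 - tt[1]) * spec$d_bp * u1
  stems <- list(list(p5 = p5, p3 = p3, q = q))
  first_p5 <- p5

  total_sweep <- 0
  ref <- theta0
  advance_ref <- function(newang) {
    total_sweep <<- total_sweep + ang_norm(newang - ref)
    ref <<- newang
  }
  # intersection of the main (possibly shifted) circle with the reach circle;
  # always records one defect component (0 when the intersection exists) so
  # the constraint vector has a fixed length
  step_to <- function(center_shift, from_pt) {
    cand <- circle_intersect(center_shift, r, from_pt, spec$d_nt)
    if (is.null(cand)) {
      p <- center_shift + r * {
        v <- from_pt - center_shift
        if (vnorm(v) < 1e-12) unit_vec(ref) else v / vnorm(v)
      }
      defects <<- c(defects, abs(vnorm(p - from_pt) - spec$d_nt))
      return(p)
    }
    defects <<- c(defects, 0)
    ang_from <- angle_of(from_pt - center_shift)
    pick <- cand[[1]]
    d1 <- ang_norm(angle_of(cand[[1]] - center_shift) - ang_from)
    d2 <- ang_norm(angle_of(cand[[2]] - center_shift) - ang_from)
    if (d2 > d1) pick <- cand[[2]]
    pick
  }

  segments <- vector("list", k)
  seg_first <- vector("list", k)  # first backbone point of each segment
  seg_last <- vector("list", k)
  for (i in seq_len(k)) {
    kinds <- spec$seg_kinds[[i]]
    last_pt <- stems[[i]]$p3
    nts <- list(); vars <- list()
    first_pt <- NULL
    th <- NA_real_
    for (kind in kinds) {
      if (kind == "nt") {
        if (is.na(th)) {
          p <- step_to(c(0, 0), last_pt)
          th <- angle_of(p)
        } else {
          th <- th + a_nt
          p <- r * unit_vec(th)
        }
        advance_ref(th)
        nts[[length(nts) + 1L]] <- list(pos = p, dir = th + pi / 2)
        if (is.null(first_pt)) first_pt <- p
        last_pt <- p
      } else {
        Lidx <- Lidx + 1L
        sweep <- Ls[Lidx] / r
        th_here <- if (is.na(th)) angle_of(last_pt) else th
        vars[[length(vars) + 1L]] <-
          list(center = c(0, 0), radius = r,
               theta0 = th_here, theta1 = th_here + sweep, len = Ls[Lidx])
        th <- th_here + sweep
        advance_ref(th)
        last_pt <- r * unit_vec(th)
        if (is.null(first_pt)) first_pt <- last_pt
      }
    }
    segments[[i]] <- list(nt = nts, var = vars)
    seg_first[i] <- list(first_pt)
    seg_last[i] <- list(last_pt)

    j <- if (i == k) 1L else i + 1L
    uj <- stem_chord_dir(spec, j)
    p5j <- step_to(-tt[j] * spec$d_bp * uj, last_pt)
    qj <- p5j + tt[j] * spec$d_bp * uj
    p3j <- qj + (1 - tt[j]) * spec$d_bp * uj
    advance_ref(angle_of(qj))
    if (i < k) stems[[j]] <- list(p5 = p5j, p3 = p3j, q = qj)
  }

  # objective ingredients: radial distance of each paired nucleotide and of
  # its backbone-adjacent nucleotide
  dn <- numeric(0); da <- numeric(0)
  for (i in seq_len(k)) {
    prev <- if (i == 1) k else i - 1L
    adj5 <- seg_last[[prev]] %||% stems[[prev]]$p3
    adj3 <- seg_first[[i]] %||% stems[[if (i == k) 1L else i + 1L]]$p5
    dn <- c(dn, vnorm(stems[[i]]$p5), vnorm(stems[[i]]$p3))
    da <- c(da, vnorm(adj5), vnorm(adj3))
  }

  list(center = c(0, 0), r = r,
       stems = list(
         p5x = vapply(stems, function(s) s$p5[1], numeric(1)),
         p5y = vapply(stems, function(s) s$p5[2], numeric(1)),
         p3x = vapply(stems, function(s) s$p3[1], numeric(1)),
         p3y = vapply(stems, function(s) s$p3[2], numeric(1))),
       segments = segments, total_sweep = total_sweep,
       defects = defects, paired_dn = dn, paired_da = da)
}

nlp_formulation23 <- function(spec, formulation) {
  k <- spec$k
  V <- n_var_regions(spec)
  var_len0 <- 3 * spec$d_nt
  r0 <- warm_circle(spec, var_len0)

  # variable slots: r, cx, cy, then per stem either (x, y) of its 5'
  # nucleotide or, when the preceding segment is empty, a single angle
  empty_before <- vapply(seq_len(k), function(i) {
    prev <- if (i == 1) k else i - 1L
    length(spec$seg_kinds[[prev]]) == 0
  }, logical(1))
  empty_before[1] <- FALSE   # stem 1 anchors the gauge with explicit x, y

  var_names <- c("r", "cx", "cy")
  for (i in seq_len(k))
    var_names <- c(var_names, if (empty_before[i]) paste0("psi", i)
                   else paste0(c("x", "y"), i))
  if (V) var_names <- c(var_names, paste0("L", seq_len(V)))

  # warm start: stems placed at their commanded directions on the r0 circle
  warm <- warm_positions(spec, r0)
  x0 <- c(r0, warm$center)
  for (i in seq_len(k)) {
    if (empty_before[i]) {
      prev <- if (i == 1) k else i - 1L
      x0 <- c(x0, angle_of(warm$p5[[i]] - warm$p3[[prev]]))
    } else x0 <- c(x0, warm$p5[[i]])
  }
  if (V) x0 <- c(x0, rep(var_len0, V))

  nfree <- length(x0)
  lower <- rep(-Inf, nfree); upper <- rep(Inf, nfree)
  lower[1] <- max(spec$d_nt, spec$d_bp) / 2 * 1.0001
  upper[1] <- r0 * 20
  if (V) {
    lower[(nfree - V + 1):nfree] <- 0.5 * spec$d_nt
    upper[(nfree - V + 1):nfree] <- 10 * spec$d_nt
  }

  decode <- memoize_decode(function(x)
    decode_formulation23(spec, x, empty_before))
  env <- new.env(parent = emptyenv())
  env$extra_heq <- list()
  problem <- list(formulation = formulation, spec = spec, x0 = x0,
                  lower = lower, upper = upper, var_names = var_names,
                  env = env,
                  sample_counts = vapply(spec$seg_kinds, function(kinds)
                    seg_nt_count(kinds) + 2L + 3L * seg_var_count(kinds),
                    integer(1)))
  problem$decode <- decode
  problem$objective <- function(x) {
    d <- decode(x)
    if (formulation == 2L) {
      sum(vapply(d$samples, function(sp)
        sum((sqrt(colSums((t(sp$pts) - d$center)^2)) - d$r)^2), numeric(1)))
    } else {
      tot <- 0
      for (sp in d$samples) {
        if (is.null(sp$seg_center)) next
        for (row in seq_len(nrow(sp$pts))) {
          p <- sp$pts[row, ]
          v1 <- d$center - p; v2 <- sp$seg_center - p
          n1 <- vnorm(v1); n2 <- vnorm(v2)
          if (n1 < 1e-9 || n2 < 1e-9) next
          tot <- tot + (sum(v1 * v2) / (n1 * n2) - 1)^2
        }
      }
      tot
    }
  }
  problem$heq <- function(x) {
    d <- decode(x)
    c(d$gauge, d$eq, extra_heq_values(env, d))
  }
  problem$hin <- function(x) decode(x)$slack   # components must be <= 0
  class(problem) <- "junction_nlp"
  problem
}

warm_positions <- function(spec, r0, var_len0 = 3 * spec$d_nt) {
  # stems sit at cumulative chord-fit angles (not the commanded directions:
  # unequal segments need unequal gaps), chords oriented as commanded
  beta <- step_angle(spec$d_bp, r0)
  alpha <- step_angle(spec$d_nt, r0)
  steps <- vapply(spec$seg_kinds, function(kinds)
    seg_nt_count(kinds) + 1 + seg_var_count(kinds) * var_len0 / spec$d_nt,
    numeric(1))
  p5 <- list(); p3 <- list()
  mid_r <- sqrt(max(r0^2 - (spec$d_bp / 2)^2, 0))
  psi <- spec$dirs[1]
  for (i in seq_len(spec$k)) {
    u <- stem_chord_dir(spec, i)
    m <- mid_r * unit_vec(psi)
    p5[[i]] <- m - spec$d_bp / 2 * u
    p3[[i]] <- m + spec$d_bp / 2 * u
    psi <- psi + beta + steps[i] * alpha
  }
  shift <- p5[[1]]
  list(p5 = lapply(p5, function(p) p - shift),
       p3 = lapply(p3, function(p) p - shift),
       center = -shift)
}

decode_formulation23 <- function(spec, x, empty_before) {
  k <- spec$k
  r <- x[1]; ctr <- x[2:3]
  V <- n_var_regions(spec)
  Ls <- if (V) x[(length(x) - V + 1):length(x)] else numeric(0)
  body <- x[-c(1:3, if (V) (length(x) - V + 1):length(x))]

  p5 <- vector("list", k); p3 <- vector("list", k)
  psi <- rep(NA_real_, k)
  j <- 1L
  for (i in seq_len(k)) {
    if (empty_before[i]) {
      psi[i] <- body[j]; j <- j + 1L
    } else {
      p5[[i]] <- body[j:(j + 1)]; j <- j + 2L
    }
  }
  for (i in seq_len(k))
    if (!is.null(p5[[i]]))
      p3[[i]] <- p5[[i]] + spec$d_bp * stem_chord_dir(spec, i)
  # resolve angle-linked stems (previous segment empty)
  for (rep_pass in 1:2) {
    for (i in seq_len(k)) {
      if (is.null(p5[[i]]) && !is.na(psi[i])) {
        prev <- if (i == 1) k else i - 1L
        if (!is.null(p3[[prev]])) {
          p5[[i]] <- p3[[prev]] + spec$d_nt * unit_vec(psi[i])
          p3[[i]] <- p5[[i]] + spec$d_bp * stem_chord_dir(spec, i)
        }
      }
    }
  }

  eq <- numeric(0)      # exact-gap equalities (empty segment into stem 1)
  slack <- numeric(0)   # over-stretch slacks D - m d_nt, feasible when <= 0
  Lidx <- 0L
  segments <- vector("list", k)
  samples <- vector("list", k)
  for (i in seq_len(k)) {
    kinds <- spec$seg_kinds[[i]]
    nxt <- if (i == k) 1L else i + 1L
    Fp <- p3[[i]]; Gp <- p5[[nxt]]
    n_v <- seg_var_count(kinds)
    seg_L <- if (n_v) { Lseg <- Ls[(Lidx + 1):(Lidx + n_v)]; Lidx <- Lidx + n_v
                        Lseg } else numeric(0)
    if (!length(kinds)) {
      segments[[i]] <- list(nt = list(), var = list())
      samples[[i]] <- list(pts = rbind(Fp, Gp), seg_center = NULL)
      # a psi-linked next stem fixes this gap by construction; an explicitly
      # positioned one (stem 1) needs the single-step spacing enforced
      if (!empty_before[nxt]) eq <- c(eq, vnorm(Gp - Fp) - spec$d_nt)
      next
    }
    m_steps <- seg_nt_count(kinds) + 1 + sum(seg_L) / spec$d_nt
    slack <- c(slack, vnorm(Gp - Fp) - m_steps * spec$d_nt)
    geom <- segment_circle(Fp, Gp, kinds, seg_L, spec$d_nt, ctr)
    segments[[i]] <- list(nt = geom$nt, var = geom$var)
    samples[[i]] <- list(pts = geom$sample_pts, seg_center = geom$center,
                         seg_r = geom$radius)
  }

  list(center = ctr, r = r,
       stems = list(
         p5x = vapply(p5, `[`, numeric(1), 1),
         p5y = vapply(p5, `[`, numeric(1), 2),
         p3x = vapply(p3, `[`, numeric(1), 1),
         p3y = vapply(p3, `[`, numeric(1), 2)),
       segments = segments, samples = samples,
       eq = eq, slack = slack,
       gauge = c(p5[[1]][1], p5[[1]][2]))
}

# Independent circle through the flanking paired positions with the fixed
# backbone spacing: total subtended angle A solves
# d_nt sin(A/2) / sin(A/(2 m)) = |F - G| with m effective unit steps.
segment_circle <- function(Fp, Gp, kinds, seg_L, d_nt, main_center) {
  m <- seg_nt_count(kinds) + 1 + sum(seg_L) / d_nt
  D <- vnorm(Gp - Fp)
  vi <- 0L
  steps <- numeric(length(kinds))
  for (z in seq_along(kinds))
    steps[z] <- if (kinds[z] == "nt") 1 else { vi <- vi + 1L
                                               seg_L[vi] / d_nt }

  if (D >= m * d_nt - 1e-12) {
    # straight (or over-stretched) segment; the defect drives the solver back
    defect <- max(0, D - m * d_nt)
    dirv <- if (D > 0) (Gp - Fp) / D else c(1, 0)
    per_step <- D / m
    cum <- cumsum(steps)
    nt <- list(); var <- list(); pts <- list(Fp)
    for (z in seq_along(kinds)) {
      at <- Fp + dirv * per_step * cum[z]
      if (kinds[z] == "nt") {
        nt[[length(nt) + 1L]] <- list(pos = at, dir = angle_of(dirv))
        pts[[length(pts) + 1L]] <- at
      } else {
        var[[length(var) + 1L]] <- list(center = Fp + 1e6 * rot90(dirv),
                                        radius = 1e6,
                                        theta0 = 0, theta1 = 1e-9,
                                        len = steps[z] * d_nt)
        start <- Fp + dirv * per_step * (cum[z] - steps[z])
        for (f in c(0.25, 0.5, 0.75))
          pts[[length(pts) + 1L]] <- start + f * dirv * per_step * steps[z]
      }
    }
    pts[[length(pts) + 1L]] <- Gp
    return(list(nt = nt, var = var, center = NULL, radius = Inf,
                sample_pts = do.call(rbind, pts), defect = defect))
  }

  g <- function(A) d_nt * sin(A / 2) / sin(A / (2 * m)) - D
  lo <- 1e-9; hi <- 2 * pi - 1e-9
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  A <- (lo + hi) / 2
  rho <- d_nt / (2 * sin(A / (2 * m)))
  mid_pt <- (Fp + Gp) / 2
  perp <- rot90((Gp - Fp) / D)
  q <- sqrt(max(rho^2 - (D / 2)^2, 0))
  toward <- sign(sum((main_center - mid_pt) * perp))
  if (toward == 0) toward <- 1
  o <- mid_pt + (if (A <= pi) toward else -toward) * q * perp

  aF <- angle_of(Fp - o); aG <- angle_of(Gp - o)
  delta <- ang_norm(aG - aF)
  sweep <- if (A <= pi) delta else delta - sign(delta) * 2 * pi
  a_unit <- sweep / m   # signed angle per unit step

  nt <- list(); var <- list(); pts <- list(Fp)
  cum <- 0
  for (z in seq_along(kinds)) {
    if (kinds[z] == "nt") {
      cum <- cum + 1
      th <- aF + a_unit * cum
      p <- o + rho * unit_vec(th)
      nt[[length(nt) + 1L]] <- list(pos = p,
                                    dir = th + sign(sweep) * pi / 2)
      pts[[length(pts) + 1L]] <- p
    } else {
      th0 <- aF + a_unit * cum
      cum <- cum + steps[z]
      th1 <- aF + a_unit * cum
      var[[length(var) + 1L]] <- list(center = o, radius = rho,
                                      theta0 = th0, theta1 = th1,
                                      len = steps[z] * d_nt)
      for (f in c(0.25, 0.5, 0.75))
        pts[[length(pts) + 1L]] <- o + rho * unit_vec(th0 + f * (th1 - th0))
    }
  }
  pts[[length(pts) + 1L]] <- Gp
  list(nt = nt, var = var, center = o, radius = rho,
       sample_pts = do.call(rbind, pts), defect = 0)
}

# ---- alignment constraints --------------------------------------------------

#' Add alignment constraints to a junction NLP
#'
#' Alignment at an arbitrary axis uses scalar projections: for axis angle
#' `phi` the projections of the constrained points onto the axis normal must
#' agree. `spec$aligns` aligns stem rung midpoints pairwise along an axis;
#' `spec$centroids` equates the centroid of a group of stems with a target
#' stem on the axis normal. A horizontal axis (0 degrees) reduces to equal
#' `y`; a vertical axis (90 degrees) to equal `x`.
#'
#' @param problem A `junction_nlp`.
#' @param spec The [junction_spec()] carrying `aligns`/`centroids`.
#' @return The problem with the constraints appended.
#' @export
add_alignment_constraints <- function(problem, spec) {
  midpoint <- function(d, i) {
    if (i < 1 || i > length(d$stems$p5x))
      stop("alignment constraint references absent stem ", i, call. = FALSE)
    c((d$stems$p5x[i] + d$stems$p3x[i]) / 2,
      (d$stems$p5y[i] + d$stems$p3y[i]) / 2)
  }
  add <- function(f) problem$env$extra_heq <-
      c(problem$env$extra_heq, list(f))
  for (al in spec$aligns) {
    add(local({
      stems <- al$stems
      nrm <- rot90(unit_vec(al$angle_deg * pi / 180))
      function(d) vapply(seq_len(length(stems) - 1), function(z)
        sum((midpoint(d, stems[z]) - midpoint(d, stems[z + 1])) * nrm),
        numeric(1))
    }))
  }
  for (ct in spec$centroids) {
    add(local({
      grp <- ct$group; tgt <- ct$target
      nrm <- rot90(unit_vec(ct$angle_deg * pi / 180))
      function(d) {
        cen <- colMeans(do.call(rbind, lapply(grp, function(i)
          midpoint(d, i))))
        sum((cen - midpoint(d, tgt)) * nrm)
      }
    }))
  }
  problem
}

extra_heq_values <- function(env, decoded) {
  if (!length(env$extra_heq)) return(numeric(0))
  unlist(lapply(env$extra_heq, function(f) f(decoded)))
}

# ---- solving ----------------------------------------------------------------

#' Solve a junction NLP
#'
#' Runs SLSQP from the warm start (the plain circular layout projected onto
#' the variables) and, if that fails to reach feasibility, from up to eight
#' Gaussian-perturbed restarts (sigma = 0.1 r0, fixed seed list for
#' determinism). Formulation-1 solutions get a one-dimensional feasibility
#' polish on the radius that drives the angle closure to machine precision.
#'
#' @param problem A `junction_nlp` from [junction_nlp()].
#' @param seeds Integer seeds for the restart perturbations.
#' @param feas_tol Maximum accepted constraint violation (default `1e-6`).
#' @return Object of class `rna_junction_solution`: stem rung positions,
#'   segment nucleotide positions and variable-length arcs, `center`,
#'   `radius`, `objective`, `max_violation`, and for formulation 1 the
#'   swept-angle sum `swept_deg`.
#' @export
solve_junction <- function(problem, seeds = 1:8, feas_tol = 1e-6) {
  starts <- list(problem$x0)
  r0 <- problem$x0[1]
  for (sd in seeds) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    set.seed(sd)
    pert <- problem$x0 + stats::rnorm(length(problem$x0), 0, 0.1 * r0)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    starts[[length(starts) + 1L]] <- pmin(pmax(pert, problem$lower),
                                          problem$upper)
  }
  best <- NULL
  for (x0 in starts) {
    fit <- tryCatch(
      if (is.null(problem$hin))
        nloptr::slsqp(x0, fn = problem$objective, heq = problem$heq,
                      lower = problem$lower, upper = problem$upper,
                      control = list(xtol_rel = 1e-10, maxeval = 800))
      else
        nloptr::slsqp(x0, fn = problem$objective, heq = problem$heq,
                      hin = problem$hin, deprecatedBehavior = FALSE,
                      lower = problem$lower, upper = problem$upper,
                      control = list(xtol_rel = 1e-10, maxeval = 800)),
      error = function(e) NULL)
    if (is.null(fit)) next
    x <- pmin(pmax(fit$par, problem$lower), problem$upper)
    if (problem$formulation == 1L) x <- polish_closure(problem, x)
    viol <- max(abs(problem$heq(x)), 0,
                if (!is.null(problem$hin)) pmax(problem$hin(x), 0))
    if (!is.finite(viol) || viol >= feas_tol) next
    obj <- problem$objective(x)
    if (is.null(best) || obj < best$obj) best <- list(x = x, obj = obj,
                                                      viol = viol)
    if (!is.null(best) && identical(x0, problem$x0) && best$viol < feas_tol)
      break  # warm start succeeded; restarts unnecessary
  }
  if (is.null(best))
    stop("no feasible junction layout found after restarts; ",
         "it is sometimes useful to try a different formulation (1, 2 or 3)",
         call. = FALSE)
  d <- problem$decode(best$x)
  structure(list(formulation = problem$formulation, x = best$x,
                 stems = tibble::as_tibble(d$stems[c("p5x", "p5y",
                                                     "p3x", "p3y")]),
                 segments = d$segments,
                 center = d$center, radius = d$r,
                 objective = best$obj, max_violation = best$viol,
                 swept_deg = if (problem$formulation == 1L)
                   d$total_sweep * 180 / pi else NA_real_),
            class = "rna_junction_solution")
}

# hold everything but r fixed and root-find the angle-closure component
polish_closure <- function(problem, x) {
  h1 <- function(r) { x2 <- x; x2[1] <- r; problem$heq(x2)[1] }
  r <- x[1]
  v0 <- h1(r)
  if (!is.finite(v0) || abs(v0) < 1e-13) return(x)
  for (w in c(0.01, 0.05, 0.2) * r) {
    lo <- max(problem$lower[1], r - w); hi <- min(problem$upper[1], r + w)
    vlo <- h1(lo); vhi <- h1(hi)
    if (is.finite(vlo) && is.finite(vhi) && sign(vlo) != sign(vhi)) {
      root <- stats::uniroot(h1, c(lo, hi), tol = 1e-14)$root
      x[1] <- root
      return(x)
    }
  }
  x
}

#' @export
print.rna_junction_solution <- function(x, ...) {
  cat("<rna_junction_solution> formulation ", x$formulation, ", ",
      nrow(x$stems), " stems, objective ", signif(x$objective, 4),
      ", max violation ", signif(x$max_violation, 2), "\n", sep = "")
  invisible(x)
}

#' Tidy a junction solution into a position table
#' @param x An `rna_junction_solution`.
#' @param ... Unused.
#' @return Tibble with `element`, `index`, `x`, `y`.
#' @method tidy rna_junction_solution
#' @export
tidy.rna_junction_solution <- function(x, ...) {
  st <- x$stems
  out <- list(tibble::tibble(element = "stem_p5",
                             index = seq_len(nrow(st)),
                             x = st$p5x, y = st$p5y),
              tibble::tibble(element = "stem_p3",
                             index = seq_len(nrow(st)),
                             x = st$p3x, y = st$p3y))
  for (i in seq_along(x$segments)) {
    nts <- x$segments[[i]]$nt
    if (length(nts))
      out[[length(out) + 1L]] <- tibble::tibble(
        element = paste0("seg", i), index = seq_along(nts),
        x = vapply(nts, function(p) p$pos[1], numeric(1)),
        y = vapply(nts, function(p) p$pos[2], numeric(1)))
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a junction solution
#' @param x An `rna_junction_solution`.
#' @param ... Unused.
#' @return Tibble with formulation, radius, objective, max violation.
#' @method glance rna_junction_solution
#' @export
glance.rna_junction_solution <- function(x, ...) {
  tibble::tibble(formulation = x$formulation, radius = x$radius,
                 objective = x$objective, max_violation = x$max_violation,
                 swept_deg = x$swept_deg)
}
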