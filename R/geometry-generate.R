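# Fixed internal geometry of the carbonyl scaffold (A / degrees): typical
# acyl-phosphate values; the scaffold only has to be chemically plausible,
# the scheduled observables carry the signal.
.scaffold <- list(
  d_c_ocarb = 1.23, d_c_ca = 1.52, d_c_ob = 1.36,
  ang_ocarb_c_ca = 121, ang_ocarb_c_ob = 125,
  ang_c_ca_n = 110, d_ca_n_default = 1.47
)

.pl_eval <- function(bp, rc) approx(bp$rc, bp$value, xout = rc, rule = 2)$y

.as_breakpoints <- function(x, name) {
  stopifnot(is.data.frame(x), all(c("rc", "value") %in% names(x)))
  if (is.unsorted(x$rc, strictly = TRUE)) {
    abort(sprintf("breakpoints for %s must have strictly increasing rc.", name),
          class = "chiralpmf_value_error")
  }
  as_tibble(x[, c("rc", "value")])
}

#' Piecewise-linear schedule of the reaction-site observables
#'
#' Defines, as piecewise-linear functions of the reaction coordinate, the
#' target Buergi-Dunitz angle, Flippin-Lodge angle, amino-group torsion tau,
#' and the key distances of the reaction site, plus a Gaussian noise SD per
#' observable. [generate_geometry_frames()] realizes these targets as 3-D
#' coordinates.
#'
#' @param bd,fl,tau,d_n_p5p,d_c_o3p Data frames `(rc, value)` of
#'   breakpoints (degrees for angles, A for distances).
#' @param d_n_o3p Optional breakpoints for d(N...O3'). If `NULL` (default)
#'   the distance is left emergent: N is placed from the scheduled torsion
#'   with the standard C-alpha-N bond length, so d(N...O3') follows from
#'   the cis/trans state and the approach distance, the same coupling the
#'   reaction itself shows. When scheduled, the bond length is solved so
#'   the target is met exactly; targets incompatible with the torsion
#'   raise a construction error.
#' @param d_h_o3p Optional breakpoints for d(H3'...O3'); if `NULL`
#'   (default), it is derived as `rc + d(Ccarb...O3')` so every frame's
#'   computed RC equals its nominal one exactly.
#' @param noise Named numeric vector of Gaussian SDs per observable
#'   (degrees / A); unnamed observables default to 0.
#' @return An object of class `geometry_schedule`.
#' @seealso [geometry_schedule_preset()] for ready-made L/D-alanine
#'   schedules.
#' @export
geometry_schedule <- function(bd, fl, tau, d_n_p5p, d_c_o3p,
                              d_n_o3p = NULL, d_h_o3p = NULL,
                              noise = numeric()) {
  obs <- list(bd = bd, fl = fl, tau = tau,
              d_n_p5p = d_n_p5p, d_c_o3p = d_c_o3p)
  obs <- lapply(names(obs) |> setNames(names(obs)),
                function(nm) .as_breakpoints(obs[[nm]], nm))
  if (!is.null(d_n_o3p)) obs$d_n_o3p <- .as_breakpoints(d_n_o3p, "d_n_o3p")
  if (!is.null(d_h_o3p)) obs$d_h_o3p <- .as_breakpoints(d_h_o3p, "d_h_o3p")
  for (nm in c("d_n_p5p", "d_c_o3p", "d_n_o3p", "d_h_o3p")) {
    if (!is.null(obs[[nm]]) && any(obs[[nm]]$value <= 0)) {
      abort(sprintf("distance targets for %s must be > 0.", nm),
            class = "chiralpmf_value_error")
    }
  }
  if (any(obs$bd$value < 0 | obs$bd$value > 180) ||
      any(obs$fl$value <= -90 | obs$fl$value > 90) ||
      any(obs$tau$value <= -180 | obs$tau$value > 180)) {
    abort("angle targets must lie in their principal ranges.",
          class = "chiralpmf_value_error")
  }
  ns <- setNames(rep(0, 7),
                 c("bd", "fl", "tau", "d_n_p5p", "d_c_o3p", "d_n_o3p", "d_h_o3p"))
  ns[names(noise)] <- noise
  structure(list(observables = obs, noise = ns), class = "geometry_schedule")
}

#' Ready-made geometry schedules for the L- and D-alanine pathways
#'
#' Piecewise-linear emulations of the per-window trajectories the two
#' stereochemistries follow: both share the Buergi-Dunitz rise to 105
#' degrees before the barrier and a Flippin-Lodge angle settling at 0, while
#' the D pathway undergoes the abrupt cis-to-trans flip of the amino-group
#' torsion near RC = -2.2 A, with the accompanying jump of d(N...P5') from
#' ~4.3 to 5.1 A (and to 6.3 A past the barrier), and the L pathway rotates
#' gradually to ~60 degrees keeping d(N...P5') near 4.0-4.25 A.
#'
#' @param system `"L-Ala"` or `"D-Ala"`.
#' @param noise Named noise SDs; defaults are modest per-frame fluctuations
#'   (2 deg on BD, 5 deg on FL, 8 deg on tau, 0.1-0.15 A on distances).
#' @return A [geometry_schedule()].
#' @export
#' @examples
#' sched <- geometry_schedule_preset("L-Ala")
geometry_schedule_preset <- function(system = c("L-Ala", "D-Ala"),
                                     noise = NULL) {
  system <- match.arg(system)
  bp <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble(rc = m[, 1], value = m[, 2])
  }
  common <- list(
    bd = bp(-4, 85, -1, 105, 3, 105),
    fl = bp(-4, 8, -2, 0, 3, 0),
    d_c_o3p = bp(-4, 4.96, -1, 1.96, 0, 1.75, 0.5, 1.6, 1, 1.43, 3, 1.43)
  )
  branch <- if (system == "L-Ala") {
    list(
      tau = bp(-4, 0, -2.2, 0, -0.5, 60, 3, 60),
      d_n_p5p = bp(-4, 4.25, -1.1, 4.25, -0.5, 4.0, 3, 4.0)
    )
  } else {
    list(
      tau = bp(-4, 0, -2.3, 0, -2.2, 180, 3, 180),
      d_n_p5p = bp(-4, 4.3, -2.3, 4.3, -2.2, 5.1, -0.55, 5.1, -0.45, 6.3, 3, 6.3)
    )
  }
  noise <- noise %||% c(bd = 2, fl = 5, tau = 8,
                        d_n_p5p = 0.15, d_c_o3p = 0.03)
  geometry_schedule(bd = common$bd, fl = common$fl, tau = branch$tau,
                    d_n_p5p = branch$d_n_p5p,
                    d_c_o3p = common$d_c_o3p, noise = noise)
}

# NeRF-style placement: position of D such that |C-D| = r, angle(B,C,D) =
# ang and torsion(A,B,C,D) = tor under the package's sign convention.
.place_torsion_unit <- function(A, B, C, ang_deg, tor_deg) {
  u2 <- .unit(C - B)
  n <- .unit(.cross3(B - A, C - B))
  m <- .cross3(n, u2)
  ang <- .rad(ang_deg); tor <- .rad(tor_deg)
  -cos(ang) * u2 + sin(ang) * (cos(tor) * m + sin(tor) * n)
}

.build_frame <- function(t, frame_id, rc) {
  sc <- .scaffold
  Ccarb <- c(0, 0, 0)
  Ocarb <- c(sc$d_c_ocarb, 0, 0)
  Ca <- sc$d_c_ca * c(cos(.rad(sc$ang_ocarb_c_ca)),
                      sin(.rad(sc$ang_ocarb_c_ca)), 0)
  Ob <- sc$d_c_ob * c(cos(.rad(sc$ang_ocarb_c_ob)),
                      -sin(.rad(sc$ang_ocarb_c_ob)), 0)
  a <- c(1, 0, 0)
  e_ob <- .unit(Ob - sum(Ob * a) * a)
  n_h <- .cross3(a, e_ob)                       # handed carbonyl normal
  theta <- .rad(min(179.5, max(0.5, t[["bd"]])))
  phi <- .rad(t[["fl"]])
  O3p <- Ccarb + t[["d_c_o3p"]] *
    (cos(theta) * a + sin(theta) * (cos(phi) * n_h + sin(phi) * e_ob))
  H3p <- O3p + t[["d_h_o3p"]] * .unit(O3p - Ccarb)
  # N from the scheduled torsion; if d(N...O3') is scheduled too, the
  # C-alpha-N bond length is solved so both are met
  uN <- .place_torsion_unit(Ob, Ccarb, Ca, sc$ang_c_ca_n, t[["tau"]])
  r <- sc$d_ca_n_default
  if ("d_n_o3p" %in% names(t)) {
    w <- Ca - O3p
    bq <- sum(w * uN)
    disc <- bq^2 - (sum(w * w) - t[["d_n_o3p"]]^2)
    roots <- if (disc >= 0) c(-bq - sqrt(disc), -bq + sqrt(disc)) else numeric()
    roots <- roots[roots > 1e-3]
    if (length(roots) == 0) {
      abort(sprintf("frame %s: scheduled tau and d(N...O3') are geometrically incompatible (triangle inequality).",
                    frame_id),
            class = "chiralpmf_construction_error")
    }
    r <- roots[which.min(abs(roots - sc$d_ca_n_default))]
  }
  N <- Ca + r * uN
  P5p <- N + t[["d_n_p5p"]] * .unit(N - Ccarb)
  coords <- rbind(O3p = O3p, H3p = H3p, Ccarb = Ccarb, Ocarb = Ocarb,
                  Ca = Ca, Ob = Ob, N = N, P5p = P5p)
  tibble(frame = frame_id, rc = rc, atom = rownames(coords),
         x = unname(coords[, 1]), y = unname(coords[, 2]),
         z = unname(coords[, 3]))
}

#' Generate labelled reaction-site frames along a geometric schedule
#'
#' For each reaction-coordinate value, evaluates the scheduled observables
#' (plus per-frame Gaussian noise on the targets), then constructs 3-D
#' coordinates realizing them exactly: the carbonyl scaffold in the
#' xy-plane, O3' at the scheduled Buergi-Dunitz/Flippin-Lodge direction and
#' d(Ccarb...O3'), H3' along the O3' recession line, N from the scheduled
#' torsion with the C-alpha-N bond length solved to meet d(N...O3'), and
#' P5' at the scheduled d(N...P5'). With zero noise the analyzer recovers
#' every scheduled value to machine precision.
#'
#' @param schedule A [geometry_schedule()].
#' @param rc_values Reaction-coordinate values, one frame each.
#' @param seed Integer seed for the noise.
#' @return Long tibble `(frame, rc, atom, x, y, z)`.
#' @export
#' @examples
#' fr <- generate_geometry_frames(geometry_schedule_preset("L-Ala"),
#'                                rc_values = c(-4, -2, -1), seed = 1)
#' geometry_observables(fr)
generate_geometry_frames <- function(schedule, rc_values, seed = 1L) {
  stopifnot(inherits(schedule, "geometry_schedule"), length(rc_values) >= 1)
  set.seed(seed)
  obs <- schedule$observables
  ns <- schedule$noise
  frames <- lapply(seq_along(rc_values), function(i) {
    rc <- rc_values[i]
    t <- vapply(names(obs), function(nm) .pl_eval(obs[[nm]], rc), numeric(1))
    for (nm in names(t)) {
      if (ns[[nm]] > 0) t[[nm]] <- t[[nm]] + stats::rnorm(1, 0, ns[[nm]])
    }
    if (is.null(obs$d_h_o3p)) {
      t[["d_h_o3p"]] <- rc + t[["d_c_o3p"]]
      if (ns[["d_h_o3p"]] > 0) {
        t[["d_h_o3p"]] <- t[["d_h_o3p"]] + stats::rnorm(1, 0, ns[["d_h_o3p"]])
      }
    }
    for (nm in intersect(c("d_n_o3p", "d_n_p5p", "d_c_o3p", "d_h_o3p"), names(t))) {
      t[[nm]] <- max(t[[nm]], 0.1)  # noise must not produce negative lengths
    }
    .build_frame(t, frame_id = i, rc = rc)
  })
  dplyr::bind_rows(frames)
}
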