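# Reaction-site atoms, in the fixed order used by all frame containers.
# ASCII labels: O3p = O3', H3p = H3', Ca = C-alpha, Ob = bridging phosphate
# oxygen, P5p = 5'-phosphate phosphorus.
.atom_order <- c("O3p", "H3p", "Ccarb", "Ocarb", "Ca", "Ob", "N", "P5p")

#' Reaction-site atom labels
#'
#' The eight labelled atoms of the aminoacylation site, in the canonical
#' order used by frame tibbles and XYZ files: O3', H3', Ccarb, Ocarb,
#' C-alpha, Ob (bridging phosphate oxygen), N (amino nitrogen), P5'.
#'
#' @return Character vector of length 8.
#' @export
atom_labels <- function() .atom_order

# coerce a single frame (tibble with atom,x,y,z or named matrix) to a
# rowname-indexed 8x3 matrix, validating labels and coincidence
.frame_matrix <- function(frame, need = .atom_order) {
  if (is.matrix(frame)) {
    m <- frame
  } else {
    stopifnot(is.data.frame(frame), all(c("atom", "x", "y", "z") %in% names(frame)))
    m <- as.matrix(frame[, c("x", "y", "z")])
    rownames(m) <- frame$atom
  }
  missing <- setdiff(need, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("frame is missing labelled atom(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "chiralpmf_value_error")
  }
  m <- m[need, , drop = FALSE]
  d <- as.matrix(stats::dist(m))
  if (any(d[upper.tri(d)] < 1e-6)) {
    abort("two labelled atoms coincide (pairwise distance < 1e-6 A).",
          class = "chiralpmf_value_error")
  }
  m
}

.norm3 <- function(v) sqrt(sum(v * v))
.unit <- function(v) {
  n <- .norm3(v)
  if (n < 1e-9) abort("degenerate (zero-length) vector in geometry.",
                      class = "chiralpmf_geometry_error")
  v / n
}
.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

#' Buergi-Dunitz approach angle
#'
#' The O3'...Ccarb=Ocarb angle at the carbonyl carbon: the elevation of the
#' attacking nucleophile over the carbonyl axis, canonically ~105 degrees at
#' the transition state of additions to carbonyls.
#'
#' @param frame A labelled frame: tibble with `atom, x, y, z` rows or an
#'   8x3 matrix with atom rownames (see [atom_labels()]).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
bd_angle <- function(frame) {
  m <- .frame_matrix(frame, need = c("O3p", "Ccarb", "Ocarb"))
  u <- .unit(m["O3p", ] - m["Ccarb", ])
  v <- .unit(m["Ocarb", ] - m["Ccarb", ])
  .deg(acos(max(-1, min(1, sum(u * v)))))
}

# least-squares plane normal of a point set (smallest principal axis)
.ls_plane_normal <- function(pts) {
  centered <- sweep(pts, 2, colMeans(pts))
  ev <- eigen(crossprod(centered), symmetric = TRUE)
  if (ev$values[2] < 1e-12) {
    abort("plane atoms are (nearly) collinear.",
          class = "chiralpmf_geometry_error")
  }
  ev$vectors[, 3]
}

#' Flippin-Lodge offset angle
#'
#' The in-plane offset of the nucleophile's approach: the signed angle
#' between the plane through O3', Ccarb and Ocarb and the reference plane
#' that contains the Ccarb->Ocarb axis and the carbonyl normal, measured
#' about that axis. The carbonyl plane is the least-squares plane of Ccarb,
#' Ocarb, C-alpha and Ob (which need not be exactly coplanar in sampled
#' frames), with its normal oriented right-handedly from the carbonyl axis
#' and the in-plane direction toward Ob. For frames on the normal side of
#' the carbonyl plane the sign is positive when the approach plane tilts
#' toward the bridging phosphate oxygen Ob; being a handed angle, it flips
#' sign under reflection of the frame.
#'
#' @inheritParams bd_angle
#' @return Signed angle in degrees, folded into `(-90, 90]`.
#' @export
fl_angle <- function(frame) {
  m <- .frame_matrix(frame, need = c("O3p", "Ccarb", "Ocarb", "Ca", "Ob"))
  a <- .unit(m["Ocarb", ] - m["Ccarb", ])           # carbonyl axis
  ob <- m["Ob", ] - m["Ccarb", ]
  e_ob <- ob - sum(ob * a) * a                      # toward Ob, perp to axis
  e_ob <- .unit(e_ob)
  n <- .ls_plane_normal(m[c("Ccarb", "Ocarb", "Ca", "Ob"), ])
  handed <- .cross3(a, e_ob)
  if (sum(n * handed) < 0) n <- -n                  # right-handed orientation
  n_perp <- .unit(n - sum(n * a) * a)
  v <- m["O3p", ] - m["Ccarb", ]
  v <- v - sum(v * a) * a
  if (.norm3(v) < 1e-9) {
    abort("O3' lies on the carbonyl axis; Flippin-Lodge angle undefined.",
          class = "chiralpmf_geometry_error")
  }
  ang <- .deg(atan2(sum(v * e_ob), sum(v * n_perp)))
  # the approach plane is unoriented: fold to (-90, 90]
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Signed torsion angle of four labelled atoms
#'
#' Standard IUPAC signed dihedral: looking along the central bond, a
#' clockwise rotation of the far bond relative to the near one is positive.
#' 0 degrees is the cis (eclipsed) arrangement, +/-180 the trans one
#' (reported as +180).
#'
#' @inheritParams bd_angle
#' @param atoms Four atom labels defining the torsion; default
#'   `c("Ob", "Ccarb", "Ca", "N")`, the amino-group torsion whose cis/trans
#'   flip distinguishes the two stereochemistries in this reaction.
#' @return Signed angle in degrees in `(-180, 180]`.
#' @export
dihedral_angle <- function(frame, atoms = c("Ob", "Ccarb", "Ca", "N")) {
  stopifnot(length(atoms) == 4)
  m <- .frame_matrix(frame, need = atoms)
  b1 <- m[atoms[2], ] - m[atoms[1], ]
  b2 <- m[atoms[3], ] - m[atoms[2], ]
  b3 <- m[atoms[4], ] - m[atoms[3], ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-9 || .norm3(n2) < 1e-9) {
    abort("three consecutive torsion atoms are collinear.",
          class = "chiralpmf_geometry_error")
  }
  ang <- .deg(atan2(sum(.cross3(n1, n2) * .unit(b2)), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Key distances of the reaction site
#'
#' The four distances tracked along the reaction: d(N...O3') and d(N...P5')
#' (the electrostatic contacts of the charged amino group), and
#' d(Ccarb...O3') and d(H3'...O3') (the two that define the reaction
#' coordinate). The frame's RC value d(H3'...O3') - d(Ccarb...O3') is
#' attached.
#'
#' @inheritParams bd_angle
#' @return One-row tibble: `d_n_o3p`, `d_n_p5p`, `d_c_o3p`, `d_h_o3p`,
#'   `rc`.
#' @export
key_distances <- function(frame) {
  m <- .frame_matrix(frame)
  d <- function(a, b) .norm3(m[a, ] - m[b, ])
  d_c <- d("Ccarb", "O3p")
  d_h <- d("H3p", "O3p")
  tibble(d_n_o3p = d("N", "O3p"), d_n_p5p = d("N", "P5p"),
         d_c_o3p = d_c, d_h_o3p = d_h,
         rc = reaction_coordinate_value(d_h, d_c))
}

#' All geometric observables of a set of frames
#'
#' @param frames Long tibble `(frame, [rc,] atom, x, y, z)` as produced by
#'   [generate_geometry_frames()] or [read_xyz_frames()].
#' @return One row per frame: `frame`, `rc` (the frame's nominal RC if
#'   present, else the computed one), `bd`, `fl`, `tau`, the four key
#'   distances, and `rc_computed`.
#' @export
geometry_observables <- function(frames) {
  stopifnot(is.data.frame(frames), "frame" %in% names(frames))
  has_rc <- "rc" %in% names(frames)
  split_frames <- split(frames, frames$frame)
  rows <- lapply(split_frames, function(fr) {
    m <- .frame_matrix(fr)
    kd <- key_distances(m)
    tibble(frame = fr$frame[1],
           rc = if (has_rc) fr$rc[1] else kd$rc,
           bd = bd_angle(m), fl = fl_angle(m), tau = dihedral_angle(m),
           d_n_o3p = kd$d_n_o3p, d_n_p5p = kd$d_n_p5p,
           d_c_o3p = kd$d_c_o3p, d_h_o3p = kd$d_h_o3p,
           rc_computed = kd$rc)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$frame)
}

# principal-range reduction to (-180, 180]
.wrap180 <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

.circular_mean_sd <- function(deg) {
  s <- mean(sin(.rad(deg)))
  c <- mean(cos(.rad(deg)))
  r <- min(1, sqrt(s^2 + c^2))
  list(mean = .wrap180(.deg(atan2(s, c))),
       sd = .deg(sqrt(max(0, -2 * log(max(r, 1e-300))))))
}

#' Per-window statistics of a geometric observable
#'
#' Assigns each frame to the nearest window center and reports the mean and
#' SD of the chosen observable per window, the way per-window averages are
#' plotted against the reaction coordinate. With `circular = TRUE` the
#' vector (circular) mean and circular SD are used, which is the right
#' treatment for torsions fluctuating about +/-180 degrees.
#'
#' @param observables Per-frame tibble from [geometry_observables()] (any
#'   tibble with an `rc` column works).
#' @param observable Name of the observable column, e.g. `"bd"`.
#' @param windows A window schedule; frames are grouped by nearest center.
#' @param circular Use circular statistics (for angles in degrees).
#' @param range Keep only windows with centers inside this RC range
#'   (default `c(-4, 0)`, the pre-transition-state region usually plotted).
#' @return Tibble `(window_center, mean, sd, n, circular)`.
#' @export
window_statistics <- function(observables, observable, windows,
                              circular = FALSE, range = c(-4, 0)) {
  stopifnot(is.data.frame(observables), observable %in% names(observables),
            "rc" %in% names(observables))
  centers <- sort(windows$center)
  idx <- vapply(observables$rc, function(r) which.min(abs(centers - r)),
                integer(1))
  groups <- split(observables[[observable]], centers[idx])
  rows <- lapply(names(groups), function(ctr) {
    v <- groups[[ctr]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      warn(sprintf("window at %s A has no finite values; skipped.", ctr))
      return(NULL)
    }
    if (circular) {
      cs <- .circular_mean_sd(v)
      m <- cs$mean; s <- cs$sd
    } else {
      m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
    }
    tibble(window_center = as.numeric(ctr), mean = m, sd = s,
           n = length(v), circular = circular)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[out$window_center >= range[1] & out$window_center <= range[2], ]
  dplyr::arrange(out, .data$window_center)
}

#' Plot per-window observable profiles
#'
#' @param stats A tibble from [window_statistics()], optionally with a
#'   grouping column `system` (e.g. "L-Ala" / "D-Ala").
#' @param ylab Axis label.
#' @return A ggplot with mean +/- SD error bars vs window center.
#' @export
plot_window_observable <- function(stats, ylab = "observable") {
  aes <- if ("system" %in% names(stats)) {
    ggplot2::aes(x = .data$window_center, y = .data$mean,
                 colour = .data$system)
  } else {
    ggplot2::aes(x = .data$window_center, y = .data$mean)
  }
  ggplot2::ggplot(stats, aes) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (Å)", y = ylab)
}
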