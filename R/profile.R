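.as_profile_tbl <- function(pmf) {
  if (inherits(pmf, "pmf_fit")) return(pmf$profile)
  if (inherits(pmf, "model_surface")) {
    x <- seq(pmf$domain[1], pmf$domain[2], by = 0.005)
    return(tibble(bin_center = x, pmf = surface_energy(pmf, x)))
  }
  stopifnot(is.data.frame(pmf), all(c("bin_center", "pmf") %in% names(pmf)))
  as_tibble(pmf)
}

#' Locate the transition state and reaction energetics of a profile
#'
#' Finds the barrier top as the argmax of the PMF on the interior of the
#' search range (ties broken toward smaller RC), the reactant minimum as the
#' profile minimum left of the barrier, and the product minimum right of it.
#' Barrier and overall free energy are differences, so any constant shift of
#' the profile cancels. Extrema sit on bin centers by default, matching the
#' resolution the data actually have; `refine = "quadratic"` additionally
#' reports a three-point parabolic refinement of the barrier top.
#'
#' @param pmf A `pmf_fit`, a profile tibble `(bin_center, pmf[,
#'   bootstrap_sd])`, or a `model_surface` (evaluated exactly on a dense
#'   grid).
#' @param search Length-2 numeric: RC interval searched for the barrier top
#'   (default `c(-2, 1)`, bracketing the barrier region of this reaction
#'   while excluding the end plateaus).
#' @param refine `"none"` (default) or `"quadratic"`.
#' @return One-row tibble: `ts_rc`, `barrier`, `reactant_min_rc`,
#'   `product_min_rc`, `overall_dG`, `ts_uncertainty` (bootstrap SD at the
#'   barrier bin, `NA` if unavailable), and `ts_rc_refined`,
#'   `barrier_refined` when refinement is requested.
#' @export
#' @examples
#' locate_transition_state(surface_from_landmarks(-3, -0.5, 17, 2, -7))
locate_transition_state <- function(pmf, search = c(-2, 1),
                                    refine = c("none", "quadratic")) {
  refine <- match.arg(refine)
  prof <- .as_profile_tbl(pmf)
  prof <- prof[is.finite(prof$pmf), ]
  sel <- which(prof$bin_center >= search[1] & prof$bin_center <= search[2])
  if (length(sel) < 3) {
    abort("profile has fewer than 3 defined bins inside the search range.",
          class = "chiralpmf_value_error")
  }
  g <- prof$pmf[sel]
  if (all(diff(g) >= 0) || all(diff(g) <= 0)) {
    abort("profile is monotone on the search range: no barrier.",
          class = "chiralpmf_no_barrier_error")
  }
  i_loc <- which.max(g)  # which.max takes the first (smaller RC) on ties
  if (i_loc == 1 || i_loc == length(sel)) {
    abort("barrier top sits on the search boundary; widen the search range.",
          class = "chiralpmf_value_error")
  }
  i_ts <- sel[i_loc]
  left <- prof[prof$bin_center <= prof$bin_center[i_ts], ]
  right <- prof[prof$bin_center >= prof$bin_center[i_ts], ]
  i_r <- which.min(left$pmf)
  i_p <- which.min(right$pmf)
  out <- tibble(
    ts_rc = prof$bin_center[i_ts],
    barrier = prof$pmf[i_ts] - left$pmf[i_r],
    reactant_min_rc = left$bin_center[i_r],
    product_min_rc = right$bin_center[i_p],
    overall_dG = right$pmf[i_p] - left$pmf[i_r],
    ts_uncertainty = if ("bootstrap_sd" %in% names(prof))
      prof$bootstrap_sd[i_ts] else NA_real_
  )
  if (refine == "quadratic") {
    x <- prof$bin_center[(i_ts - 1):(i_ts + 1)]
    y <- prof$pmf[(i_ts - 1):(i_ts + 1)]
    fit <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
    if (is.finite(fit[3]) && fit[3] < 0) {
      xv <- unname(-fit[2] / (2 * fit[3]))
      out$ts_rc_refined <- xv
      out$barrier_refined <-
        unname(fit[1] + fit[2] * xv + fit[3] * xv^2) - left$pmf[i_r]
    } else {
      out$ts_rc_refined <- out$ts_rc
      out$barrier_refined <- out$barrier
    }
  }
  out
}

#' Boltzmann selectivity ratio from a barrier difference
#'
#' `exp(delta_barrier / (kB T))`: the rate ratio two reactions with equal
#' prefactors would show if their barriers differ by `delta_barrier`.
#'
#' @param delta_barrier Barrier difference in kcal/mol.
#' @param temperature Temperature in K.
#' @return Dimensionless ratio.
#' @export
#' @examples
#' selectivity_ratio(0.8265)  # ~4, the observed L/D product ratio
selectivity_ratio <- function(delta_barrier, temperature = 300) {
  stopifnot(temperature > 0)
  exp(delta_barrier / thermal_energy(temperature))
}

#' Barrier difference required for a given selectivity ratio
#'
#' Inverse of [selectivity_ratio()]: `kB T log(ratio)`.
#'
#' @param ratio Dimensionless selectivity ratio (>= 1).
#' @param temperature Temperature in K.
#' @return Barrier difference in kcal/mol.
#' @export
#' @examples
#' barrier_required_for_ratio(4)  # ~0.83 kcal/mol, below 1 kcal/mol
barrier_required_for_ratio <- function(ratio, temperature = 300) {
  if (any(ratio < 1)) {
    abort("`ratio` must be >= 1.", class = "chiralpmf_value_error")
  }
  thermal_energy(temperature) * log(ratio)
}

#' Compare two reaction profiles (e.g. L- vs D-amino-acid systems)
#'
#' @param pmf_a,pmf_b Profiles accepted by [locate_transition_state()];
#'   `pmf_a` is the reference (e.g. the L system).
#' @param search,temperature Passed through / used for the Boltzmann ratio.
#' @return One-row tibble with both summaries' barriers, the barrier
#'   difference `ddG` (b minus a) and the implied `selectivity` for a.
#' @export
compare_profiles <- function(pmf_a, pmf_b, search = c(-2, 1),
                             temperature = 300) {
  a <- locate_transition_state(pmf_a, search = search)
  b <- locate_transition_state(pmf_b, search = search)
  ddg <- b$barrier - a$barrier
  tibble(
    barrier_a = a$barrier, ts_rc_a = a$ts_rc, overall_dG_a = a$overall_dG,
    barrier_b = b$barrier, ts_rc_b = b$ts_rc, overall_dG_b = b$overall_dG,
    ddG = ddg,
    selectivity = selectivity_ratio(ddg, temperature)
  )
}
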