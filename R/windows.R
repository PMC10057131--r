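#' Describe one segment of an umbrella window schedule
#'
#' A segment covers `[start, stop]` on the reaction coordinate with window
#' centers every `step` angstrom. Boundary-inclusion flags let adjacent
#' segments share a boundary without duplicating the window that sits on it.
#'
#' @param start,stop Segment limits in A; `start < stop`.
#' @param step Center spacing in A; must be > 0.
#' @param include_start,include_stop Whether the windows at `start` / `stop`
#'   belong to this segment.
#' @return A one-row tibble with the segment fields.
#' @seealso [build_window_schedule()], [umbrella_segments()]
#' @export
#' @examples
#' schedule_segment(-1, 1, 0.5)
schedule_segment <- function(start, stop, step,
                             include_start = TRUE, include_stop = TRUE) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0) {
    abort("`step` must be a single positive number.", class = "chiralpmf_value_error")
  }
  if (!is.numeric(start) || !is.numeric(stop) || start >= stop) {
    abort("`start` must be strictly smaller than `stop`.",
          class = "chiralpmf_value_error")
  }
  tibble(start = start, stop = stop, step = step,
         include_start = isTRUE(include_start),
         include_stop = isTRUE(include_stop))
}

#' The reference umbrella schedule of the aminoacylation study
#'
#' Three segments along RC = d(H3'...O3') - d(Ccarb...O3'): 0.1 A spacing on
#' `[-4.0, -1.5)` and `(1.5, 3.0]`, and 0.05 A spacing on `[-1.5, 1.5]`,
#' giving 101 windows in total. The shared boundaries at -1.5 and +1.5 A are
#' owned by the fine segment, the only assignment consistent with the window
#' count.
#'
#' @return A tibble of three schedule segments.
#' @export
#' @examples
#' nrow(build_window_schedule(umbrella_segments()))  # 101
umbrella_segments <- function() {
  dplyr::bind_rows(
    schedule_segment(-4.0, -1.5, 0.1, include_start = TRUE, include_stop = FALSE),
    schedule_segment(-1.5, 1.5, 0.05, include_start = TRUE, include_stop = TRUE),
    schedule_segment(1.5, 3.0, 0.1, include_start = FALSE, include_stop = TRUE)
  )
}

.segment_centers <- function(start, stop, step, include_start, include_stop) {
  # integer stepping, then rounding, so boundaries land exactly on the grid
  n <- floor((stop - start) / step + 1e-9)
  centers <- round(start + (0:n) * step, 3)
  if (!include_start) centers <- centers[-1]
  nc <- length(centers)
  if (nc > 0 && !include_stop && centers[nc] == round(stop, 3)) {
    centers <- centers[-nc]
  }
  centers
}

#' Build an umbrella window schedule from segments
#'
#' Expands schedule segments into one window per center. Centers are computed
#' by integer stepping from each segment start and rounded to 3 decimals, so
#' floating-point drift can never duplicate a shared boundary.
#'
#' @param segments A tibble of segments, see [schedule_segment()].
#' @param force_constant Harmonic restraint force constant k in
#'   kcal/mol/A^2 (default 500, the production restraint of the study).
#' @param n_equil_samples Equilibration samples discarded per window
#'   (default 2000 = 10 ps at the 5 fs cadence).
#' @param n_prod_samples Production samples retained per window
#'   (default 4000 = 20 ps at the 5 fs cadence).
#' @param sample_interval Sampling interval in fs (default 5).
#' @return A tibble with one row per window: `index` (0-based), `center`,
#'   `force_constant`, `n_equil_samples`, `n_prod_samples`,
#'   `sample_interval`.
#' @export
#' @examples
#' build_window_schedule(schedule_segment(-1, 1, 0.5))
build_window_schedule <- function(segments, force_constant = 500,
                                  n_equil_samples = 2000,
                                  n_prod_samples = 4000,
                                  sample_interval = 5) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (!is.numeric(force_constant) || force_constant <= 0) {
    abort("`force_constant` must be > 0.", class = "chiralpmf_value_error")
  }
  if (n_prod_samples <= 0 || n_equil_samples < 0) {
    abort("need n_prod_samples > 0 and n_equil_samples >= 0.",
          class = "chiralpmf_value_error")
  }
  if (any(segments$step <= 0)) {
    abort("segment `step` must be > 0.", class = "chiralpmf_value_error")
  }
  centers <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    .segment_centers(s$start, s$stop, s$step, s$include_start, s$include_stop)
  }))
  if (anyDuplicated(centers) || is.unsorted(centers, strictly = TRUE)) {
    abort("segments overlap after boundary-inclusion flags are applied.",
          class = "chiralpmf_schedule_error")
  }
  tibble(
    index = seq_along(centers) - 1L,
    center = centers,
    force_constant = force_constant,
    n_equil_samples = as.integer(n_equil_samples),
    n_prod_samples = as.integer(n_prod_samples),
    sample_interval = sample_interval
  )
}

.bias_prefactor <- function(convention = c("half_k", "full_k")) {
  convention <- match.arg(convention)
  if (convention == "half_k") 0.5 else 1.0
}

#' Umbrella bias energy
#'
#' Harmonic restraint energy of a window at reaction-coordinate value `xi`.
#' The default convention is `w(xi) = 1/2 k (xi - xi0)^2`; the alternative
#' `"full_k"` convention `w(xi) = k (xi - xi0)^2` (the AMBER NMR-restraint
#' form) is available because published protocols use both.
#'
#' @param xi Reaction-coordinate value(s) in A.
#' @param center Window center xi0 in A.
#' @param force_constant Force constant k in kcal/mol/A^2.
#' @param convention `"half_k"` (default) or `"full_k"`.
#' @param offset Constant added to the bias in kcal/mol (default 0). The
#'   estimated profile is invariant to it; it exists to express gauge shifts.
#' @return Bias energies in kcal/mol, same length as `xi`.
#' @export
#' @examples
#' bias_energy(-3.9, center = -4, force_constant = 500)  # 2.5 kcal/mol
bias_energy <- function(xi, center, force_constant,
                        convention = c("half_k", "full_k"), offset = 0) {
  pref <- .bias_prefactor(convention)
  pref * force_constant * (xi - center)^2 + offset
}

#' Reaction-coordinate value from the two defining distances
#'
#' RC = d(H3'...O3') - d(Ccarb...O3'): negative while the 3'-hydroxyl proton
#' is still bonded and the carbonyl carbon is far, positive after aminoacyl
#' transfer.
#'
#' @param d_ho Distance H3'...O3' in A (>= 0).
#' @param d_co Distance Ccarb...O3' in A (>= 0).
#' @return RC in A.
#' @export
#' @examples
#' reaction_coordinate_value(0.96, 4.96)  # -4, the starting state
reaction_coordinate_value <- function(d_ho, d_co) {
  if (any(d_ho < 0) || any(d_co < 0)) {
    abort("distances must be non-negative.", class = "chiralpmf_value_error")
  }
  d_ho - d_co
}

#' Chloride count required to neutralize the simulation box
#'
#' Monovalent-anion bookkeeping: with a solute of charge `solute_charge` (in
#' elementary charge units, negative for nucleic acids), `n_divalent_cations`
#' divalent and `n_monovalent_cations` monovalent cations, neutrality needs
#' `solute_charge + 2 * n_divalent_cations + n_monovalent_cations` anions.
#'
#' @param solute_charge Net solute charge in e (integer, may be negative).
#' @param n_divalent_cations,n_monovalent_cations Cation counts (>= 0).
#' @return Required number of monovalent anions (integer >= 0).
#' @export
#' @examples
#' required_anions_for_neutrality(-9, 10, 52)  # 63
required_anions_for_neutrality <- function(solute_charge, n_divalent_cations,
                                           n_monovalent_cations) {
  stopifnot(n_divalent_cations >= 0, n_monovalent_cations >= 0)
  n <- solute_charge + 2 * n_divalent_cations + n_monovalent_cations
  if (n < 0) {
    abort("system cannot be neutralized by anions alone (negative count).",
          class = "chiralpmf_value_error")
  }
  as.integer(round(n))
}

#' Net charge of an ion inventory
#'
#' @inheritParams required_anions_for_neutrality
#' @param n_monovalent_anions Anion count (>= 0).
#' @return Net charge in e.
#' @export
ion_net_charge <- function(solute_charge, n_divalent_cations,
                           n_monovalent_cations, n_monovalent_anions) {
  solute_charge + 2 * n_divalent_cations + n_monovalent_cations -
    n_monovalent_anions
}
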