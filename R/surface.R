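#' Parametric one-dimensional model free-energy surface
#'
#' G(xi) = sum_j a_j exp(-(xi - c_j)^2 / (2 w_j^2)) + s * xi + offset on a
#' finite domain. Sums of Gaussians plus a linear term are smooth, have
#' analytic gradients, and can be shaped to any single-barrier profile, which
#' makes them convenient stand-ins for the true free-energy surface that an
#' umbrella-sampling campaign estimates.
#'
#' @param gaussians Tibble/data frame with columns `amplitude` (kcal/mol),
#'   `center` (A), `width` (A, > 0). May have zero rows (flat + linear).
#' @param linear_slope Linear term s in kcal/mol/A.
#' @param offset Constant offset in kcal/mol.
#' @param domain Length-2 numeric, the interval on which the surface is used;
#'   Langevin trajectories are reflected at its edges.
#' @return An object of class `model_surface`.
#' @seealso [surface_from_landmarks()], [surface_energy()]
#' @export
#' @examples
#' s <- model_surface(tibble::tibble(amplitude = -3, center = 0, width = 0.5))
#' surface_energy(s, 0)
model_surface <- function(gaussians = tibble(amplitude = numeric(),
                                             center = numeric(),
                                             width = numeric()),
                          linear_slope = 0, offset = 0,
                          domain = c(-4.5, 3.5)) {
  gaussians <- as_tibble(gaussians)
  stopifnot(all(c("amplitude", "center", "width") %in% names(gaussians)),
            length(domain) == 2, domain[1] < domain[2],
            is.numeric(linear_slope), is.numeric(offset))
  if (nrow(gaussians) > 0 && any(gaussians$width <= 0)) {
    abort("gaussian widths must be > 0.", class = "chiralpmf_value_error")
  }
  structure(
    list(gaussians = gaussians, linear_slope = linear_slope,
         offset = offset, domain = as.numeric(domain)),
    class = "model_surface"
  )
}

#' Evaluate a model surface
#'
#' @param surface A [model_surface()].
#' @param xi Reaction-coordinate values in A.
#' @return G(xi) in kcal/mol.
#' @export
surface_energy <- function(surface, xi) {
  g <- surface$gaussians
  e <- surface$linear_slope * xi + surface$offset
  for (j in seq_len(nrow(g))) {
    z <- (xi - g$center[j]) / g$width[j]
    e <- e + g$amplitude[j] * exp(-0.5 * z^2)
  }
  e
}

#' Analytic gradient dG/dxi of a model surface
#'
#' @inheritParams surface_energy
#' @return dG/dxi in kcal/mol/A.
#' @export
surface_gradient <- function(surface, xi) {
  g <- surface$gaussians
  d <- rep(surface$linear_slope, length(xi))
  for (j in seq_len(nrow(g))) {
    z <- (xi - g$center[j]) / g$width[j]
    d <- d - g$amplitude[j] * z / g$width[j] * exp(-0.5 * z^2)
  }
  d
}

#' Construct a surface from reaction landmarks
#'
#' Builds a [model_surface()] whose profile has a reactant minimum at
#' `reactant_rc` with G = 0, a barrier top at `ts_rc` with G = `barrier`, and
#' a product minimum at `product_rc` with G = `overall_dG`. Four Gaussians
#' (centered at the three landmarks and between barrier and product) plus the
#' linear slope and offset are fit to the six value/derivative constraints by
#' an exactly-determined least-squares solve, then the landmark conditions
#' are verified on a dense grid.
#'
#' @param reactant_rc,ts_rc,product_rc Landmark positions in A, strictly
#'   increasing.
#' @param barrier Barrier height in kcal/mol; must exceed
#'   `max(0, overall_dG)`.
#' @param overall_dG Overall reaction free energy in kcal/mol (product minus
#'   reactant).
#' @param domain Optional domain; default extends 1.5 A beyond the outer
#'   landmarks and covers at least `[-4.5, 3.5]`.
#' @param tol Verification tolerance: landmark energies within `tol`
#'   kcal/mol and positions within `tol` A (default 0.05).
#' @return A `model_surface`.
#' @export
#' @examples
#' s <- surface_from_landmarks(-3, -0.5, 17, 2, -7)
#' glance(s)
surface_from_landmarks <- function(reactant_rc, ts_rc, barrier, product_rc,
                                   overall_dG, domain = NULL, tol = 0.05) {
  if (!(reactant_rc < ts_rc && ts_rc < product_rc)) {
    abort("need reactant_rc < ts_rc < product_rc.",
          class = "chiralpmf_value_error")
  }
  if (!(barrier > max(0, overall_dG))) {
    abort("`barrier` must exceed max(0, overall_dG).",
          class = "chiralpmf_value_error")
  }
  dl <- ts_rc - reactant_rc
  dr <- product_rc - ts_rc
  # four shaping gaussians at/between the landmarks plus two confining ones
  # one landmark gap outside the outer minima, so the wells are genuine
  # minima and biased sampling beyond them stays bounded
  centers <- c(reactant_rc, ts_rc, product_rc, (ts_rc + product_rc) / 2,
               reactant_rc - dl, product_rc + dr)
  widths <- c(0.6 * dl, 0.45 * min(dl, dr), 0.6 * dr, 0.5 * dr,
              0.6 * dl, 0.6 * dr)
  nb <- length(centers)

  basis_val <- function(x) {
    vapply(seq_len(nb), function(j) {
      exp(-0.5 * ((x - centers[j]) / widths[j])^2)
    }, numeric(1))
  }
  basis_grad <- function(x) {
    vapply(seq_len(nb), function(j) {
      z <- (x - centers[j]) / widths[j]
      -z / widths[j] * exp(-0.5 * z^2)
    }, numeric(1))
  }
  pts <- c(reactant_rc, ts_rc, product_rc)
  # rows: G and G' at the three landmarks, then confinement values at the
  # outer centers; cols: a1..a6, slope, offset
  A <- rbind(
    t(vapply(pts, function(x) c(basis_val(x), x, 1), numeric(nb + 2))),
    t(vapply(pts, function(x) c(basis_grad(x), 1, 0), numeric(nb + 2))),
    c(basis_val(centers[5]), centers[5], 1),
    c(basis_val(centers[6]), centers[6], 1)
  )
  b <- c(0, barrier, overall_dG, 0, 0, 0,
         barrier, overall_dG + barrier)
  coef <- tryCatch(solve(A, b), error = function(e) {
    abort("landmark system is singular; cannot construct surface.",
          class = "chiralpmf_construction_error")
  })
  if (is.null(domain)) {
    domain <- c(min(reactant_rc - 1.5, -4.5), max(product_rc + 1.5, 3.5))
  }
  surf <- model_surface(
    gaussians = tibble(amplitude = coef[1:nb], center = centers, width = widths),
    linear_slope = coef[nb + 1], offset = coef[nb + 2], domain = domain
  )

  lm <- .surface_grid_landmarks(surf, reactant_rc - 0.45 * dl,
                                product_rc + 0.45 * dr)
  ok <- is.finite(lm$barrier) &&
    abs(lm$reactant_g) <= tol &&
    abs(lm$barrier - barrier) <= tol &&
    abs(lm$overall_dG - overall_dG) <= tol &&
    abs(lm$reactant_rc - reactant_rc) <= tol &&
    abs(lm$ts_rc - ts_rc) <= tol &&
    abs(lm$product_rc - product_rc) <= tol
  if (!ok) {
    abort("landmark surface failed grid verification (infeasible landmark set).",
          class = "chiralpmf_construction_error")
  }
  surf
}

# dense-grid extraction of reactant/TS/product landmarks on [lo, hi]
.surface_grid_landmarks <- function(surface, lo, hi, dx = 0.002) {
  lo <- max(surface$domain[1], lo)
  hi <- min(surface$domain[2], hi)
  x <- seq(lo, hi, by = dx)
  g <- surface_energy(surface, x)
  i_ts <- which.max(g[-c(1, length(g))]) + 1L
  i_r <- which.min(g[1:i_ts])
  i_p <- i_ts - 1L + which.min(g[i_ts:length(g)])
  list(
    reactant_rc = x[i_r], reactant_g = g[i_r],
    ts_rc = x[i_ts], barrier = g[i_ts] - g[i_r],
    product_rc = x[i_p], overall_dG = g[i_p] - g[i_r]
  )
}

#' @export
print.model_surface <- function(x, ...) {
  cat("<model_surface>\n")
  cat(sprintf("  %d gaussian(s), slope %.4g kcal/mol/A, offset %.4g kcal/mol\n",
              nrow(x$gaussians), x$linear_slope, x$offset))
  cat(sprintf("  domain [%.2f, %.2f] A\n", x$domain[1], x$domain[2]))
  invisible(x)
}

#' Tidy the Gaussian components of a model surface
#'
#' @param x A `model_surface`.
#' @param ... Unused.
#' @return A tibble with one row per Gaussian (`amplitude`, `center`,
#'   `width`).
#' @method tidy model_surface
#' @export
tidy.model_surface <- function(x, ...) x$gaussians

#' One-row landmark summary of a model surface
#'
#' Extracts reactant minimum, barrier top and product minimum on a dense
#' grid. The search region defaults to the domain shrunk by 1 A on each
#' side, which excludes the steep confining tails outside the landmark
#' region.
#'
#' @param x A `model_surface`.
#' @param search Length-2 numeric search interval for the landmarks.
#' @param ... Unused.
#' @return One-row tibble: `reactant_rc`, `ts_rc`, `product_rc`, `barrier`,
#'   `overall_dG`.
#' @method glance model_surface
#' @export
glance.model_surface <- function(x, search = x$domain + c(1, -1), ...) {
  lm <- .surface_grid_landmarks(x, search[1], search[2])
  tibble(reactant_rc = lm$reactant_rc, ts_rc = lm$ts_rc,
         product_rc = lm$product_rc, barrier = lm$barrier,
         overall_dG = lm$overall_dG)
}

#' Plot a model surface
#'
#' @param object A `model_surface`.
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot model_surface
#' @export
autoplot.model_surface <- function(object, n = 500, ...) {
  x <- seq(object$domain[1], object$domain[2], length.out = n)
  df <- tibble(xi = x, free_energy = surface_energy(object, x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "G (kcal/mol)")
}
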