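# Windows may carry an optional `bias_offset` column (kcal/mol added to the
# window bias); the anchored PMF is invariant to it (gauge freedom).
.window_bias_matrix <- function(windows, bin_centers, convention) {
  offs <- if ("bias_offset" %in% names(windows)) windows$bias_offset else
    rep(0, nrow(windows))
  t(vapply(seq_len(nrow(windows)), function(i) {
    bias_energy(bin_centers, windows$center[i], windows$force_constant[i],
                convention = convention, offset = offs[i])
  }, numeric(length(bin_centers))))
}

.series_split <- function(series, windows) {
  stopifnot(is.data.frame(series), all(c("window_index", "xi") %in% names(series)))
  vals <- split(series$xi, factor(series$window_index, levels = windows$index))
  empty <- vapply(vals, length, integer(1)) == 0
  if (any(empty)) {
    abort(sprintf("no samples for window index %s.",
                  paste(windows$index[empty], collapse = ", ")),
          class = "chiralpmf_value_error")
  }
  if (any(!vapply(vals, function(v) all(is.finite(v)), logical(1)))) {
    abort("non-finite reaction-coordinate samples.",
          class = "chiralpmf_value_error")
  }
  vals
}

#' Histogram biased window series on a shared grid
#'
#' Bins each window's samples with the half-open convention `[lo, hi)`:
#' a value exactly on a bin edge belongs to the bin on its right. Values
#' outside the range are counted per window and reported, not silently
#' dropped.
#'
#' @param series Long tibble `(window_index, xi)` as returned by
#'   [generate_campaign()] or [read_campaign()].
#' @param windows The window schedule the series belong to.
#' @param bin_width Bin width in A (default 0.02).
#' @param range Length-2 numeric; default spans the data min/max padded by
#'   one bin.
#' @return A list: `counts` (windows x bins matrix), `bin_centers`,
#'   `breaks`, `n_total` (per-window in-range totals), `n_outside`.
#' @export
histogram_windows <- function(series, windows, bin_width = 0.02,
                              range = NULL) {
  stopifnot(bin_width > 0)
  vals <- .series_split(series, windows)
  if (is.null(range)) {
    r <- base::range(series$xi)
    range <- c(r[1] - bin_width, r[2] + bin_width)
  }
  breaks <- seq(range[1], range[2] + bin_width * 1e-9, by = bin_width)
  if (tail(breaks, 1) < range[2] - 1e-12) breaks <- c(breaks, tail(breaks, 1) + bin_width)
  nb <- length(breaks) - 1
  counts <- t(vapply(vals, function(v) {
    idx <- findInterval(v, breaks, left.open = FALSE, rightmost.closed = FALSE)
    tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  }, numeric(nb)))
  n_total <- rowSums(counts)
  n_outside <- vapply(vals, length, numeric(1)) - n_total
  if (any(n_total == 0)) {
    bad <- windows$index[n_total == 0]
    abort(sprintf("window index %s has no samples inside the histogram range.",
                  paste(bad, collapse = ", ")),
          class = "chiralpmf_value_error")
  }
  list(counts = counts, bin_centers = breaks[-length(breaks)] + bin_width / 2,
       breaks = breaks, n_total = n_total, n_outside = n_outside)
}

.anchor_pmf <- function(pmf, bin_centers, anchor_below) {
  defined <- is.finite(pmf)
  anchor <- defined & bin_centers < anchor_below
  if (!any(anchor)) anchor <- defined  # fall back to global minimum
  pmf - min(pmf[anchor])
}

#' Estimate the potential of mean force by WHAM
#'
#' Combines the biased histograms of all umbrella windows into one unbiased
#' profile by self-consistent iteration of the WHAM equations
#' \deqn{P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i e^{(f_i - w_i(b))/k_BT}},
#'       \qquad f_i = -k_BT \ln \sum_b P(b) e^{-w_i(b)/k_BT},}
#' stopping when the largest change in any window free energy f_i drops
#' below `tolerance` (in kcal/mol). The PMF is `-kB T log P`, anchored so
#' that its minimum over the reactant region (bin centers below
#' `anchor_below`) is zero; bins with zero counts are `NA`.
#'
#' @inheritParams histogram_windows
#' @param tolerance Convergence tolerance on `max |delta f_i|` in kcal/mol
#'   (default 1e-7).
#' @param max_iterations Iteration cap; non-convergence returns a result
#'   flagged `converged = FALSE` with a warning.
#' @param temperature Temperature in K (default 300).
#' @param convention Bias convention, see [bias_energy()].
#' @param anchor_below Reactant-region boundary for anchoring (default -2 A,
#'   left of any plausible barrier top). If no defined bin lies below it the
#'   global minimum anchors instead.
#' @param f_init Optional warm-start window free energies (kcal/mol).
#' @return A `pmf_fit` object: see [tidy.pmf_fit()] and [glance.pmf_fit()].
#' @export
#' @examples
#' w <- build_window_schedule(schedule_segment(-0.5, 0.5, 0.25),
#'                            force_constant = 20, n_prod_samples = 500)
#' surf <- model_surface()
#' camp <- generate_campaign(surf, w, langevin_params(seed = 3))
#' fit <- solve_wham(camp, w, bin_width = 0.05)
#' glance(fit)
solve_wham <- function(series, windows, bin_width = 0.02, range = NULL,
                       tolerance = 1e-7, max_iterations = 100000,
                       temperature = 300,
                       convention = c("half_k", "full_k"),
                       anchor_below = -2, f_init = NULL) {
  convention <- match.arg(convention)
  stopifnot(tolerance > 0)
  hist <- histogram_windows(series, windows, bin_width = bin_width,
                            range = range)
  if (sum(hist$counts) == 0) {
    abort("all histograms are empty.", class = "chiralpmf_value_error")
  }
  .check_overlap(hist, windows)
  kT <- thermal_energy(temperature)
  bias <- .window_bias_matrix(windows, hist$bin_centers, convention)
  f0 <- f_init %||% rep(0, nrow(windows))
  sol <- wham_solve_cpp(hist$counts, hist$n_total, bias, kT,
                        tolerance, as.integer(max_iterations), f0)
  if (!sol$converged) {
    warn(sprintf("WHAM did not converge in %d iterations (max |delta f| = %.3g kcal/mol).",
                 sol$iterations, sol$max_delta))
  }
  pmf <- -kT * log(sol$p)
  pmf <- .anchor_pmf(pmf, hist$bin_centers, anchor_below)
  profile <- tibble(bin_center = hist$bin_centers, pmf = pmf,
                    counts = colSums(hist$counts))
  structure(
    list(profile = profile,
         window_free_energies = tibble(window_index = windows$index,
                                       center = windows$center,
                                       f = as.numeric(sol$f)),
         iterations = sol$iterations,
         converged = sol$converged,
         config = list(bin_width = bin_width, range = hist$breaks[c(1, length(hist$breaks))],
                       tolerance = tolerance, max_iterations = max_iterations,
                       temperature = temperature, convention = convention,
                       anchor_below = anchor_below),
         histogram = hist, windows = windows),
    class = "pmf_fit"
  )
}

.check_overlap <- function(hist, windows) {
  n <- nrow(hist$counts)
  if (n < 2) return(invisible(TRUE))
  ord <- order(windows$center)
  for (j in seq_len(n - 1)) {
    a <- hist$counts[ord[j], ] > 0
    b <- hist$counts[ord[j + 1], ] > 0
    if (!any(a & b)) {
      warn(sprintf("windows at %.3f and %.3f A share no occupied bins; the profile may be disconnected.",
                   windows$center[ord[j]], windows$center[ord[j + 1]]))
    }
  }
  invisible(TRUE)
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat("<pmf_fit>\n")
  cat(sprintf("  %d windows, %d bins (%d defined), bin width %.3g A\n",
              nrow(x$window_free_energies), nrow(x$profile),
              sum(is.finite(x$profile$pmf)), x$config$bin_width))
  cat(sprintf("  converged: %s after %d iterations (tol %.1e kcal/mol)\n",
              x$converged, x$iterations, x$config$tolerance))
  invisible(x)
}

#' Per-bin tidy view of a WHAM fit
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return A tibble `(bin_center, pmf, counts[, bootstrap_sd])`; `pmf` is
#'   `NA` for unoccupied bins.
#' @method tidy pmf_fit
#' @export
tidy.pmf_fit <- function(x, ...) x$profile

#' One-row summary of a WHAM fit
#'
#' @param x A `pmf_fit`.
#' @param ... Unused.
#' @return One-row tibble with window/bin counts, iterations and
#'   convergence flag.
#' @method glance pmf_fit
#' @export
glance.pmf_fit <- function(x, ...) {
  tibble(n_windows = nrow(x$window_free_energies),
         n_bins = nrow(x$profile),
         n_samples = sum(x$profile$counts),
         iterations = x$iterations,
         converged = x$converged,
         temperature = x$config$temperature,
         bin_width = x$config$bin_width)
}

#' Plot an estimated PMF
#'
#' @param object A `pmf_fit`.
#' @param ... Unused.
#' @return A ggplot; a ribbon of +/- one bootstrap SD is drawn when
#'   [bootstrap_pmf()] has been run.
#' @method autoplot pmf_fit
#' @export
autoplot.pmf_fit <- function(object, ...) {
  df <- dplyr::filter(object$profile, is.finite(.data$pmf))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$pmf))
  if ("bootstrap_sd" %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pmf - .data$bootstrap_sd,
                   ymax = .data$pmf + .data$bootstrap_sd),
      alpha = 0.3)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (Å)", y = "PMF (kcal/mol)")
}

#' Monte Carlo bootstrap uncertainties for a WHAM profile
#'
#' Resamples each window's value set with replacement (optionally in
#' contiguous blocks of `block_length` samples to respect serial
#' correlation), re-solves WHAM per replicate (warm-started from the base
#' fit), and records the per-bin standard deviation of the anchored PMF and
#' the per-window SD of the free energies f_i. Deterministic given `seed`.
#' Replicates that fail to converge are dropped and counted; more than 20%
#' dropped is an error.
#'
#' @param fit A `pmf_fit` from [solve_wham()].
#' @param series The same long series tibble used for the fit.
#' @param n_boot Number of replicates (>= 2).
#' @param seed Integer seed for the resampling.
#' @param block_length Optional block length for block bootstrap.
#' @return The `pmf_fit` with a `bootstrap_sd` profile column, an `f_sd`
#'   column on the window free energies, and `n_boot_dropped` recorded.
#' @export
bootstrap_pmf <- function(fit, series, n_boot = 50, seed = 1L,
                          block_length = NULL) {
  stopifnot(inherits(fit, "pmf_fit"), n_boot >= 2)
  windows <- fit$windows
  cfg <- fit$config
  vals <- .series_split(series, windows)
  resample <- function(v) {
    n <- length(v)
    if (is.null(block_length) || block_length <= 1) {
      v[sample.int(n, n, replace = TRUE)]
    } else {
      nblk <- ceiling(n / block_length)
      starts <- sample.int(n, nblk, replace = TRUE)
      idx <- as.vector(outer(0:(block_length - 1), starts, `+`)) %% n + 1L
      v[idx[seq_len(n)]]
    }
  }
  pmf_mat <- matrix(NA_real_, nrow = n_boot, ncol = nrow(fit$profile))
  f_mat <- matrix(NA_real_, nrow = n_boot, ncol = nrow(windows))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(derive_seed(seed, b))
    boot_series <- tibble(
      window_index = rep(windows$index, lengths(vals)),
      xi = unlist(lapply(vals, resample), use.names = FALSE)
    )
    rep_fit <- withCallingHandlers(
      solve_wham(boot_series, windows, bin_width = cfg$bin_width,
                 range = cfg$range, tolerance = cfg$tolerance,
                 max_iterations = cfg$max_iterations,
                 temperature = cfg$temperature, convention = cfg$convention,
                 anchor_below = cfg$anchor_below,
                 f_init = fit$window_free_energies$f),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (!rep_fit$converged) {
      dropped <- dropped + 1L
      next
    }
    # replicate grid equals the base grid because range is fixed
    pmf_mat[b, ] <- rep_fit$profile$pmf
    f_mat[b, ] <- rep_fit$window_free_energies$f
  }
  if (dropped > 0.2 * n_boot) {
    abort(sprintf("%d of %d bootstrap replicates failed to converge.",
                  dropped, n_boot),
          class = "chiralpmf_bootstrap_error")
  }
  if (dropped > 0) {
    warn(sprintf("%d bootstrap replicate(s) dropped (non-convergence).", dropped))
  }
  fit$profile$bootstrap_sd <- apply(pmf_mat, 2, sd, na.rm = TRUE)
  fit$profile$bootstrap_sd[!is.finite(fit$profile$pmf)] <- NA_real_
  fit$window_free_energies$f_sd <- apply(f_mat, 2, sd, na.rm = TRUE)
  fit$n_boot <- n_boot
  fit$n_boot_dropped <- dropped
  fit
}
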