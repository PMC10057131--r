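#' Write / read a two-column biased time series file
#'
#' Plain whitespace-separated text, `time_fs  xi`, the format consumed by
#' standard WHAM tools. Lines starting with `#` are comments.
#'
#' @param series Tibble with `time_fs` and `xi` columns.
#' @param path File path.
#' @return `write_series_file()` returns `path` invisibly;
#'   `read_series_file()` returns a tibble `(time_fs, xi)`.
#' @export
write_series_file <- function(series, path) {
  stopifnot(all(c("time_fs", "xi") %in% names(series)))
  writeLines(sprintf("%.6f %.10f", series$time_fs, series$xi), path)
  invisible(path)
}

#' @rdname write_series_file
#' @export
read_series_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed series line %d.", path, bad[1]),
          class = "chiralpmf_parse_error")
  }
  vals <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  if (anyNA(vals)) {
    abort(sprintf("%s: non-numeric series values.", path),
          class = "chiralpmf_parse_error")
  }
  tibble(time_fs = vals[1, ], xi = vals[2, ])
}

#' Write / read a Grossfield-style WHAM metadata file
#'
#' One whitespace-separated line per window: `timeseries-path center
#' force-constant`.
#'
#' @param windows Window schedule tibble.
#' @param paths Character vector of series-file paths, one per window.
#' @param path Metadata file path.
#' @return `write_wham_metadata()` returns `path` invisibly;
#'   `read_wham_metadata()` returns a tibble `(path, center,
#'   force_constant)`.
#' @export
write_wham_metadata <- function(windows, paths, path) {
  stopifnot(length(paths) == nrow(windows))
  writeLines(sprintf("%s %.3f %.6f", paths, windows$center,
                     windows$force_constant), path)
  invisible(path)
}

#' @rdname write_wham_metadata
#' @export
read_wham_metadata <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- lapply(which(keep), function(i) {
    p <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(p) < 3 || anyNA(suppressWarnings(as.numeric(p[2:3])))) {
      abort(sprintf("%s: malformed metadata line %d.", path, i),
            class = "chiralpmf_parse_error")
    }
    tibble(path = p[1], center = as.numeric(p[2]),
           force_constant = as.numeric(p[3]))
  })
  dplyr::bind_rows(out)
}

#' Write a window schedule as TSV
#'
#' @param windows Window schedule tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(windows, path) {
  utils::write.table(windows[, c("index", "center", "force_constant")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a sampled campaign as series files plus metadata
#'
#' Writes one two-column series file per window (`window_000.dat`, ...) and
#' a Grossfield-style metadata file `wham_metadata.txt` into `dir`.
#'
#' @param campaign Long tibble from [generate_campaign()].
#' @param windows The window schedule.
#' @param dir Output directory (created if needed).
#' @return The metadata file path, invisibly.
#' @export
write_campaign <- function(campaign, windows, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, sprintf("window_%03d.dat", windows$index))
  for (i in seq_len(nrow(windows))) {
    s <- campaign[campaign$window_index == windows$index[i], ]
    write_series_file(s, paths[i])
  }
  write_wham_metadata(windows, paths, file.path(dir, "wham_metadata.txt"))
  invisible(file.path(dir, "wham_metadata.txt"))
}

#' Read a campaign back from a metadata file
#'
#' @param metadata_path Path to a Grossfield-style metadata file; series
#'   paths are resolved relative to its directory when not absolute.
#' @param force_constant_default Used if a metadata line omits k (none do
#'   when written by this package).
#' @return A list: `series` (long tibble `(window_index, time_fs, xi)`) and
#'   `windows` (schedule tibble reconstructed from the metadata).
#' @export
read_campaign <- function(metadata_path, force_constant_default = 500) {
  meta <- read_wham_metadata(metadata_path)
  base <- dirname(metadata_path)
  series <- lapply(seq_len(nrow(meta)), function(i) {
    p <- meta$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    s <- read_series_file(p)
    tibble(window_index = i - 1L, s)
  })
  n_samp <- vapply(series, nrow, integer(1))
  windows <- tibble(
    index = seq_len(nrow(meta)) - 1L,
    center = meta$center,
    force_constant = ifelse(is.na(meta$force_constant),
                            force_constant_default, meta$force_constant),
    n_equil_samples = 0L,
    n_prod_samples = as.integer(n_samp),
    sample_interval = 5
  )
  list(series = dplyr::bind_rows(series), windows = windows)
}

#' Write / read labelled frames as multi-frame XYZ
#'
#' Standard XYZ blocks (atom count, comment, then `label x y z` lines) with
#' the fixed reaction-site atom order of [atom_labels()]. The comment line
#' records the frame's RC value as `rc=<value>`.
#'
#' @param frames Long tibble `(frame, rc, atom, x, y, z)`.
#' @param path File path.
#' @return `write_xyz_frames()` returns `path` invisibly;
#'   `read_xyz_frames()` returns the long frame tibble.
#' @export
write_xyz_frames <- function(frames, path) {
  blocks <- split(frames, frames$frame)
  out <- unlist(lapply(blocks, function(fr) {
    m <- .frame_matrix(fr)
    rc <- if ("rc" %in% names(fr)) fr$rc[1] else NA_real_
    c(sprintf("%d", nrow(m)),
      sprintf("frame %s rc=%.6f", fr$frame[1], rc),
      sprintf("%-6s %14.8f %14.8f %14.8f", rownames(m),
              m[, 1], m[, 2], m[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_xyz_frames
#' @export
read_xyz_frames <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frame_id <- 0L
  out <- list()
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || i + nat + 1L > length(lines) + 1L) {
      abort(sprintf("%s: malformed XYZ header at line %d.", path, i),
            class = "chiralpmf_parse_error")
    }
    comment <- lines[i + 1L]
    rc <- suppressWarnings(as.numeric(sub(".*rc=([-0-9.eE+]+).*", "\\1", comment)))
    frame_id <- frame_id + 1L
    rows <- lapply(seq_len(nat), function(j) {
      p <- strsplit(trimws(lines[i + 1L + j]), "\\s+")[[1]]
      if (length(p) < 4) {
        abort(sprintf("%s: malformed XYZ atom line %d.", path, i + 1L + j),
              class = "chiralpmf_parse_error")
      }
      tibble(frame = frame_id, rc = rc, atom = p[1],
             x = as.numeric(p[2]), y = as.numeric(p[3]), z = as.numeric(p[4]))
    })
    out[[frame_id]] <- dplyr::bind_rows(rows)
    i <- i + 2L + nat
  }
  dplyr::bind_rows(out)
}

#' Read a run configuration file
#'
#' YAML configuration driving the command-line pipeline: schedule segments,
#' surface landmarks, Langevin parameters, WHAM settings, bootstrap
#' settings, geometry schedule, transition-state search range, output
#' directory and master seed. Missing blocks fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list with a `config_path` attribute.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "chiralpmf_config_error")
  }
  cfg <- yaml::read_yaml(path)
  attr(cfg, "config_path") <- normalizePath(path)
  cfg
}

#' Write a PMF profile and its JSON sidecar
#'
#' TSV columns `bin_center`, `pmf`, `bootstrap_sd`, `counts`; the sidecar
#' records the window free energies, iteration count, convergence flag and
#' the exact configuration used.
#'
#' @param fit A `pmf_fit`.
#' @param path TSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pmf_tsv <- function(fit, path) {
  prof <- fit$profile
  if (!"bootstrap_sd" %in% names(prof)) prof$bootstrap_sd <- NA_real_
  utils::write.table(
    prof[, c("bin_center", "pmf", "bootstrap_sd", "counts")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    window_free_energies = fit$window_free_energies,
    iterations = fit$iterations,
    converged = fit$converged,
    n_boot = fit$n_boot %||% NULL,
    n_boot_dropped = fit$n_boot_dropped %||% NULL,
    config = fit$config
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a PMF profile written by [write_pmf_tsv()]
#'
#' @param path TSV path.
#' @return Profile tibble `(bin_center, pmf, bootstrap_sd, counts)`.
#' @export
read_pmf_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
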