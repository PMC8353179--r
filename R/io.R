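#' Read and write CEST profiles as plain text
#'
#' Profiles travel as tab-separated text with columns `offset_hz`,
#' `intensity` and optionally `sat_time_s` and `sigma`; lines starting with
#' `#` carry `key: value` metadata (echoed configuration, seed).  Numeric
#' content round-trips losslessly (written with 17 significant digits).
#' Offsets are sorted on read (with a warning if the file was unsorted).
#'
#' @param path file path.
#' @return [read_cest_profile()]: a `cest_profile` tibble with a `meta`
#'   attribute holding the header fields.
#' @export
read_cest_profile <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  dat <- utils::read.delim(text = paste(body, collapse = "\n"),
                           check.names = FALSE)
  if (!"offset_hz" %in% names(dat)) {
    stop("column `offset_hz` missing from ", path)
  }
  if (!"intensity" %in% names(dat)) {
    stop("column `intensity` missing from ", path)
  }
  if (!"sat_time_s" %in% names(dat)) dat$sat_time_s <- NA_real_
  out <- tibble::as_tibble(dat)
  if (is.unsorted(out$offset_hz)) {
    warning("offsets in ", path, " were not sorted; sorting")
  }
  out <- dplyr::arrange(out, .data$offset_hz, .data$sat_time_s)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    m <- regmatches(kv, regexec("^([^:]+):\\s*(.*)$", kv))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) m[3] else val
    }
  }
  attr(out, "meta") <- meta
  class(out) <- c("cest_profile", class(out))
  out
}

#' @rdname read_cest_profile
#' @param profile a `cest_profile` tibble.
#' @param meta optional named list written as `# key: value` header lines
#'   (defaults to scalar fields of the profile's `meta` attribute).
#' @export
write_cest_profile <- function(profile, path, meta = NULL) {
  if (is.null(meta)) meta <- flatten_meta(attr(profile, "meta"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
  }
  cols <- intersect(c("offset_hz", "intensity", "sat_time_s", "sigma"),
                    names(profile))
  writeLines(paste(cols, collapse = "\t"), con)
  rows <- do.call(paste, c(lapply(profile[cols], function(x) {
    if (is.numeric(x)) format(x, digits = 17, trim = TRUE) else as.character(x)
  }), sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

flatten_meta <- function(meta) {
  if (is.null(meta)) return(list())
  out <- list()
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (inherits(v, "experiment_params")) {
      for (f in c("omega_rf_hz", "offset_hz", "omega_mas_hz", "sat_time_s",
                  "t1_s", "n_rotor_steps")) {
        if (!is.null(v[[f]])) out[[f]] <- v[[f]]
      }
    } else if (is.atomic(v) && length(v) == 1) {
      out[[nm]] <- v
    }
  }
  out
}

#' Generate a synthetic noisy CEST dataset
#'
#' Simulates the configured model and adds i.i.d. Gaussian noise of standard
#' deviation `noise_sigma` to every intensity (clipped below at 0), the
#' stand-in for an experimental profile with a known generating model.
#' Identical `(arguments, seed)` give byte-identical files.
#'
#' @inheritParams simulate_cest_profile
#' @param noise_sigma noise standard deviation on the normalized intensity.
#' @param seed integer RNG seed, recorded in the file header.
#' @param path optional output file (written via [write_cest_profile()]).
#' @param ... forwarded to [simulate_cest_profile()].
#' @return the noisy `cest_profile` (invisibly the path when written).
#' @export
make_fixture <- function(network, params, offsets_hz, sat_times_s,
                         noise_sigma = 0.01, seed = 1, path = NULL, ...) {
  prof <- simulate_cest_profile(network, params, offsets_hz, sat_times_s, ...)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  noisy <- pmax(prof$intensity + stats::rnorm(nrow(prof), 0, noise_sigma), 0)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  prof$intensity <- noisy
  prof$sigma <- rep(noise_sigma, nrow(prof))
  meta <- attr(prof, "meta")
  meta$noise_sigma <- noise_sigma
  meta$seed <- seed
  attr(prof, "meta") <- meta
  if (!is.null(path)) {
    write_cest_profile(prof, path)
  }
  prof
}
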