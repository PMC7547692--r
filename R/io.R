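#' Read a gridded field from an ESRI ASCII grid file
#'
#' Parses the standard six-line ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`, `cellsize`,
#' `nodata_value`) followed by rows of values from north to south. The result
#' is stored south-up (row 1 = southern edge) to match the package's grid
#' convention; nodata cells become `NA`.
#'
#' @param path File to read.
#' @param expected Optional content tag (`"elevation"`, `"landcover"`,
#'   `"surface_soc"`); recorded as an attribute, and surface-SOC grids are
#'   checked to be strictly positive where defined.
#' @return A list with `values` (matrix), `domain` ([grid_domain()] with a
#'   provisional boundary outlet), `xll`, `yll`, `nodata`.
#' @export
read_raster <- function(path, expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!(key %in% c("ncols", "nrows", "xllcorner", "xllcenter", "yllcorner",
                     "yllcenter", "cellsize", "nodata_value"))) break
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      stop("malformed header: field '", key, "' has a non-numeric value",
           call. = FALSE)
    }
    hdr[[key]] <- val
    i <- i + 1
  }
  for (f in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[f]])) {
      stop("malformed header: missing field '", f, "'", call. = FALSE)
    }
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[i:length(lines)]), "\\s+"))))
  if (length(vals) != nr * nc) {
    stop("data block has ", length(vals), " values; header implies ",
         nr * nc, call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals[vals == nodata] <- NA_real_
  # file rows run north->south; flip to south-up storage
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)[nr:1, , drop = FALSE]
  if (identical(expected, "surface_soc") && any(m[!is.na(m)] <= 0)) {
    stop("surface SOC grid must be strictly positive", call. = FALSE)
  }
  domain <- grid_domain(nr, nc, hdr$cellsize)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else
    if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else
    if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2 else 0
  structure(list(values = m, domain = domain, xll = xll, yll = yll,
                 nodata = nodata),
            expected = expected, class = "socscape_raster")
}

#' Write a gridded field as an ESRI ASCII grid file
#'
#' The write is atomic (temporary file + rename) and round-trips losslessly
#' through [read_raster()] at the stated precision.
#'
#' @param values Matrix in the package's south-up convention.
#' @param domain A [grid_domain()].
#' @param path Output file.
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata Value written for `NA` cells.
#' @param digits Significant digits retained.
#' @return `path`, invisibly.
#' @export
write_raster <- function(values, domain, path, xll = 0, yll = 0,
                         nodata = -9999, digits = 10) {
  stopifnot(nrow(values) == domain$n_rows, ncol(values) == domain$n_cols)
  v <- values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", domain$n_cols),
    sprintf("nrows %d", domain$n_rows),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", domain$cell_size),
    sprintf("nodata_value %.10g", nodata)
  )
  rows <- apply(v[domain$n_rows:1, , drop = FALSE], 1, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(c(hdr, rows), tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a daily precipitation forcing series
#'
#' Expects a CSV with a `date` column (ISO `YYYY-MM-DD`) and a `precip_mm`
#' column. Dates must be strictly increasing, gap-free and daily; negative
#' precipitation is rejected with the offending row numbers.
#'
#' @param path CSV file.
#' @return A `daily_forcing` data frame with `date` (Date) and `precip_mm`.
#' @export
read_forcing <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "precip_mm") %in% names(df))) {
    stop("forcing CSV needs columns 'date' and 'precip_mm'", call. = FALSE)
  }
  d <- as.Date(df$date)
  if (any(is.na(d))) {
    stop("unparseable dates at rows: ",
         paste(which(is.na(d)), collapse = ", "), call. = FALSE)
  }
  dup <- which(duplicated(d))
  if (length(dup)) {
    stop("duplicate dates: ", paste(format(d[dup]), collapse = ", "),
         call. = FALSE)
  }
  gaps <- which(diff(as.integer(d)) != 1L)
  if (length(gaps)) {
    stop("non-consecutive dates after: ",
         paste(format(d[gaps]), collapse = ", "), call. = FALSE)
  }
  neg <- which(df$precip_mm < 0)
  if (length(neg)) {
    stop("negative precipitation at rows: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(date = d, precip_mm = as.numeric(df$precip_mm)),
            class = c("daily_forcing", "data.frame"))
}

#' Write a daily forcing series as CSV (ISO dates)
#' @param forcing A `daily_forcing` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_forcing <- function(forcing, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(
    data.frame(date = format(forcing$date, "%Y-%m-%d"),
               precip_mm = forcing$precip_mm),
    tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and validate a run configuration (YAML)
#'
#' The schema is versioned; unknown top-level keys are rejected so that typos
#' fail loudly rather than being silently ignored.
#'
#' @param path YAML file.
#' @return A named list of configuration values merged over the defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema_version", "domain", "duration_years",
             "reporting_interval_days", "seed", "scenario", "transport",
             "transform", "hydrology", "profiles", "litter", "weather")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$schema_version)) cfg$schema_version <- 1L
  cfg
}

#' Write a run manifest
#'
#' Records the configuration digest (MD5 of the canonical YAML serialization),
#' input files with checksums, package version, seeds and timestamps, as JSON.
#' Identical configuration and seeds produce identical manifests up to the
#' timestamp fields.
#'
#' @param config Configuration list.
#' @param inputs Character vector of input file paths (checksummed).
#' @param seeds Named or unnamed integer seeds used by the run.
#' @param outdir Output directory (one manifest per directory).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, inputs = character(), seeds = integer(),
                           outdir = ".") {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(config, tf)
  digest <- unname(tools::md5sum(tf))
  checks <- if (length(inputs)) {
    data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)))
  } else NULL
  manifest <- list(
    config_digest = digest,
    inputs = checks,
    package_version = as.character(utils::packageVersion("socscape")),
    seeds = seeds,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(outdir, "manifest.json")
  tmp <- paste0(path, ".tmp", Sys.getpid())
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  file.rename(tmp, path)
  invisible(manifest)
}
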