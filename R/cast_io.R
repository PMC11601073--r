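# CSV dialect: long format, one row per (cast, depth).
# Header: cast_id,time,depth_m,fluorescence[,chl_ug_L,temperature_C,salinity_PSU]
# UTF-8, "." decimal separator, ISO-8601 times with explicit UTC offset.

CAST_REQUIRED_COLS <- c("cast_id", "time", "depth_m", "fluorescence")
CAST_OPTIONAL_COLS <- c("chl_ug_L", "temperature_C", "salinity_PSU")

#' Read a cast series from CSV
#'
#' Parses the long-format cast dialect (one row per cast and depth), groups
#' rows by `cast_id` into casts sorted by time, and sorts rows within each
#' cast by depth. Input row order is immaterial.
#'
#' @param path Path to a CSV file with columns
#'   `cast_id,time,depth_m,fluorescence` and optionally
#'   `chl_ug_L,temperature_C,salinity_PSU`.
#' @param site_depth_m Nominal bottom depth of the site (m).
#' @return A [cast_series()].
#' @export
read_cast_series <- function(path, site_depth_m) {
  if (!file.exists(path)) abort_dvm(sprintf("file not found: %s", path), "dvm_io_error")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(CAST_REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    abort_dvm(sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")), "dvm_format_error")
  }
  times <- parse_time_iso(df$time)
  bad <- which(is.na(times))
  if (length(bad)) {
    abort_dvm(sprintf("unparseable timestamp at data row %d: '%s'",
                      bad[1], df$time[bad[1]]), "dvm_validation_error")
  }
  num <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NULL
  depth <- num("depth_m")
  if (anyDuplicated(df[, c("cast_id", "depth_m")])) {
    abort_dvm("duplicate (cast_id, depth) row", "dvm_validation_error")
  }
  opt <- lapply(CAST_OPTIONAL_COLS, num)
  names(opt) <- CAST_OPTIONAL_COLS
  # drop optional channels that are entirely empty
  opt <- Filter(function(v) !is.null(v) && !all(is.na(v)), opt)
  ids <- unique(df$cast_id)
  casts <- lapply(ids, function(id) {
    i <- which(df$cast_id == id)
    cast(
      cast_id = id, time = times[i[1]],
      depth_m = depth[i], fluorescence = num("fluorescence")[i],
      chl_ug_L = opt$chl_ug_L[i], temperature_C = opt$temperature_C[i],
      salinity_PSU = opt$salinity_PSU[i]
    )
  })
  cast_series(casts, site_depth_m = site_depth_m)
}

#' Write a cast series to CSV
#'
#' Inverse of [read_cast_series()]: emits the same long-format dialect.
#' Numeric values are rendered with 17 significant digits so that
#' write-then-read restores every double exactly; output is byte-identical
#' across runs for identical input. Optional channels absent from every cast
#' are omitted from the header.
#'
#' @param series A [cast_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cast_series <- function(series, path) {
  stopifnot(inherits(series, "dvm_cast_series"))
  present <- CAST_OPTIONAL_COLS[vapply(
    CAST_OPTIONAL_COLS,
    function(col) any(vapply(series$casts, function(cc) !is.null(cc[[col]]), logical(1))),
    logical(1)
  )]
  cols <- c(CAST_REQUIRED_COLS, present)
  rows <- lapply(series$casts, function(cc) {
    n <- length(cc$depth_m)
    r <- data.frame(
      cast_id = rep(cc$cast_id, n),
      time = rep(format_time_iso(cc$time), n),
      depth_m = fmt_num(cc$depth_m),
      fluorescence = fmt_num(cc$fluorescence),
      stringsAsFactors = FALSE
    )
    for (col in present) {
      r[[col]] <- if (is.null(cc[[col]])) rep("", n) else fmt_num(cc[[col]])
    }
    r
  })
  out <- do.call(rbind, rows)[, cols]
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    abort_dvm(sprintf("cannot open '%s' for writing", path), "dvm_io_error")
  })
  on.exit(close(con))
  writeLines(paste(cols, collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read discrete bottle samples from CSV
#'
#' Expects columns `time,depth_m` plus either `chl_ug_L` or per-taxon count
#' columns named `count_<taxon>` (cells/mL); optional per-taxon carbon
#' weights as `carbon_<taxon>` (pg C/cell). One record per row, order
#' preserved.
#'
#' @param path Path to the CSV file.
#' @return A list of [discrete_sample()] objects.
#' @export
read_discrete_samples <- function(path) {
  if (!file.exists(path)) abort_dvm(sprintf("file not found: %s", path), "dvm_io_error")
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- setdiff(c("time", "depth_m"), names(df))
  if (length(need)) {
    abort_dvm(sprintf("missing required column(s): %s", paste(need, collapse = ", ")),
              "dvm_format_error")
  }
  count_cols <- grep("^count_", names(df), value = TRUE)
  carbon_cols <- grep("^carbon_", names(df), value = TRUE)
  if (!("chl_ug_L" %in% names(df)) && !length(count_cols)) {
    abort_dvm("need either a chl_ug_L column or count_<taxon> columns",
              "dvm_format_error")
  }
  times <- parse_time_iso(df$time)
  lapply(seq_len(nrow(df)), function(i) {
    counts <- vapply(count_cols, function(cl) as.numeric(df[[cl]][i]), numeric(1))
    names(counts) <- sub("^count_", "", count_cols)
    counts <- counts[!is.na(counts)]
    if (any(counts < 0)) {
      abort_dvm(sprintf("negative cell count at data row %d", i), "dvm_validation_error")
    }
    carbon <- NULL
    if (length(carbon_cols)) {
      carbon <- vapply(carbon_cols, function(cl) as.numeric(df[[cl]][i]), numeric(1))
      names(carbon) <- sub("^carbon_", "", carbon_cols)
      carbon <- carbon[!is.na(carbon)]
      if (!length(carbon)) carbon <- NULL
    }
    discrete_sample(
      time = times[i], depth_m = as.numeric(df$depth_m[i]),
      chl_ug_L = if ("chl_ug_L" %in% names(df)) as.numeric(df$chl_ug_L[i]) else NA_real_,
      taxon_counts = counts, carbon_per_cell = carbon
    )
  })
}

#' Write discrete bottle samples to CSV
#'
#' Inverse of [read_discrete_samples()]; taxa become `count_<taxon>` and
#' `carbon_<taxon>` columns (union over records).
#'
#' @param samples List of [discrete_sample()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_discrete_samples <- function(samples, path) {
  taxa <- unique(unlist(lapply(samples, function(s) names(s$taxon_counts))))
  carbon_taxa <- unique(unlist(lapply(samples, function(s) names(s$carbon_per_cell))))
  rows <- lapply(samples, function(s) {
    r <- data.frame(
      time = format_time_iso(s$time), depth_m = fmt_num(s$depth_m),
      chl_ug_L = fmt_num(s$chl_ug_L), stringsAsFactors = FALSE
    )
    for (tx in taxa) r[[paste0("count_", tx)]] <- fmt_num(unname(s$taxon_counts[tx]))
    for (tx in carbon_taxa) {
      r[[paste0("carbon_", tx)]] <- fmt_num(unname(s$carbon_per_cell[tx]))
    }
    r
  })
  out <- do.call(rbind, rows)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}
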