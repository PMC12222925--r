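#' Read an occurrence table
#'
#' Expects columns `species, longitude, latitude, elevation_m, bio1_degC,
#' bio12_mm` (per-record climate values are assumed pre-extracted; raster
#' handling is out of scope). Coordinates are validated against their ranges.
#'
#' @param path CSV file path.
#' @return A tibble of occurrence records.
#' @export
read_occurrences <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_occurrences(df)
}

#' Validate occurrence records
#' @param df Data frame of occurrence records.
#' @return The validated tibble.
#' @export
validate_occurrences <- function(df) {
  df <- tibble::as_tibble(df)
  req <- c("species", "longitude", "latitude", "elevation_m")
  miss <- setdiff(req, names(df))
  if (length(miss)) abort(paste0("occurrence table missing columns: ", paste(miss, collapse = ", ")))
  if (any(abs(df$longitude) > 180, na.rm = TRUE) ||
    any(abs(df$latitude) > 90, na.rm = TRUE)) {
    abort("coordinates out of range")
  }
  df
}

#' Drop exact duplicate occurrence coordinates per species
#'
#' Removes records sharing (species, longitude, latitude), keeping the first
#' after a deterministic sort. Precedes grid subsampling in the staged
#' filtering pipeline; counts in/out are logged.
#'
#' @param records Occurrence tibble.
#' @param quiet Suppress the count log.
#' @return Deduplicated tibble.
#' @export
dedup_occurrences <- function(records, quiet = FALSE) {
  n_in <- nrow(records)
  out <- dplyr::arrange(
    records, .data$species, .data$longitude, .data$latitude, .data$elevation_m
  )
  out <- dplyr::distinct(out, .data$species, .data$longitude, .data$latitude,
    .keep_all = TRUE
  )
  if (!quiet) inform(sprintf("dedup: %d -> %d records", n_in, nrow(out)))
  out
}

#' Thin occurrences to one record per species per grid cell
#'
#' Each species keeps at most one record per geographic cell of
#' `cell_size_deg` degrees (default 1/120 degree, approximately 1 km at the
#' equator, matching 30 arc-second climate rasters). The retained record is
#' the first under a deterministic sort by (longitude, latitude, elevation),
#' so the result is invariant to input row order.
#'
#' @param records Occurrence tibble.
#' @param cell_size_deg Cell size in degrees (> 0).
#' @param quiet Suppress the count log.
#' @return Thinned tibble, sorted by (species, longitude, latitude).
#' @export
grid_subsample <- function(records, cell_size_deg = 1 / 120, quiet = FALSE) {
  stopifnot(cell_size_deg > 0)
  if (nrow(records) == 0) {
    return(records)
  }
  n_in <- nrow(records)
  out <- records |>
    dplyr::mutate(
      .cx = floor(.data$longitude / cell_size_deg),
      .cy = floor(.data$latitude / cell_size_deg)
    ) |>
    dplyr::arrange(
      .data$species, .data$longitude, .data$latitude, .data$elevation_m
    ) |>
    dplyr::distinct(.data$species, .data$.cx, .data$.cy, .keep_all = TRUE) |>
    dplyr::select(-".cx", -".cy") |>
    dplyr::arrange(.data$species, .data$longitude, .data$latitude)
  if (!quiet) inform(sprintf("grid_subsample: %d -> %d records", n_in, nrow(out)))
  out
}

#' Categorize elevation into the four analysis bins
#'
#' Left-closed bins: E1 below 500 m, E2 500-1000 m, E3 1000-1500 m, E4 at or
#' above 1500 m. Negative elevations (coastal raster artifacts) map to E1
#' with a warning.
#'
#' @param e Elevation(s) in metres.
#' @param breaks Bin boundaries (metres), default `c(500, 1000, 1500)`.
#' @return Factor with levels `E1..E4`.
#' @examples
#' categorize_elevation(c(499, 500, 1000, 1600))
#' @export
categorize_elevation <- function(e, breaks = ELEV_BIN_BREAKS) {
  stopifnot(all(is.finite(e) | is.na(e)), length(breaks) == 3)
  if (any(e < 0, na.rm = TRUE)) {
    warn(sprintf("%d negative elevation(s) mapped to E1", sum(e < 0, na.rm = TRUE)))
  }
  idx <- findInterval(e, breaks, left.open = FALSE) + 1L # left-closed bins
  factor(ELEV_BINS[idx], levels = ELEV_BINS)
}

#' Summarize occurrence records into per-species niche summaries
#'
#' Computes per-species medians of elevation, temperature (bio1) and
#' precipitation (bio12), the median of absolute latitude, the elevation bin
#' of the median elevation, montane flags under the 500/1000/1500 m cutoffs,
#' and (when climate columns are present) the Whittaker biome of the species'
#' median climate.
#'
#' @param records Occurrence tibble (columns as in [read_occurrences()]).
#' @param abs_latitude Summarize latitude as absolute latitude (default TRUE);
#'   set FALSE for signed latitude.
#' @return A tibble, one row per species.
#' @export
summarize_species <- function(records, abs_latitude = TRUE) {
  stopifnot(nrow(records) > 0)
  lat_fun <- if (abs_latitude) function(x) median(abs(x)) else median
  out <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      elevation_m = median(.data$elevation_m),
      bio1_degC = if ("bio1_degC" %in% names(records)) median(.data$bio1_degC) else NA_real_,
      bio12_mm = if ("bio12_mm" %in% names(records)) median(.data$bio12_mm) else NA_real_,
      latitude = lat_fun(.data$latitude),
      .groups = "drop"
    )
  out$elev_bin <- categorize_elevation(out$elevation_m)
  out$montane_500 <- out$elevation_m > 500
  out$montane_1000 <- out$elevation_m > 1000
  out$montane_1500 <- out$elevation_m > 1500
  if (all(is.finite(out$bio1_degC)) && all(is.finite(out$bio12_mm))) {
    bm <- assign_whittaker_biome(out$bio1_degC, out$bio12_mm)
    out$biome_id <- bm$biome_id
    out$biome_name <- bm$biome_name
    out$biome_extrapolated <- bm$extrapolated
  }
  out
}

#' Chi-squared contingency analysis of biome occupation
#'
#' Pearson chi-squared on the group x biome count table with standardized
#' residuals r_ij = (O_ij - E_ij) / sqrt(E_ij (1 - rowsum_i/n)(1 - colsum_j/n));
#' cells with absolute standardized residual above 2 indicate a strong
#' contribution. Empty rows/columns are dropped with a warning.
#'
#' @param groups Named character/factor vector: species -> group label, or a
#'   data frame with columns `species` and `group`.
#' @param summaries Species niche summary tibble with `species` and `biome_id`
#'   (as from [summarize_species()]); alternatively pass a pre-built
#'   contingency table via `table_override`.
#' @param table_override Optional matrix of counts (groups x biomes).
#' @return An object of class `biome_chisq`: list with `table`, `statistic`,
#'   `df`, `p_value`, `stdres`, `flagged` (cells with |r| > 2), `dropped`.
#' @export
biome_chisq <- function(groups = NULL, summaries = NULL, table_override = NULL) {
  if (is.null(table_override)) {
    if (is.data.frame(groups)) {
      g <- setNames(as.character(groups$group), groups$species)
    } else {
      g <- groups
    }
    sp <- intersect(names(g), summaries$species)
    tab <- table(
      group = g[sp],
      biome = summaries$biome_id[match(sp, summaries$species)]
    )
    tab <- unclass(tab)
  } else {
    tab <- as.matrix(table_override)
  }
  empty_r <- which(rowSums(tab) == 0)
  empty_c <- which(colSums(tab) == 0)
  dropped <- list(
    rows = if (is.null(rownames(tab))) empty_r else rownames(tab)[empty_r],
    cols = if (is.null(colnames(tab))) empty_c else colnames(tab)[empty_c]
  )
  if (length(empty_r) || length(empty_c)) {
    warn(sprintf(
      "dropping %d empty row(s) and %d empty column(s) from contingency table",
      length(empty_r), length(empty_c)
    ))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("need >= 2 groups and >= 2 occupied biomes")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  flagged <- which(abs(ct$stdres) > 2, arr.ind = TRUE)
  structure(
    list(
      table = tab, statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = unname(ct$p.value), expected = ct$expected,
      stdres = ct$stdres, flagged = flagged, dropped = dropped
    ),
    class = "biome_chisq"
  )
}

#' @export
print.biome_chisq <- function(x, ...) {
  cat(sprintf(
    "Biome chi-squared: X2 = %.4g, df = %d, p = %.3g\n",
    x$statistic, x$df, x$p_value
  ))
  cat("Standardized residuals (|r| > 2 flagged):\n")
  print(round(x$stdres, 2))
  invisible(x)
}

#' Total anther pore area
#'
#' `A = pi * a * b` with `a` half the pore height and `b` half the pore width.
#'
#' @param pore_height_mm Pore height (mm, >= 0).
#' @param pore_width_mm Pore width (mm, >= 0).
#' @return Pore area in mm^2.
#' @examples
#' pore_area(2, 2) # pi
#' @export
pore_area <- function(pore_height_mm, pore_width_mm) {
  if (any(pore_height_mm < 0, na.rm = TRUE) || any(pore_width_mm < 0, na.rm = TRUE)) {
    abort("pore dimensions must be non-negative")
  }
  pi * (pore_height_mm / 2) * (pore_width_mm / 2)
}
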