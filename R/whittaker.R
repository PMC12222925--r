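#' Load the packaged Whittaker biome polygons
#'
#' The nine classic Whittaker biomes are delimited in the mean annual
#' temperature x annual precipitation plane. The polygon set shipped with this
#' package is a simplified, straight-edged synthetic digitization of the
#' classic diagram (temperature -15..30 degC, precipitation 0..4500 mm); it is
#' versioned with the package so that biome assignment is fully reproducible.
#'
#' @return A tibble with columns `biome_id`, `biome_name`, `vertex`,
#'   `temp_c`, `precip_mm`.
#' @export
load_whittaker_biomes <- function() {
  path <- system.file("extdata", "whittaker_biomes_synthetic.csv",
    package = "pollshift"
  )
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

# squared distance from point (x, y) to segment (x1,y1)-(x2,y2)
.seg_dist2 <- function(x, y, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0,
    pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / pmax(len2, 1e-300)))
  )
  (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
}

#' Assign Whittaker biomes from climate summaries
#'
#' Point-in-polygon assignment in the temperature x precipitation plane. A
#' point falling outside every polygon is assigned the biome whose boundary is
#' nearest (axes scaled to the diagram's ranges, 45 degC and 4500 mm) and
#' flagged as extrapolated. Missing climate values yield a missing biome.
#'
#' @param bio1 Mean annual temperature (degC).
#' @param bio12 Annual precipitation (mm); must be non-negative.
#' @param polygons Polygon tibble as from [load_whittaker_biomes()].
#' @return A tibble with columns `biome_id`, `biome_name`, `extrapolated`.
#' @examples
#' assign_whittaker_biome(26, 3500) # tropical rain forest
#' @export
assign_whittaker_biome <- function(bio1, bio12, polygons = load_whittaker_biomes()) {
  stopifnot(length(bio1) == length(bio12))
  if (any(bio12 < 0, na.rm = TRUE)) {
    abort("negative precipitation in biome assignment")
  }
  ids <- sort(unique(polygons$biome_id))
  names_by_id <- vapply(ids, function(i) polygons$biome_name[polygons$biome_id == i][1], "")
  n <- length(bio1)
  biome <- rep(NA_integer_, n)
  extrap <- rep(FALSE, n)
  ok <- is.finite(bio1) & is.finite(bio12)
  if (any(ok)) {
    pts <- cbind(bio1[ok], bio12[ok])
    assigned <- rep(NA_integer_, nrow(pts))
    for (i in ids) {
      poly <- polygons[polygons$biome_id == i, ]
      inside <- mgcv::in.out(
        as.matrix(poly[, c("temp_c", "precip_mm")]), pts
      )
      assigned[is.na(assigned) & inside] <- i
    }
    # nearest boundary for leftovers, axes normalized to diagram ranges
    left <- which(is.na(assigned))
    if (length(left)) {
      for (j in left) {
        x <- pts[j, 1] / 45
        y <- pts[j, 2] / 4500
        best <- NA_integer_
        bestd <- Inf
        for (i in ids) {
          poly <- polygons[polygons$biome_id == i, ]
          nv <- nrow(poly)
          vx <- poly$temp_c / 45
          vy <- poly$precip_mm / 4500
          nxt <- c(2:nv, 1)
          d <- min(.seg_dist2(x, y, vx, vy, vx[nxt], vy[nxt]))
          if (d < bestd) {
            bestd <- d
            best <- i
          }
        }
        assigned[j] <- best
      }
      extrap_ok <- rep(FALSE, nrow(pts))
      extrap_ok[left] <- TRUE
      extrap[ok] <- extrap_ok
    }
    biome[ok] <- assigned
  }
  tibble::tibble(
    biome_id = biome,
    biome_name = ifelse(is.na(biome), NA_character_, names_by_id[match(biome, ids)]),
    extrapolated = extrap
  )
}
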