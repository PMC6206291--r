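#' Vincenty inverse geodesic distance on the WGS84 ellipsoid
#'
#' Iterative inverse solution for the geodesic distance between two points
#' on an oblate ellipsoid. With the default parameters this is the WGS84
#' distance in metres, the standard tool for quantifying geocoding error at
#' regional scale.
#'
#' Nearly antipodal point pairs can fail to converge; such cases raise an
#' error rather than returning a silently wrong value.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees WGS84
#'   (vectors are recycled to a common length).
#' @param a semi-major axis in metres (default WGS84).
#' @param f flattening (default WGS84).
#' @param tol convergence tolerance on the longitude difference, radians.
#' @param max_iter iteration cap.
#' @return numeric vector of distances in metres.
#' @export
vincenty_distance <- function(lat1, lon1, lat2, lon2,
                              a = 6378137, f = 1 / 298.257223563,
                              tol = 1e-12, max_iter = 200L) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  if (any(abs(lat1) > 90 | abs(lat2) > 90 |
          abs(lon1) > 180 | abs(lon2) > 180))
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  b <- a * (1 - f)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (lat1[i] == lat2[i] && lon1[i] == lon2[i]) { out[i] <- 0; next }
    phi1 <- lat1[i] * pi / 180; phi2 <- lat2[i] * pi / 180
    L <- (lon2[i] - lon1[i]) * pi / 180
    U1 <- atan((1 - f) * tan(phi1)); U2 <- atan((1 - f) * tan(phi2))
    sinU1 <- sin(U1); cosU1 <- cos(U1)
    sinU2 <- sin(U2); cosU2 <- cos(U2)
    lambda <- L
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      sinL <- sin(lambda); cosL <- cos(lambda)
      sin_sigma <- sqrt((cosU2 * sinL)^2 +
                        (cosU1 * sinU2 - sinU1 * cosU2 * cosL)^2)
      if (sin_sigma == 0) { out[i] <- 0; converged <- TRUE; break }
      cos_sigma <- sinU1 * sinU2 + cosU1 * cosU2 * cosL
      sigma <- atan2(sin_sigma, cos_sigma)
      sin_alpha <- cosU1 * cosU2 * sinL / sin_sigma
      cos2_alpha <- 1 - sin_alpha^2
      cos_2sigma_m <- if (cos2_alpha == 0) 0 else
        cos_sigma - 2 * sinU1 * sinU2 / cos2_alpha
      C <- f / 16 * cos2_alpha * (4 + f * (4 - 3 * cos2_alpha))
      lambda_prev <- lambda
      lambda <- L + (1 - C) * f * sin_alpha *
        (sigma + C * sin_sigma *
           (cos_2sigma_m + C * cos_sigma * (-1 + 2 * cos_2sigma_m^2)))
      if (abs(lambda - lambda_prev) < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop(sprintf(paste0("Vincenty inverse did not converge within %d ",
                          "iterations for (%.4f, %.4f) -> (%.4f, %.4f); ",
                          "points may be nearly antipodal"),
                   max_iter, lat1[i], lon1[i], lat2[i], lon2[i]),
           call. = FALSE)
    if (out[i] == 0 && sin_sigma == 0) next
    u2 <- cos2_alpha * (a^2 - b^2) / b^2
    A <- 1 + u2 / 16384 * (4096 + u2 * (-768 + u2 * (320 - 175 * u2)))
    B <- u2 / 1024 * (256 + u2 * (-128 + u2 * (74 - 47 * u2)))
    delta_sigma <- B * sin_sigma *
      (cos_2sigma_m + B / 4 *
         (cos_sigma * (-1 + 2 * cos_2sigma_m^2) -
            B / 6 * cos_2sigma_m * (-3 + 4 * sin_sigma^2) *
            (-3 + 4 * cos_2sigma_m^2)))
    out[i] <- b * A * (sigma - delta_sigma)
  }
  out
}

#' Resolve location texts against a gazetteer
#'
#' Exact-label lookup replacing an online geocoding API: a text that occurs
#' verbatim as a gazetteer label resolves to that entry's coordinates;
#' anything else is flagged unmatched. Duplicate labels make the lookup
#' ambiguous and are a configuration error.
#'
#' @param location_text character vector of texts to resolve.
#' @param gazetteer data frame with columns `label`, `lat`, `lon`; labels
#'   must be unique.
#' @return data frame with columns `location_text`, `matched`, `lat`, `lon`
#'   (`NA` where unmatched).
#' @export
geocode <- function(location_text, gazetteer) {
  if (!nrow(gazetteer)) stop("gazetteer is empty", call. = FALSE)
  if (anyDuplicated(gazetteer$label))
    stop("duplicate labels in gazetteer", call. = FALSE)
  idx <- match(location_text, gazetteer$label)
  data.frame(location_text = location_text,
             matched = !is.na(idx),
             lat = gazetteer$lat[idx], lon = gazetteer$lon[idx],
             stringsAsFactors = FALSE)
}

#' @describeIn geocode adds `matched`, `lat`, `lon` columns to a specimen
#'   table by resolving its `location_text` column.
#' @param specimens specimen data frame with a `location_text` column.
#' @export
geocode_specimens <- function(specimens, gazetteer) {
  res <- geocode(specimens$location_text, gazetteer)
  specimens$matched <- res$matched
  specimens$lat <- res$lat
  specimens$lon <- res$lon
  specimens
}

#' Summary statistics of geocoding displacement
#'
#' Computes per-pair Vincenty distances between geocoded and reference
#' coordinates and reports their mean, standard error (sd/sqrt(n)) and
#' quartiles in kilometres. Quartiles use linear interpolation between order
#' statistics, the same rule as the taxon quartile summaries.
#'
#' @param geocoded,reference data frames with columns `lat`, `lon`, equal
#'   row counts, at least one row.
#' @return one-row data frame: `n`, `mean_km`, `se_km`, `q1_km`,
#'   `median_km`, `q3_km`.
#' @export
accuracy_stats <- function(geocoded, reference) {
  n <- nrow(geocoded)
  if (n < 1 || nrow(reference) != n)
    stop("need n >= 1 coordinate pairs of equal length", call. = FALSE)
  d_km <- vincenty_distance(geocoded$lat, geocoded$lon,
                            reference$lat, reference$lon) / 1000
  q <- stats::quantile(d_km, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = n, mean_km = mean(d_km),
             se_km = if (n > 1) stats::sd(d_km) / sqrt(n) else 0,
             q1_km = q[1], median_km = q[2], q3_km = q[3])
}
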