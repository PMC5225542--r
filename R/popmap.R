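#' Population map
#'
#' Assigns each genotyped individual to a population and a region (ocean
#' basin), optionally with per-population site coordinates in decimal
#' degrees (WGS-84). Longitudes are normalised to `[-180, 180)`; pairwise
#' geographic distances use great circles, so the antimeridian introduces
#' no cut.
#'
#' @param individual,population,region Character vectors of equal length.
#' @param coords Optional tibble with columns `population`, `lat`, `lon`.
#' @return A tibble of class `pop_map` with columns `individual`,
#'   `population`, `region`, and the coordinates stored in attribute
#'   `"coords"`.
#' @export
pop_map <- function(individual, population, region = "all", coords = NULL) {
  map <- tibble::tibble(individual = as.character(individual),
                        population = as.character(population),
                        region = rep_len(as.character(region), length(individual)))
  if (anyDuplicated(map$individual)) {
    stop("duplicate individuals in population map", call. = FALSE)
  }
  if (!is.null(coords)) {
    coords <- tibble::as_tibble(coords)
    stopifnot(all(c("population", "lat", "lon") %in% names(coords)))
    if (any(coords$lat < -90 | coords$lat > 90)) {
      stop("latitudes must lie in [-90, 90]", call. = FALSE)
    }
    coords$lon <- ((coords$lon + 180) %% 360) - 180
  }
  structure(map, coords = coords, class = c("pop_map", class(map)))
}

#' @rdname pop_map
#' @param map A `pop_map`.
#' @export
pop_coords <- function(map) attr(map, "coords")

#' Read a population map from CSV
#'
#' The map file has columns `individual,population,region`; the optional
#' coordinates file has columns `population,lat,lon`.
#'
#' @param path Map CSV path.
#' @param coords_path Optional coordinates CSV path.
#' @return A [pop_map()].
#' @export
read_pop_map <- function(path, coords_path = NULL) {
  m <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("individual", "population") %in% names(m)))
  if (!"region" %in% names(m)) m$region <- "all"
  coords <- NULL
  if (!is.null(coords_path)) {
    coords <- utils::read.csv(coords_path)
    coords$lat <- as.numeric(coords$lat)
    coords$lon <- as.numeric(coords$lon)
  }
  pop_map(m$individual, m$population, m$region, coords)
}

#' @rdname read_pop_map
#' @param map A [pop_map()].
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(map, path, coords_path = NULL) {
  utils::write.csv(as.data.frame(map[, c("individual", "population", "region")]),
                   path, row.names = FALSE, quote = FALSE)
  if (!is.null(coords_path) && !is.null(pop_coords(map))) {
    utils::write.csv(as.data.frame(pop_coords(map)), coords_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Checks that every individual of G is mapped; returns the population
# factor aligned with rows of G.
map_factor <- function(G, map, level = c("population", "region")) {
  level <- match.arg(level)
  ids <- individuals(G)
  i <- match(ids, map$individual)
  if (anyNA(i)) {
    stop("individuals missing from population map: ",
         paste(utils::head(ids[is.na(i)], 5), collapse = ", "), call. = FALSE)
  }
  factor(map[[level]][i], levels = unique(map[[level]][i]))
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6,371 km.
#'
#' @param a,b Numeric vectors `c(lat, lon)` in decimal degrees, or
#'   two-column matrices (lat, lon).
#' @return Distance in kilometres.
#' @export
great_circle_km <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  geosphere::distHaversine(cbind(a[, 2], a[, 1]), cbind(b[, 2], b[, 1]),
                           r = 6371)
}

#' Pairwise great-circle distance matrix between populations
#'
#' @param map A [pop_map()] with coordinates attached.
#' @return A symmetric matrix of distances in km, labelled by population.
#' @export
geo_dist_matrix <- function(map) {
  coords <- pop_coords(map)
  if (is.null(coords)) stop("population map has no coordinates", call. = FALSE)
  n <- nrow(coords)
  d <- matrix(0, n, n, dimnames = list(coords$population, coords$population))
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d[i, j] <- d[j, i] <- great_circle_km(
      c(coords$lat[i], coords$lon[i]),
      cbind(coords$lat[j], coords$lon[j]))
  }
  d
}
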