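#' Dispersal run configuration
#'
#' Defaults follow the larval-dispersal protocol the package reproduces:
#' hourly time step, horizontal turbulent diffusion coefficient
#' E_h = 5 m^2/s, 25,600 particles released per seed region per day for
#' 14 days, and a 90-day forward run.
#'
#' @param timestep_s Integration step in seconds; must divide one day.
#' @param e_h Horizontal turbulent diffusion coefficient, m^2/s.
#' @param particles_per_day Particles released per seed region per day.
#' @param release_days Number of consecutive daily releases.
#' @param run_days Forward run length in days (>= release_days).
#' @param extraction_days Extra snapshot days (post first seeding).
#' @param beaching `"stay"`: a particle whose destination is a land cell
#'   keeps its position for that step and stays active; `"freeze"`:
#'   it is deactivated at its last water position.
#' @param seed Integer RNG seed.
#' @return A list of class `dispersal_config`.
#' @export
dispersal_config <- function(timestep_s = 3600, e_h = 5,
                             particles_per_day = 25600, release_days = 14,
                             run_days = 90, extraction_days = NULL,
                             beaching = c("stay", "freeze"), seed = 1L) {
  beaching <- match.arg(beaching)
  stopifnot(timestep_s > 0, 86400 %% timestep_s == 0, e_h >= 0,
            particles_per_day >= 1, release_days >= 1,
            run_days == 0 || run_days >= release_days)
  structure(list(timestep_s = timestep_s, e_h = e_h,
                 particles_per_day = particles_per_day,
                 release_days = release_days, run_days = run_days,
                 extraction_days = extraction_days, beaching = beaching,
                 seed = as.integer(seed)),
            class = "dispersal_config")
}

#' Random-walk eddy-diffusivity displacement
#'
#' Per axis, K = sqrt(-4 E_h dt log(1 - R_NA)) cos(2 pi R_NB) with R_NA,
#' R_NB independent uniform draws on [0, 1); the two axes use independent
#' draw pairs. The displacement variance per axis is 2 E_h dt.
#'
#' @param e_h Horizontal turbulent diffusion coefficient, m^2/s.
#' @param dt Time step, seconds.
#' @param n Number of particles.
#' @return An `n x 2` matrix of metre displacements (x, y).
#' @export
diffusive_step <- function(e_h, dt, n) {
  stopifnot(e_h >= 0, dt > 0)
  draw <- function() {
    r_na <- stats::runif(n)
    r_nb <- stats::runif(n)
    sqrt(-4 * e_h * dt * log(1 - r_na)) * cos(2 * pi * r_nb)
  }
  cbind(x = draw(), y = draw())
}

deg_per_m_lat <- 1 / 111320

#' Advance a particle ensemble by one time step
#'
#' Forward-Euler update: metre displacement = interpolated surface
#' velocity times dt plus the random-walk eddy-diffusivity term,
#' converted to degrees with the local equirectangular scale
#' (111,320 m per degree latitude, scaled by cos(lat) for longitude).
#' Only surface currents act; vertical movement is neglected. A particle
#' whose destination falls on a masked (land) cell keeps its position
#' for this step; one leaving the grid is deactivated. Ages advance by
#' dt for active particles.
#'
#' @param particles Tibble with `lon`, `lat`, `age` (days), `seed_region`,
#'   `active`.
#' @param field A [current_field()].
#' @param t Current time in days.
#' @param cfg A [dispersal_config()].
#' @return The updated particle tibble.
#' @export
step_particles <- function(particles, field, t, cfg) {
  act <- which(particles$active)
  if (!length(act)) return(particles)
  dt <- cfg$timestep_s
  uv <- interp_velocity(field, t, particles$lon[act], particles$lat[act])
  k <- if (cfg$e_h > 0) diffusive_step(cfg$e_h, dt, length(act))
       else matrix(0, length(act), 2)
  exited <- is.na(uv[, 1])
  dx <- uv[, 1] * dt + k[, 1]
  dy <- uv[, 2] * dt + k[, 2]
  new_lon <- particles$lon[act] +
    dx * deg_per_m_lat / cos(particles$lat[act] * pi / 180)
  new_lat <- particles$lat[act] + dy * deg_per_m_lat
  nx <- length(field$lon); ny <- length(field$lat)
  dest_out <- new_lon < field$lon[1] | new_lon > field$lon[nx] |
    new_lat < field$lat[1] | new_lat > field$lat[ny]
  exited <- exited | dest_out
  on_land <- !on_water(field, new_lon, new_lat)
  ok <- !exited & !on_land
  move <- act[ok]
  particles$lon[move] <- new_lon[ok]
  particles$lat[move] <- new_lat[ok]
  if (any(on_land & !exited)) {
    stuck <- act[on_land & !exited]
    if (cfg$beaching == "freeze") particles$active[stuck] <- FALSE
    # "stay": position unchanged, still active
  }
  particles$active[act[exited]] <- FALSE
  still <- act[particles$active[act]]
  particles$age[still] <- particles$age[still] + dt / 86400
  particles
}

# TRUE when the position falls inside the grid on a cell with at least
# one water corner (consistent with the interpolation mask handling).
on_water <- function(field, lon, lat) {
  nx <- length(field$lon); ny <- length(field$lat)
  inside <- lon >= field$lon[1] & lon <= field$lon[nx] &
    lat >= field$lat[1] & lat <= field$lat[ny]
  out <- rep(FALSE, length(lon))
  if (!any(inside)) return(out)
  xi <- findInterval(lon[inside], field$lon, all.inside = TRUE)
  yi <- findInterval(lat[inside], field$lat, all.inside = TRUE)
  out[inside] <- field$mask[cbind(xi, yi)] | field$mask[cbind(xi + 1, yi)] |
    field$mask[cbind(xi, yi + 1)] | field$mask[cbind(xi + 1, yi + 1)]
  out
}

#' Ray-casting point-in-polygon test
#'
#' @param lon,lat Point coordinates (vectors).
#' @param poly Two-column matrix of polygon vertices (lon, lat), open or
#'   closed ring.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, poly) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > lat) != (py[j] > lat)
    if (any(cross)) {
      xint <- px[i] + (lat - py[i]) * (px[j] - px[i]) / (py[j] - py[i])
      flip <- cross & lon < xint
      inside[flip] <- !inside[flip]
    }
    j <- i
  }
  inside
}

#' Seed particles uniformly over a polygon's water area
#'
#' Rejection sampling over the polygon bounding box, keeping draws that
#' fall inside the polygon and on water.
#'
#' @param n Number of particles.
#' @param polygon Two-column matrix (lon, lat).
#' @param field A [current_field()] providing the land mask.
#' @param seed_region Label attached to the particles.
#' @return A particle tibble (`lon`, `lat`, `age`, `seed_region`,
#'   `active`). Errors when the polygon contains no water.
#' @export
seed_particles <- function(n, polygon, field, seed_region = "seed") {
  bb <- apply(polygon, 2, range)
  out_lon <- numeric(0); out_lat <- numeric(0)
  tries <- 0L
  while (length(out_lon) < n) {
    m <- max(2L * (n - length(out_lon)), 100L)
    lon <- stats::runif(m, bb[1, 1], bb[2, 1])
    lat <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_polygon(lon, lat, polygon) & on_water(field, lon, lat)
    out_lon <- c(out_lon, lon[keep]); out_lat <- c(out_lat, lat[keep])
    tries <- tries + 1L
    if (tries > 1000L && !length(out_lon)) {
      stop("seed polygon contains no water", call. = FALSE)
    }
  }
  tibble::tibble(lon = out_lon[seq_len(n)], lat = out_lat[seq_len(n)],
                 age = 0, seed_region = seed_region, active = TRUE)
}

#' Run a Lagrangian dispersal simulation
#'
#' Particles are released in each seed region at the start of each of the
#' first `release_days` days, advected by the (temporally and bilinearly
#' interpolated) surface currents with the random-walk eddy-diffusivity
#' term, and stepped forward hourly (or at the configured step) for
#' `run_days` days. Daily snapshots are retained at the configured
#' extraction days plus the final day. No mortality or competency
#' behaviour is simulated; trajectories are deterministic under a fixed
#' seed.
#'
#' @param field A [current_field()] spanning the run window.
#' @param cfg A [dispersal_config()].
#' @param seed_polygons Named list of two-column (lon, lat) polygon
#'   matrices.
#' @return A list with `particles` (final state) and `snapshots`
#'   (tibble of particle states at each extraction day, column `day`).
#' @export
run_dispersal <- function(field, cfg, seed_polygons) {
  if (max(field$time) - min(field$time) < cfg$run_days) {
    stop("current field shorter than the run window", call. = FALSE)
  }
  set.seed(cfg$seed)
  steps_per_day <- 86400 / cfg$timestep_s
  snap_days <- sort(unique(c(cfg$extraction_days, cfg$run_days)))
  particles <- tibble::tibble(lon = numeric(), lat = numeric(), age = numeric(),
                              seed_region = character(), active = logical())
  snapshots <- list()
  t0 <- min(field$time)
  if (cfg$run_days == 0) {
    for (nm in names(seed_polygons)) {
      particles <- dplyr::bind_rows(
        particles, seed_particles(cfg$particles_per_day, seed_polygons[[nm]],
                                  field, nm))
    }
    snapshots[["0"]] <- dplyr::mutate(particles, day = 0)
  }
  day <- 0
  while (day < cfg$run_days) {
    if (day < cfg$release_days) {
      for (nm in names(seed_polygons)) {
        particles <- dplyr::bind_rows(
          particles, seed_particles(cfg$particles_per_day, seed_polygons[[nm]],
                                    field, nm))
      }
    }
    for (s in seq_len(steps_per_day)) {
      t <- t0 + day + (s - 1) / steps_per_day
      particles <- step_particles(particles, field, t, cfg)
    }
    day <- day + 1
    if (day %in% snap_days) {
      snapshots[[as.character(day)]] <- dplyr::mutate(particles, day = day)
    }
  }
  list(particles = particles, snapshots = dplyr::bind_rows(snapshots))
}

#' Source-to-sink connectivity matrix
#'
#' Entry (s, k) is the fraction of particles seeded in region s that lie
#' inside sink polygon k at the snapshot time. A particle inside several
#' (overlapping) sinks counts towards the first in declared order, with a
#' warning. Rows sum to at most 1; the remainder is outside every sink or
#' deactivated.
#'
#' @param particles A particle tibble (one snapshot).
#' @param sink_polygons Named list of two-column polygon matrices.
#' @param denominator `"seeded"` counts every seeded particle;
#'   `"active"` restricts to still-active particles.
#' @return A source x sink matrix of fractions.
#' @export
connectivity_matrix <- function(particles, sink_polygons,
                                denominator = c("seeded", "active")) {
  denominator <- match.arg(denominator)
  stopifnot(nrow(particles) > 0)
  sources <- unique(particles$seed_region)
  sinks <- names(sink_polygons)
  inside <- vapply(sink_polygons, function(pp)
    point_in_polygon(particles$lon, particles$lat, pp) & particles$active,
    logical(nrow(particles)))
  inside <- matrix(inside, nrow = nrow(particles))
  if (any(rowSums(inside) > 1)) {
    warning("overlapping sink polygons: particles counted in the first by order")
    first <- max.col(inside, ties.method = "first")
    has <- rowSums(inside) > 0
    inside[] <- FALSE
    inside[cbind(which(has), first[has])] <- TRUE
  }
  out <- matrix(0, length(sources), length(sinks),
                dimnames = list(sources, sinks))
  for (s in sources) {
    rows <- particles$seed_region == s
    denom <- if (denominator == "seeded") sum(rows)
             else sum(rows & particles$active)
    if (denom == 0) next
    out[s, ] <- colSums(inside[rows, , drop = FALSE]) / denom
  }
  out
}
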