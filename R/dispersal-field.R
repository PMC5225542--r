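#' Gridded daily surface-current field
#'
#' Time series of (u, v) surface velocities on a regular lon/lat lattice
#' with an optional land mask, the in-memory analogue of a daily
#' hydrodynamic-model surface-current product.
#'
#' @param lon,lat Strictly increasing node axes in decimal degrees.
#' @param time Numeric day stamps (>= 2 for temporal interpolation).
#' @param u,v Arrays `length(lon) x length(lat) x length(time)`, m/s.
#' @param mask Logical `length(lon) x length(lat)` matrix, `TRUE` =
#'   water. Default all water.
#' @param meta Free-form metadata list (the synthetic generator stores
#'   the analytic closed form here).
#' @return An object of class `current_field`.
#' @export
current_field <- function(lon, lat, time, u, v, mask = NULL, meta = list()) {
  stopifnot(all(diff(lon) > 0), all(diff(lat) > 0), all(diff(time) >= 0))
  dims <- c(length(lon), length(lat), length(time))
  stopifnot(identical(dim(u), dims), identical(dim(v), dims))
  if (is.null(mask)) mask <- matrix(TRUE, length(lon), length(lat))
  stopifnot(identical(dim(mask), dims[1:2]))
  if (any(!is.finite(u[rep(mask, length(time))])) ||
      any(!is.finite(v[rep(mask, length(time))]))) {
    stop("non-finite velocity on water nodes", call. = FALSE)
  }
  structure(list(lon = lon, lat = lat, time = time, u = u, v = v,
                 mask = mask, meta = meta),
            class = "current_field")
}

#' @export
print.current_field <- function(x, ...) {
  cat(sprintf("<current_field> %d x %d nodes, %d days, %.0f%% water\n",
              length(x$lon), length(x$lat), length(x$time),
              100 * mean(x$mask)))
  invisible(x)
}

#' Generate an analytic synthetic current field
#'
#' Daily (u, v) snapshots on a lon/lat lattice emulating a 1/12-degree
#' daily surface-current product, with an analytic closed form retained
#' in the metadata so trajectories can be checked against exact
#' solutions. Kinds: `uniform` (constant `u`, `v`), `solid_body`
#' (rotation at angular rate `omega` rad/s about `lon0`, `lat0`;
#' velocities are linear in the local-plane offsets so particle orbits
#' are circles), and `double_gyre` (the standard time-dependent
#' two-gyre stream function with amplitude `a` m/s, perturbation `eps`
#' and angular frequency `omega` rad/day; divergence-free).
#'
#' @param kind `"uniform"`, `"solid_body"` or `"double_gyre"`.
#' @param lon_range,lat_range Domain bounds (degrees).
#' @param res Grid spacing in degrees (default 1/12).
#' @param days Number of daily snapshots (>= 2).
#' @param params Named list of kind-specific parameters.
#' @param land Optional list of rectangles
#'   `list(c(lon_min, lon_max, lat_min, lat_max), ...)` masked as land.
#' @return A [current_field()].
#' @export
simulate_current_field <- function(kind = c("uniform", "solid_body", "double_gyre"),
                                   lon_range = c(0, 5), lat_range = c(-2.5, 2.5),
                                   res = 1 / 12, days = 10, params = list(),
                                   land = NULL) {
  kind <- match.arg(kind)
  stopifnot(res > 0, days >= 1)
  lon <- seq(lon_range[1], lon_range[2], by = res)
  lat <- seq(lat_range[1], lat_range[2], by = res)
  time <- seq_len(max(days, 2)) - 1
  deg_m <- 111320
  analytic <- switch(kind,
    uniform = {
      u0 <- params$u %||% 0.1; v0 <- params$v %||% 0
      function(lon, lat, t) cbind(u = rep(u0, length(lon)), v = rep(v0, length(lon)))
    },
    solid_body = {
      lon0 <- params$lon0 %||% mean(lon_range)
      lat0 <- params$lat0 %||% mean(lat_range)
      omega <- params$omega %||% 1e-5
      scale <- cos(lat0 * pi / 180)
      function(lon, lat, t) {
        x <- (lon - lon0) * deg_m * scale
        y <- (lat - lat0) * deg_m
        cbind(u = -omega * y, v = omega * x)
      }
    },
    double_gyre = {
      a <- params$a %||% 0.1
      eps <- params$eps %||% 0.25
      om <- params$omega %||% (2 * pi / 10)   # rad/day
      lx <- diff(lon_range); ly <- diff(lat_range)
      function(lon, lat, t) {
        xs <- 2 * (lon - lon_range[1]) / lx    # [0, 2]
        ys <- (lat - lat_range[1]) / ly        # [0, 1]
        aa <- eps * sin(om * t)
        bb <- 1 - 2 * eps * sin(om * t)
        fx <- aa * xs^2 + bb * xs
        dfx <- 2 * aa * xs + bb
        cbind(u = -pi * a * sin(pi * fx) * cos(pi * ys),
              v = pi * a * cos(pi * fx) * sin(pi * ys) * dfx)
      }
    })
  grid <- expand.grid(lon = lon, lat = lat)
  nt <- length(time)
  u <- array(0, c(length(lon), length(lat), nt))
  v <- array(0, c(length(lon), length(lat), nt))
  for (k in seq_len(nt)) {
    uv <- analytic(grid$lon, grid$lat, time[k])
    u[, , k] <- matrix(uv[, 1], length(lon), length(lat))
    v[, , k] <- matrix(uv[, 2], length(lon), length(lat))
  }
  mask <- matrix(TRUE, length(lon), length(lat))
  if (!is.null(land)) {
    for (r in land) {
      mask[lon >= r[1] & lon <= r[2], lat >= r[3] & lat <= r[4]] <- FALSE
    }
  }
  current_field(lon, lat, time, u, v, mask,
                meta = list(kind = kind, params = params, analytic = analytic))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interpolate velocity at particle positions
#'
#' Linear interpolation in time between the bracketing daily snapshots,
#' then bilinear in space. Land corner nodes receive zero weight with the
#' remaining weights renormalised; a cell with all four corners on land
#' yields velocity (0, 0). Positions outside the grid return `NA`
#' velocities (the stepper deactivates such particles).
#'
#' @param field A [current_field()].
#' @param t Time in days (within the field's span).
#' @param lon,lat Particle positions (vectors).
#' @return A two-column matrix `u`, `v` in m/s.
#' @export
interp_velocity <- function(field, t, lon, lat) {
  nt <- length(field$time)
  t <- min(max(t, field$time[1]), field$time[nt])
  k <- findInterval(t, field$time, all.inside = TRUE)
  wt <- if (field$time[k + 1] > field$time[k])
    (t - field$time[k]) / (field$time[k + 1] - field$time[k]) else 0
  interp_one <- function(a) {
    slice <- a[, , k] * (1 - wt) + a[, , k + 1] * wt
    bilinear_masked(field$lon, field$lat, slice, field$mask, lon, lat)
  }
  cbind(u = interp_one(field$u), v = interp_one(field$v))
}

bilinear_masked <- function(xg, yg, z, mask, x, y) {
  nx <- length(xg); ny <- length(yg)
  out <- rep(NA_real_, length(x))
  inside <- x >= xg[1] & x <= xg[nx] & y >= yg[1] & y <= yg[ny]
  if (!any(inside)) return(out)
  xi <- findInterval(x[inside], xg, all.inside = TRUE)
  yi <- findInterval(y[inside], yg, all.inside = TRUE)
  tx <- (x[inside] - xg[xi]) / (xg[xi + 1] - xg[xi])
  ty <- (y[inside] - yg[yi]) / (yg[yi + 1] - yg[yi])
  w00 <- (1 - tx) * (1 - ty) * mask[cbind(xi, yi)]
  w10 <- tx * (1 - ty) * mask[cbind(xi + 1, yi)]
  w01 <- (1 - tx) * ty * mask[cbind(xi, yi + 1)]
  w11 <- tx * ty * mask[cbind(xi + 1, yi + 1)]
  wsum <- w00 + w10 + w01 + w11
  val <- w00 * z[cbind(xi, yi)] + w10 * z[cbind(xi + 1, yi)] +
    w01 * z[cbind(xi, yi + 1)] + w11 * z[cbind(xi + 1, yi + 1)]
  out[inside] <- ifelse(wsum > 0, val / wsum, 0)
  out
}

#' Serialise a current field to plain text
#'
#' Writes a long-format CSV (`day`, `lon`, `lat`, `u`, `v`, `water`) plus
#' a JSON sidecar with the axes; [read_current_field()] restores the
#' object (without the analytic metadata).
#'
#' @param field A [current_field()].
#' @param path Base path; `.csv` and `.json` files are written.
#' @return `path`, invisibly.
#' @export
write_current_field <- function(field, path) {
  grid <- expand.grid(lon = field$lon, lat = field$lat)
  rows <- purrr::map_dfr(seq_along(field$time), function(k)
    tibble::tibble(day = field$time[k], lon = grid$lon, lat = grid$lat,
                   u = as.vector(field$u[, , k]), v = as.vector(field$v[, , k]),
                   water = as.vector(field$mask)))
  readr::write_csv(rows, paste0(path, ".csv"))
  jsonlite::write_json(list(lon = field$lon, lat = field$lat, time = field$time),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_current_field
#' @export
read_current_field <- function(path) {
  axes <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- readr::read_csv(paste0(path, ".csv"), show_col_types = FALSE)
  nl <- length(axes$lon); nla <- length(axes$lat); nt <- length(axes$time)
  ord <- order(match(rows$day, axes$time),
               match(rows$lat, axes$lat), match(rows$lon, axes$lon))
  rows <- rows[ord, ]
  current_field(axes$lon, axes$lat, axes$time,
                array(rows$u, c(nl, nla, nt)), array(rows$v, c(nl, nla, nt)),
                matrix(rows$water[seq_len(nl * nla)], nl, nla))
}
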