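# Region representation: zones with age-structured populations, stroke
# centers, dispatch sites, and a travel-time lookup.

#' Age band definitions
#'
#' Zone populations are stored in 5-year age bands from 0--4 up to 95+,
#' following national-statistics conventions. Returns a data.frame with the
#' band lower bound, upper bound (Inf for the open band) and the population
#' column name used in `zones.csv`.
#'
#' @return data.frame with columns `lower`, `upper`, `column`.
#' @export
age_bands <- function() {
  lower <- seq(0, 95, by = 5)
  upper <- c(seq(4, 94, by = 5), Inf)
  column <- c(sprintf("pop_%02d_%02d", lower[-20], upper[-20]), "pop_95plus")
  data.frame(lower = lower, upper = upper, column = column,
             stringsAsFactors = FALSE)
}

travel_key <- function(from, to) paste(from, to, sep = "\r")

build_travel_lookup <- function(travel) {
  lk <- travel$minutes
  names(lk) <- travel_key(travel$from_id, travel$to_id)
  lk
}

#' Look up travel times
#'
#' Travel times are supplied as a long-format table, never computed from a
#' road network inside the model. Missing pairs are an error.
#'
#' @param region a `msu_region` object
#' @param from,to character vectors of ids (recycled to common length)
#' @return numeric vector of minutes
#' @export
travel_time <- function(region, from, to) {
  mins <- region$travel_lookup[travel_key(from, to)]
  if (anyNA(mins)) {
    bad <- paste(from, "->", to)[is.na(mins)]
    stop("travel time not defined for pair(s): ",
         paste(unique(bad), collapse = ", "))
  }
  unname(mins)
}

has_travel_time <- function(region, from, to) {
  !is.na(region$travel_lookup[travel_key(from, to)])
}

#' Construct a region from its component tables
#'
#' Assembles and validates a region from hand-built data.frames with the
#' same columns as the delimited interchange files (`zones.csv`,
#' `hospitals.csv`, `sites.csv`, `travel.csv`).
#'
#' @param zones data.frame: `zone_id`, `x_km`, `y_km`, one population
#'   column per age band (see [age_bands()])
#' @param hospitals data.frame: `hospital_id`, `x_km`, `y_km`, `tsc`,
#'   `dtn_min`, `dtg_min` (TSC only), `dido_min` (non-TSC only)
#' @param sites data.frame: `site_id`, `x_km`, `y_km`, `msu_capable`
#' @param travel long-format data.frame: `from_id`, `to_id`, `minutes`;
#'   must cover every (site, zone) and (zone, hospital) pair, and may add
#'   site-hospital and hospital-hospital rows used by the busy model and
#'   transfer legs
#' @return a validated `msu_region`
#' @export
region <- function(zones, hospitals, sites, travel) {
  new_region(zones, hospitals, sites, travel)
}

new_region <- function(zones, hospitals, sites, travel) {
  region <- structure(
    list(zones = zones, hospitals = hospitals, sites = sites,
         travel = travel, travel_lookup = build_travel_lookup(travel)),
    class = "msu_region")
  validate_region(region)
  region
}

#' Validate a region
#'
#' Checks structural invariants: non-negative populations and travel times,
#' door-to-groin present iff thrombectomy-capable (and door-in-door-out iff
#' not), no dangling ids in the travel table, and completeness of the travel
#' table over every (site, zone) and (zone, hospital) pair. Errors name the
#' offending rows or pairs.
#'
#' @param region a `msu_region` object
#' @return the region, invisibly
#' @export
validate_region <- function(region) {
  z <- region$zones; h <- region$hospitals; s <- region$sites; tr <- region$travel
  ab <- age_bands()

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " missing column(s): ",
                           paste(miss, collapse = ", "))
  }
  need(z, c("zone_id", "x_km", "y_km", ab$column), "zones")
  need(h, c("hospital_id", "x_km", "y_km", "tsc", "dtn_min", "dtg_min",
            "dido_min"), "hospitals")
  need(s, c("site_id", "x_km", "y_km", "msu_capable"), "sites")
  need(tr, c("from_id", "to_id", "minutes"), "travel")

  if (anyDuplicated(z$zone_id)) stop("duplicate zone_id")
  if (anyDuplicated(h$hospital_id)) stop("duplicate hospital_id")
  if (anyDuplicated(s$site_id)) stop("duplicate site_id")
  if (nrow(s) < 1) stop("at least one dispatch site is required")

  pop <- as.matrix(z[, ab$column])
  if (any(pop < 0)) {
    stop("negative population count in zone(s): ",
         paste(z$zone_id[rowSums(pop < 0) > 0], collapse = ", "))
  }
  if (any(h$dtn_min < 0, na.rm = TRUE)) stop("negative door-to-needle time")
  tsc <- as.logical(h$tsc)
  bad_dtg <- (tsc & is.na(h$dtg_min)) | (!tsc & !is.na(h$dtg_min))
  if (any(bad_dtg)) {
    stop("door-to-groin must be present iff tsc; offending hospital(s): ",
         paste(h$hospital_id[bad_dtg], collapse = ", "))
  }
  bad_dido <- (!tsc & is.na(h$dido_min)) | (tsc & !is.na(h$dido_min))
  if (any(bad_dido)) {
    stop("door-in-door-out must be present iff not tsc; offending hospital(s): ",
         paste(h$hospital_id[bad_dido], collapse = ", "))
  }
  if (any(c(h$dtg_min, h$dido_min) < 0, na.rm = TRUE)) {
    stop("negative in-hospital workflow time")
  }

  if (any(tr$minutes < 0)) {
    i <- which(tr$minutes < 0)[1]
    stop("negative travel time in row ", i, " (", tr$from_id[i], " -> ",
         tr$to_id[i], ")")
  }
  known <- c(z$zone_id, h$hospital_id, s$site_id)
  dangling <- !(tr$from_id %in% known) | !(tr$to_id %in% known)
  if (any(dangling)) {
    i <- which(dangling)[1]
    stop("travel row ", i, " references unknown id (", tr$from_id[i], " -> ",
         tr$to_id[i], ")")
  }

  lk <- region$travel_lookup
  sz <- expand.grid(from = s$site_id, to = z$zone_id,
                    stringsAsFactors = FALSE)
  miss <- is.na(lk[travel_key(sz$from, sz$to)])
  if (any(miss)) {
    stop("travel table missing (site, zone) pair(s): ",
         paste(paste0("(", sz$from[miss], ", ", sz$to[miss], ")")[seq_len(min(5, sum(miss)))],
               collapse = ", "))
  }
  zh <- expand.grid(from = z$zone_id, to = h$hospital_id,
                    stringsAsFactors = FALSE)
  miss <- is.na(lk[travel_key(zh$from, zh$to)])
  if (any(miss)) {
    stop("travel table missing (zone, hospital) pair(s): ",
         paste(paste0("(", zh$from[miss], ", ", zh$to[miss], ")")[seq_len(min(5, sum(miss)))],
               collapse = ", "))
  }
  invisible(region)
}

# Approximate national 5-year age structure (shares, youngest to 95+),
# normalised at use.
.default_age_shares <- c(
  0.049, 0.052, 0.053, 0.058, 0.063, 0.065, 0.064, 0.060, 0.058, 0.063,
  0.071, 0.070, 0.063, 0.055, 0.052, 0.040, 0.027, 0.016, 0.008, 0.003)

# Largest-remainder rounding of non-negative weights to integers summing to
# `total`.
apportion <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Generate a synthetic study region
#'
#' Builds a stand-in for a real region description (postal-code populations,
#' stroke-center locations, ambulance dispatch sites, driving times): zones
#' scattered on a planar square with population density decaying away from an
#' urban core, an approximately national age structure with zone-level
#' jitter, primary and thrombectomy-capable stroke centers with
#' hospital-specific workflow times, and travel times derived from Euclidean
#' distance at a mean road speed inflated by a detour factor (a standard
#' road-network approximation). Defaults emulate a region of 1.77 million
#' inhabitants over about 1,600 km2 served by 7 primary stroke centers and 2
#' thrombectomy-capable centers.
#'
#' @param n_zones number of zones (>= 1)
#' @param n_psc number of primary stroke centers
#' @param n_tsc number of thrombectomy-capable stroke centers
#'   (`n_psc + n_tsc >= 1`)
#' @param total_population total inhabitants apportioned across zones
#' @param area_km2 region area; zones are placed on a square of this area
#' @param density_decay_km e-folding distance of population density away
#'   from the urban core
#' @param speed_kmh mean road speed (> 0)
#' @param detour_factor ratio of road distance to straight-line distance
#' @param n_sites number of EMS dispatch sites (all MSU-capable)
#' @param seed RNG seed; the same seed reproduces the region exactly
#' @return a `msu_region` object
#' @export
generate_synthetic_region <- function(n_zones = 60, n_psc = 7, n_tsc = 2,
                                      total_population = 1.77e6,
                                      area_km2 = 1592,
                                      density_decay_km = 12,
                                      speed_kmh = 60, detour_factor = 1.3,
                                      n_sites = 3, seed = 1L) {
  if (n_zones < 1) stop("n_zones must be >= 1")
  if (n_psc < 0 || n_tsc < 0 || n_psc + n_tsc < 1) {
    stop("need at least one hospital (n_psc + n_tsc >= 1)")
  }
  if (speed_kmh <= 0) stop("speed_kmh must be > 0")
  if (n_sites < 1) stop("n_sites must be >= 1")
  set.seed(seed)

  side <- sqrt(area_km2)
  core <- c(side / 2, side / 2)
  ab <- age_bands()

  zx <- stats::runif(n_zones, 0, side)
  zy <- stats::runif(n_zones, 0, side)
  d_core <- sqrt((zx - core[1])^2 + (zy - core[2])^2)
  w <- exp(-d_core / density_decay_km) + 0.05
  zone_pop <- apportion(w, round(total_population))

  shares <- .default_age_shares / sum(.default_age_shares)
  pop <- matrix(0L, n_zones, 20)
  for (i in seq_len(n_zones)) {
    jitter <- stats::rgamma(20, shape = 60, rate = 60)  # mild heterogeneity
    pop[i, ] <- apportion(shares * jitter, zone_pop[i])
  }
  colnames(pop) <- ab$column
  zones <- data.frame(zone_id = sprintf("Z%03d", seq_len(n_zones)),
                      x_km = zx, y_km = zy, stringsAsFactors = FALSE)
  zones <- cbind(zones, as.data.frame(pop))

  n_h <- n_psc + n_tsc
  # TSCs sit near the urban core, PSCs spread over the region
  hx <- c(core[1] + stats::rnorm(n_tsc, 0, density_decay_km / 3),
          stats::runif(n_psc, 0.1 * side, 0.9 * side))
  hy <- c(core[2] + stats::rnorm(n_tsc, 0, density_decay_km / 3),
          stats::runif(n_psc, 0.1 * side, 0.9 * side))
  tsc <- c(rep(TRUE, n_tsc), rep(FALSE, n_psc))
  hospitals <- data.frame(
    hospital_id = sprintf("H%02d", seq_len(n_h)),
    x_km = pmin(pmax(hx, 0), side), y_km = pmin(pmax(hy, 0), side),
    tsc = tsc,
    dtn_min = round(stats::runif(n_h, 22, 35), 1),
    dtg_min = ifelse(tsc, round(stats::runif(n_h, 50, 80), 1), NA_real_),
    dido_min = ifelse(!tsc, round(stats::runif(n_h, 45, 90), 1), NA_real_),
    stringsAsFactors = FALSE)

  # first site near the core (default MSU base), others spread out
  sx <- c(core[1] + stats::rnorm(1, 0, density_decay_km / 2),
          stats::runif(n_sites - 1, 0.1 * side, 0.9 * side))
  sy <- c(core[2] + stats::rnorm(1, 0, density_decay_km / 2),
          stats::runif(n_sites - 1, 0.1 * side, 0.9 * side))
  sites <- data.frame(site_id = LETTERS[seq_len(n_sites)],
                      x_km = pmin(pmax(sx, 0), side),
                      y_km = pmin(pmax(sy, 0), side),
                      msu_capable = rep(TRUE, n_sites),
                      stringsAsFactors = FALSE)

  minutes_between <- function(x1, y1, x2, y2) {
    sqrt((x1 - x2)^2 + (y1 - y2)^2) / speed_kmh * 60 * detour_factor
  }
  pairs <- function(a, b) {
    g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    data.frame(from_id = a[[1]][g$i], to_id = b[[1]][g$j],
               minutes = minutes_between(a$x_km[g$i], a$y_km[g$i],
                                         b$x_km[g$j], b$y_km[g$j]),
               stringsAsFactors = FALSE)
  }
  travel <- rbind(pairs(sites, zones),        # site -> zone (required)
                  pairs(zones, hospitals),    # zone -> hospital (required)
                  pairs(sites, hospitals),    # optional extras used by the
                  pairs(hospitals, hospitals))# busy model and transfers
  travel$minutes <- round(travel$minutes, 2)

  new_region(zones, hospitals, sites, travel)
}

#' Nearest qualifying hospital for a zone
#'
#' Returns the hospital minimising zone-to-hospital travel time among
#' qualifying hospitals (all hospitals, or thrombectomy-capable centers only
#' when `require_tsc`). Ties are broken by lexicographic `hospital_id` order
#' so results are deterministic.
#'
#' @param region a `msu_region`
#' @param zone_id a zone id
#' @param require_tsc restrict to thrombectomy-capable centers
#' @return one-row data.frame (the hospital record)
#' @export
nearest_hospital <- function(region, zone_id, require_tsc = FALSE) {
  h <- region$hospitals
  if (require_tsc) h <- h[as.logical(h$tsc), , drop = FALSE]
  if (nrow(h) == 0) {
    stop("no qualifying hospital",
         if (require_tsc) " (region has no thrombectomy-capable center)")
  }
  mins <- travel_time(region, rep(zone_id, nrow(h)), h$hospital_id)
  ord <- order(mins, h$hospital_id)
  h[ord[1], , drop = FALSE]
}

# Per-zone routing table used by the time and dispatch engines: nearest
# stroke center of any kind and nearest thrombectomy-capable center.
region_routing <- function(region) {
  z <- region$zones$zone_id
  any_tsc <- any(as.logical(region$hospitals$tsc))
  rows <- lapply(z, function(zid) {
    hn <- nearest_hospital(region, zid, require_tsc = FALSE)
    out <- data.frame(zone_id = zid,
                      near_id = hn$hospital_id,
                      near_is_tsc = as.logical(hn$tsc),
                      near_min = travel_time(region, zid, hn$hospital_id),
                      near_dtn = hn$dtn_min,
                      near_dtg = hn$dtg_min,
                      near_dido = hn$dido_min,
                      stringsAsFactors = FALSE)
    if (any_tsc) {
      ht <- nearest_hospital(region, zid, require_tsc = TRUE)
      out$tsc_id <- ht$hospital_id
      out$tsc_min <- travel_time(region, zid, ht$hospital_id)
      out$tsc_dtg <- ht$dtg_min
      # transfer leg: PSC -> TSC driving time when available in the travel
      # table, otherwise the zone -> TSC time as a documented fallback
      out$transfer_min <- if (!out$near_is_tsc &&
                              has_travel_time(region, out$near_id, out$tsc_id)) {
        travel_time(region, out$near_id, out$tsc_id)
      } else {
        out$tsc_min
      }
    } else {
      out$tsc_id <- NA_character_; out$tsc_min <- NA_real_
      out$tsc_dtg <- NA_real_; out$transfer_min <- NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Write a region to delimited files
#'
#' Writes `zones.csv`, `hospitals.csv`, `sites.csv` and `travel.csv` into a
#' directory. The round trip through [read_region()] reproduces the region
#' exactly.
#'
#' @param region a `msu_region`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_region <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(region$zones, file.path(dir, "zones.csv"),
                   row.names = FALSE)
  h <- region$hospitals
  h$tsc <- as.integer(h$tsc)
  utils::write.csv(h, file.path(dir, "hospitals.csv"), row.names = FALSE)
  s <- region$sites
  s$msu_capable <- as.integer(s$msu_capable)
  utils::write.csv(s, file.path(dir, "sites.csv"), row.names = FALSE)
  utils::write.csv(region$travel, file.path(dir, "travel.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a region from delimited files
#'
#' @param dir directory containing `zones.csv`, `hospitals.csv`, `sites.csv`
#'   and `travel.csv` with the documented headers
#' @return a validated `msu_region`
#' @export
read_region <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing region file: ", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  zones <- rd("zones.csv")
  hospitals <- rd("hospitals.csv")
  if ("tsc" %in% names(hospitals)) hospitals$tsc <- hospitals$tsc != 0
  sites <- rd("sites.csv")
  if ("msu_capable" %in% names(sites)) {
    sites$msu_capable <- sites$msu_capable != 0
  }
  travel <- rd("travel.csv")
  new_region(zones, hospitals, sites, travel)
}

#' @export
print.msu_region <- function(x, ...) {
  ab <- age_bands()
  total <- sum(as.matrix(x$zones[, ab$column]))
  cat("Study region:", nrow(x$zones), "zones,",
      formatC(total, big.mark = ",", format = "d"), "inhabitants\n")
  cat("  hospitals:", sum(!x$hospitals$tsc), "PSC,",
      sum(as.logical(x$hospitals$tsc)), "TSC\n")
  cat("  dispatch sites:", paste(x$sites$site_id, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a region
#'
#' @param object a `msu_region`
#' @param ... unused
#' @return list with total population, zone/hospital/site counts
#' @export
summary.msu_region <- function(object, ...) {
  ab <- age_bands()
  list(total_population = sum(as.matrix(object$zones[, ab$column])),
       n_zones = nrow(object$zones),
       n_psc = sum(!as.logical(object$hospitals$tsc)),
       n_tsc = sum(as.logical(object$hospitals$tsc)),
       n_sites = nrow(object$sites))
}
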