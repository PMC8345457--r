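#' Field (cultivated polygon) definition
#'
#' A field is a simple (non-self-intersecting) polygon carrying a crop
#' schedule and two adjustable bands: an inner band just inside the boundary
#' (in-field margin) and an outer band just outside (off-field margin
#' receiving drift).
#'
#' @param field_id unique identifier.
#' @param polygon two-column matrix of vertices (x, y), open or closed ring.
#' @param crop_schedule data frame with columns `crop`, `start_day`, `end_day`
#'   (non-overlapping intervals), or `NULL`.
#' @param inner_band_width,outer_band_width band widths (landscape units, >= 0).
#' @return an object of class `lagopop_field`.
#' @export
field <- function(field_id, polygon, crop_schedule = NULL,
                  inner_band_width = 0, outer_band_width = 0) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2) stop_config("polygon must have two columns (x, y)")
  # drop a closing vertex if present
  n <- nrow(polygon)
  if (n > 1 && all(polygon[1, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3) stop_config("field %s: polygon needs >= 3 vertices", field_id)
  if (inner_band_width < 0 || outer_band_width < 0)
    stop_config("band widths must be >= 0")
  a <- polygon_area(polygon)
  if (a <= 0) stop_config("field %s: polygon has non-positive area", field_id)
  if (!is.null(crop_schedule)) {
    crop_schedule <- as.data.frame(crop_schedule)
    stopifnot(all(c("crop", "start_day", "end_day") %in% names(crop_schedule)))
    o <- order(crop_schedule$start_day)
    cs <- crop_schedule[o, ]
    if (any(cs$end_day < cs$start_day) ||
        (nrow(cs) > 1 && any(cs$start_day[-1] <= cs$end_day[-nrow(cs)])))
      stop_config("field %s: crop intervals overlap or are inverted", field_id)
  }
  structure(list(field_id = field_id, polygon = polygon,
                 crop_schedule = crop_schedule,
                 inner_band_width = inner_band_width,
                 outer_band_width = outer_band_width,
                 is_rect = is_axis_rect(polygon)),
            class = "lagopop_field")
}

#' Rectangular field helper
#'
#' Convenience constructor for the axis-aligned rectangular fields used in
#' generic assessments.
#'
#' @param field_id identifier.
#' @param xmin,ymin,xmax,ymax rectangle corners.
#' @param ... passed to [field()].
#' @return a [field()] object.
#' @export
rect_field <- function(field_id, xmin, ymin, xmax, ymax, ...) {
  field(field_id, cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)),
        ...)
}

#' Landscape: a collection of fields
#'
#' @param fields list of [field()] objects. A point lying in several fields is
#'   assigned to the first field in declaration order.
#' @param extent optional bounding rectangle `c(xmin, ymin, xmax, ymax)`;
#'   computed from the fields when omitted.
#' @return an object of class `lagopop_landscape`.
#' @export
landscape <- function(fields = list(), extent = NULL) {
  for (f in fields) stopifnot(inherits(f, "lagopop_field"))
  ids <- vapply(fields, `[[`, character(1), "field_id")
  if (anyDuplicated(ids)) stop_config("duplicated field ids")
  if (is.null(extent)) {
    if (length(fields)) {
      xs <- do.call(rbind, lapply(fields, `[[`, "polygon"))
      pad <- max(vapply(fields, `[[`, numeric(1), "outer_band_width"))
      extent <- c(min(xs[, 1]) - pad, min(xs[, 2]) - pad,
                  max(xs[, 1]) + pad, max(xs[, 2]) + pad)
    } else extent <- c(0, 0, 1, 1)
  }
  structure(list(fields = fields, extent = extent),
            class = "lagopop_landscape")
}

#' Circular feeding area of a nest
#'
#' @param nest_id identifier.
#' @param center numeric `c(x, y)`.
#' @param radius positive radius (landscape units).
#' @return an object of class `lagopop_feeding_area`.
#' @export
feeding_area <- function(nest_id, center, radius) {
  if (radius <= 0) stop_config("feeding radius must be positive")
  structure(list(nest_id = nest_id, center = center, radius = radius),
            class = "lagopop_feeding_area")
}

# ---- planar geometry helpers (base R; no planar-GIS package is available) --

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

is_axis_rect <- function(p) {
  nrow(p) == 4 &&
    length(unique(p[, 1])) == 2 && length(unique(p[, 2])) == 2
}

# Even-odd rule point-in-polygon, vectorised over points.
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Euclidean distance from points to the polygon boundary.
dist_to_boundary <- function(px, py, poly) {
  d2 <- rep(Inf, length(px))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    L2 <- vx * vx + vy * vy
    t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
    dx <- px - (ax + t * vx); dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
    j <- i
  }
  sqrt(d2)
}

# Zone classification of points for one field: "core", "inner", "outer" or NA
# (not related to this field). Rectangles use rectangular offsets so band
# rings are rectangles themselves; general polygons use Euclidean distance to
# the boundary (exact erosion/dilation for convex shapes).
classify_field_zone <- function(px, py, fld) {
  wi <- fld$inner_band_width; wo <- fld$outer_band_width
  out <- rep(NA_character_, length(px))
  if (fld$is_rect) {
    x1 <- min(fld$polygon[, 1]); x2 <- max(fld$polygon[, 1])
    y1 <- min(fld$polygon[, 2]); y2 <- max(fld$polygon[, 2])
    inside <- px >= x1 & px <= x2 & py >= y1 & py <= y2
    core <- px >= x1 + wi & px <= x2 - wi & py >= y1 + wi & py <= y2 - wi
    expanded <- px >= x1 - wo & px <= x2 + wo & py >= y1 - wo & py <= y2 + wo
    out[expanded] <- "outer"
    out[inside] <- "inner"
    out[inside & core] <- "core"
  } else {
    inside <- points_in_polygon(px, py, fld$polygon)
    d <- dist_to_boundary(px, py, fld$polygon)
    out[!inside & d <= wo] <- "outer"
    out[inside] <- ifelse(d[inside] > wi, "core", "inner")
  }
  if (wo == 0) out[out == "outer"] <- NA_character_
  out
}

#' Partition a field into core, inner band and outer band
#'
#' The inner band is the ring of `inner_band_width` just inside the field
#' boundary, the core the remainder of the field, and the outer band the ring
#' of `outer_band_width` just outside. Core and inner band together tile the
#' field. For axis-aligned rectangular fields the ring areas are analytic
#' (rectangular offsets); for general polygons they are estimated by
#' classifying a grid of cell centers at the given resolution.
#'
#' @param fld a [field()] object.
#' @param resolution grid spacing for non-rectangular fields (default: 1/200
#'   of the smaller bounding-box dimension).
#' @return list with `areas` (named: core, inner, outer) and `classify`, a
#'   `function(x, y)` returning the zone of each point (or `NA`).
#' @export
zone_partition <- function(fld, resolution = NULL) {
  stopifnot(inherits(fld, "lagopop_field"))
  wi <- fld$inner_band_width; wo <- fld$outer_band_width
  x1 <- min(fld$polygon[, 1]); x2 <- max(fld$polygon[, 1])
  y1 <- min(fld$polygon[, 2]); y2 <- max(fld$polygon[, 2])
  if (2 * wi >= min(x2 - x1, y2 - y1))
    stop_config("field %s: inner band width %g leaves no core (field %g x %g)",
                fld$field_id, wi, x2 - x1, y2 - y1)
  if (fld$is_rect) {
    full <- (x2 - x1) * (y2 - y1)
    core <- (x2 - x1 - 2 * wi) * (y2 - y1 - 2 * wi)
    outer <- (x2 - x1 + 2 * wo) * (y2 - y1 + 2 * wo) - full
    areas <- c(core = core, inner = full - core, outer = outer)
  } else {
    res <- resolution %||% (min(x2 - x1, y2 - y1) / 200)
    gx <- seq(x1 - wo + res / 2, x2 + wo, by = res)
    gy <- seq(y1 - wo + res / 2, y2 + wo, by = res)
    pts <- expand.grid(x = gx, y = gy)
    z <- classify_field_zone(pts$x, pts$y, fld)
    cell <- res * res
    areas <- c(core = sum(z == "core", na.rm = TRUE) * cell,
               inner = sum(z == "inner", na.rm = TRUE) * cell,
               outer = sum(z == "outer", na.rm = TRUE) * cell)
  }
  list(areas = areas,
       classify = function(x, y) classify_field_zone(x, y, fld))
}

#' Overlap of a feeding area with landscape zones
#'
#' Rasterizes the feeding disc at the given resolution and classifies each
#' cell center against the landscape (first field in declaration order wins
#' where fields overlap). Zone labels are `"<field_id>:core"`,
#' `"<field_id>:inner"`, `"<field_id>:outer"` and `"background"`.
#'
#' @param area a [feeding_area()].
#' @param land a [landscape()].
#' @param resolution cell size; default `radius / 100`. Must be smaller than
#'   the radius. Fraction error is of order `resolution / radius`.
#' @return named numeric vector of area fractions summing to 1.
#' @export
feeding_zone_overlap <- function(area, land, resolution = area$radius / 100) {
  stopifnot(inherits(area, "lagopop_feeding_area"),
            inherits(land, "lagopop_landscape"))
  if (resolution >= area$radius)
    stop_config("resolution (%g) must be well below the feeding radius (%g)",
                resolution, area$radius)
  r <- area$radius; cx <- area$center[1]; cy <- area$center[2]
  g <- seq(-r + resolution / 2, r, by = resolution)
  pts <- expand.grid(dx = g, dy = g)
  pts <- pts[pts$dx^2 + pts$dy^2 <= r^2, ]
  px <- cx + pts$dx; py <- cy + pts$dy
  zone <- rep("background", length(px))
  unassigned <- rep(TRUE, length(px))
  for (fld in land$fields) {
    if (!any(unassigned)) break
    z <- classify_field_zone(px[unassigned], py[unassigned], fld)
    hit <- !is.na(z)
    if (any(hit)) {
      idx <- which(unassigned)[hit]
      zone[idx] <- paste0(fld$field_id, ":", z[hit])
      unassigned[idx] <- FALSE
    }
  }
  tab <- table(zone)
  fr <- as.numeric(tab) / length(px)
  names(fr) <- names(tab)
  fr
}

#' Diet fractions over landscape zones
#'
#' Combines zone area fractions with relative food availability weights:
#' the diet fraction of a (zone, food item) pair is proportional to
#' `area_fraction * weight`, normalized to sum to one. With all weights equal
#' the diet is purely area-proportional.
#'
#' @param area_fractions named vector from [feeding_zone_overlap()].
#' @param food_weights data frame with columns `zone`, `food_item`, `weight`
#'   (non-negative). Zones absent from `area_fractions` are dropped.
#' @return data frame with columns `zone`, `food_item`, `fraction` summing to
#'   one.
#' @export
diet_fractions <- function(area_fractions, food_weights) {
  food_weights <- as.data.frame(food_weights)
  stopifnot(all(c("zone", "food_item", "weight") %in% names(food_weights)))
  if (any(food_weights$weight < 0)) stop_config("food weights must be >= 0")
  fw <- food_weights[food_weights$zone %in% names(area_fractions), ]
  raw <- fw$weight * area_fractions[fw$zone]
  tot <- sum(raw)
  if (!length(raw) || tot <= 0)
    stop_config("no food available in any occupied zone")
  data.frame(zone = fw$zone, food_item = fw$food_item,
             fraction = as.numeric(raw / tot), row.names = NULL)
}
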