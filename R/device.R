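#' Wick specification
#'
#' Describes the porous wick of an atomizer, either as a cylinder (lateral
#' surface area is derived as pi * diameter * length) or by a directly
#' measured outer surface area. Dual builds carry one physical wick per
#' coil, so `wick_count = 2`.
#'
#' @param kind `"cylinder"` or `"measured"`.
#' @param diameter Wick diameter in mm (cylinder only).
#' @param length Wick length in mm (cylinder only).
#' @param area Measured outer surface area in mm^2 (measured only).
#' @param count Number of physical wicks (1 for single/parallel, 2 for dual).
#' @return An object of class `wick_spec`.
#' @examples
#' wick_spec("cylinder", diameter = 3, length = 10)
#' wick_spec("measured", area = 50)
#' @export
wick_spec <- function(kind = c("cylinder", "measured"),
                      diameter = NULL, length = NULL, area = NULL,
                      count = 1L) {
  kind <- match.arg(kind)
  count <- as.integer(count)
  if (is.na(count) || count < 1L)
    stop("wick `count` must be a positive integer", call. = FALSE)
  if (kind == "cylinder") {
    if (is.null(diameter) || is.null(length) ||
        !is.finite(diameter) || !is.finite(length) ||
        diameter <= 0 || length <= 0)
      stop("cylinder wick requires positive `diameter` and `length` (mm)",
           call. = FALSE)
    area <- pi * diameter * length
  } else {
    if (is.null(area) || !is.finite(area) || area <= 0)
      stop("measured wick requires positive `area` (mm^2)", call. = FALSE)
    diameter <- NA_real_
    length <- NA_real_
  }
  structure(
    list(kind = kind, diameter = diameter, length = length,
         area_per_wick = area, count = count),
    class = "wick_spec"
  )
}

#' Coil specification
#'
#' Describes the heating coil: style (`single` = one wire, `parallel` = two
#' wires sharing one wick, `dual` = two independently wrapped coil+wick
#' units), orientation relative to airflow, per-wire length, and wraps
#' (turns per coil). Parallel and dual builds contain two identical wires.
#'
#' @param style `"single"`, `"parallel"` or `"dual"`.
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param wire_length Length of one wire in mm.
#' @param wraps Number of turns per coil (integer >= 1).
#' @param material Optional wire material (metadata).
#' @param gauge Optional wire gauge (metadata).
#' @return An object of class `coil_spec`.
#' @examples
#' coil_spec("dual", "horizontal", wire_length = 98.04, wraps = 8)
#' @export
coil_spec <- function(style = c("single", "parallel", "dual"),
                      orientation = c("horizontal", "vertical"),
                      wire_length, wraps,
                      material = NA_character_, gauge = NA_real_) {
  style <- match.arg(style)
  orientation <- match.arg(orientation)
  if (!is.finite(wire_length) || wire_length <= 0)
    stop("`wire_length` must be positive (mm)", call. = FALSE)
  wraps <- as.integer(wraps)
  if (is.na(wraps) || wraps < 1L)
    stop("`wraps` must be an integer >= 1", call. = FALSE)
  wire_count <- if (style == "single") 1L else 2L
  structure(
    list(style = style, orientation = orientation,
         wire_length = wire_length, wire_count = wire_count,
         wraps = wraps, material = material, gauge = gauge),
    class = "coil_spec"
  )
}

#' Atomizer device
#'
#' Bundles a coil, a wick and a power setting into one device record. Power
#' is the manufacturer-recommended maximum wattage at which the device is
#' operated; it is required only by score models that reference `W`.
#' For dual builds the number of physical wicks must equal the number of
#' wires (each coil is wrapped with its own wick).
#'
#' @param device_id Unique device identifier.
#' @param coil A [coil_spec()].
#' @param wick A [wick_spec()].
#' @param power Power setting in W, or `NA` if unknown.
#' @param resistance Optional coil resistance in ohm (metadata).
#' @return An object of class `atomizer_device`.
#' @examples
#' atomizer_device("EC1",
#'   coil_spec("single", "horizontal", wire_length = 100, wraps = 10),
#'   wick_spec("measured", area = 50), power = 40)
#' @export
atomizer_device <- function(device_id, coil, wick, power = NA_real_,
                            resistance = NA_real_) {
  stopifnot(inherits(coil, "coil_spec"), inherits(wick, "wick_spec"))
  if (!is.character(device_id) || length(device_id) != 1L ||
      is.na(device_id) || !nzchar(device_id))
    stop("`device_id` must be a non-empty string", call. = FALSE)
  if (!is.na(power) && power <= 0)
    stop("`power` must be positive when present", call. = FALSE)
  if (coil$style == "dual" && wick$count != coil$wire_count)
    stop("dual builds need one wick per coil (wick count ",
         wick$count, " != wire count ", coil$wire_count, ")", call. = FALSE)
  structure(
    list(device_id = device_id, coil = coil, wick = wick,
         power = as.numeric(power), resistance = as.numeric(resistance)),
    class = "atomizer_device"
  )
}

#' @export
print.atomizer_device <- function(x, ...) {
  cat(sprintf("<atomizer_device> %s: %s %s coil, %g mm x %d wire(s), %d wraps, wick %g mm^2 x %d, %s W\n",
              x$device_id, x$coil$orientation, x$coil$style,
              x$coil$wire_length, x$coil$wire_count, x$coil$wraps,
              signif(x$wick$area_per_wick, 5), x$wick$count,
              ifelse(is.na(x$power), "?", format(x$power))))
  invisible(x)
}

#' Wick outer surface area
#'
#' Total outer (lateral) surface area of the wick(s) in mm^2: the measured
#' area, or pi * diameter * length for a cylinder, summed over the number
#' of physical wicks. End caps are excluded: the wick ends abut the tank
#' and are not heated contact surface.
#'
#' @param wick A [wick_spec()].
#' @return Total area in mm^2.
#' @examples
#' wick_outer_surface_area(wick_spec("cylinder", diameter = 2, length = 10,
#'                                   count = 2))  # 2 * 20 * pi
#' @export
wick_outer_surface_area <- function(wick) {
  stopifnot(inherits(wick, "wick_spec"))
  wick$area_per_wick * wick$count
}

#' Effective device geometry
#'
#' Aggregates a multi-wire build into the three geometry variables of the
#' score models: total coil length L (mm), total wick outer surface area SA
#' (mm^2) and wraps n (turns per coil). Under the default `"sum_wires"`
#' convention, wire lengths sum over wires and wick areas sum over wicks
#' while wraps stay per-coil, so a dual device made of two identical
#' single-coil halves scores exactly like one half. The `"per_coil"`
#' convention divides the summed length and area by the number of wires,
#' for inventories that record totals per coil already.
#'
#' @param device An [atomizer_device()].
#' @param aggregation `"sum_wires"` (default) or `"per_coil"`.
#' @return Named list with `L` (mm), `SA` (mm^2), `n` (wraps).
#' @export
effective_geometry <- function(device,
                               aggregation = c("sum_wires", "per_coil")) {
  stopifnot(inherits(device, "atomizer_device"))
  aggregation <- match.arg(aggregation)
  L <- device$coil$wire_length * device$coil$wire_count
  SA <- wick_outer_surface_area(device$wick)
  if (aggregation == "per_coil") {
    L <- L / device$coil$wire_count
    SA <- SA / device$coil$wire_count
  }
  list(L = L, SA = SA, n = device$coil$wraps)
}

#' Wire length of a tight helix
#'
#' Convenience for users who measured wrap geometry instead of unwound wire
#' length: a tight helix of negligible pitch has circumferential length
#' wraps * pi * (core_diameter + wire_diameter).
#'
#' @param core_diameter Diameter of the winding core (mm).
#' @param wire_diameter Diameter of the wire (mm).
#' @param wraps Number of turns.
#' @return Wire length in mm.
#' @examples
#' helix_wire_length(2.5, 0.3, 8)  # 8 * pi * 2.8
#' @export
helix_wire_length <- function(core_diameter, wire_diameter, wraps) {
  if (!is.finite(core_diameter) || core_diameter <= 0 ||
      !is.finite(wire_diameter) || wire_diameter <= 0 ||
      !is.finite(wraps) || wraps <= 0)
    stop("all helix inputs must be positive", call. = FALSE)
  wraps * pi * (core_diameter + wire_diameter)
}

# ---- fleet container and CSV interface ---------------------------------

#' Construct a fleet from a list of devices
#'
#' @param devices List of [atomizer_device()] objects with unique ids.
#' @return An object of class `atomizer_fleet` (a named list of devices).
#' @export
atomizer_fleet <- function(devices) {
  stopifnot(all(vapply(devices, inherits, logical(1), "atomizer_device")))
  ids <- vapply(devices, `[[`, character(1), "device_id")
  if (anyDuplicated(ids))
    stop("duplicate device_id in fleet: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(stats::setNames(devices, ids), class = "atomizer_fleet")
}

#' @export
print.atomizer_fleet <- function(x, ...) {
  cat(sprintf("<atomizer_fleet> %d device(s)\n", length(x)))
  for (d in x) print(d)
  invisible(x)
}

#' @export
as.data.frame.atomizer_fleet <- function(x, ...) {
  do.call(rbind, lapply(unclass(x), function(d) {
    data.frame(
      device_id = d$device_id,
      coil_style = d$coil$style,
      orientation = d$coil$orientation,
      wire_length_mm = d$coil$wire_length,
      wire_count = d$coil$wire_count,
      wraps = d$coil$wraps,
      wick_kind = d$wick$kind,
      wick_diameter_mm = d$wick$diameter,
      wick_length_mm = d$wick$length,
      wick_area_mm2 = d$wick$area_per_wick,
      wick_count = d$wick$count,
      power_w = d$power,
      resistance_ohm = d$resistance,
      stringsAsFactors = FALSE
    )
  }))
}

#' Read a device inventory from CSV
#'
#' Expected columns: `device_id, coil_style, orientation, wire_length_mm,
#' wire_count, wraps, wick_kind, wick_diameter_mm, wick_length_mm,
#' wick_area_mm2, wick_count, power_w, resistance_ohm`. Blank cells are
#' permitted only where the wick kind makes them inapplicable (e.g. no
#' diameter for a measured wick); anything else fails loudly with the row
#' number.
#'
#' @param path Path to a CSV file.
#' @return An `atomizer_fleet`.
#' @export
read_devices <- function(path) {
  if (!file.exists(path)) stop("devices file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("device_id", "coil_style", "orientation", "wire_length_mm",
                "wraps", "wick_kind", "wick_count", "power_w")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("devices file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  devices <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    wk <- tryCatch({
      if (identical(row$wick_kind, "cylinder")) {
        wick_spec("cylinder", diameter = row$wick_diameter_mm,
                  length = row$wick_length_mm, count = row$wick_count)
      } else if (identical(row$wick_kind, "measured")) {
        wick_spec("measured", area = row$wick_area_mm2,
                  count = row$wick_count)
      } else {
        stop("unknown wick_kind: ", row$wick_kind, call. = FALSE)
      }
    }, error = function(e) {
      stop("devices file row ", i, " (", row$device_id, "): ",
           conditionMessage(e), call. = FALSE)
    })
    tryCatch({
      cl <- coil_spec(row$coil_style, row$orientation,
                      wire_length = row$wire_length_mm, wraps = row$wraps)
      atomizer_device(as.character(row$device_id), cl, wk,
                      power = if ("power_w" %in% names(row))
                        row$power_w else NA_real_,
                      resistance = if ("resistance_ohm" %in% names(row))
                        row$resistance_ohm else NA_real_)
    }, error = function(e) {
      stop("devices file row ", i, " (", row$device_id, "): ",
           conditionMessage(e), call. = FALSE)
    })
  })
  atomizer_fleet(devices)
}

#' Write a device inventory to CSV
#'
#' Inverse of [read_devices()]; round-trips a fleet exactly.
#'
#' @param fleet An `atomizer_fleet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_devices <- function(fleet, path) {
  stopifnot(inherits(fleet, "atomizer_fleet"))
  utils::write.csv(as.data.frame(fleet), path, row.names = FALSE, na = "")
  invisible(path)
}
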