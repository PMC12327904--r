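#' @importFrom stats quantile rmultinom runif setNames
#' @importFrom utils head modifyList
NULL

# Column contracts for the delimited-text region layers. Readers check these
# before anything else so failures name the file and the missing column.
.region_schemas <- list(
  municipalities = c("id", "name", "population", "aging_rate", "land_area_km2", "pop_75plus"),
  meshes         = c("id", "municipality_id", "center_x", "center_y", "size_m", "pop_75plus"),
  facilities     = c("id", "kind", "x", "y", "is_provider"),
  network_nodes  = c("id", "x", "y"),
  network_edges  = c("u", "v", "length_m", "speed_kmh", "road_class")
)

#' Construct a road network
#'
#' An undirected road network given as node and edge tables. Coordinates are
#' planar projected meters. Edge travel time in minutes is
#' `length_m / (speed_kmh * 1000 / 60)`.
#'
#' @param nodes tibble with columns `id`, `x`, `y` (meters).
#' @param edges tibble with columns `u`, `v`, `length_m`, `speed_kmh`,
#'   `road_class`.
#' @return An object of class `road_network`.
#' @export
road_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  nodes$id <- as.character(nodes$id)
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  structure(list(nodes = nodes, edges = edges), class = "road_network")
}

#' Edge travel times of a network
#'
#' @param network a `road_network`.
#' @return numeric vector of per-edge travel times in minutes.
#' @export
edge_travel_time_min <- function(network) {
  with(network$edges, length_m / (speed_kmh * 1000 / 60))
}

#' Assemble a study region
#'
#' Bundles the four layers of a study region: municipality attributes, the
#' population mesh for ages >= 75, the facility registry with its nested
#' provider subset, and the road network. All coordinates are planar meters.
#'
#' @param municipalities tibble: `id`, `name`, `population`, `aging_rate`
#'   (fraction in \[0,1\]), `land_area_km2`, `pop_75plus`.
#' @param meshes tibble: `id`, `municipality_id`, `center_x`, `center_y`,
#'   `size_m`, `pop_75plus`. Cells are axis-aligned squares identified by
#'   center and size.
#' @param facilities tibble: `id`, `kind` (`"hospital"` or `"clinic"`),
#'   `x`, `y`, `is_provider` (logical). The provider subset defines the
#'   actual scenario; all facilities define the ideal scenario.
#' @param network a [road_network()].
#' @param validate run [validate_region()] and stop on violations.
#' @return An object of class `study_region`.
#' @export
study_region <- function(municipalities, meshes, facilities, network,
                         validate = TRUE) {
  region <- structure(
    list(
      municipalities = tibble::as_tibble(municipalities),
      meshes = tibble::as_tibble(meshes),
      facilities = tibble::as_tibble(facilities),
      network = network
    ),
    class = "study_region"
  )
  region$municipalities$id <- as.character(region$municipalities$id)
  region$meshes$id <- as.character(region$meshes$id)
  region$meshes$municipality_id <- as.character(region$meshes$municipality_id)
  region$facilities$id <- as.character(region$facilities$id)
  if (validate) {
    problems <- validate_region(region)
    if (length(problems) > 0) {
      stop(region_error("invalid study region", problems))
    }
  }
  region
}

#' @export
print.study_region <- function(x, ...) {
  cat("<study_region>\n")
  cat("  municipalities:", nrow(x$municipalities), "\n")
  cat("  mesh cells:    ", nrow(x$meshes),
      sprintf("(pop75 total %d)", sum(x$meshes$pop_75plus)), "\n")
  cat("  facilities:    ", nrow(x$facilities),
      sprintf("(%d providers)", sum(x$facilities$is_provider)), "\n")
  cat("  network:       ", nrow(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges\n")
  invisible(x)
}

region_error <- function(msg, problems = character()) {
  structure(
    class = c("homereach_load_error", "error", "condition"),
    list(message = paste0(
      msg,
      if (length(problems) > 0)
        paste0("\n", paste0("  - ", problems, collapse = "\n"))
    ), call = NULL, problems = problems)
  )
}

#' Validate a study region
#'
#' Checks every structural invariant of the region layers and returns the
#' violations as a character vector (empty when valid): unique ids, positive
#' land areas, `pop_75plus <= population`, every mesh cell resolving to
#' exactly one municipality, non-overlapping cells, mesh-to-municipality
#' population conservation, facility kinds restricted to hospital/clinic,
#' edge endpoints present in the node table, and edge lengths at least the
#' straight-line distance between their endpoints. Network connectivity is
#' reported as a note (`"note: ..."`) rather than a violation, since
#' disconnected components are handled downstream via reachability flags.
#'
#' @param region a `study_region` (or compatible list).
#' @return character vector of problems; `character(0)` if the region is valid.
#' @export
validate_region <- function(region) {
  p <- character()
  m <- region$municipalities
  if (anyDuplicated(m$id)) p <- c(p, "duplicate municipality ids")
  if (any(m$land_area_km2 <= 0)) p <- c(p, "municipality with land_area_km2 <= 0")
  if (any(m$population < 0) || any(m$pop_75plus < 0))
    p <- c(p, "negative municipality population")
  if (any(m$pop_75plus > m$population))
    p <- c(p, "municipality with pop_75plus > population")
  if (any(m$aging_rate < 0 | m$aging_rate > 1))
    p <- c(p, "aging_rate outside [0,1]")

  mesh <- region$meshes
  if (anyDuplicated(mesh$id)) p <- c(p, "duplicate mesh ids")
  orphan <- setdiff(unique(mesh$municipality_id), m$id)
  if (length(orphan) > 0)
    p <- c(p, paste0("mesh cells reference unknown municipality \"", orphan, "\""))
  if (any(mesh$pop_75plus < 0)) p <- c(p, "negative mesh population")
  if (any(mesh$size_m <= 0)) p <- c(p, "mesh cell with size_m <= 0")
  if (anyDuplicated(mesh[, c("center_x", "center_y")]))
    p <- c(p, "overlapping mesh cells (duplicated centers)")
  # population conservation per municipality
  agg <- tapply(mesh$pop_75plus, mesh$municipality_id, sum)
  for (id in m$id) {
    cell_sum <- if (id %in% names(agg)) unname(agg[[id]]) else 0L
    if (nrow(mesh) > 0 && cell_sum != m$pop_75plus[m$id == id]) {
      p <- c(p, paste0("mesh pop_75plus sum (", cell_sum,
                       ") != municipality pop_75plus for \"", id, "\""))
    }
  }

  f <- region$facilities
  if (nrow(f) == 0) p <- c(p, "no facilities")
  if (anyDuplicated(f$id)) p <- c(p, "duplicate facility ids")
  bad_kind <- setdiff(unique(f$kind), c("hospital", "clinic"))
  if (length(bad_kind) > 0)
    p <- c(p, paste0("facility kind outside {hospital, clinic}: \"", bad_kind, "\""))
  if (!is.logical(f$is_provider)) p <- c(p, "is_provider is not logical")

  net <- region$network
  missing_nodes <- setdiff(unique(c(net$edges$u, net$edges$v)), net$nodes$id)
  if (length(missing_nodes) > 0)
    p <- c(p, paste0("edge endpoint not in node table: \"",
                     head(missing_nodes, 5), "\""))
  if (any(net$edges$length_m <= 0)) p <- c(p, "edge with length_m <= 0")
  if (any(net$edges$speed_kmh <= 0)) p <- c(p, "edge with speed_kmh <= 0")
  if (length(missing_nodes) == 0 && nrow(net$edges) > 0) {
    xy <- setNames(split(net$nodes[, c("x", "y")], seq_len(nrow(net$nodes))),
                   net$nodes$id)
    chord <- sqrt((unlist(lapply(xy[net$edges$u], `[[`, "x")) -
                     unlist(lapply(xy[net$edges$v], `[[`, "x")))^2 +
                  (unlist(lapply(xy[net$edges$u], `[[`, "y")) -
                     unlist(lapply(xy[net$edges$v], `[[`, "y")))^2)
    if (any(net$edges$length_m < chord - 1e-6))
      p <- c(p, "edge shorter than straight-line distance between endpoints")
    g <- network_graph(net)
    comp <- igraph::components(g)
    if (comp$no > 1)
      p <- c(p, sprintf("note: network has %d connected components", comp$no))
  }
  p
}

read_region_csv <- function(path, layer) {
  if (!file.exists(path)) {
    stop(region_error(paste0("missing input file: ", path)))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(.region_schemas[[layer]], names(df))
  if (length(missing) > 0) {
    stop(region_error(paste0(
      basename(path), ": missing column(s) ", paste(missing, collapse = ", ")
    )))
  }
  df
}

read_points_geojson <- function(path, coord_names = c("x", "y")) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop(region_error(paste0(basename(path), ": not a GeoJSON FeatureCollection")))
  rows <- lapply(gj$features, function(feat) {
    props <- feat$properties
    coords <- feat$geometry$coordinates
    props[[coord_names[1]]] <- coords[[1]]
    props[[coord_names[2]]] <- coords[[2]]
    tibble::as_tibble(props)
  })
  dplyr::bind_rows(rows)
}

write_points_geojson <- function(df, path, coord_names = c("x", "y")) {
  features <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, setdiff(names(df), coord_names)])
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df[[coord_names[1]]][i],
                                      df[[coord_names[2]]][i])),
      properties = row
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
}

#' Load a study region from a directory of delimited-text layers
#'
#' Expects `municipalities.csv`, `meshes.csv`, `facilities.csv`,
#' `network_nodes.csv` and `network_edges.csv` under `dir` (UTF-8, header
#' row, the documented column names). Facilities and meshes may instead be
#' provided as GeoJSON point layers (`facilities.geojson`,
#' `meshes.geojson`); coordinates there are still planar meters.
#'
#' @param dir directory containing the layer files.
#' @return a validated [study_region()].
#' @export
load_region <- function(dir) {
  muni <- read_region_csv(file.path(dir, "municipalities.csv"), "municipalities")

  mesh_gj <- file.path(dir, "meshes.geojson")
  mesh <- if (file.exists(mesh_gj) && !file.exists(file.path(dir, "meshes.csv"))) {
    df <- read_points_geojson(mesh_gj, c("center_x", "center_y"))
    missing <- setdiff(.region_schemas$meshes, names(df))
    if (length(missing) > 0)
      stop(region_error(paste0("meshes.geojson: missing field(s) ",
                               paste(missing, collapse = ", "))))
    df
  } else {
    read_region_csv(file.path(dir, "meshes.csv"), "meshes")
  }

  fac_gj <- file.path(dir, "facilities.geojson")
  fac <- if (file.exists(fac_gj) && !file.exists(file.path(dir, "facilities.csv"))) {
    df <- read_points_geojson(fac_gj, c("x", "y"))
    missing <- setdiff(.region_schemas$facilities, names(df))
    if (length(missing) > 0)
      stop(region_error(paste0("facilities.geojson: missing field(s) ",
                               paste(missing, collapse = ", "))))
    df$is_provider <- as.logical(df$is_provider)
    df
  } else {
    read_region_csv(file.path(dir, "facilities.csv"), "facilities")
  }

  nodes <- read_region_csv(file.path(dir, "network_nodes.csv"), "network_nodes")
  edges <- read_region_csv(file.path(dir, "network_edges.csv"), "network_edges")

  region <- structure(
    list(
      municipalities = dplyr::mutate(muni, id = as.character(id)),
      meshes = dplyr::mutate(mesh, id = as.character(id),
                             municipality_id = as.character(municipality_id)),
      facilities = dplyr::mutate(fac, id = as.character(id)),
      network = road_network(nodes, edges)
    ),
    class = "study_region"
  )
  problems <- validate_region(region)
  hard <- problems[!startsWith(problems, "note:")]
  if (length(hard) > 0) {
    stop(region_error(paste0("invalid region loaded from ", dir), hard))
  }
  region
}

#' Save a study region as delimited-text layers
#'
#' Writes `municipalities.csv`, `meshes.csv`, `facilities.csv`,
#' `network_nodes.csv` and `network_edges.csv` so that [load_region()]
#' inverts the save exactly (ids and integer fields exact; coordinates at
#' full double precision). Optionally also emits the point layers as
#' GeoJSON.
#'
#' @param region a `study_region`.
#' @param dir output directory (created if absent).
#' @param geojson also write `facilities.geojson` and `meshes.geojson`.
#' @return invisibly, the paths written.
#' @export
save_region <- function(region, dir, geojson = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    municipalities = file.path(dir, "municipalities.csv"),
    meshes = file.path(dir, "meshes.csv"),
    facilities = file.path(dir, "facilities.csv"),
    network_nodes = file.path(dir, "network_nodes.csv"),
    network_edges = file.path(dir, "network_edges.csv")
  )
  readr::write_csv(region$municipalities, paths["municipalities"], progress = FALSE)
  readr::write_csv(region$meshes, paths["meshes"], progress = FALSE)
  readr::write_csv(region$facilities, paths["facilities"], progress = FALSE)
  readr::write_csv(region$network$nodes, paths["network_nodes"], progress = FALSE)
  readr::write_csv(region$network$edges, paths["network_edges"], progress = FALSE)
  if (geojson) {
    write_points_geojson(region$facilities, file.path(dir, "facilities.geojson"))
    write_points_geojson(region$meshes, file.path(dir, "meshes.geojson"),
                         c("center_x", "center_y"))
    paths <- c(paths, geojson_facilities = file.path(dir, "facilities.geojson"),
               geojson_meshes = file.path(dir, "meshes.geojson"))
  }
  invisible(paths)
}

#' Per-municipality characteristics table
#'
#' One row per municipality with population, aging rate, land area,
#' population density (`population / land_area_km2`, persons per square
#' km), optional claim counts and usage rates, plus a `Total` row whose
#' population and claim counts are column sums and whose density is
#' summed population over summed area. `density` carries the unrounded
#' value; `density_display` is rounded to one decimal for presentation.
#'
#' @param municipalities a `study_region` or a municipalities tibble.
#' @param claims_summary optional tibble with `municipality_id`, `n_claims`,
#'   `usage_rate` (as produced by [usage_summary()]).
#' @return tibble in column order: name, population, aging rate (percent),
#'   land area, density, claims, usage rate (percent).
#' @export
municipality_summary_table <- function(municipalities, claims_summary = NULL) {
  m <- if (inherits(municipalities, "study_region")) {
    municipalities$municipalities
  } else {
    tibble::as_tibble(municipalities)
  }
  if (any(m$land_area_km2 <= 0)) {
    stop(region_error("municipality with zero or negative land area"))
  }
  out <- tibble::tibble(
    municipality = m$name,
    population = m$population,
    aging_rate_pct = round(m$aging_rate * 100, 1),
    land_area_km2 = m$land_area_km2,
    density = m$population / m$land_area_km2,
    n_claims = NA_integer_,
    usage_rate_pct = NA_real_
  )
  if (!is.null(claims_summary)) {
    idx <- match(m$id, claims_summary$municipality_id)
    out$n_claims <- claims_summary$n_claims[idx]
    out$usage_rate_pct <- round(claims_summary$usage_rate[idx] * 100, 1)
  }
  total <- tibble::tibble(
    municipality = "Total",
    population = sum(out$population),
    aging_rate_pct = round(
      sum(m$aging_rate * m$population) / sum(m$population) * 100, 1),
    land_area_km2 = sum(out$land_area_km2),
    density = sum(out$population) / sum(out$land_area_km2),
    n_claims = if (all(is.na(out$n_claims))) NA_integer_ else
      sum(out$n_claims, na.rm = TRUE),
    usage_rate_pct = NA_real_
  )
  res <- dplyr::bind_rows(out, total)
  res$density_display <- round(res$density, 1)
  res
}

#' Published municipal statistics for Nara Prefecture (FY2019)
#'
#' The published per-municipality table for the 39 municipalities of Nara
#' Prefecture: population, aging rate, land area, population density, home
#' medical care claim counts, and usage rate among residents aged >= 75.
#' Shipped as packaged reference data; used for internal-consistency checks
#' (column sums, density recomputation) and as a realistic calibration
#' target for the synthetic generator.
#'
#' @param include_total keep the printed `Total` row (default `FALSE`).
#' @return tibble with columns `municipality`, `population`,
#'   `aging_rate_pct`, `land_area_km2`, `density_printed`, `n_claims`,
#'   `usage_rate_pct`.
#' @export
nara_municipal_stats <- function(include_total = FALSE) {
  path <- system.file("extdata", "nara_municipal_stats.csv", package = "homereach")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!include_total) df <- df[df$municipality != "Total", ]
  df
}
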