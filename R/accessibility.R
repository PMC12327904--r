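# igraph view of a road_network, with both cost attributes on every edge.
network_graph <- function(network) {
  edges <- network$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v,
               length_m = edges$length_m,
               time_min = edges$length_m / (edges$speed_kmh * 1000 / 60)),
    directed = FALSE,
    vertices = data.frame(name = network$nodes$id,
                          x = network$nodes$x, y = network$nodes$y)
  )
  g
}

#' Travel-cost model for closest-facility analysis
#'
#' Controls how the cost of reaching a patient is measured. The default —
#' network metric, minimized travel time, snap legs excluded — reflects the
#' closest-facility convention: patients and facilities are snapped to
#' their Euclidean-nearest network node, the facility minimizing network
#' travel time is chosen, and both the minutes and the meters of that same
#' optimal path are reported. Setting `objective = "distance"` minimizes
#' path length instead. With `access_leg = "straight_line"`, the
#' straight-line snap distances at both ends are added to the reported
#' distance, and their traversal at `access_speed_kmh` to the reported
#' time, after the facility has been chosen on network cost.
#'
#' @param metric `"network"` (shortest path on the road graph) or
#'   `"euclidean"` (straight line, diagnostic baseline).
#' @param objective `"time"` (minutes, default) or `"distance"` (meters).
#' @param access_leg `"excluded"` (default) or `"straight_line"`.
#' @param access_speed_kmh speed used for the straight-line legs and for
#'   converting Euclidean distance to time (km/h).
#' @return an object of class `cost_model`.
#' @export
cost_model <- function(metric = c("network", "euclidean"),
                       objective = c("time", "distance"),
                       access_leg = c("excluded", "straight_line"),
                       access_speed_kmh = 40) {
  stopifnot(access_speed_kmh > 0)
  structure(
    list(metric = match.arg(metric), objective = match.arg(objective),
         access_leg = match.arg(access_leg),
         access_speed_kmh = access_speed_kmh),
    class = "cost_model"
  )
}

#' Snap points to their nearest network node
#'
#' Euclidean-nearest node for each point; exact ties broken by the smallest
#' node id (lexicographic).
#'
#' @param points tibble with `x`, `y`.
#' @param network a [road_network()].
#' @return tibble with `node_id`, `snap_distance_m`, one row per point.
#' @export
snap_to_network <- function(points, network) {
  nodes <- network$nodes[order(network$nodes$id), , drop = FALSE]
  if (nrow(nodes) == 0) stop(region_error("cannot snap to an empty network"))
  nx <- nodes$x; ny <- nodes$y
  idx <- integer(nrow(points)); d <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (nx - points$x[i])^2 + (ny - points$y[i])^2
    j <- which.min(d2)       # first minimum = smallest id after the sort
    idx[i] <- j; d[i] <- sqrt(d2[j])
  }
  tibble::tibble(node_id = nodes$id[idx], snap_distance_m = d)
}

#' Closest facility and its network travel cost, per patient
#'
#' For every patient point, finds the facility minimizing the cost model's
#' objective over the road network, via a shortest-path query from all
#' facility nodes at once, and reports the travel time (minutes) and
#' distance (meters) of that same optimal path. Facilities anywhere in the
#' region are eligible — not only those in the patient's municipality.
#' Patients with no route to any facility are retained with
#' `reachable = FALSE` and infinite costs rather than dropped.
#'
#' Ties are broken by the smallest facility id; among equal-cost optimal
#' paths, the secondary metric is measured on the path the shortest-path
#' search returns.
#'
#' @param patients tibble of patient points (`id`, `x`, `y`, and carried
#'   columns such as `municipality_id`, `trial`).
#' @param facilities facilities tibble (`id`, `x`, `y`).
#' @param network a [road_network()].
#' @param model a [cost_model()].
#' @return tibble with `patient_id`, `facility_id`, `network_distance_m`,
#'   `travel_time_min`, `reachable`, `snap_distance_patient_m`,
#'   `snap_distance_facility_m`, plus any `municipality_id`/`trial` columns
#'   carried over from `patients`.
#' @export
nearest_facility <- function(patients, facilities, network,
                             model = cost_model()) {
  stopifnot(nrow(facilities) >= 1)
  if (model$metric == "euclidean") {
    return(euclidean_nearest(patients, facilities,
                             speed_kmh = model$access_speed_kmh))
  }
  fac <- facilities[order(facilities$id), , drop = FALSE]
  fac_snap <- snap_to_network(fac, network)
  pat_snap <- snap_to_network(patients, network)

  g <- network_graph(network)
  w <- if (model$objective == "time") igraph::E(g)$time_min else
    igraph::E(g)$length_m

  fac_nodes_u <- unique(fac_snap$node_id)
  pat_nodes_u <- unique(pat_snap$node_id)
  D <- igraph::distances(g, v = fac_nodes_u, to = pat_nodes_u, weights = w)
  cost <- D[match(fac_snap$node_id, fac_nodes_u),
            match(pat_snap$node_id, pat_nodes_u), drop = FALSE]

  n <- nrow(patients)
  chosen <- integer(n); best <- numeric(n)
  for (i in seq_len(n)) {
    j <- which.min(cost[, i])    # first minimum = smallest facility id
    if (length(j) == 0 || !is.finite(cost[j, i])) {
      chosen[i] <- NA_integer_; best[i] <- Inf
    } else {
      chosen[i] <- j; best[i] <- cost[j, i]
    }
  }

  # both metrics along the objective-optimal path, grouped by facility node
  dist_m <- rep(Inf, n); time_min <- rep(Inf, n)
  ok <- !is.na(chosen)
  pairs <- tibble::tibble(
    i = which(ok),
    fnode = fac_snap$node_id[chosen[ok]],
    pnode = pat_snap$node_id[ok]
  )
  for (fn in unique(pairs$fnode)) {
    sub <- pairs[pairs$fnode == fn, , drop = FALSE]
    targets <- unique(sub$pnode)
    sp <- igraph::shortest_paths(g, from = fn, to = targets, weights = w,
                                 output = "epath")
    for (k in seq_along(targets)) {
      eids <- sp$epath[[k]]
      rows <- sub$i[sub$pnode == targets[k]]
      dist_m[rows] <- sum(igraph::E(g)$length_m[as.integer(eids)])
      time_min[rows] <- sum(igraph::E(g)$time_min[as.integer(eids)])
    }
  }

  snap_f <- ifelse(ok, fac_snap$snap_distance_m[chosen], NA_real_)
  if (model$access_leg == "straight_line") {
    leg <- pat_snap$snap_distance_m + ifelse(is.na(snap_f), 0, snap_f)
    dist_m[ok] <- dist_m[ok] + leg[ok]
    time_min[ok] <- time_min[ok] + leg[ok] / (model$access_speed_kmh * 1000 / 60)
  }

  res <- tibble::tibble(
    patient_id = as.character(patients$id),
    facility_id = ifelse(ok, fac$id[chosen], NA_character_),
    network_distance_m = dist_m,
    travel_time_min = time_min,
    reachable = ok & is.finite(best),
    snap_distance_patient_m = pat_snap$snap_distance_m,
    snap_distance_facility_m = snap_f
  )
  carry_patient_cols(res, patients)
}

carry_patient_cols <- function(res, patients) {
  for (col in intersect(c("municipality_id", "trial", "mesh_id"),
                        names(patients))) {
    res[[col]] <- patients[[col]]
  }
  res
}

#' Straight-line nearest facility (diagnostic baseline)
#'
#' Assigns each patient the facility at the smallest Euclidean distance
#' (ties to the smallest facility id); travel time is that distance at a
#' representative speed. Since road edges are never shorter than the
#' straight line between their endpoints, this bounds the network distance
#' from below.
#'
#' @inheritParams nearest_facility
#' @param speed_kmh representative travel speed (km/h).
#' @return tibble with the same schema as [nearest_facility()].
#' @export
euclidean_nearest <- function(patients, facilities, speed_kmh = 40) {
  stopifnot(nrow(facilities) >= 1, speed_kmh > 0)
  fac <- facilities[order(facilities$id), , drop = FALSE]
  n <- nrow(patients)
  chosen <- integer(n); d <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (fac$x - patients$x[i])^2 + (fac$y - patients$y[i])^2
    j <- which.min(d2)
    chosen[i] <- j; d[i] <- sqrt(d2[j])
  }
  res <- tibble::tibble(
    patient_id = as.character(patients$id),
    facility_id = fac$id[chosen],
    network_distance_m = d,
    travel_time_min = d / (speed_kmh * 1000 / 60),
    reachable = TRUE,
    snap_distance_patient_m = 0,
    snap_distance_facility_m = 0
  )
  carry_patient_cols(res, patients)
}
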