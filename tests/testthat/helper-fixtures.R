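# Minimal hand-built region: 1 municipality, 4 mesh cells (500 m), 2
# facilities, 4-node square network. Every number below is chosen so paths
# and allocations can be checked by hand.
mini_region <- function() {
  muni <- tibble::tibble(
    id = "M1", name = "Mini", population = 100L, aging_rate = 0.5,
    land_area_km2 = 1, pop_75plus = 20L
  )
  mesh <- tibble::tibble(
    id = c("c1", "c2", "c3", "c4"),
    municipality_id = "M1",
    center_x = c(250, 750, 250, 750),
    center_y = c(250, 250, 750, 750),
    size_m = 500,
    pop_75plus = c(10L, 5L, 5L, 0L)
  )
  fac <- tibble::tibble(
    id = c("F1", "F2"),
    kind = c("clinic", "hospital"),
    x = c(250, 750), y = c(250, 750),
    is_provider = c(TRUE, FALSE)
  )
  nodes <- tibble::tibble(
    id = c("n1", "n2", "n3", "n4"),
    x = c(250, 750, 250, 750),
    y = c(250, 250, 750, 750)
  )
  edges <- tibble::tibble(
    u = c("n1", "n1", "n2", "n3"),
    v = c("n2", "n3", "n4", "n4"),
    length_m = 500, speed_kmh = 30, road_class = "local"
  )
  study_region(muni, mesh, fac, road_network(nodes, edges))
}

# Small generator settings used in property loops (kept small so 20-seed
# sweeps stay fast).
small_params <- function(seed, ...) {
  generator_params(
    n_municipalities = 3, urban_fraction = 1 / 3,
    urban_grid = c(6, 6), rural_grid = c(8, 3),
    urban_pop75 = 600, rural_pop75 = 100,
    n_facilities = 12,
    seed = seed, ...
  )
}

# Connected random road network with facilities/patients sitting exactly on
# nodes (so snapping is the identity and node-level oracles apply exactly).
random_network_case <- function(n_nodes, n_facilities, n_patients, seed) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  x <- runif(n_nodes, 0, 10000)
  y <- runif(n_nodes, 0, 10000)
  # random spanning tree keeps the graph connected, plus random extra edges
  u <- integer(0); v <- integer(0)
  for (i in 2:n_nodes) {
    j <- sample(i - 1, 1)
    u <- c(u, i); v <- c(v, j)
  }
  n_extra <- sample(0:n_nodes, 1)
  if (n_extra > 0) {
    a <- sample(n_nodes, n_extra, replace = TRUE)
    b <- sample(n_nodes, n_extra, replace = TRUE)
    ok <- a != b
    u <- c(u, a[ok]); v <- c(v, b[ok])
  }
  chord <- sqrt((x[u] - x[v])^2 + (y[u] - y[v])^2)
  edges <- tibble::tibble(
    u = ids[u], v = ids[v],
    length_m = chord * runif(length(u), 1.0, 1.6) + 1,
    speed_kmh = sample(c(30, 40, 60), length(u), replace = TRUE),
    road_class = "local"
  )
  net <- road_network(tibble::tibble(id = ids, x = x, y = y), edges)
  fac_nodes <- sample(n_nodes, n_facilities)
  pat_nodes <- sample(n_nodes, n_patients, replace = TRUE)
  list(
    network = net,
    facilities = tibble::tibble(
      id = sprintf("F%02d", seq_len(n_facilities)),
      kind = "clinic", x = x[fac_nodes], y = y[fac_nodes],
      is_provider = TRUE),
    fac_node_ids = ids[fac_nodes],
    patients = tibble::tibble(
      id = sprintf("p%03d", seq_len(n_patients)),
      x = x[pat_nodes], y = y[pat_nodes]),
    pat_node_ids = ids[pat_nodes]
  )
}

# Independent reference shortest-path oracle: plain O(V^2) Dijkstra over the
# edge list, no graph library involved.
ref_dijkstra <- function(network, weights, source) {
  ids <- network$nodes$id
  edges <- network$edges
  dist <- setNames(rep(Inf, length(ids)), ids)
  done <- setNames(rep(FALSE, length(ids)), ids)
  dist[source] <- 0
  repeat {
    u <- NA_character_; best <- Inf
    for (id in ids) {
      if (!done[[id]] && dist[[id]] < best) { best <- dist[[id]]; u <- id }
    }
    if (is.na(u)) break
    done[[u]] <- TRUE
    inc <- which(edges$u == u | edges$v == u)
    for (j in inc) {
      other <- if (edges$u[j] == u) edges$v[j] else edges$u[j]
      nd <- dist[[u]] + weights[j]
      if (nd < dist[[other]]) dist[[other]] <- nd
    }
  }
  dist
}

edge_time_weights <- function(network) {
  network$edges$length_m / (network$edges$speed_kmh * 1000 / 60)
}

# Exhaustive closest-facility oracle: min over per-facility single-source
# reference Dijkstra runs, ties to the smallest facility id.
brute_force_nearest <- function(case, weights) {
  fac_order <- order(case$facilities$id)
  costs <- sapply(fac_order, function(k) {
    d <- ref_dijkstra(case$network, weights, case$fac_node_ids[k])
    d[case$pat_node_ids]
  })
  costs <- matrix(costs, nrow = length(case$pat_node_ids))
  best <- apply(costs, 1, min)
  which_fac <- apply(costs, 1, which.min)
  list(cost = best,
       facility_id = case$facilities$id[fac_order][which_fac])
}
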