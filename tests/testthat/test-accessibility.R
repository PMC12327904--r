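test_that("snapping picks the Euclidean-nearest node with id tie-break", {
  net <- road_network(
    tibble::tibble(id = c("b", "a"), x = c(0, 100), y = c(0, 0)),
    tibble::tibble(u = "a", v = "b", length_m = 100, speed_kmh = 30,
                   road_class = "local")
  )
  s <- snap_to_network(tibble::tibble(x = 100, y = 0), net)
  expect_equal(s$node_id, "a")
  expect_equal(s$snap_distance_m, 0)
  # exactly halfway: tie broken by smaller id
  tie <- snap_to_network(tibble::tibble(x = 50, y = 0), net)
  expect_equal(tie$node_id, "a")

  # brute force over 100 random points
  case <- random_network_case(40, 2, 1, seed = 5)
  pts <- tibble::tibble(x = runif(100, 0, 10000), y = runif(100, 0, 10000))
  s2 <- snap_to_network(pts, case$network)
  for (i in seq_len(100)) {
    d <- sqrt((case$network$nodes$x - pts$x[i])^2 +
                (case$network$nodes$y - pts$y[i])^2)
    expect_equal(s2$snap_distance_m[i], min(d))
  }
})

test_that("a hand-computed line graph gives exact distance and time", {
  # A - B - C, each edge 1000 m at 30 km/h; facility at A, patient at C
  net <- road_network(
    tibble::tibble(id = c("A", "B", "C"), x = c(0, 1000, 2000), y = 0),
    tibble::tibble(u = c("A", "B"), v = c("B", "C"), length_m = 1000,
                   speed_kmh = 30, road_class = "local")
  )
  fac <- tibble::tibble(id = "F1", kind = "clinic", x = 0, y = 0,
                        is_provider = TRUE)
  pat <- tibble::tibble(id = "p1", x = 2000, y = 0)
  res <- nearest_facility(pat, fac, net)
  expect_equal(res$network_distance_m, 2000)
  expect_equal(res$travel_time_min, 4.0)
  expect_true(res$reachable)

  # patient at the facility's node costs nothing
  res0 <- nearest_facility(tibble::tibble(id = "p0", x = 0, y = 0), fac, net)
  expect_equal(res0$network_distance_m, 0)
  expect_equal(res0$travel_time_min, 0)
})

test_that("multi-source result equals the exhaustive per-facility oracle", {
  for (seed in 1:30) {
    case <- random_network_case(n_nodes = sample(10:50, 1),
                                n_facilities = sample(1:4, 1),
                                n_patients = 8, seed = seed)
    w <- edge_time_weights(case$network)
    oracle <- brute_force_nearest(case, w)
    res <- nearest_facility(case$patients, case$facilities, case$network,
                            cost_model(objective = "time"))
    expect_equal(res$travel_time_min, unname(oracle$cost), tolerance = 1e-10)
    expect_equal(res$facility_id, oracle$facility_id)
    # distance objective agrees with the distance-weighted oracle too
    oracle_d <- brute_force_nearest(case, case$network$edges$length_m)
    res_d <- nearest_facility(case$patients, case$facilities, case$network,
                              cost_model(objective = "distance"))
    expect_equal(res_d$network_distance_m, unname(oracle_d$cost),
                 tolerance = 1e-10)
  }
})

test_that("unreachable patients are flagged, not dropped", {
  # two disconnected components; facility only in the first
  net <- road_network(
    tibble::tibble(id = c("a", "b", "c", "d"),
                   x = c(0, 100, 5000, 5100), y = 0),
    tibble::tibble(u = c("a", "c"), v = c("b", "d"), length_m = 100,
                   speed_kmh = 30, road_class = "local")
  )
  fac <- tibble::tibble(id = "F1", kind = "clinic", x = 0, y = 0,
                        is_provider = TRUE)
  pats <- tibble::tibble(id = c("p1", "p2"), x = c(100, 5000), y = 0)
  res <- nearest_facility(pats, fac, net)
  expect_equal(res$reachable, c(TRUE, FALSE))
  expect_true(is.na(res$facility_id[2]))
  expect_equal(res$network_distance_m[2], Inf)
})

test_that("euclidean baseline bounds network distance from below", {
  fac <- tibble::tibble(id = c("F2", "F1"), kind = "clinic",
                        x = c(100, 300), y = 0, is_provider = TRUE)
  pat <- tibble::tibble(id = "p", x = 200, y = 0)
  res <- euclidean_nearest(pat, fac)
  expect_equal(res$facility_id, "F1")   # tie at 100 m -> lower id
  expect_equal(res$network_distance_m, 100)
  expect_equal(res$travel_time_min, 100 / (40 * 1000 / 60))

  case <- random_network_case(30, 3, 20, seed = 77)
  net_res <- nearest_facility(case$patients, case$facilities, case$network,
                              cost_model(objective = "distance"))
  euc_res <- euclidean_nearest(case$patients, case$facilities)
  ok <- net_res$reachable
  expect_true(all(net_res$network_distance_m[ok] >=
                    euc_res$network_distance_m[ok] - 1e-9))
})

test_that("adding facilities never worsens any patient's cost", {
  for (seed in 1:10) {
    case <- random_network_case(30, 4, 15, seed = seed + 100)
    small <- case$facilities[1:2, ]
    res_small <- nearest_facility(case$patients, small, case$network)
    res_big <- nearest_facility(case$patients, case$facilities, case$network)
    expect_true(all(res_big$travel_time_min <= res_small$travel_time_min + 1e-9))
  }
})

test_that("the straight-line access leg adds snap distances after choice", {
  net <- road_network(
    tibble::tibble(id = c("A", "B"), x = c(0, 1000), y = 0),
    tibble::tibble(u = "A", v = "B", length_m = 1000, speed_kmh = 60,
                   road_class = "local")
  )
  fac <- tibble::tibble(id = "F1", kind = "clinic", x = 0, y = 30,
                        is_provider = TRUE)
  pat <- tibble::tibble(id = "p", x = 1000, y = 40)
  base <- nearest_facility(pat, fac, net)
  withleg <- nearest_facility(pat, fac, net,
                              cost_model(access_leg = "straight_line",
                                         access_speed_kmh = 60))
  expect_equal(base$network_distance_m, 1000)
  expect_equal(withleg$network_distance_m, 1070)
  expect_equal(withleg$travel_time_min, base$travel_time_min + 70 / 1000)
})
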