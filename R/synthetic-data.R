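#' Parameters for the synthetic prefecture generator
#'
#' Describes a small study region with the statistical structure the
#' accessibility analysis assumes: a few municipalities arranged west to
#' east, the first `urban_fraction` of them urban (dense, compact
#' population core), the rest rural (sparse, elongated, few populated
#' cells, thinned road network), facilities placed preferentially where
#' people live with the provider subset biased toward urban municipalities,
#' and per-municipality usage rates of home medical care. Defaults emulate
#' the published contrast between an urban core and depopulated mountainous
#' municipalities: usage rates spanning roughly 1-10 percent of the
#' population aged >= 75, a provider subset of roughly a quarter of all
#' facilities, and a single-corridor road connection between neighboring
#' municipalities.
#'
#' @param n_municipalities number of municipalities.
#' @param urban_fraction fraction (rounded up) that are urban.
#' @param urban_grid,rural_grid mesh dimensions `c(nx, ny)` per type.
#' @param urban_pop75,rural_pop75 total population aged >= 75 per
#'   municipality of each type.
#' @param cell_size_m mesh cell edge length in meters (default 500, the
#'   standard national population grid).
#' @param n_facilities total hospitals + clinics in the region.
#' @param provider_fraction fraction of facilities that actually provide
#'   home medical care (the nested "actual" set).
#' @param urban_provider_bias relative weight of an urban facility when the
#'   provider subset is drawn (>= 1 concentrates providers in cities).
#' @param rural_edge_keep probability of keeping each non-spine road edge
#'   in a rural municipality (thinning creates detours).
#' @param speed_map named numeric vector of km/h by road class.
#' @param usage_rates optional named vector of per-municipality usage
#'   rates in `[0,1]`; defaults span about 0.01-0.10.
#' @param max_claims_per_patient each planted patient files 1..k
#'   qualifying claims.
#' @param decoy_fraction non-qualifying decoy claims as a fraction of
#'   qualifying ones.
#' @param fiscal_year fiscal year stamped on qualifying claims.
#' @param seed master seed; everything the generator draws derives from it.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_municipalities = 6,
                             urban_fraction = 1 / 3,
                             urban_grid = c(10, 10),
                             rural_grid = c(20, 4),
                             urban_pop75 = 2000,
                             rural_pop75 = 150,
                             cell_size_m = 500,
                             n_facilities = 40,
                             provider_fraction = 0.3,
                             urban_provider_bias = 4,
                             rural_edge_keep = 0.6,
                             speed_map = c(trunk = 60, local = 30),
                             usage_rates = NULL,
                             max_claims_per_patient = 3,
                             decoy_fraction = 0.3,
                             fiscal_year = 2019,
                             seed = 1) {
  stopifnot(n_municipalities >= 1,
            urban_fraction >= 0, urban_fraction <= 1,
            rural_edge_keep >= 0, rural_edge_keep <= 1,
            provider_fraction >= 0, provider_fraction <= 1,
            n_facilities >= 1, cell_size_m > 0,
            max_claims_per_patient >= 1)
  if (provider_fraction * n_facilities < 1) {
    stop(region_error(
      "infeasible parameters: at least one provider facility is required"))
  }
  if (!is.null(usage_rates)) {
    stopifnot(all(usage_rates >= 0), all(usage_rates <= 1))
  }
  structure(as.list(environment()), class = "generator_params")
}

muni_ids <- function(params) {
  sprintf("M%02d", seq_len(params$n_municipalities))
}

n_urban <- function(params) {
  max(0L, min(params$n_municipalities,
              ceiling(params$n_municipalities * params$urban_fraction)))
}

# largest-remainder rounding of total*weights to integers summing to total
apportion <- function(total, weights) {
  if (sum(weights) == 0) return(integer(length(weights)))
  exact <- total * weights / sum(weights)
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    take <- order(-(exact - base), seq_along(base))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

#' Generate a synthetic study region with ground truth
#'
#' Builds the full region — municipalities, 500 m population mesh,
#' facilities with their provider subset, and a lattice road network with a
#' single trunk corridor between neighboring municipalities and thinned
#' edges in rural ones — together with the generator's bookkeeping
#' (`ground_truth`): the true provider set, the planted per-municipality
#' patient ids and counts, and the planted usage rates (stored as the
#' realized counts over population, so recovery from the emitted claims is
#' exact). Rural municipalities receive fewer facilities, sparser
#' population, and longer network detours by construction.
#'
#' @param params a [generator_params()].
#' @return list with elements `region` (a validated [study_region()]) and
#'   `ground_truth` (list: `providers`, `patient_counts`, `patient_ids`,
#'   `usage_rates`).
#' @export
generate_region <- function(params = generator_params()) {
  with_substream(substream_seed(params$seed, 0, "region"), {
    ids <- muni_ids(params)
    nu <- n_urban(params)
    s <- params$cell_size_m

    meshes <- list(); munis <- list(); blocks <- list()
    x_off <- 0
    for (k in seq_along(ids)) {
      urban <- k <= nu
      grid <- if (urban) params$urban_grid else params$rural_grid
      pop75 <- if (urban) params$urban_pop75 else params$rural_pop75
      nx <- grid[1]; ny <- grid[2]
      cx <- x_off + (seq_len(nx) - 0.5) * s
      cy <- (seq_len(ny) - 0.5) * s
      cells <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
      cells$center_x <- cx[cells$ix]; cells$center_y <- cy[cells$iy]
      if (urban) {
        # compact core: Gaussian weight around the block center
        mx <- mean(cx); my <- mean(cy); sigma <- 0.25 * nx * s
        w <- exp(-((cells$center_x - mx)^2 + (cells$center_y - my)^2) /
                   (2 * sigma^2))
      } else {
        # sparse: only ~20% of cells populated, random weights
        w <- numeric(nrow(cells))
        pick <- sample(nrow(cells), max(2, round(0.2 * nrow(cells))))
        w[pick] <- runif(length(pick), 0.2, 1)
      }
      cell_pop <- apportion(pop75, w)
      meshes[[k]] <- tibble::tibble(
        id = sprintf("%s_c%03d", ids[k], seq_len(nrow(cells))),
        municipality_id = ids[k],
        center_x = cells$center_x, center_y = cells$center_y,
        size_m = s, pop_75plus = cell_pop,
        .ix = cells$ix, .iy = cells$iy
      )
      share75 <- if (urban) 0.12 else 0.25
      aging <- if (urban) runif(1, 0.27, 0.33) else runif(1, 0.45, 0.60)
      munis[[k]] <- tibble::tibble(
        id = ids[k],
        name = ids[k],
        population = as.integer(round(sum(cell_pop) / share75)),
        aging_rate = round(aging, 3),
        land_area_km2 = nx * ny * (s / 1000)^2,
        pop_75plus = sum(cell_pop)
      )
      blocks[[k]] <- list(id = ids[k], urban = urban, nx = nx, ny = ny,
                          x_off = x_off)
      x_off <- x_off + nx * s
    }
    mesh <- dplyr::bind_rows(meshes)
    muni <- dplyr::bind_rows(munis)

    # road lattice: nodes at cell centers; per-block spanning comb
    # (all vertical chains + horizontal row 1) always kept, other
    # horizontal edges thinned in rural blocks; one trunk corridor link
    # between neighboring blocks at row 1.
    nodes <- tibble::tibble(id = paste0("n_", mesh$id),
                            x = mesh$center_x, y = mesh$center_y)
    edges <- list()
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      sub <- mesh[mesh$municipality_id == b$id, , drop = FALSE]
      node_of <- function(ix, iy)
        paste0("n_", sub$id[match(paste(ix, iy), paste(sub$.ix, sub$.iy))])
      e <- list()
      for (ix in seq_len(b$nx)) for (iy in seq_len(b$ny - 1)) {
        e[[length(e) + 1]] <- c(node_of(ix, iy), node_of(ix, iy + 1), "keep")
      }
      for (ix in seq_len(b$nx - 1)) for (iy in seq_len(b$ny)) {
        e[[length(e) + 1]] <- c(node_of(ix, iy), node_of(ix + 1, iy),
                                if (iy == 1) "keep" else "thin")
      }
      em <- do.call(rbind, e)
      if (b$urban) {
        keep <- rep(TRUE, nrow(em))
      } else {
        keep <- em[, 3] == "keep" | runif(nrow(em)) < params$rural_edge_keep
      }
      em <- em[keep, , drop = FALSE]
      edges[[length(edges) + 1]] <- tibble::tibble(
        u = em[, 1], v = em[, 2], length_m = s,
        speed_kmh = unname(params$speed_map["local"]), road_class = "local")
      if (k < length(blocks)) {
        nxt <- blocks[[k + 1]]
        nxt_sub <- mesh[mesh$municipality_id == nxt$id, , drop = FALSE]
        right <- sub$id[sub$.ix == b$nx & sub$.iy == 1]
        left <- nxt_sub$id[nxt_sub$.ix == 1 & nxt_sub$.iy == 1]
        edges[[length(edges) + 1]] <- tibble::tibble(
          u = paste0("n_", right), v = paste0("n_", left), length_m = s,
          speed_kmh = unname(params$speed_map["trunk"]), road_class = "trunk")
      }
    }
    net <- road_network(nodes, dplyr::bind_rows(edges))
    mesh$.ix <- NULL; mesh$.iy <- NULL

    # facilities: counts per municipality proportional to pop75, placed at
    # populated cells with within-cell jitter
    fac_counts <- apportion(params$n_facilities, muni$pop_75plus)
    fac <- list()
    for (k in seq_along(ids)) {
      nf <- fac_counts[k]
      if (nf == 0) next
      sub <- mesh[mesh$municipality_id == ids[k] & mesh$pop_75plus > 0, ,
                  drop = FALSE]
      pick <- sample(nrow(sub), nf, replace = nf > nrow(sub),
                     prob = sub$pop_75plus)
      fac[[k]] <- tibble::tibble(
        municipality_id = ids[k],
        kind = ifelse(runif(nf) < 0.15, "hospital", "clinic"),
        x = sub$center_x[pick] + runif(nf, -0.4, 0.4) * s,
        y = sub$center_y[pick] + runif(nf, -0.4, 0.4) * s
      )
    }
    fac <- dplyr::bind_rows(fac)
    fac$id <- sprintf("F%03d", seq_len(nrow(fac)))

    n_prov <- max(1L, round(params$provider_fraction * nrow(fac)))
    wt <- ifelse(fac$municipality_id %in% ids[seq_len(nu)],
                 params$urban_provider_bias, 1)
    prov <- sample(fac$id, n_prov, prob = wt)
    fac$is_provider <- fac$id %in% prov
    fac_muni <- fac$municipality_id
    fac$municipality_id <- NULL

    region <- study_region(muni, mesh, fac[, c("id", "kind", "x", "y",
                                               "is_provider")], net)

    rates <- if (!is.null(params$usage_rates)) {
      params$usage_rates[ids]
    } else {
      setNames(ifelse(seq_along(ids) <= nu, 0.05,
                      seq(0.01, 0.10,
                          length.out = max(1, length(ids) - nu))[
                            pmax(1, seq_along(ids) - nu)]),
               ids)
    }
    counts <- as.integer(round(rates * muni$pop_75plus))
    patient_ids <- lapply(seq_along(ids), function(k) {
      if (counts[k] == 0) character(0) else
        sprintf("%s_pt%04d", ids[k], seq_len(counts[k]))
    })
    names(patient_ids) <- ids

    ground_truth <- list(
      providers = sort(fac$id[fac$is_provider]),
      patient_counts = tibble::tibble(municipality_id = ids,
                                      n_patients = counts),
      patient_ids = patient_ids,
      # realized rates (counts over population) so recovery is exact
      usage_rates = setNames(counts / muni$pop_75plus, ids),
      facility_municipality = setNames(fac_muni, fac$id)
    )
    list(region = region, ground_truth = ground_truth)
  })
}

#' Generate a claims table consistent with the ground truth
#'
#' Every planted patient files 1 to `max_claims_per_patient` qualifying
#' claims (a home medical care service code, age >= 75, the configured
#' fiscal year) billed by provider facilities, with billing spread so that
#' every true provider appears on at least one qualifying claim. Decoy
#' claims from separate decoy patients are interleaved, each failing
#' exactly one qualifying criterion at a time — wrong service code, age
#' under 75, or a different fiscal year — so each filter clause is
#' independently exercised. Applying the claims filter to the output
#' recovers the ground truth exactly.
#'
#' @param region a `study_region` from [generate_region()].
#' @param ground_truth the matching ground-truth list.
#' @param params the [generator_params()] used for the region.
#' @return tibble of claim records (`patient_id`, `patient_age`,
#'   `patient_municipality_id`, `facility_id`, `service_code`,
#'   `fiscal_year`).
#' @export
generate_claims <- function(region, ground_truth, params) {
  with_substream(substream_seed(params$seed, 0, "claims"), {
    gt <- ground_truth
    codes <- home_care_service_codes()
    providers <- gt$providers
    rows <- list()
    for (mid in names(gt$patient_ids)) {
      for (pid in gt$patient_ids[[mid]]) {
        k <- sample(params$max_claims_per_patient, 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          patient_id = pid,
          patient_age = 75L + sample(0:20, 1),
          patient_municipality_id = mid,
          facility_id = sample(providers, k, replace = TRUE),
          service_code = sample(codes, k, replace = TRUE),
          fiscal_year = as.integer(params$fiscal_year)
        )
      }
    }
    q <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
      patient_id = character(), patient_age = integer(),
      patient_municipality_id = character(), facility_id = character(),
      service_code = character(), fiscal_year = integer())
    if (nrow(q) > 0) {
      if (nrow(q) < length(providers)) {
        stop(region_error(paste0(
          "infeasible parameters: ", nrow(q), " qualifying claims cannot ",
          "cover ", length(providers), " providers")))
      }
      # force-cover providers with no qualifying claim yet, moving claims
      # away from facilities that can spare one
      uncovered <- setdiff(providers, unique(q$facility_id))
      for (f in uncovered) {
        counts <- table(q$facility_id)
        donor <- names(counts)[counts >= 2][1]
        if (is.na(donor)) donor <- names(counts)[1]
        q$facility_id[which(q$facility_id == donor)[1]] <- f
      }
    }

    n_decoy <- round(params$decoy_fraction * max(nrow(q), 10))
    decoys <- NULL
    if (n_decoy > 0) {
      fail <- sample(c("code", "age", "year"), n_decoy, replace = TRUE)
      decoys <- tibble::tibble(
        patient_id = sprintf("dcy%05d", seq_len(n_decoy)),
        patient_age = ifelse(fail == "age", sample(40:74, n_decoy, TRUE),
                             75L + sample(0:20, n_decoy, TRUE)),
        patient_municipality_id = sample(region$municipalities$id,
                                         n_decoy, TRUE),
        facility_id = sample(region$facilities$id, n_decoy, TRUE),
        service_code = ifelse(fail == "code",
                              sprintf("99%07d", sample(1e6, n_decoy)),
                              sample(codes, n_decoy, TRUE)),
        fiscal_year = ifelse(fail == "year",
                             as.integer(params$fiscal_year) - 1L,
                             as.integer(params$fiscal_year))
      )
    }
    all_claims <- dplyr::bind_rows(q, decoys)
    all_claims[sample(nrow(all_claims)), , drop = FALSE]
  })
}

#' Packaged demonstration study
#'
#' A deterministic small study (fixed seed): one urban and two rural
#' municipalities, well under 500 patients per trial and 200 network nodes,
#' running end-to-end in seconds. The last rural municipality is forced to
#' have no provider facility at all — its residents' nearest provider lies
#' across the trunk corridor in another municipality — so the
#' actual-vs-ideal contrast is clearly visible there, emulating depopulated
#' municipalities where no local hospital or clinic provides the service.
#'
#' @param dir optional directory; when given, the region layers, the claims
#'   table and a ready-to-run study config (`config.yaml`) are written
#'   there.
#' @return list with `region`, `claims`, `ground_truth`, `params`, and
#'   `config` (a list accepted by [run_full_study()]).
#' @export
make_demo_fixture <- function(dir = NULL) {
  params <- generator_params(
    n_municipalities = 3,
    urban_fraction = 1 / 3,
    urban_grid = c(8, 8),
    rural_grid = c(12, 3),
    urban_pop75 = 1400,
    rural_pop75 = 120,
    n_facilities = 18,
    provider_fraction = 0.35,
    urban_provider_bias = 4,
    rural_edge_keep = 0.5,
    usage_rates = c(M01 = 0.05, M02 = 0.05, M03 = 0.05),
    seed = 20190401
  )
  gen <- generate_region(params)
  region <- gen$region
  gt <- gen$ground_truth

  # strip provider status from the last (depopulated) municipality
  no_prov <- "M03"
  in_target <- gt$facility_municipality[region$facilities$id] == no_prov
  if (!any(in_target)) {
    # deterministic fallback: move the last facility into the target block
    cells <- region$meshes[region$meshes$municipality_id == no_prov &
                             region$meshes$pop_75plus > 0, ]
    i <- nrow(region$facilities)
    region$facilities$x[i] <- cells$center_x[1]
    region$facilities$y[i] <- cells$center_y[1]
    in_target[i] <- TRUE
    gt$facility_municipality[region$facilities$id[i]] <- no_prov
  }
  region$facilities$is_provider[in_target] <- FALSE
  if (!any(region$facilities$is_provider)) {
    region$facilities$is_provider[which(!in_target)[1]] <- TRUE
  }
  gt$providers <- sort(region$facilities$id[region$facilities$is_provider])

  claims <- generate_claims(region, gt, params)
  config <- list(region = region, claims = claims,
                 n_trials = 10, seed = params$seed,
                 fiscal_year = params$fiscal_year)
  if (!is.null(dir)) {
    save_region(region, dir)
    readr::write_csv(claims, file.path(dir, "claims.csv"), progress = FALSE)
    yaml::write_yaml(
      list(input_dir = dir, n_trials = 10, seed = params$seed,
           fiscal_year = params$fiscal_year),
      file.path(dir, "config.yaml"))
  }
  list(region = region, claims = claims, ground_truth = gt,
       params = params, config = config)
}
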