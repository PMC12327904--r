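# Seed discipline: one master seed; a deterministic substream per
# (trial, municipality) so adding a municipality never perturbs the draws
# of another, and trials are mutually independent and reproducible.
substream_seed <- function(seed, trial, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  (abs(as.numeric(seed)) %% 2147483647 + 1000003 * trial + h) %% 2147483647
}

with_substream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Allocate a municipality's patient count to its mesh cells
#'
#' Distributes `n` patients over mesh cells proportionally to the cell
#' population aged >= 75. `"multinomial"` draws the counts randomly with
#' cell probabilities `pop_i / sum(pop)`; `"largest_remainder"` returns the
#' deterministic proportional rounding (floors plus the largest fractional
#' remainders, ties to the earlier cell). Cells with zero population never
#' receive patients, and the counts always sum to `n`.
#'
#' @param n non-negative integer patient count for the municipality.
#' @param mesh_populations non-negative numeric vector of per-cell
#'   populations aged >= 75.
#' @param mode `"multinomial"` (default) or `"largest_remainder"`.
#' @return integer vector of per-cell counts summing to `n`.
#' @export
allocate_to_meshes <- function(n, mesh_populations,
                               mode = c("multinomial", "largest_remainder")) {
  mode <- match.arg(mode)
  stopifnot(n >= 0, all(mesh_populations >= 0))
  k <- length(mesh_populations)
  if (n == 0) return(integer(k))
  tot <- sum(mesh_populations)
  if (tot <= 0) {
    stop(region_error("cannot allocate patients: all mesh populations are zero"))
  }
  p <- mesh_populations / tot
  if (mode == "multinomial") {
    as.integer(rmultinom(1, n, p))
  } else {
    exact <- n * p
    base <- floor(exact)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- exact - base
      take <- order(-frac, seq_along(frac))[seq_len(rem)]
      base[take] <- base[take] + 1
    }
    as.integer(base)
  }
}

#' Sample a uniform point inside a mesh cell
#'
#' Draws `n` points uniformly over the cell square
#' `[cx - s/2, cx + s/2) x [cy - s/2, cy + s/2)`, in continuous planar
#' coordinates (no snapping).
#'
#' @param cell a one-row mesh tibble (or list) with `center_x`, `center_y`,
#'   `size_m`.
#' @param n number of points.
#' @return tibble with columns `x`, `y`.
#' @export
sample_point_in_cell <- function(cell, n = 1) {
  s <- cell$size_m
  tibble::tibble(
    x = cell$center_x - s / 2 + runif(n) * s,
    y = cell$center_y - s / 2 + runif(n) * s
  )
}

#' Generate one trial of hypothetical patient points
#'
#' For each municipality, allocates its requested patient count to mesh
#' cells proportionally to the cell population aged >= 75, then places each
#' patient uniformly at random within its cell. The random stream is seeded
#' per (trial, municipality), so the same `seed` and `trial_index` always
#' reproduce the same points and municipalities do not interact.
#'
#' @param region a `study_region`.
#' @param patient_counts named integer vector or tibble
#'   (`municipality_id`, `n_patients`) of patients per municipality.
#' @param trial_index trial number (>= 1), part of the seed derivation.
#' @param seed master seed.
#' @param mode allocation mode, see [allocate_to_meshes()].
#' @return tibble of patient points: `id`, `trial`, `municipality_id`,
#'   `mesh_id`, `x`, `y`.
#' @export
generate_trial <- function(region, patient_counts, trial_index, seed,
                           mode = c("multinomial", "largest_remainder")) {
  mode <- match.arg(mode)
  counts <- normalize_counts(patient_counts)
  unknown <- setdiff(names(counts), region$municipalities$id)
  if (length(unknown) > 0) {
    stop(region_error(paste0("patient counts for unknown municipality \"",
                             unknown, "\"")))
  }
  out <- list()
  for (mid in sort(names(counts))) {
    n_m <- counts[[mid]]
    if (n_m == 0) next
    cells <- region$meshes[region$meshes$municipality_id == mid, , drop = FALSE]
    if (nrow(cells) == 0 || sum(cells$pop_75plus) == 0) {
      stop(region_error(paste0(
        "municipality \"", mid, "\" has ", n_m,
        " patients but no populated mesh cells")))
    }
    pts <- with_substream(substream_seed(seed, trial_index, mid), {
      alloc <- allocate_to_meshes(n_m, cells$pop_75plus, mode)
      pieces <- lapply(which(alloc > 0), function(i) {
        xy <- sample_point_in_cell(cells[i, ], alloc[i])
        xy$mesh_id <- cells$id[i]
        xy
      })
      dplyr::bind_rows(pieces)
    })
    pts$municipality_id <- mid
    out[[mid]] <- pts
  }
  if (length(out) == 0) {
    return(tibble::tibble(id = character(), trial = integer(),
                          municipality_id = character(), mesh_id = character(),
                          x = numeric(), y = numeric()))
  }
  res <- dplyr::bind_rows(out)
  tibble::tibble(
    id = sprintf("t%d_p%05d", trial_index, seq_len(nrow(res))),
    trial = as.integer(trial_index),
    municipality_id = res$municipality_id,
    mesh_id = res$mesh_id,
    x = res$x, y = res$y
  )
}

normalize_counts <- function(patient_counts) {
  if (is.data.frame(patient_counts)) {
    setNames(as.integer(patient_counts$n_patients),
             as.character(patient_counts$municipality_id))
  } else {
    stopifnot(!is.null(names(patient_counts)))
    setNames(as.integer(patient_counts), names(patient_counts))
  }
}
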