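#' National fee-schedule service codes for home medical care
#'
#' The eight 9-digit medical service codes in the national fee schedule that
#' identify home medical care service fees. A claim carrying any one of
#' these codes marks both the billing facility as a provider and the
#' patient as a user of home medical care.
#'
#' @return character vector of eight 9-digit code strings.
#' @export
home_care_service_codes <- function() {
  c("114001110", "114030310", "114042110", "114042210",
    "114042810", "114046310", "114027710", "114027810")
}

#' Qualifying rule for home medical care claims
#'
#' A claim qualifies when its service code is in `code_set`, the patient is
#' at least `min_age` years old, and the claim falls in `fiscal_year`.
#' Defaults reproduce the cohort definition used throughout the package:
#' the eight home medical care fee codes, age >= 75, FY2019.
#'
#' @param code_set character vector of 9-digit service code strings.
#' @param min_age minimum patient age in years.
#' @param fiscal_year fiscal year of the claim (exact integer match).
#' @return an object of class `qualifying_rule`.
#' @export
qualifying_rule <- function(code_set = home_care_service_codes(),
                            min_age = 75, fiscal_year = 2019) {
  stopifnot(length(code_set) >= 1, min_age >= 0)
  if (!all(grepl("^[0-9]+$", code_set))) {
    stop("service codes must be digit strings")
  }
  structure(
    list(code_set = as.character(code_set), min_age = as.integer(min_age),
         fiscal_year = as.integer(fiscal_year)),
    class = "qualifying_rule"
  )
}

#' Does a claim qualify as home medical care usage?
#'
#' Vectorized over claims: `TRUE` where the service code belongs to the
#' rule's code set, patient age is at least the rule's minimum, and the
#' fiscal year matches exactly.
#'
#' @param claims tibble of claim records with columns `patient_id`,
#'   `patient_age`, `patient_municipality_id`, `facility_id`,
#'   `service_code`, `fiscal_year`.
#' @param rule a [qualifying_rule()].
#' @return logical vector, one element per claim row.
#' @export
is_qualifying <- function(claims, rule = qualifying_rule()) {
  as.character(claims$service_code) %in% rule$code_set &
    claims$patient_age >= rule$min_age &
    claims$fiscal_year == rule$fiscal_year
}

#' Identify facilities that actually provided home medical care
#'
#' A facility is a provider when it appears on at least one qualifying
#' claim. Returns the sorted set of such facility ids.
#'
#' @inheritParams is_qualifying
#' @return character vector of provider facility ids (possibly empty).
#' @export
identify_providers <- function(claims, rule = qualifying_rule()) {
  if (nrow(claims) == 0) return(character(0))
  sort(unique(as.character(claims$facility_id[is_qualifying(claims, rule)])))
}

#' Per-municipality usage of home medical care
#'
#' Counts qualifying claim lines and distinct qualifying patients per
#' municipality, and computes the usage rate as distinct patients divided
#' by the municipality's population aged >= 75. A patient with qualifying
#' claims in more than one municipality of residence is attributed to the
#' municipality on their first qualifying claim (in claim-table order);
#' such conflicts are reported in the `conflicts` attribute.
#'
#' @inheritParams is_qualifying
#' @param municipalities municipalities tibble (or `study_region`) with
#'   `id` and `pop_75plus`.
#' @return tibble with `municipality_id`, `n_claims` (qualifying claim
#'   lines), `n_patients` (distinct qualifying patients), `pop_75plus`,
#'   `usage_rate`; one row per municipality, including zeros.
#' @export
usage_summary <- function(claims, rule = qualifying_rule(), municipalities) {
  m <- if (inherits(municipalities, "study_region")) {
    municipalities$municipalities
  } else {
    tibble::as_tibble(municipalities)
  }
  q <- claims[is_qualifying(claims, rule), , drop = FALSE]
  unknown <- setdiff(unique(as.character(q$patient_municipality_id)), m$id)
  if (length(unknown) > 0) {
    stop(region_error(paste0(
      "claims reference unknown municipality \"", unknown, "\"")))
  }

  # first qualifying claim wins on residence conflicts
  first_seen <- !duplicated(q$patient_id)
  residence <- setNames(as.character(q$patient_municipality_id[first_seen]),
                        q$patient_id[first_seen])
  conflicts <- unique(q$patient_id[
    as.character(q$patient_municipality_id) != residence[as.character(q$patient_id)]])

  n_claims <- table(factor(as.character(q$patient_municipality_id), levels = m$id))
  n_patients <- table(factor(unname(residence), levels = m$id))
  out <- tibble::tibble(
    municipality_id = m$id,
    n_claims = as.integer(n_claims),
    n_patients = as.integer(n_patients),
    pop_75plus = m$pop_75plus
  )
  if (any(out$pop_75plus == 0 & out$n_patients > 0)) {
    bad <- out$municipality_id[out$pop_75plus == 0 & out$n_patients > 0]
    stop(region_error(paste0(
      "municipality \"", bad, "\" has qualifying patients but pop_75plus = 0")))
  }
  out$usage_rate <- ifelse(out$pop_75plus > 0,
                           out$n_patients / out$pop_75plus, 0)
  attr(out, "conflicts") <- conflicts
  out
}
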