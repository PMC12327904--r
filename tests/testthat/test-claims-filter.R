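claim_row <- function(pid = "p1", age = 80L, muni = "M1", fac = "F1",
                      code = "114001110", fy = 2019L) {
  tibble::tibble(patient_id = pid, patient_age = age,
                 patient_municipality_id = muni, facility_id = fac,
                 service_code = code, fiscal_year = fy)
}

test_that("a claim qualifies only on code AND age AND fiscal year", {
  rule <- qualifying_rule()
  expect_true(is_qualifying(claim_row(), rule))
  expect_false(is_qualifying(claim_row(age = 74L), rule))
  expect_false(is_qualifying(claim_row(code = "999999999"), rule))
  expect_false(is_qualifying(claim_row(fy = 2018L), rule))
  # boundary: exactly the minimum age qualifies
  expect_true(is_qualifying(claim_row(age = 75L), rule))
  # all eight published codes qualify
  codes <- home_care_service_codes()
  expect_length(codes, 8)
  expect_true(all(is_qualifying(
    dplyr::bind_rows(lapply(codes, function(cd) claim_row(code = cd))), rule)))
})

test_that("providers are exactly the facilities on qualifying claims", {
  rule <- qualifying_rule()
  expect_identical(identify_providers(claim_row()[0, ], rule), character(0))
  claims <- dplyr::bind_rows(
    claim_row(pid = "p1", fac = "F1"),                     # qualifying
    claim_row(pid = "p1", fac = "F1", code = "000000000"), # wrong code
    claim_row(pid = "p2", fac = "F1", age = 60L),          # under age
    claim_row(pid = "p3", fac = "F2", fy = 2017L)          # wrong year
  )
  expect_identical(identify_providers(claims, rule), "F1")
})

test_that("usage counts deduplicate patients and use pop_75plus denominators", {
  rule <- qualifying_rule()
  m <- tibble::tibble(id = c("M1", "M2"), name = c("A", "B"),
                      population = c(100L, 50L), aging_rate = 0.4,
                      land_area_km2 = 1, pop_75plus = c(20L, 10L))
  claims <- dplyr::bind_rows(
    claim_row(pid = "p1", muni = "M1"),
    claim_row(pid = "p1", muni = "M1", code = "114030310"),
    claim_row(pid = "p2", muni = "M2")
  )
  us <- usage_summary(claims, rule, m)
  expect_equal(us$n_claims, c(2L, 1L))
  expect_equal(us$n_patients, c(1L, 1L))
  expect_equal(us$usage_rate, c(1 / 20, 1 / 10))
  expect_true(all(us$n_patients <= us$n_claims))

  # municipality with no qualifying claims reports rate 0
  us0 <- usage_summary(claims[3, ], rule, m)
  expect_equal(us0$usage_rate[us0$municipality_id == "M1"], 0)
})

test_that("residence conflicts take the first qualifying claim and are logged", {
  rule <- qualifying_rule()
  m <- tibble::tibble(id = c("M1", "M2"), name = c("A", "B"),
                      population = 100L, aging_rate = 0.4,
                      land_area_km2 = 1, pop_75plus = 20L)
  claims <- dplyr::bind_rows(
    claim_row(pid = "p1", muni = "M2"),
    claim_row(pid = "p1", muni = "M1")
  )
  us <- usage_summary(claims, rule, m)
  expect_equal(us$n_patients[us$municipality_id == "M2"], 1L)
  expect_equal(us$n_patients[us$municipality_id == "M1"], 0L)
  expect_identical(attr(us, "conflicts"), "p1")
})

test_that("patients in a zero-population municipality is an error", {
  rule <- qualifying_rule()
  m <- tibble::tibble(id = "M1", name = "A", population = 0L,
                      aging_rate = 0, land_area_km2 = 1, pop_75plus = 0L)
  expect_error(usage_summary(claim_row(), rule, m), "pop_75plus = 0")
})

test_that("enlarging the code set never shrinks providers or patient counts", {
  m <- tibble::tibble(id = c("M1", "M2"), name = c("A", "B"),
                      population = 1000L, aging_rate = 0.4,
                      land_area_km2 = 1, pop_75plus = 500L)
  set.seed(42)
  for (rep in 1:10) {
    claims <- tibble::tibble(
      patient_id = sprintf("p%02d", sample(30, 60, replace = TRUE)),
      patient_age = sample(60:95, 60, replace = TRUE),
      patient_municipality_id = sample(c("M1", "M2"), 60, replace = TRUE),
      facility_id = sprintf("F%02d", sample(10, 60, replace = TRUE)),
      service_code = sample(c(home_care_service_codes(), "000000001",
                              "000000002"), 60, replace = TRUE),
      fiscal_year = sample(2018:2020, 60, replace = TRUE)
    )
    small <- qualifying_rule(home_care_service_codes()[1:3])
    big <- qualifying_rule(c(home_care_service_codes(), "000000001"))
    expect_true(all(identify_providers(claims, small) %in%
                      identify_providers(claims, big)))
    us_s <- usage_summary(claims, small, m)
    us_b <- usage_summary(claims, big, m)
    expect_true(all(us_b$n_patients >= us_s$n_patients))
    expect_true(all(us_b$n_claims >= us_s$n_claims))
    # per-municipality patients sum to distinct qualifying patients overall
    q <- claims[is_qualifying(claims, big), ]
    expect_equal(sum(us_b$n_patients), length(unique(q$patient_id)))
    # providers are a subset of facility ids present in the claims
    expect_true(all(identify_providers(claims, big) %in% claims$facility_id))
  }
})
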