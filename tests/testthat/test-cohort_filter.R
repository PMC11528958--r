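test_that("three-clause identification rule: ICD-10 F, ICPC-2 P, service flag", {
  # F32.1 qualifies
  v <- visit_table(visit_row("p1", "h1", icd = "F32.1"))
  expect_identical(identify_mh_patients(v), "p1")
  # F03 (dementia) alone is excluded
  v <- visit_table(visit_row("p1", "h1", icd = "F03"))
  expect_identical(identify_mh_patients(v), character())
  # hand-evaluated toy: {F10, P76, flag-only, K50, F81} -> first three
  v <- visit_table(visit_row("p1", "h1", icd = "F10"),
                   visit_row("p2", "h1", icpc = "P76"),
                   visit_row("p3", "h1", flag = TRUE, svc = "mh_substance"),
                   visit_row("p4", "h1", icd = "K50"),
                   visit_row("p5", "h1", icd = "F81"))
  expect_identical(identify_mh_patients(v), c("p1", "p2", "p3"))
  # flag clause can be switched off
  defn <- cohort_definition(use_service_flag = FALSE)
  expect_identical(identify_mh_patients(v, defn), c("p1", "p2"))
  # excluded ICPC codes do not qualify
  v <- visit_table(visit_row("p1", "h1", icpc = "P70"))
  expect_identical(identify_mh_patients(v), character())
})

test_that("multiple semicolon-packed codes are each evaluated", {
  v <- visit_table(visit_row("p1", "h1", icd = "Z00.0;F41.1"))
  expect_identical(identify_mh_patients(v), "p1")
  v <- visit_table(visit_row("p1", "h1", icd = "F03;F81.0"))
  expect_identical(identify_mh_patients(v), character())
})

test_that("visit exclusions remove the right rows in the right order", {
  # 10 rows: 2 home-care, 1 pharmacist, 7 clean -> 7 remain
  v <- visit_table(
    visit_row("p1", "h1", svc = "home_care"),
    visit_row("p1", "h2"), visit_row("p1", "h3"),
    visit_row("p2", "h1", svc = "home_care"),
    visit_row("p2", "h2"), visit_row("p2", "h4", occ = "pharmacist"),
    visit_row("p3", "h1"), visit_row("p3", "h2"),
    visit_row("p4", "h5"), visit_row("p4", "h2"))
  res <- apply_visit_exclusions(v)
  expect_identical(nrow(res$visits), 7L)
  expect_identical(res$report$step,
                   c("input", "remove_home_care", "remove_undefined_service_type",
                     "remove_occupational_health", "remove_missing_fields",
                     "remove_excluded_occupations"))
  expect_identical(res$report$n_visits, c(10L, 8L, 8L, 8L, 8L, 7L))

  # no-op input passes through untouched
  clean <- visit_table(visit_row("p1", "h1"), visit_row("p2", "h2"))
  res2 <- apply_visit_exclusions(clean)
  expect_equal(as.data.frame(res2$visits), as.data.frame(clean), ignore_attr = TRUE)
  expect_true(all(res2$report$n_visits == 2L))

  # everything excluded -> empty, no error
  allhc <- visit_table(visit_row("p1", "h1", svc = "home_care"),
                       visit_row("p2", "h2", svc = "home_care"))
  expect_identical(nrow(apply_visit_exclusions(allhc)$visits), 0L)
})

test_that("patient exclusions: single-visit then single-professional, one pass", {
  # {A, A, A} -> dropped (one professional)
  v <- visit_table(visit_row("p1", "A"), visit_row("p1", "A"), visit_row("p1", "A"))
  expect_identical(nrow(apply_patient_exclusions(v)$visits), 0L)
  # {A, B} -> kept (minimal pass)
  v <- visit_table(visit_row("p1", "A"), visit_row("p1", "B"))
  expect_identical(nrow(apply_patient_exclusions(v)$visits), 2L)
  # 6-patient toy: one single-visit, one single-professional, four valid
  v <- visit_table(
    visit_row("p1", "A"),                                        # single visit
    visit_row("p2", "A"), visit_row("p2", "A"),                  # single professional
    visit_row("p3", "A"), visit_row("p3", "B"),
    visit_row("p4", "A"), visit_row("p4", "C"),
    visit_row("p5", "B"), visit_row("p5", "C"),
    visit_row("p6", "A"), visit_row("p6", "B"), visit_row("p6", "C"))
  res <- apply_patient_exclusions(v)
  expect_identical(sort(unique(res$visits$patient_id)), c("p3", "p4", "p5", "p6"))
  expect_identical(res$report$n_patients, c(6L, 5L, 4L))
})

test_that("exclusion operations are idempotent", {
  fc <- small_cohort()
  again_v <- apply_visit_exclusions(fc$visits)
  expect_equal(as.data.frame(again_v$visits), as.data.frame(fc$visits),
               ignore_attr = TRUE)
  again_p <- apply_patient_exclusions(fc$visits)
  expect_equal(as.data.frame(again_p$visits), as.data.frame(fc$visits),
               ignore_attr = TRUE)
})

test_that("filter report counts are non-increasing and in narrative order", {
  fc <- small_cohort()
  expect_true(all(diff(fc$report$n_visits) <= 0))
  expect_true(all(diff(fc$report$n_patients) <= 0))
  expect_identical(fc$report$step,
                   c("input", "identify_mh_patients", "remove_home_care",
                     "remove_undefined_service_type", "remove_occupational_health",
                     "remove_missing_fields", "remove_excluded_occupations",
                     "remove_single_visit_patients",
                     "remove_single_professional_patients"))
})

test_that("subgroup extraction keeps ALL visits of member patients", {
  # psychosis member via one F20.0 visit: the Z00 visit comes along
  v <- visit_table(visit_row("p1", "h1", icd = "F20.0"),
                   visit_row("p1", "h2", icd = "Z00"))
  sub <- extract_subgroup(v, cohort_definition(subgroup = "psychosis"))
  expect_identical(nrow(sub), 2L)
  # F32-only patient is not in the substance subgroup
  v <- visit_table(visit_row("p1", "h1", icd = "F32"), visit_row("p1", "h2"))
  expect_identical(nrow(extract_subgroup(v, cohort_definition(subgroup = "substance"))), 0L)
  # F19 + F29 -> both substance and psychosis
  v <- visit_table(visit_row("p1", "h1", icd = "F19"),
                   visit_row("p1", "h2", icd = "F29"))
  expect_identical(nrow(extract_subgroup(v, cohort_definition(subgroup = "substance"))), 2L)
  expect_identical(nrow(extract_subgroup(v, cohort_definition(subgroup = "psychosis"))), 2L)
  # unknown label errors
  expect_error(cohort_definition(subgroup = "bipolar"), "specification error")
})

test_that("every subgroup patient set is a subset of the identified cohort", {
  fc <- small_cohort()
  cohort <- unique(fc$visits$patient_id)
  for (sg in c("substance", "psychosis", "depressive")) {
    sub <- extract_subgroup(fc$visits, cohort_definition(subgroup = sg))
    expect_true(all(unique(sub$patient_id) %in% cohort))
    expect_gt(length(unique(sub$patient_id)), 0)
  }
})
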