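# Cohort identification and exclusion cascade.
#
# A patient enters the cohort if at least one visit carries (1) an ICD-10
# chapter-F diagnosis outside configured exclusion ranges (dementia, mental
# retardation, specific developmental disorders by default), (2) an ICPC-2
# chapter-P code outside an exclusion list, or (3) a service-type flag
# marking the visit as mental-health / substance-abuse related.  Once a
# patient is identified, ALL their visits are retained: the downstream
# network should reflect everything their care touches, not only psychiatric
# contacts.

#' Cohort and subgroup definition
#'
#' @param icd10_exclude_ranges list of `c(lower, upper)` ICD-10 code-range
#'   pairs excluded from the chapter-F inclusion rule.  Defaults: F00-F03
#'   (dementia), F70-F79 (mental retardation), F80-F83 (specific
#'   developmental disorders).
#' @param icpc2_exclude_codes ICPC-2 chapter-P codes excluded from the
#'   inclusion rule (defaults: P70 dementia, P85 mental retardation,
#'   P24 specific learning problem).
#' @param use_service_flag whether the mental-health service-type flag
#'   qualifies a visit (rule 3).
#' @param subgroup optional diagnosis subgroup: `"substance"` (F10-F19),
#'   `"psychosis"` (F20-F29), `"depressive"` (F30-F39, exactly as printed,
#'   although F30-F31 are manic/bipolar codes) or `"all"`.
#' @return an object of class `cohort_definition`.
#' @export
cohort_definition <- function(icd10_exclude_ranges = list(c("F00", "F03"),
                                                          c("F70", "F79"),
                                                          c("F80", "F83")),
                              icpc2_exclude_codes = c("P70", "P85", "P24"),
                              use_service_flag = TRUE,
                              subgroup = "all") {
  for (r in icd10_exclude_ranges) {
    if (length(r) != 2L || substr(r[1], 1, 1) != substr(r[2], 1, 1) || r[1] > r[2]) {
      stop("invalid exclusion range: ", paste(r, collapse = "-"), call. = FALSE)
    }
  }
  subgroups <- c("all", "substance", "psychosis", "depressive")
  if (!subgroup %in% subgroups) {
    stop("specification error: unknown subgroup '", subgroup, "'; must be one of ",
         paste(subgroups, collapse = ", "), call. = FALSE)
  }
  structure(list(icd10_include_prefix = "F",
                 icd10_exclude_ranges = icd10_exclude_ranges,
                 icpc2_include_prefix = "P",
                 icpc2_exclude_codes = icpc2_exclude_codes,
                 use_service_flag = use_service_flag,
                 subgroup = subgroup),
            class = "cohort_definition")
}

SUBGROUP_RANGES <- list(substance = c("F10", "F19"),
                        psychosis = c("F20", "F29"),
                        depressive = c("F30", "F39"))

# Three-character category of an ICD-10 code ("F32.1" -> "F32").
icd_category <- function(codes) substr(codes, 1L, 3L)

# Which codes fall in chapter `prefix` but outside all exclusion ranges /
# the exclusion list.  Range comparison is on the 3-character category,
# inclusive on both ends.
qualifies_icd <- function(codes, defn) {
  cat3 <- icd_category(codes)
  ok <- startsWith(codes, defn$icd10_include_prefix)
  for (r in defn$icd10_exclude_ranges) {
    ok <- ok & !(cat3 >= r[1] & cat3 <= r[2])
  }
  ok
}

qualifies_icpc <- function(codes, defn) {
  startsWith(codes, defn$icpc2_include_prefix) &
    !(icd_category(codes) %in% defn$icpc2_exclude_codes)
}

# Per-row qualification under the three-clause rule.
visit_qualifies <- function(visits, defn) {
  icd_hit <- vapply(split_codes(visits$icd10_codes),
                    function(v) any(qualifies_icd(v, defn)), TRUE)
  icpc_hit <- vapply(split_codes(visits$icpc2_codes),
                     function(v) any(qualifies_icpc(v, defn)), TRUE)
  flag_hit <- if (defn$use_service_flag) visits$mh_service_flag else FALSE
  icd_hit | icpc_hit | flag_hit
}

#' Identify the mental-health / substance-use patient cohort
#'
#' @param visits a visit table (see [read_visits()] for the schema).
#' @param defn a [cohort_definition()].
#' @return character vector of qualifying patient ids (possibly empty).
#' @export
identify_mh_patients <- function(visits, defn = cohort_definition()) {
  if (nrow(visits) == 0L) return(character())
  sort(unique(visits$patient_id[visit_qualifies(visits, defn)]))
}

new_filter_report <- function(step, n_patients, n_visits) {
  data.frame(step = step, n_patients = n_patients, n_visits = n_visits,
             stringsAsFactors = FALSE)
}

report_row <- function(visits, step) {
  new_filter_report(step, length(unique(visits$patient_id)), nrow(visits))
}

#' Visit-level exclusion cascade
#'
#' Removes, in order: home-care visits; visits with undefined service type;
#' occupational-health visits; rows missing professional id, occupation code
#' or service type; and visits to occupations unlikely to be involved in
#' direct patient care (secretaries, managers, pharmacists, opticians by
#' default).  The report records patient and visit counts after each step.
#'
#' @param visits a visit table.
#' @param excluded_occupations occupation codes dropped in the final step.
#' @param excluded_settings service types treated as care settings to drop
#'   (home care and occupational health by default; listed separately so
#'   the audit report keeps the narrative step order).
#' @return list with elements `visits` (the filtered table) and `report`
#'   (a data.frame of `(step, n_patients, n_visits)`).
#' @export
apply_visit_exclusions <- function(visits,
                                   excluded_occupations = c("secretary", "manager",
                                                            "pharmacist", "optician"),
                                   excluded_settings = c("home_care",
                                                         "occupational_health")) {
  visits <- data.table::as.data.table(visits)
  report <- report_row(visits, "input")
  steps <- list(
    list(name = "remove_home_care",
         keep = function(v) !(v$service_type %in% intersect("home_care", excluded_settings))),
    list(name = "remove_undefined_service_type",
         keep = function(v) v$service_type != "undefined"),
    list(name = "remove_occupational_health",
         keep = function(v) !(v$service_type %in% intersect("occupational_health", excluded_settings))),
    list(name = "remove_missing_fields",
         keep = function(v) nzchar(v$professional_id) & !is.na(v$professional_id) &
                            nzchar(v$occupation_code) & !is.na(v$occupation_code) &
                            nzchar(v$service_type) & !is.na(v$service_type)),
    list(name = "remove_excluded_occupations",
         keep = function(v) !(v$occupation_code %in% excluded_occupations)))
  for (s in steps) {
    visits <- visits[s$keep(visits), ]
    report <- rbind(report, report_row(visits, s$name))
  }
  list(visits = visits[], report = report)
}

#' Patient-level exclusion cascade
#'
#' Drops patients with exactly one remaining visit, then patients whose
#' remaining visits are all to the same single professional.  Applied once,
#' sequentially: a patient left with one visit only because of some later
#' consideration is not re-dropped, mirroring a single-pass accounting.
#'
#' @param visits a visit table, visit-level exclusions already applied.
#' @return list with elements `visits` and `report`.
#' @export
apply_patient_exclusions <- function(visits) {
  visits <- data.table::as.data.table(visits)
  report <- report_row(visits, "input")
  n_by_pat <- visits[, .N, by = "patient_id"]
  keep1 <- n_by_pat$patient_id[n_by_pat$N > 1L]
  visits <- visits[visits$patient_id %in% keep1, ]
  report <- rbind(report, report_row(visits, "remove_single_visit_patients"))
  nprof <- visits[, list(nprof = data.table::uniqueN(professional_id)),
                  by = "patient_id"]
  keep2 <- nprof$patient_id[nprof$nprof > 1L]
  visits <- visits[visits$patient_id %in% keep2, ]
  report <- rbind(report, report_row(visits, "remove_single_professional_patients"))
  list(visits = visits[], report = report)
}

#' Run the full identification and exclusion cascade
#'
#' Convenience wrapper: identify the cohort, keep all its visits, apply
#' visit-level then patient-level exclusions, and return a combined audit
#' report in narrative order.
#'
#' @inheritParams apply_visit_exclusions
#' @param defn a [cohort_definition()].
#' @return list with `visits` and `report`.
#' @export
filter_cohort <- function(visits, defn = cohort_definition(),
                          excluded_occupations = c("secretary", "manager",
                                                   "pharmacist", "optician")) {
  visits <- data.table::as.data.table(visits)
  report <- report_row(visits, "input")
  cohort <- identify_mh_patients(visits, defn)
  visits <- visits[visits$patient_id %in% cohort, ]
  report <- rbind(report, report_row(visits, "identify_mh_patients"))
  ve <- apply_visit_exclusions(visits, excluded_occupations)
  report <- rbind(report, ve$report[-1, ])
  pe <- apply_patient_exclusions(ve$visits)
  report <- rbind(report, pe$report[-1, ])
  rownames(report) <- NULL
  list(visits = pe$visits, report = report)
}

#' Extract a diagnosis subgroup
#'
#' Returns ALL visits of patients having at least one visit with an ICD-10
#' code in the subgroup's category range (e.g. F20-F29 for psychosis) —
#' not only the visits carrying the diagnosis.  Patients may belong to
#' several subgroups.
#'
#' @param visits a (filtered) visit table.
#' @param defn a [cohort_definition()] with `subgroup` set.
#' @return the subgroup's visit table.
#' @export
extract_subgroup <- function(visits, defn) {
  if (defn$subgroup == "all") return(data.table::as.data.table(visits)[])
  rng <- SUBGROUP_RANGES[[defn$subgroup]]
  if (is.null(rng)) {
    stop("specification error: unknown subgroup '", defn$subgroup, "'", call. = FALSE)
  }
  visits <- data.table::as.data.table(visits)
  hit <- vapply(split_codes(visits$icd10_codes), function(v) {
    cat3 <- icd_category(v)
    any(cat3 >= rng[1] & cat3 <= rng[2])
  }, TRUE)
  members <- unique(visits$patient_id[hit])
  visits[visits$patient_id %in% members, ][]
}

#' Default fine-occupation to occupation-class lookup
#'
#' Maps fine-grained occupation codes to the three analysis classes
#' (physician; nurse — including registered, practical and other nurses
#' such as radiographers or community health nurses; other — psychologists,
#' therapists, social workers).  Non-care occupations map to `"excluded"`.
#' Editable: pass your own table to [resolve_attributes()].
#'
#' @return data.frame with columns `occupation_code`, `occupation_class`.
#' @export
default_occupation_map <- function() {
  data.frame(
    occupation_code = unlist(FINE_OCCUPATIONS, use.names = FALSE),
    occupation_class = rep(names(FINE_OCCUPATIONS),
                           lengths(FINE_OCCUPATIONS)),
    stringsAsFactors = FALSE)
}
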