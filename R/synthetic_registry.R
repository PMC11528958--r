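# Synthetic visit-level registry generator.
#
# Emulates the statistical structure of a primary-care visit register:
# patients with mental-health / substance-use diagnosis groups, professionals
# with occupation and municipality attributes, right-skewed visit counts, and
# deliberately planted "dirty" rows (home-care visits, undefined service
# types, excluded occupations, single-visit and single-professional patients)
# so that the filtering cascade has real work to do.

DIAGNOSIS_GROUPS <- c("substance", "psychosis", "depressive")

# ICD-10 / ICPC-2 code pools per diagnosis group.  Depressive uses the
# printed F30-F39 range (which includes manic/bipolar codes); see docs.
ICD_POOLS <- list(
  substance    = c("F10.1", "F10.2", "F11.2", "F12.1", "F13.2", "F15.1", "F19.2"),
  psychosis    = c("F20.0", "F20.9", "F22.0", "F23.9", "F25.1", "F29"),
  depressive   = c("F32.0", "F32.1", "F32.9", "F33.1", "F33.2", "F31.3"),
  other_mental = c("F41.0", "F41.1", "F41.9", "F43.1", "F43.2", "F48.9", "F60.3")
)
ICPC_QUALIFYING <- c("P74", "P76", "P79", "P02", "P06")
ICD_EXCLUDED_POOL <- c("F03", "F00.1", "F71", "F81.0")   # dementia / retardation / developmental
SOMATIC_POOL <- c("Z00.0", "K50.9", "I10", "E11.9", "M54.5", "J06.9")

FINE_OCCUPATIONS <- list(
  physician = c("gp", "physician_specialist"),
  nurse     = c("registered_nurse", "practical_nurse", "community_health_nurse", "radiographer"),
  other     = c("psychologist", "physiotherapist", "social_worker", "therapist"),
  excluded  = c("secretary", "manager", "pharmacist", "optician")
)

SERVICE_TYPES <- c("general_care", "mh_substance", "routine", "other",
                   "home_care", "occupational_health", "undefined")

VISIT_COLUMNS <- c("patient_id", "professional_id", "visit_date", "municipality",
                   "occupation_code", "service_type", "icd10_codes", "icpc2_codes",
                   "mh_service_flag")

#' Configuration for the synthetic registry generator
#'
#' Defaults reproduce the printed marginals of the source setting: seven
#' municipalities, occupation mix 26/62/12 percent
#' physicians/nurses/others, median 14 visits per patient overall with
#' higher medians (20/21/17) in the substance-use, psychotic and depressive
#' diagnosis groups, and a service-type mix of roughly 43/30/10/17 percent
#' over general care, mental-health/substance care, routine and other
#' visits.  Group sizes follow the published cohort shares (870, 513 and
#' 2,187 of 8,217 patients).
#'
#' @param n_patients_total number of patients to simulate.
#' @param group_proportions named fractions over
#'   `c(substance, psychosis, depressive, other_mental)`; must sum to 1.
#' @param n_professionals number of professionals.
#' @param occupation_mix named fractions over `c(physician, nurse, other)`.
#' @param n_municipalities number of municipalities (codes `M1`, `M2`, ...).
#' @param visits_per_patient per-group list of `list(median=, dispersion=)`
#'   for a negative-binomial visit-count family; medians must be >= 2.
#' @param p_within_municipality probability a care-team member is drawn from
#'   the patient's home municipality.
#' @param occupational_assortativity named per-group log-scale weights
#'   concentrating a patient's care team within one occupation class.
#' @param service_type_mix named fractions over the four core service types.
#' @param p_single_visit fraction of patients planted with exactly one visit
#'   (exercises the single-visit exclusion).
#' @param p_single_professional fraction of patients whose visits all go to
#'   one professional (exercises the single-professional exclusion).
#' @param p_home_care,p_undefined,p_occupational_health per-visit
#'   probabilities of dirty service types that the filter removes.
#' @param p_excluded_occupation fraction of professionals given
#'   non-care occupations (secretary, manager, pharmacist, optician).
#' @param p_missing_field per-visit probability of a blanked
#'   professional id or occupation code.
#' @param p_diagnosis_on_visit probability that any given visit of a patient
#'   carries that patient's diagnosis codes (at least one visit always does).
#' @param p_comorbid probability a patient belongs to a second diagnosis
#'   group (groups overlap, as in real registries).
#' @param p_non_mh fraction of patients with no qualifying mental-health
#'   marker at all (somatic or excluded-range codes only).
#' @param team_size_exponent,team_size_scale care-team size is
#'   `ceiling(scale * visits^exponent)`.
#' @param popularity_dispersion gamma shape of the per-professional
#'   popularity weight (mean 1).  Small values concentrate care on a core
#'   subset of professionals, as in real registries where a mental-health
#'   team sees most of the cohort; this concentration is what makes a
#'   shared-patient threshold of 5 attainable.  Default 0.3.
#' @param group_concentration gamma shape of the per-professional,
#'   per-diagnosis-group affinity weight.  Small values mean each diagnosis
#'   group is treated by its own small specialized team (substance-abuse
#'   nurses, psychosis teams), which makes diagnosis-group networks denser
#'   than size-matched samples of the whole cohort.  Default 0.3.
#' @param year calendar year for visit dates.
#' @param seed integer seed; the whole registry is a pure function of the
#'   configuration including this seed.
#' @return an object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_patients_total = 2000,
                             group_proportions = c(substance = 0.106,
                                                   psychosis = 0.062,
                                                   depressive = 0.266,
                                                   other_mental = 0.566),
                             n_professionals = 380,
                             occupation_mix = c(physician = 0.26,
                                                nurse = 0.62,
                                                other = 0.12),
                             n_municipalities = 7,
                             visits_per_patient = list(
                               substance    = list(median = 20, dispersion = 2.5),
                               psychosis    = list(median = 21, dispersion = 2.5),
                               depressive   = list(median = 17, dispersion = 2.5),
                               other_mental = list(median = 14, dispersion = 2.5)),
                             p_within_municipality = 0.85,
                             occupational_assortativity = c(substance = 0.5,
                                                            psychosis = 0.5,
                                                            depressive = 0.5,
                                                            other_mental = 0.5),
                             service_type_mix = c(general_care = 0.43,
                                                  mh_substance = 0.30,
                                                  routine = 0.10,
                                                  other = 0.17),
                             p_single_visit = 0.05,
                             p_single_professional = 0.05,
                             p_home_care = 0.03,
                             p_undefined = 0.02,
                             p_occupational_health = 0.02,
                             p_excluded_occupation = 0.03,
                             p_missing_field = 0.01,
                             p_diagnosis_on_visit = 0.30,
                             p_comorbid = 0.05,
                             p_non_mh = 0.08,
                             team_size_exponent = 0.6,
                             team_size_scale = 1,
                             popularity_dispersion = 0.3,
                             group_concentration = 0.3,
                             year = 2021,
                             seed = 1L) {
  cfg <- list(n_patients_total = check_count(n_patients_total, "n_patients_total", min = 0),
              group_proportions = check_proportions(group_proportions, "group_proportions"),
              n_professionals = check_count(n_professionals, "n_professionals"),
              occupation_mix = check_proportions(occupation_mix, "occupation_mix"),
              n_municipalities = check_count(n_municipalities, "n_municipalities"),
              visits_per_patient = visits_per_patient,
              p_within_municipality = p_within_municipality,
              occupational_assortativity = occupational_assortativity,
              service_type_mix = check_proportions(service_type_mix, "service_type_mix"),
              p_single_visit = p_single_visit,
              p_single_professional = p_single_professional,
              p_home_care = p_home_care,
              p_undefined = p_undefined,
              p_occupational_health = p_occupational_health,
              p_excluded_occupation = p_excluded_occupation,
              p_missing_field = p_missing_field,
              p_diagnosis_on_visit = p_diagnosis_on_visit,
              p_comorbid = p_comorbid,
              p_non_mh = p_non_mh,
              team_size_exponent = team_size_exponent,
              team_size_scale = team_size_scale,
              popularity_dispersion = popularity_dispersion,
              group_concentration = group_concentration,
              year = check_count(year, "year"),
              seed = check_count(seed, "seed", min = 0))
  groups <- c(DIAGNOSIS_GROUPS, "other_mental")
  if (!setequal(names(cfg$group_proportions), groups)) {
    stop("configuration error: 'group_proportions' must be named ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (!setequal(names(cfg$occupation_mix), c("physician", "nurse", "other"))) {
    stop("configuration error: 'occupation_mix' must be named physician, nurse, other",
         call. = FALSE)
  }
  for (g in groups) {
    vp <- cfg$visits_per_patient[[g]]
    if (is.null(vp) || is.null(vp$median) || is.null(vp$dispersion)) {
      stop(sprintf("configuration error: 'visits_per_patient$%s' needs median and dispersion", g),
           call. = FALSE)
    }
    if (vp$median < 2) {
      stop(sprintf("configuration error: 'visits_per_patient$%s$median' must be >= 2", g),
           call. = FALSE)
    }
    if (vp$dispersion <= 0) {
      stop(sprintf("configuration error: 'visits_per_patient$%s$dispersion' must be > 0", g),
           call. = FALSE)
    }
  }
  for (f in c("p_within_municipality", "p_single_visit", "p_single_professional",
              "p_home_care", "p_undefined", "p_occupational_health",
              "p_excluded_occupation", "p_missing_field", "p_diagnosis_on_visit",
              "p_comorbid", "p_non_mh")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("configuration error: '%s' must be a probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  structure(cfg, class = "synthetic_config")
}

# Negative-binomial mean whose median equals `med` at the given dispersion
# (size).  qnbinom is a step function of mu, so binary-search the smallest mu
# whose median reaches med.
nb_mu_for_median <- function(med, size) {
  lo <- med / 4
  hi <- med * 4
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (stats::qnbinom(0.5, size = size, mu = mid) >= med) hi <- mid else lo <- mid
  }
  hi
}

empty_visit_table <- function() {
  data.table::data.table(patient_id = character(), professional_id = character(),
                         visit_date = character(), municipality = character(),
                         occupation_code = character(), service_type = character(),
                         icd10_codes = character(), icpc2_codes = character(),
                         mh_service_flag = logical())
}

#' Generate a synthetic visit-level registry
#'
#' Produces one row per visit with the schema expected by [read_visits()]:
#' patient and professional pseudonymous ids, visit date, municipality,
#' fine-grained occupation code, service type, semicolon-separated ICD-10
#' and ICPC-2 code lists, and a mental-health service flag.  The registry is
#' byte-identical for identical configurations (seed included).
#'
#' @param config a [synthetic_config()] object.
#' @return a `data.table` of visits, with the generating configuration
#'   attached as attribute `"config"` and the per-patient diagnosis-group
#'   assignment as attribute `"truth"`.
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop("configuration error: 'config' must be created by synthetic_config()", call. = FALSE)
  }
  if (config$n_patients_total == 0L) {
    out <- empty_visit_table()
    data.table::setattr(out, "config", config)
    return(out)
  }
  with_seed(config$seed, generate_registry_impl(config))
}

generate_registry_impl <- function(config) {
  nP <- config$n_patients_total
  nH <- config$n_professionals
  munis <- paste0("M", seq_len(config$n_municipalities))

  ## ---- professionals -------------------------------------------------
  n_excl <- round(config$p_excluded_occupation * nH)
  n_care <- nH - n_excl
  occ_class <- c(sample(names(config$occupation_mix), n_care, replace = TRUE,
                        prob = config$occupation_mix),
                 rep("excluded", n_excl))
  prof <- data.table::data.table(
    professional_id = sprintf("HCP%04d", seq_len(nH)),
    occ_class = occ_class,
    fine_code = vapply(occ_class, function(cl) sample(FINE_OCCUPATIONS[[cl]], 1L), ""),
    home_muni = sample(munis, nH, replace = TRUE),
    popularity = stats::rgamma(nH, shape = config$popularity_dispersion,
                               rate = config$popularity_dispersion) + 0.01)
  # per-group specialized-team affinity (columns: substance, psychosis,
  # depressive); other_mental / non-MH patients use plain popularity
  affinity <- matrix(stats::rgamma(nH * length(DIAGNOSIS_GROUPS),
                                   shape = config$group_concentration,
                                   rate = config$group_concentration) + 0.01,
                     nrow = nH, dimnames = list(NULL, DIAGNOSIS_GROUPS))

  ## ---- patients ------------------------------------------------------
  groups <- c(DIAGNOSIS_GROUPS, "other_mental")
  primary <- sample(groups, nP, replace = TRUE, prob = config$group_proportions)
  non_mh <- stats::runif(nP) < config$p_non_mh
  comorbid <- !non_mh & stats::runif(nP) < config$p_comorbid
  second <- rep(NA_character_, nP)
  for (i in which(comorbid)) {
    second[i] <- sample(setdiff(DIAGNOSIS_GROUPS, primary[i]), 1L)
  }
  channel <- ifelse(primary == "other_mental",
                    sample(c("icd", "icpc", "flag"), nP, replace = TRUE,
                           prob = c(0.7, 0.15, 0.15)),
                    "icd")

  mus <- vapply(groups, function(g) {
    vp <- config$visits_per_patient[[g]]
    nb_mu_for_median(vp$median, vp$dispersion)
  }, 0)
  sizes <- vapply(groups, function(g) config$visits_per_patient[[g]]$dispersion, 0)

  n_visits <- pmax(2L, stats::rnbinom(nP, size = sizes[primary], mu = mus[primary]))
  single_visit <- stats::runif(nP) < config$p_single_visit
  n_visits[single_visit] <- 1L
  single_prof <- stats::runif(nP) < config$p_single_professional

  pat_muni <- sample(munis, nP, replace = TRUE)
  anchor_occ <- sample(names(config$occupation_mix), nP, replace = TRUE,
                       prob = config$occupation_mix)

  year0 <- as.Date(sprintf("%d-01-01", config$year))
  n_days <- as.integer(as.Date(sprintf("%d-12-31", config$year)) - year0) + 1L

  w_mun_out <- (1 - config$p_within_municipality) / max(1L, config$n_municipalities - 1L)
  all_fine <- unlist(FINE_OCCUPATIONS, use.names = FALSE)
  svc_core <- names(config$service_type_mix)

  rows <- vector("list", nP)
  for (i in seq_len(nP)) {
    v <- n_visits[i]
    team_size <- if (single_prof[i]) 1L else
      min(nH, max(1L, ceiling(config$team_size_scale * v^config$team_size_exponent)))
    w <- prof$popularity *
      ifelse(prof$home_muni == pat_muni[i], config$p_within_municipality, w_mun_out)
    if (!non_mh[i] && primary[i] %in% DIAGNOSIS_GROUPS) {
      w <- w * affinity[, primary[i]]
    }
    a <- config$occupational_assortativity[[if (non_mh[i]) "other_mental" else primary[i]]]
    w <- w * ifelse(prof$occ_class == anchor_occ[i], exp(a), 1)
    w <- w * ifelse(prof$occ_class == "excluded", 0.3, 1)
    team <- sample.int(nH, team_size, prob = w)
    alloc <- if (team_size == 1L) rep(1L, v) else
      sample(seq_len(team_size), v, replace = TRUE, prob = stats::rexp(team_size) + 0.1)
    hcp <- team[alloc]

    svc <- sample(svc_core, v, replace = TRUE, prob = config$service_type_mix)
    dirty <- stats::runif(v)
    p1 <- config$p_home_care
    p2 <- p1 + config$p_undefined
    p3 <- p2 + config$p_occupational_health
    svc[dirty < p1] <- "home_care"
    svc[dirty >= p1 & dirty < p2] <- "undefined"
    svc[dirty >= p2 & dirty < p3] <- "occupational_health"
    if (non_mh[i]) svc[svc == "mh_substance"] <- "general_care"

    occ_code <- prof$fine_code[hcp]
    flip <- stats::runif(v) < 0.1
    if (any(flip)) occ_code[flip] <- sample(all_fine, sum(flip), replace = TRUE)

    icd <- character(v)
    icpc <- character(v)
    flag <- rep(FALSE, v)
    if (non_mh[i]) {
      has_code <- stats::runif(v) < 0.5
      pool <- if (stats::runif(1) < 0.25) ICD_EXCLUDED_POOL else SOMATIC_POOL
      icd[has_code] <- sample(pool, sum(has_code), replace = TRUE)
    } else {
      qual <- stats::runif(v) < config$p_diagnosis_on_visit
      if (!any(qual)) qual[sample.int(v, 1L)] <- TRUE
      grp_codes <- ICD_POOLS[[primary[i]]]
      if (channel[i] == "icd") {
        icd[qual] <- sample(grp_codes, sum(qual), replace = TRUE)
      } else if (channel[i] == "icpc") {
        icpc[qual] <- sample(ICPC_QUALIFYING, sum(qual), replace = TRUE)
      } else {
        flag[qual] <- TRUE
        svc[qual] <- "mh_substance"
      }
      if (!is.na(second[i])) {
        k <- sample.int(v, max(1L, round(v * config$p_diagnosis_on_visit / 2)))
        icd[k] <- ifelse(nzchar(icd[k]), paste0(icd[k], ";"), "")
        icd[k] <- paste0(icd[k], sample(ICD_POOLS[[second[i]]], length(k), replace = TRUE))
      }
      somatic <- !qual & stats::runif(v) < 0.3
      icd[somatic] <- sample(SOMATIC_POOL, sum(somatic), replace = TRUE)
    }

    pid <- prof$professional_id[hcp]
    ocode <- occ_code
    miss <- stats::runif(v) < config$p_missing_field
    if (any(miss)) {
      half <- stats::runif(sum(miss)) < 0.5
      pid[miss][half] <- ""
      ocode[miss][!half] <- ""
    }

    rows[[i]] <- data.table::data.table(
      patient_id = sprintf("PT%05d", i),
      professional_id = pid,
      visit_date = as.character(year0 + sample.int(n_days, v, replace = TRUE) - 1L),
      municipality = ifelse(stats::runif(v) < 0.9, prof$home_muni[hcp],
                            sample(munis, v, replace = TRUE)),
      occupation_code = ocode,
      service_type = svc,
      icd10_codes = icd,
      icpc2_codes = icpc,
      mh_service_flag = flag)
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, patient_id, visit_date, professional_id)
  truth <- data.table::data.table(
    patient_id = sprintf("PT%05d", seq_len(nP)),
    group = ifelse(non_mh, "non_mh", primary),
    second_group = second,
    n_visits_planned = n_visits)
  data.table::setattr(out, "config", config)
  data.table::setattr(out, "truth", truth)
  out[]
}

#' Write a registry with a provenance sidecar
#'
#' Writes the visit table as UTF-8 tab-separated text and a JSON sidecar
#' (`<path>.provenance.json`) recording the generating configuration and
#' seed, if the table carries one.
#'
#' @param visits a visit table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(visits, path) {
  write_visits(visits, path)
  cfg <- attr(visits, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Simulate a professional network directly from a dyad-independent ERGM
#'
#' Draws node attributes from the supplied mixes, then places each unordered
#' dyad's edge independently with probability
#' `plogis(theta %*% change_statistics)` — the same per-dyad Bernoulli
#' mechanism used by [simulate_from_fit()], here with user-chosen truth.
#' Used for ERGM parameter-recovery experiments.
#'
#' @param n_nodes number of professionals.
#' @param occupation_mix named fractions over occupation classes.
#' @param n_municipalities number of municipality levels.
#' @param spec an [ergm_spec()] naming only dyad-independent terms on the
#'   `occupation` and/or `municipality` attributes.
#' @param theta named coefficient vector; names must exactly match the
#'   design columns implied by `spec` (see [change_statistics()]).
#' @param seed integer seed.
#' @return an `igraph` patient-sharing network (edge weights 1).
#' @export
generate_ergm_network <- function(n_nodes, occupation_mix, n_municipalities,
                                  spec, theta, seed = 1L) {
  check_count(n_nodes, "n_nodes", min = 1)
  check_proportions(occupation_mix, "occupation_mix")
  check_count(n_municipalities, "n_municipalities")
  with_seed(seed, {
    nodes <- data.frame(
      name = sprintf("HCP%04d", seq_len(n_nodes)),
      occupation = sample(names(occupation_mix), n_nodes, replace = TRUE,
                          prob = occupation_mix),
      municipality = sample(paste0("M", seq_len(n_municipalities)), n_nodes,
                            replace = TRUE),
      stringsAsFactors = FALSE)
    des <- dyad_design(nodes, spec)
    if (!identical(sort(names(theta)), sort(colnames(des$X)))) {
      stop("specification error: theta names must match the design columns: ",
           paste(colnames(des$X), collapse = ", "), call. = FALSE)
    }
    p <- stats::plogis(drop(des$X %*% theta[colnames(des$X)]))
    y <- stats::rbinom(length(p), 1L, p) == 1L
    g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    igraph::V(g)$name <- nodes$name
    igraph::V(g)$occupation <- nodes$occupation
    igraph::V(g)$municipality <- nodes$municipality
    if (any(y)) {
      g <- igraph::add_edges(g, t(des$dyads[y, , drop = FALSE]))
      igraph::E(g)$weight <- 1
    }
    g$min_shared <- NA_integer_
    g
  })
}
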