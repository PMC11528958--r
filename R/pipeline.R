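# End-to-end pipeline orchestration and all file input/output.
#
# Every artifact is plain text (TSV, GraphML, JSON) and bit-stable under a
# fixed master seed: all stage seeds are derived from the master seed via
# derive_seed(), so changing one stage's iteration count never perturbs
# another stage's randomness, and the run manifest (artifact paths + MD5
# hashes + configuration snapshot) is byte-identical across reruns.

#' Read a visit table from delimited text
#'
#' Expects a UTF-8 header-ed delimited file with the columns
#' `patient_id, professional_id, visit_date, municipality, occupation_code,
#' service_type, icd10_codes, icpc2_codes, mh_service_flag`; the two code
#' columns pack multiple codes with semicolons.  Schema violations are
#' reported with row numbers (first 20 shown).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a `data.table` visit table.
#' @export
read_visits <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = sep, colClasses = list(
    character = c("patient_id", "professional_id", "visit_date", "municipality",
                  "occupation_code", "service_type", "icd10_codes", "icpc2_codes")),
    encoding = "UTF-8", na.strings = NULL, fill = TRUE)
  missing_cols <- setdiff(VISIT_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop("validation error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, VISIT_COLUMNS, with = FALSE]
  if (!is.logical(dt$mh_service_flag)) {
    dt[, mh_service_flag := as.logical(mh_service_flag)]
  }
  bad <- which(!nzchar(dt$patient_id) | is.na(dt$patient_id) |
                 is.na(dt$mh_service_flag) |
                 is.na(suppressWarnings(as.Date(dt$visit_date))))
  if (length(bad)) {
    shown <- utils::head(bad, 20)
    stop("validation error: ", length(bad), " malformed row(s); first rows: ",
         paste(shown, collapse = ", "), call. = FALSE)
  }
  dt[]
}

#' Write a visit table as delimited text
#'
#' @param visits a visit table.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path, sep = "\t") {
  data.table::fwrite(data.table::as.data.table(visits)[, VISIT_COLUMNS, with = FALSE],
                     path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Write a sharing network as GraphML and edge-list text
#'
#' GraphML carries vertex attributes `occupation` and `municipality` and
#' edge attribute `weight` (shared-patient count); the companion
#' `<path>.edges.tsv` is a three-column delimited edge list.
#'
#' @param net a sharing network (`igraph`).
#' @param path GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  el <- igraph::as_edgelist(net)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      shared_patients = if (igraph::ecount(net))
                        igraph::E(net)$weight else numeric(),
                      stringsAsFactors = FALSE)
  data.table::fwrite(edges, paste0(path, ".edges.tsv"), sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a report object as structured text
#'
#' Data frames go to TSV; everything else (lists, fit summaries) to JSON.
#'
#' @param obj the object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  if (is.data.frame(obj)) {
    data.table::fwrite(obj, path, sep = "\t", quote = FALSE)
  } else {
    jsonlite::write_json(report_as_list(obj), path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

report_as_list <- function(obj) {
  if (inherits(obj, "ergm_fit")) {
    list(coefficients = obj$coefficients, loglik = obj$loglik, aic = obj$aic,
         bic = obj$bic, n_dyads = obj$n_dyads, n_nodes = obj$n_nodes,
         converged = obj$converged, separated = obj$separated)
  } else if (inherits(obj, "gof_report")) {
    list(coverage = as.list(obj$coverage), n_sim = obj$n_sim,
         degree = obj$degree, esp = obj$esp, geodesic = obj$geodesic)
  } else if (inherits(obj, "network_stats")) {
    unclass(obj)
  } else {
    obj
  }
}

#' Pipeline run configuration
#'
#' @param input path to a visit-table file, or `NULL` to generate a
#'   synthetic registry from `synthetic`.
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`.
#' @param subgroups subset of `c("all", "substance", "psychosis",
#'   "depressive")` to analyze; `"all"` is always included.
#' @param min_shared sharing threshold tau (default 5).
#' @param keep_isolates isolate policy for all networks.
#' @param M resampling iterations for the null comparison (default 100).
#' @param ergm_steps which model steps to fit: subset of `c(1, 2)`.
#' @param include_municipality include municipality terms in the ERGMs.
#' @param n_sim goodness-of-fit simulation count (default 100).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = synthetic_config(),
                       subgroups = c("all", "substance", "psychosis", "depressive"),
                       min_shared = 5L, keep_isolates = TRUE, M = 100L,
                       ergm_steps = c(1L, 2L), include_municipality = TRUE,
                       n_sim = 100L, seed = 1L, out_dir = "psnet_run") {
  check_count(min_shared, "min_shared")
  check_count(M, "M")
  check_count(n_sim, "n_sim")
  check_count(seed, "seed", min = 0)
  allowed <- c("all", "substance", "psychosis", "depressive")
  if (!all(subgroups %in% allowed)) {
    stop("configuration error: 'subgroups' must be a subset of ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  subgroups <- union("all", subgroups)
  if (!all(ergm_steps %in% c(1L, 2L))) {
    stop("configuration error: 'ergm_steps' must be a subset of c(1, 2)", call. = FALSE)
  }
  structure(list(input = input, synthetic = synthetic, subgroups = subgroups,
                 min_shared = as.integer(min_shared),
                 keep_isolates = isTRUE(keep_isolates), M = as.integer(M),
                 ergm_steps = as.integer(ergm_steps),
                 include_municipality = isTRUE(include_municipality),
                 n_sim = as.integer(n_sim), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[psnet] ", fmt), ...))
}

#' Run the full patient-sharing network pipeline
#'
#' Generates or reads the registry, runs the identification and exclusion
#' cascade, then per subgroup: builds the thresholded sharing network,
#' computes its statistics, compares each diagnosis group to the
#' size-matched resampled all-patients null, fits step-1 and step-2
#' dyad-independent ERGMs with simulation-based goodness-of-fit, and
#' exports a pruned force-directed layout.  All artifacts are written under
#' `config$out_dir` and listed, with MD5 hashes, in `manifest.json`.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  emit <- function(obj, name, writer = write_report) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }

  ## ---- registry ------------------------------------------------------
  if (is.null(config$input)) {
    cfg <- config$synthetic
    cfg$seed <- derive_seed(config$seed, "registry")
    cfg <- do.call(synthetic_config, cfg[setdiff(names(cfg), NULL)])
    registry <- generate_registry(cfg)
    path <- file.path(config$out_dir, "registry.tsv")
    write_registry(registry, path)
    artifacts <- c(artifacts, path, paste0(path, ".provenance.json"))
  } else {
    registry <- read_visits(config$input)
  }
  log_stage("registry: %d visits, %d patients (%.1fs)", nrow(registry),
            length(unique(registry$patient_id)), proc.time()[["elapsed"]] - t0)

  ## ---- cohort filtering ----------------------------------------------
  fc <- filter_cohort(registry)
  emit(fc$report, "filter_report.tsv")
  emit(fc$visits, "cohort_visits.tsv", write_visits)
  professionals <- resolve_attributes(fc$visits,
                                      seed = derive_seed(config$seed, "attributes"))
  emit(as.data.frame(professionals), "professionals.tsv")
  log_stage("cohort: %d visits, %d patients, %d professionals",
            nrow(fc$visits), length(unique(fc$visits$patient_id)),
            nrow(professionals))

  ## ---- per-subgroup analysis -----------------------------------------
  nets <- list()
  stats <- list()
  n_patients <- list()
  for (sg in config$subgroups) {
    sub <- extract_subgroup(fc$visits, cohort_definition(subgroup = sg))
    n_patients[[sg]] <- length(unique(sub$patient_id))
    net <- project_sharing(build_bipartite(sub), min_shared = config$min_shared,
                           professionals = professionals,
                           keep_isolates = config$keep_isolates)
    nets[[sg]] <- net
    stats[[sg]] <- network_summary(net)
    emit(net, paste0("network_", sg, ".graphml"), write_network)
    artifacts <- c(artifacts, file.path(config$out_dir,
                                        paste0("network_", sg, ".graphml.edges.tsv")))
    emit(stats[[sg]], paste0("stats_", sg, ".json"))
    if (igraph::vcount(net) > 0) {
      pruned <- prune_small_components(net, 5L)
      if (igraph::vcount(pruned) > 0) {
        lay <- export_layout(pruned, seed = derive_seed(config$seed, paste0("layout:", sg)))
        emit(lay, paste0("layout_", sg, ".tsv"))
      }
    }
    log_stage("subgroup %s: %d patients, %d nodes, %d edges", sg,
              n_patients[[sg]], igraph::vcount(net), igraph::ecount(net))
  }

  for (sg in setdiff(config$subgroups, "all")) {
    tab <- comparison_table(stats[[sg]], fc$visits, n_patients[[sg]],
                            M = config$M,
                            seed = derive_seed(config$seed, paste0("compare:", sg)),
                            professionals = professionals,
                            min_shared = config$min_shared,
                            keep_isolates = config$keep_isolates)
    emit(tab, paste0("comparison_", sg, ".tsv"))
    log_stage("comparison %s done", sg)
  }

  ## ---- ERGMs ----------------------------------------------------------
  for (sg in config$subgroups) {
    net <- nets[[sg]]
    occ_levels <- unique(igraph::V(net)$occupation)
    if (igraph::vcount(net) < 3 || length(occ_levels) < 2) {
      log_stage("ERGM %s skipped: too few nodes or occupation levels", sg)
      next
    }
    inc_mun <- config$include_municipality &&
      length(unique(igraph::V(net)$municipality)) >= 2
    for (step in config$ergm_steps) {
      spec <- if (step == 1L) ergm_spec_step1(inc_mun) else ergm_spec_step2(inc_mun)
      fit <- fit_ergm(net, spec)
      emit(fit, sprintf("ergm_%s_step%d.json", sg, step))
      if (fit$converged) {
        g <- gof(fit, net, n_sim = config$n_sim,
                 seed = derive_seed(config$seed, sprintf("gof:%s:%d", sg, step)))
        emit(g, sprintf("gof_%s_step%d.json", sg, step))
      }
      log_stage("ERGM %s step %d: BIC %.1f", sg, step, fit$bic)
    }
  }

  ## ---- manifest --------------------------------------------------------
  manifest <- list(
    config = c(list(input = config$input %||% "synthetic"),
               config[c("subgroups", "min_shared", "keep_isolates", "M",
                        "ergm_steps", "include_municipality", "n_sim", "seed")]),
    artifacts = lapply(sort(unique(artifacts)), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("pipeline finished in %.1fs", proc.time()[["elapsed"]] - t0)
  invisible(manifest)
}
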