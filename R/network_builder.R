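# Bipartite patient-professional graph and thresholded one-mode projection.
#
# Professionals are connected in the patient-sharing network when they
# treated at least `min_shared` (default 5) distinct common patients within
# the study window.  Isolated professionals are kept as degree-0 nodes by
# default: node counts are "number of professionals", and silently dropping
# isolates would change density.

#' Resolve professional attributes (modal occupation and municipality)
#'
#' Per professional, the most frequently recorded mapped occupation class
#' and the municipality where most visits were recorded.  Exact frequency
#' ties are broken by a seeded uniform draw among the tied values; each
#' professional's draw is derived from `(seed, professional_id)` so the
#' outcome does not depend on processing order.  Tie-break outcomes are
#' returned in the `tie_breaks` attribute.
#'
#' @param visits a filtered visit table.
#' @param seed integer seed for tie-breaking.
#' @param occupation_map lookup data.frame (see [default_occupation_map()]).
#' @return data.frame with columns `professional_id`, `occupation`,
#'   `municipality`; professionals with zero visits are absent.
#' @export
resolve_attributes <- function(visits, seed = 1L,
                               occupation_map = default_occupation_map()) {
  visits <- data.table::as.data.table(visits)
  if (nrow(visits) == 0L) {
    return(structure(data.frame(professional_id = character(),
                                occupation = character(),
                                municipality = character(),
                                stringsAsFactors = FALSE),
                     tie_breaks = data.frame()))
  }
  map <- stats::setNames(occupation_map$occupation_class,
                         occupation_map$occupation_code)
  v <- visits[nzchar(professional_id)]
  v[, occ_mapped := unname(map[occupation_code])]
  v[is.na(occ_mapped), occ_mapped := "other"]

  modal <- function(x, rng_seed) {
    tab <- table(x)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) {
      list(value = top, tied = FALSE)
    } else {
      list(value = with_seed(rng_seed, sample(sort(top), 1L)), tied = TRUE)
    }
  }

  ids <- sort(unique(v$professional_id))
  occ <- character(length(ids)); mun <- character(length(ids))
  ties <- list()
  for (k in seq_along(ids)) {
    vv <- v[professional_id == ids[k]]
    mo <- modal(vv$occ_mapped, derive_seed(seed, paste0("occ:", ids[k])))
    mm <- modal(vv$municipality, derive_seed(seed, paste0("mun:", ids[k])))
    occ[k] <- mo$value; mun[k] <- mm$value
    if (mo$tied) ties[[length(ties) + 1L]] <-
      data.frame(professional_id = ids[k], attribute = "occupation", chosen = mo$value)
    if (mm$tied) ties[[length(ties) + 1L]] <-
      data.frame(professional_id = ids[k], attribute = "municipality", chosen = mm$value)
  }
  out <- data.frame(professional_id = ids, occupation = occ, municipality = mun,
                    stringsAsFactors = FALSE)
  attr(out, "tie_breaks") <- if (length(ties)) do.call(rbind, ties) else data.frame()
  out
}

#' Build the bipartite patient-professional graph
#'
#' One tie per (patient, professional) pair with at least one visit; tie
#' weight is the visit count.  Ties are only ever between the two node sets.
#'
#' @param visits a visit table.
#' @return an object of class `bipartite_graph`: a list with `ties`
#'   (data.table `patient_id`, `professional_id`, `n_visits`), `patients`
#'   and `professionals` (character vectors).
#' @export
build_bipartite <- function(visits) {
  visits <- data.table::as.data.table(visits)
  if (nrow(visits) == 0L) {
    ties <- data.table::data.table(patient_id = character(),
                                   professional_id = character(),
                                   n_visits = integer())
  } else {
    ties <- visits[nzchar(professional_id),
                   list(n_visits = .N), by = c("patient_id", "professional_id")]
    data.table::setorder(ties, patient_id, professional_id)
  }
  structure(list(ties = ties,
                 patients = sort(unique(ties$patient_id)),
                 professionals = sort(unique(ties$professional_id))),
            class = "bipartite_graph")
}

#' Project the bipartite graph to the patient-sharing network
#'
#' Professionals i and j are connected iff they share at least `min_shared`
#' distinct patients; the edge weight is the number of shared patients.
#' Isolated professionals are retained as degree-0 nodes when
#' `keep_isolates = TRUE` (the default).
#'
#' @param bg a `bipartite_graph` from [build_bipartite()].
#' @param min_shared co-occurrence threshold tau (>= 1); default 5.
#' @param professionals optional attribute table from [resolve_attributes()];
#'   when given, `occupation` and `municipality` become vertex attributes.
#' @param keep_isolates keep professionals with no qualifying edge.
#' @return an undirected simple `igraph` with edge attribute `weight`
#'   (shared-patient count) and graph attribute `min_shared`.
#' @export
project_sharing <- function(bg, min_shared = 5L, professionals = NULL,
                            keep_isolates = TRUE) {
  stopifnot(inherits(bg, "bipartite_graph"))
  if (min_shared < 1) stop("'min_shared' must be >= 1", call. = FALSE)
  profs <- bg$professionals
  nH <- length(profs)
  if (nH == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    g$min_shared <- as.integer(min_shared)
    return(g)
  }
  # shared-patient counts via the 0/1 incidence crossproduct
  i <- match(bg$ties$patient_id, bg$patients)
  j <- match(bg$ties$professional_id, profs)
  B <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(bg$patients), nH))
  S <- Matrix::crossprod(B)
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  keep <- S@x >= min_shared
  ei <- S@i[keep] + 1L
  ej <- S@j[keep] + 1L
  w <- S@x[keep]

  g <- igraph::make_empty_graph(n = nH, directed = FALSE)
  igraph::V(g)$name <- profs
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    igraph::E(g)$weight <- w
  }
  if (!is.null(professionals)) {
    idx <- match(profs, professionals$professional_id)
    igraph::V(g)$occupation <- professionals$occupation[idx]
    igraph::V(g)$municipality <- professionals$municipality[idx]
  }
  if (!keep_isolates) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  g$min_shared <- as.integer(min_shared)
  g
}

#' Remove small connected components
#'
#' Drops components with fewer than `min_size` nodes.  Intended for layout
#' export only — a force-directed drawing of many tiny components is
#' unreadable; all statistics are computed on the unpruned network.
#'
#' @param net a sharing network (`igraph`).
#' @param min_size minimum component size to keep; default 5.
#' @return the pruned `igraph`.
#' @export
prune_small_components <- function(net, min_size = 5L) {
  comp <- igraph::components(net)
  small <- which(comp$csize < min_size)
  igraph::delete_vertices(net, which(comp$membership %in% small))
}

#' Force-directed layout export
#'
#' Fruchterman-Reingold coordinates with node degree and occupation class,
#' matching the usual published encoding (node size = degree, colour =
#' occupation).  Deterministic under a fixed seed.
#'
#' @param net a sharing network (`igraph`), non-empty.
#' @param seed integer seed.
#' @return data.frame `id, x, y, degree, occupation`.
#' @export
export_layout <- function(net, seed = 1L) {
  if (igraph::vcount(net) == 0L) stop("cannot lay out an empty network", call. = FALSE)
  xy <- with_seed(seed, igraph::layout_with_fr(net))
  data.frame(id = igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net))),
             x = xy[, 1], y = xy[, 2],
             degree = igraph::degree(net),
             occupation = if (!is.null(igraph::V(net)$occupation))
               igraph::V(net)$occupation else NA_character_,
             stringsAsFactors = FALSE, row.names = NULL)
}
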