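# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (double loops, explicit path enumeration)
# and share no code with the implementation paths they check.

# -- visit-row builder ------------------------------------------------------
visit_row <- function(patient, prof, date = "2021-03-01", muni = "M1",
                      occ = "gp", svc = "general_care", icd = "", icpc = "",
                      flag = FALSE) {
  data.frame(patient_id = patient, professional_id = prof, visit_date = date,
             municipality = muni, occupation_code = occ, service_type = svc,
             icd10_codes = icd, icpc2_codes = icpc, mh_service_flag = flag,
             stringsAsFactors = FALSE)
}

visit_table <- function(...) do.call(rbind, list(...))

# -- memoized small synthetic registry (shared across test files) -----------
.fixture_env <- new.env(parent = emptyenv())

small_registry <- function() {
  if (is.null(.fixture_env$reg)) {
    cfg <- synthetic_config(n_patients_total = 400, n_professionals = 90, seed = 11)
    .fixture_env$reg <- generate_registry(cfg)
    .fixture_env$cohort <- filter_cohort(.fixture_env$reg)
    .fixture_env$profs <- resolve_attributes(.fixture_env$cohort$visits, seed = 5)
  }
  .fixture_env$reg
}
small_cohort <- function() { small_registry(); .fixture_env$cohort }
small_professionals <- function() { small_registry(); .fixture_env$profs }

# -- graph builders ---------------------------------------------------------
attr_graph <- function(edges, n, occupation = NULL, municipality = NULL,
                       name = paste0("n", seq_len(n))) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- name
  if (!is.null(occupation)) igraph::V(g)$occupation <- occupation
  if (!is.null(municipality)) igraph::V(g)$municipality <- municipality
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

random_bipartite <- function(n_prof = 20, n_pat = 100, density = 0.2, seed = 1) {
  pairs <- expand.grid(patient_id = sprintf("P%03d", seq_len(n_pat)),
                       professional_id = sprintf("H%02d", seq_len(n_prof)),
                       stringsAsFactors = FALSE)
  keep <- with_fixed_seed(seed, stats::runif(nrow(pairs)) < density)
  ties <- data.table::as.data.table(pairs[keep, ])
  ties$n_visits <- 1L
  structure(list(ties = ties,
                 patients = sort(unique(ties$patient_id)),
                 professionals = sort(unique(ties$professional_id))),
            class = "bipartite_graph")
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# -- oracle: thresholded projection by double-loop intersection -------------
oracle_projection <- function(bg, tau) {
  profs <- bg$professionals
  pats_of <- lapply(profs, function(h) bg$ties$patient_id[bg$ties$professional_id == h])
  names(pats_of) <- profs
  out <- list()
  for (a in seq_along(profs)) {
    for (b in seq_along(profs)) {
      if (a >= b) next
      shared <- length(intersect(pats_of[[a]], pats_of[[b]]))
      if (shared >= tau) {
        out[[length(out) + 1L]] <- data.frame(from = profs[a], to = profs[b],
                                              weight = shared)
      }
    }
  }
  if (!length(out)) return(data.frame(from = character(), to = character(),
                                      weight = numeric()))
  do.call(rbind, out)
}

# -- oracle: betweenness by explicit shortest-path enumeration --------------
# For every ordered pair (s, t), enumerate ALL shortest s-t paths by
# backtracking a BFS predecessor DAG, and credit each interior vertex with
# the fraction of paths through it.  Undirected convention: each unordered
# pair counted once.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  score <- numeric(n)
  for (s in seq_len(n)) {
    # BFS from s
    dist <- rep(Inf, n); dist[s] <- 0
    preds <- vector("list", n)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1) preds[[w]] <- c(preds[[w]], v)
      }
    }
    all_paths <- function(t) {
      if (t == s) return(list(s))
      out <- list()
      for (p in preds[[t]]) {
        for (pp in all_paths(p)) out[[length(out) + 1L]] <- c(pp, t)
      }
      out
    }
    for (t in seq_len(n)) {
      if (t <= s || !is.finite(dist[t])) next
      paths <- all_paths(t)
      for (pt in paths) {
        interior <- setdiff(pt, c(s, t))
        score[interior] <- score[interior] + 1 / length(paths)
      }
    }
  }
  score
}

# -- oracle: per-dyad ERGM change statistics by naive double loop -----------
oracle_change_stats <- function(nodes, spec) {
  n <- nrow(nodes)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      row <- c()
      for (term in spec$terms) {
        a <- term$attribute
        if (term$type == "edges") {
          row <- c(row, edges = 1)
        } else {
          levs <- term$levels
          if (is.null(levs)) levs <- sort(unique(nodes[[a]]))
          ai <- nodes[[a]][i]; aj <- nodes[[a]][j]
          if (term$type == "nodefactor") {
            ref <- if (is.null(term$ref)) levs[1] else term$ref
            for (l in setdiff(levs, ref)) {
              row <- c(row, stats::setNames(sum(ai == l) + sum(aj == l),
                                            paste("nodefactor", a, l, sep = ".")))
            }
          } else if (term$type == "nodematch_uniform") {
            row <- c(row, stats::setNames(as.numeric(ai == aj),
                                          paste("nodematch", a, sep = ".")))
          } else {
            for (l in levs) {
              row <- c(row, stats::setNames(as.numeric(ai == l && aj == l),
                                            paste("nodematch", a, l, sep = ".")))
            }
          }
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

# -- exhaustive full-ERGM likelihood on <= 5 nodes --------------------------
# log P(G = y | theta) with the normalizing constant summed explicitly over
# all 2^C(n,2) graphs.
enumerated_ergm_loglik <- function(X, y, theta) {
  nd <- nrow(X)
  G <- as.matrix(expand.grid(rep(list(0:1), nd)))
  eta <- drop((G %*% X) %*% theta)
  logZ <- max(eta) + log(sum(exp(eta - max(eta))))
  sum(drop(crossprod(X, y)) * theta) - logZ
}

enumerated_ergm_mle <- function(X, y) {
  nd <- nrow(X)
  G <- as.matrix(expand.grid(rep(list(0:1), nd)))
  S <- G %*% X
  obs <- drop(crossprod(X, y))
  negll <- function(th) {
    e <- drop(S %*% th); m <- max(e)
    -(sum(obs * th) - (m + log(sum(exp(e - m)))))
  }
  stats::optim(rep(0, ncol(X)), negll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))$par
}

five_node_attr_nodes <- function() {
  data.frame(name = paste0("n", 1:5),
             occupation = c("physician", "physician", "nurse", "nurse", "other"),
             municipality = c("M1", "M2", "M1", "M2", "M1"),
             stringsAsFactors = FALSE)
}

graph_from_dyads <- function(y, nodes, dyads) {
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes$name
  igraph::V(g)$occupation <- nodes$occupation
  igraph::V(g)$municipality <- nodes$municipality
  if (any(y == 1)) g <- igraph::add_edges(g, t(dyads[y == 1, , drop = FALSE]))
  g
}
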