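# Dyad-independent exponential random graph models.
#
# With only dyad-independent terms the ERGM likelihood factorizes into
# independent Bernoulli terms over the N(N-1)/2 dyads with
# logit P(Y_ij = 1) = theta . x_ij, where x_ij is the dyad's change-
# statistic vector.  Estimation is therefore exact maximum likelihood on
# the dyad table (Newton-Raphson, gradient tolerance 1e-8) — no MCMC.
# Terms supported: edges; nodefactor (attribute main effects, reference
# level omitted); uniform homophily (nodematch); differential homophily
# (per-level nodematch).  Dyad-dependent terms are deliberately out of
# scope.

#' ERGM term constructors
#'
#' `term_edges()` is the intercept (tie count).  `term_nodefactor()` adds
#' one column per non-reference attribute level, counting the dyad's
#' endpoints at that level (0/1/2).  `term_nodematch()` is 1 iff both
#' endpoints share the attribute (uniform homophily); with `diff = TRUE`
#' one indicator per level (differential homophily: both endpoints at that
#' level).
#'
#' @param attribute vertex attribute name.
#' @param ref reference level for `term_nodefactor` (default: first sorted
#'   level observed on the network).
#' @param diff differential (per-level) homophily?
#' @param levels optional explicit level order.
#' @return a term descriptor for [ergm_spec()].
#' @export
term_edges <- function() structure(list(type = "edges"), class = "ergm_term")

#' @rdname term_edges
#' @export
term_nodefactor <- function(attribute, ref = NULL, levels = NULL) {
  structure(list(type = "nodefactor", attribute = attribute, ref = ref,
                 levels = levels), class = "ergm_term")
}

#' @rdname term_edges
#' @export
term_nodematch <- function(attribute, diff = FALSE, levels = NULL) {
  structure(list(type = if (diff) "nodematch_differential" else "nodematch_uniform",
                 attribute = attribute, levels = levels), class = "ergm_term")
}

#' Dyad-independent ERGM specification
#'
#' @param ... term descriptors from [term_edges()], [term_nodefactor()],
#'   [term_nodematch()].  Duplicate terms, and uniform plus differential
#'   homophily on the same attribute, are rejected.
#' @return object of class `ergm_spec`.
#' @export
ergm_spec <- function(...) {
  terms <- list(...)
  if (!length(terms) || !all(vapply(terms, inherits, TRUE, "ergm_term"))) {
    stop("specification error: ergm_spec() takes term_*() descriptors", call. = FALSE)
  }
  keys <- vapply(terms, function(t) paste(t$type, t$attribute %||% "", sep = ":"), "")
  if (anyDuplicated(keys)) {
    stop("specification error: duplicate ERGM terms", call. = FALSE)
  }
  for (a in unique(unlist(lapply(terms, `[[`, "attribute")))) {
    tt <- keys[grepl(paste0(":", a, "$"), keys)]
    if (all(c(paste0("nodematch_uniform:", a),
              paste0("nodematch_differential:", a)) %in% tt)) {
      stop("specification error: uniform and differential homophily on '",
           a, "' are mutually exclusive", call. = FALSE)
    }
  }
  structure(list(terms = terms), class = "ergm_spec")
}

#' Standard model specifications
#'
#' `ergm_spec_step1()`: edges, municipality main effect and uniform
#' homophily, occupation main effect and uniform homophily.
#' `ergm_spec_step2()`: as step 1 but with differential occupation
#' homophily replacing the uniform occupation term (municipality terms
#' unchanged).  Reference levels: physician; lowest-coded municipality.
#'
#' @param include_municipality include the municipality terms (TRUE for the
#'   full published models; FALSE gives occupation-only models).
#' @return an [ergm_spec()].
#' @export
ergm_spec_step1 <- function(include_municipality = TRUE) {
  terms <- list(term_edges())
  if (include_municipality) {
    terms <- c(terms, list(term_nodefactor("municipality"),
                           term_nodematch("municipality")))
  }
  terms <- c(terms, list(term_nodefactor("occupation", ref = "physician"),
                         term_nodematch("occupation")))
  do.call(ergm_spec, terms)
}

#' @rdname ergm_spec_step1
#' @export
ergm_spec_step2 <- function(include_municipality = TRUE) {
  terms <- list(term_edges())
  if (include_municipality) {
    terms <- c(terms, list(term_nodefactor("municipality"),
                           term_nodematch("municipality")))
  }
  terms <- c(terms, list(term_nodefactor("occupation", ref = "physician"),
                         term_nodematch("occupation", diff = TRUE)))
  do.call(ergm_spec, terms)
}

# Build the per-dyad design matrix from a node attribute table.
# nodes: data.frame with one row per node and the attributes the spec
# needs.  Returns list(X, dyads) with dyads an n_dyads x 2 index matrix
# (i < j).
dyad_design <- function(nodes, spec) {
  n <- nrow(nodes)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  i <- ij[, 1]; j <- ij[, 2]
  cols <- list()
  for (term in spec$terms) {
    a <- term$attribute
    if (term$type != "edges") {
      if (is.null(nodes[[a]]) || anyNA(nodes[[a]])) {
        bad <- if (is.null(nodes[[a]])) "all" else
          paste(utils::head(which(is.na(nodes[[a]])), 5), collapse = ", ")
        stop("data error: attribute '", a, "' missing for node(s): ", bad,
             call. = FALSE)
      }
      levs <- term$levels %||% sort(unique(nodes[[a]]))
      ai <- nodes[[a]][i]; aj <- nodes[[a]][j]
    }
    switch(term$type,
      edges = {
        cols[["edges"]] <- rep(1, length(i))
      },
      nodefactor = {
        ref <- term$ref %||% levs[1]
        if (!ref %in% levs) {
          stop("specification error: reference level '", ref,
               "' not observed for attribute '", a, "'", call. = FALSE)
        }
        for (l in setdiff(levs, ref)) {
          cols[[paste("nodefactor", a, l, sep = ".")]] <- (ai == l) + (aj == l)
        }
      },
      nodematch_uniform = {
        cols[[paste("nodematch", a, sep = ".")]] <- as.numeric(ai == aj)
      },
      nodematch_differential = {
        for (l in levs) {
          cols[[paste("nodematch", a, l, sep = ".")]] <- as.numeric(ai == l & aj == l)
        }
      })
  }
  X <- do.call(cbind, cols)
  list(X = X, dyads = ij)
}

nodes_from_graph <- function(net, spec) {
  attrs <- unique(unlist(lapply(spec$terms, `[[`, "attribute")))
  nodes <- data.frame(name = igraph::V(net)$name %||%
                        as.character(seq_len(igraph::vcount(net))),
                      stringsAsFactors = FALSE)
  for (a in attrs) {
    nodes[[a]] <- igraph::vertex_attr(net, a)
    if (is.null(nodes[[a]])) {
      stop("data error: network lacks vertex attribute '", a, "'", call. = FALSE)
    }
  }
  # carry the remaining vertex attributes too, so simulations inherit them
  for (a in setdiff(igraph::vertex_attr_names(net), c("name", attrs))) {
    nodes[[a]] <- igraph::vertex_attr(net, a)
  }
  nodes
}

#' Per-dyad change statistics and edge indicators
#'
#' One row per unordered dyad (i < j, column-major over the upper
#' triangle).  Column naming follows the usual convention:
#' `edges`, `nodefactor.<attr>.<level>` (reference omitted),
#' `nodematch.<attr>`, `nodematch.<attr>.<level>`.
#'
#' @param net a sharing network (`igraph`) with the spec's attributes.
#' @param spec an [ergm_spec()].
#' @return list with `X` (n_dyads x k design matrix), `y` (0/1 edge
#'   indicator), `dyads` (n_dyads x 2 node-index matrix).
#' @export
change_statistics <- function(net, spec) {
  nodes <- nodes_from_graph(net, spec)
  des <- dyad_design(nodes, spec)
  n <- nrow(nodes)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  y <- as.numeric(A[des$dyads] > 0)
  list(X = des$X, y = y, dyads = des$dyads, nodes = nodes)
}

# Newton-Raphson logistic MLE with step halving; tolerance on the gradient
# max-norm.  Columns listed in `fixed_neg`/`fixed_pos` are held at -Inf/+Inf
# (structurally separated indicators).
logistic_mle <- function(X, y, tol = 1e-8, max_iter = 200L) {
  k <- ncol(X)
  theta <- rep(0, k)
  ll <- function(th) {
    eta <- drop(X %*% th)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - p))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    W <- p * (1 - p)
    H <- crossprod(X * W, X)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) {
      # singular Hessian (collinear columns, boundary drift): ridge fallback
      ridge <- 1e-6 * max(diag(H), 1)
      step <- tryCatch(solve(H + diag(ridge, ncol(H)), grad),
                       error = function(e) NULL)
      if (is.null(step)) break
    }
    lambda <- 1
    repeat {
      cand <- theta + lambda * step
      ll_new <- ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- theta; ll_new <- ll_old; break }
    }
    theta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% theta)
  p <- stats::plogis(eta)
  H <- crossprod(X * (p * (1 - p)), X)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  list(theta = stats::setNames(theta, colnames(X)), loglik = ll_old,
       vcov = vcov, converged = converged,
       grad_norm = max(abs(drop(crossprod(X, y - p)))))
}

# Detect structural separation: a 0/1 indicator column whose active dyads
# are all non-edges (coefficient diverges to -Inf) or all edges (+Inf).
# The `edges` column is exempt (an empty graph has a finite MLE only in the
# degenerate sense; flagged separately by callers).
detect_separation <- function(X, y) {
  out <- list(neg = character(), pos = character())
  for (cn in colnames(X)) {
    if (cn == "edges") next
    x <- X[, cn]
    if (!all(x %in% c(0, 1))) next
    act <- x == 1
    if (!any(act)) next
    if (all(y[act] == 0)) out$neg <- c(out$neg, cn)
    else if (all(y[act] == 1)) out$pos <- c(out$pos, cn)
  }
  out
}

# One-sided 95% profile bound for a structurally separated indicator
# coefficient: the value at which the profile log-likelihood (other
# coefficients re-maximized) drops qchisq(0.95, 1)/2 below the maximum.
profile_bound <- function(X, y, col, direction, loglik_max, tol = 1e-8) {
  free <- setdiff(colnames(X), col)
  crit <- loglik_max - stats::qchisq(0.95, 1) / 2
  prof <- function(val) {
    offset <- X[, col] * val
    Xf <- X[, free, drop = FALSE]
    th <- rep(0, ncol(Xf))
    for (it in 1:50) {
      eta <- drop(Xf %*% th) + offset
      p <- stats::plogis(eta)
      g <- drop(crossprod(Xf, y - p))
      if (max(abs(g)) < tol) break
      H <- crossprod(Xf * (p * (1 - p)), Xf)
      step <- tryCatch(solve(H, g), error = function(e) rep(0, ncol(Xf)))
      th <- th + step
    }
    eta <- drop(Xf %*% th) + offset
    sum(y * eta - log1p(exp(eta)))
  }
  lo <- if (direction < 0) -30 else 0
  hi <- if (direction < 0) 10 else 30
  # bound is the largest (neg. separation) value with prof(val) >= crit
  f <- function(v) prof(v) - crit
  tryCatch(stats::uniroot(f, c(lo, hi))$root, error = function(e) NA_real_)
}

#' Fit a dyad-independent ERGM by exact maximum likelihood
#'
#' Maximizes the exact dyadic Bernoulli likelihood over all N(N-1)/2 dyads
#' (valid because every supported term is dyad-independent), with Wald 95%
#' confidence intervals.  Structurally separated homophily/main-effect
#' indicators (no edge, or all edges, among their active dyads) are flagged,
#' fixed at the appropriate infinity, and reported with a one-sided 95%
#' profile-likelihood bound in place of a Wald interval.
#'
#' @param net a simple undirected sharing network (`igraph`).
#' @param spec an [ergm_spec()].
#' @param bic_n sample size for the BIC penalty; defaults to the dyad count
#'   N(N-1)/2.
#' @return object of class `ergm_fit`: `coefficients` table (term,
#'   estimate, se, ci_lower, ci_upper, separated), `loglik`, `aic`, `bic`,
#'   `n_dyads`, `n_nodes`, `converged`, `spec`, `nodes`.
#' @export
fit_ergm <- function(net, spec, bic_n = NULL) {
  cs <- change_statistics(net, spec)
  X <- cs$X; y <- cs$y
  n_dyads <- length(y)
  sep <- detect_separation(X, y)
  sep_cols <- c(sep$neg, sep$pos)
  free_cols <- setdiff(colnames(X), sep_cols)
  # separated indicator dyads contribute a likelihood factor of exactly 1
  # at the +/-Inf MLE (p -> y on those dyads); fit the rest on the others
  active_sep <- if (length(sep_cols))
    rowSums(X[, sep_cols, drop = FALSE] != 0) > 0 else rep(FALSE, n_dyads)
  mle <- logistic_mle(X[!active_sep, free_cols, drop = FALSE], y[!active_sep])
  k_free <- length(free_cols)
  se <- sqrt(pmax(diag(mle$vcov), 0))
  coefs <- data.frame(term = free_cols,
                      estimate = unname(mle$theta),
                      se = se,
                      ci_lower = unname(mle$theta) - 1.96 * se,
                      ci_upper = unname(mle$theta) + 1.96 * se,
                      separated = FALSE, stringsAsFactors = FALSE)
  # quasi-separation that only shows up jointly (e.g. every observed edge is
  # a within-municipality dyad: edges and nodematch diverge in tandem while
  # the gradient still vanishes) — flag, keep estimates
  coefs$separated[abs(coefs$estimate) > 10 & (is.na(coefs$se) | coefs$se > 10)] <- TRUE
  loglik <- mle$loglik
  if (length(sep_cols)) {
    for (cn in sep$neg) {
      b <- profile_bound(X, y, cn, -1, loglik)
      coefs <- rbind(coefs, data.frame(term = cn, estimate = -Inf, se = NA_real_,
                                       ci_lower = -Inf, ci_upper = b,
                                       separated = TRUE))
    }
    for (cn in sep$pos) {
      b <- profile_bound(X, y, cn, +1, loglik)
      coefs <- rbind(coefs, data.frame(term = cn, estimate = Inf, se = NA_real_,
                                       ci_lower = b, ci_upper = Inf,
                                       separated = TRUE))
    }
    ord <- match(colnames(X), coefs$term)
    coefs <- coefs[ord, ]
    rownames(coefs) <- NULL
  }
  k <- ncol(X)
  bn <- bic_n %||% n_dyads
  structure(list(spec = spec, coefficients = coefs, loglik = loglik,
                 aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(bn),
                 n_dyads = n_dyads, n_nodes = igraph::vcount(net),
                 converged = mle$converged,
                 separated = length(sep_cols) > 0,
                 nodes = cs$nodes),
            class = "ergm_fit")
}

#' @export
print.ergm_fit <- function(x, ...) {
  cat(sprintf("Dyad-independent ERGM: %d nodes, %d dyads, loglik %.2f\n",
              x$n_nodes, x$n_dyads, x$loglik))
  cat(sprintf("AIC %.2f   BIC %.2f   converged: %s%s\n", x$aic, x$bic,
              x$converged, if (x$separated) "   [separation detected]" else ""))
  tab <- x$coefficients
  tab$estimate <- sprintf("%.3f", tab$estimate)
  tab$ci <- sprintf("[%.3f, %.3f]", tab$ci_lower, tab$ci_upper)
  print(tab[, c("term", "estimate", "ci", "separated")], row.names = FALSE)
  invisible(x)
}

# Fitted per-dyad tie probabilities (separated terms at their limits).
fitted_dyad_probs <- function(fit) {
  des <- dyad_design(fit$nodes, fit$spec)
  th <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  eta <- rep(0, nrow(des$X))
  for (cn in colnames(des$X)) {
    v <- th[[cn]]
    contrib <- if (is.finite(v)) des$X[, cn] * v else
      ifelse(des$X[, cn] != 0, sign(v) * Inf, 0)
    eta <- eta + contrib
  }
  list(p = stats::plogis(eta), dyads = des$dyads)
}

#' Simulate networks from a fitted dyad-independent ERGM
#'
#' Each dyad is an independent Bernoulli draw with its fitted probability;
#' node attributes are copied from the observed network.
#'
#' @param fit an [fit_ergm()] result (must have converged).
#' @param n_sim number of networks (default 100).
#' @param seed integer seed.
#' @return list of `igraph` networks.
#' @export
simulate_from_fit <- function(fit, n_sim = 100L, seed = 1L) {
  if (!fit$converged) stop("refusing to simulate from an unconverged fit", call. = FALSE)
  fp <- fitted_dyad_probs(fit)
  n <- nrow(fit$nodes)
  with_seed(seed, lapply(seq_len(n_sim), function(s) {
    y <- stats::rbinom(length(fp$p), 1L, fp$p) == 1L
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- fit$nodes$name
    for (a in setdiff(names(fit$nodes), "name")) {
      g <- igraph::set_vertex_attr(g, a, value = fit$nodes[[a]])
    }
    if (any(y)) g <- igraph::add_edges(g, t(fp$dyads[y, , drop = FALSE]))
    g
  }))
}

# --- goodness-of-fit ------------------------------------------------------

degree_counts <- function(g, max_d) {
  tabulate(igraph::degree(g) + 1L, nbins = max_d + 1L)
}

# edgewise shared partners: per existing edge, |N(i) intersect N(j)|
esp_values <- function(g) {
  if (igraph::ecount(g) == 0L) return(integer())
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  CN <- A %*% A
  el <- igraph::as_edgelist(g, names = FALSE)
  as.integer(CN[el])
}

geodesic_values <- function(g) {
  d <- igraph::distances(g, weights = NA)
  d[upper.tri(d)]
}

#' Simulation-based goodness-of-fit for a dyad-independent ERGM
#'
#' Compares the observed network's degree distribution, edgewise
#' shared-partner distribution and minimum geodesic distance distribution
#' (with an unreachable category) against `n_sim` networks simulated from
#' the fitted model.  For each bin the simulated median and 2.5/97.5
#' percentiles are reported, plus the fraction of bins whose observed count
#' lies inside the envelope.
#'
#' @param fit an [fit_ergm()] result.
#' @param observed the observed network.
#' @param n_sim simulation count (default 100).
#' @param seed integer seed.
#' @return object of class `gof_report`: per-statistic data.frames
#'   (`bin`, `observed`, `sim_median`, `sim_lower`, `sim_upper`) and
#'   `coverage`, a named vector of inside-envelope fractions.
#' @export
gof <- function(fit, observed, n_sim = 100L, seed = 1L) {
  sims <- simulate_from_fit(fit, n_sim = n_sim, seed = seed)

  summarize <- function(obs_vals, sim_vals_list, bins) {
    count_in_bins <- function(v) {
      vapply(bins, function(b) {
        if (identical(b, "unreachable")) sum(!is.finite(v)) else sum(v == as.numeric(b))
      }, 0)
    }
    obs <- count_in_bins(obs_vals)
    simmat <- vapply(sim_vals_list, count_in_bins, numeric(length(bins)))
    if (is.null(dim(simmat))) simmat <- matrix(simmat, nrow = length(bins))
    data.frame(bin = bins,
               observed = obs,
               sim_median = apply(simmat, 1, stats::median),
               sim_lower = apply(simmat, 1, stats::quantile, 0.025),
               sim_upper = apply(simmat, 1, stats::quantile, 0.975),
               stringsAsFactors = FALSE)
  }

  obs_deg <- igraph::degree(observed)
  sim_deg <- lapply(sims, igraph::degree)
  deg_bins <- as.character(0:max(c(obs_deg, unlist(sim_deg), 0)))
  degree_tab <- summarize(obs_deg, sim_deg, deg_bins)

  obs_esp <- esp_values(observed)
  sim_esp <- lapply(sims, esp_values)
  esp_bins <- as.character(0:max(c(obs_esp, unlist(sim_esp), 0)))
  esp_tab <- summarize(obs_esp, sim_esp, esp_bins)

  obs_geo <- geodesic_values(observed)
  sim_geo <- lapply(sims, geodesic_values)
  finite_all <- c(obs_geo[is.finite(obs_geo)],
                  unlist(lapply(sim_geo, function(v) v[is.finite(v)])))
  max_geo <- if (length(finite_all)) max(finite_all) else 1
  geo_bins <- c(as.character(1:max_geo), "unreachable")
  geo_tab <- summarize(obs_geo, sim_geo, geo_bins)

  cov <- function(tab) mean(tab$observed >= tab$sim_lower & tab$observed <= tab$sim_upper)
  structure(list(degree = degree_tab, esp = esp_tab, geodesic = geo_tab,
                 n_sim = n_sim,
                 coverage = c(degree = cov(degree_tab), esp = cov(esp_tab),
                              geodesic = cov(geo_tab))),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("ERGM goodness-of-fit (%d simulated networks)\n", x$n_sim))
  cat("fraction of bins with observed value inside the 95% envelope:\n")
  print(round(x$coverage, 3))
  invisible(x)
}
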