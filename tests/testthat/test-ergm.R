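test_that("spec construction rejects invalid term combinations", {
  expect_error(ergm_spec(term_edges(), term_edges()), "duplicate")
  expect_error(ergm_spec(term_edges(), term_nodematch("occupation"),
                         term_nodematch("occupation", diff = TRUE)),
               "mutually exclusive")
  expect_error(ergm_spec("edges"), "term")
})

test_that("change statistics follow the dyad definitions", {
  nodes <- data.frame(name = c("a", "b", "c"),
                      occupation = c("nurse", "nurse", "other"))
  g <- attr_graph(c(1, 2), 3, occupation = nodes$occupation,
                  name = nodes$name)
  spec <- ergm_spec(term_edges(),
                    term_nodefactor("occupation", ref = "physician",
                                    levels = c("physician", "nurse", "other")),
                    term_nodematch("occupation"))
  cs <- change_statistics(g, spec)
  # dyads ordered (1,2), (1,3), (2,3)
  expect_equal(unname(cs$X[1, "nodefactor.occupation.nurse"]), 2)  # (nurse, nurse)
  expect_equal(unname(cs$X[1, "nodematch.occupation"]), 1)
  expect_equal(unname(cs$X[2, "nodefactor.occupation.other"]), 1)  # (nurse, other)
  expect_equal(unname(cs$X[2, "nodematch.occupation"]), 0)
  expect_equal(cs$y, c(1, 0, 0))
  # differential homophily: only same-level pairs score, per level
  spec_d <- ergm_spec(term_edges(), term_nodematch("occupation", diff = TRUE))
  cs_d <- change_statistics(g, spec_d)
  expect_equal(unname(cs_d$X[1, "nodematch.occupation.nurse"]), 1)
  expect_equal(unname(cs_d$X[2, "nodematch.occupation.nurse"]), 0)
  expect_equal(sum(cs_d$X[, "nodematch.occupation.other"]), 0)
  # missing attribute errors, naming the problem
  g2 <- attr_graph(c(1, 2), 3)
  expect_error(change_statistics(g2, spec), "occupation")
})

test_that("change statistics match a naive double-loop oracle on 6 nodes", {
  nodes <- data.frame(name = paste0("n", 1:6),
                      occupation = c("physician", "physician", "nurse", "nurse",
                                     "other", "other"),
                      municipality = c("M1", "M2", "M1", "M2", "M1", "M2"),
                      stringsAsFactors = FALSE)
  g <- attr_graph(c(1,2, 3,4, 5,6, 1,6), 6, occupation = nodes$occupation,
                  municipality = nodes$municipality, name = nodes$name)
  for (spec in list(ergm_spec_step1(TRUE), ergm_spec_step2(TRUE))) {
    cs <- change_statistics(g, spec)
    want <- oracle_change_stats(nodes, spec)
    expect_equal(colnames(cs$X), colnames(want))
    expect_equal(unname(cs$X), unname(want))
  }
})

test_that("edges-only MLE has the logit closed form", {
  g <- attr_graph(c(1,2, 2,3, 3,4), 4)
  fit <- fit_ergm(g, ergm_spec(term_edges()))
  expect_equal(fit$coefficients$estimate, stats::qlogis(3 / 6), tolerance = 1e-8)
  expect_true(fit$converged)
  # information-criterion identities hold by construction, asserted anyway
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 1)
  expect_equal(fit$bic, -2 * fit$loglik + 1 * log(6))
  expect_identical(fit$n_dyads, 6L)
})

test_that("dyadic likelihood equals the exhaustively enumerated ERGM likelihood", {
  nodes <- five_node_attr_nodes()
  spec <- ergm_spec_step1(TRUE)
  d <- psnet:::dyad_design(nodes, spec)
  set.seed(42)
  for (r in 1:3) {
    theta <- runif(ncol(d$X), -1.5, 1.5)
    y <- rbinom(10, 1, 0.5)
    eta <- drop(d$X %*% theta)
    dyadic <- sum(y * eta - log1p(exp(eta)))
    expect_equal(dyadic, enumerated_ergm_loglik(d$X, y, theta), tolerance = 1e-10)
  }
})

test_that("five-node MLE equals the enumeration argmax (frozen interior case)", {
  nodes <- five_node_attr_nodes()
  spec <- ergm_spec_step1(FALSE)
  d <- psnet:::dyad_design(nodes, spec)
  y <- c(0, 1, 0, 1, 0, 0, 0, 1, 0, 0)   # graph 139/1024: interior MLE
  fit <- fit_ergm(graph_from_dyads(y, nodes, d$dyads), spec)
  want <- enumerated_ergm_mle(d$X, y)
  expect_lt(max(abs(fit$coefficients$estimate - want)), 1e-6)
})

test_that("parameter recovery within 3 SE on simulated networks", {
  spec <- ergm_spec(term_edges(), term_nodematch("occupation"))
  theta <- c(edges = -2.5, nodematch.occupation = 0.8)
  ok <- 0
  for (s in 1:5) {
    g <- generate_ergm_network(300, c(physician = 0.3, nurse = 0.5, other = 0.2),
                               3, spec, theta, seed = 100 + s)
    fit <- fit_ergm(g, spec)
    est <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
    se <- stats::setNames(fit$coefficients$se, fit$coefficients$term)
    if (all(abs(est[names(theta)] - theta) <= 3 * se[names(theta)])) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("mean-value principle: expected statistics at the MLE match observed", {
  spec <- ergm_spec(term_edges(), term_nodematch("occupation"))
  g <- generate_ergm_network(120, c(physician = 0.4, nurse = 0.6), 2, spec,
                             c(edges = -1.5, nodematch.occupation = 0.6), seed = 8)
  fit <- fit_ergm(g, spec)
  cs <- change_statistics(g, spec)
  p <- psnet:::fitted_dyad_probs(fit)$p
  # at the MLE, X' p equals X' y (score = 0)
  expect_equal(drop(crossprod(cs$X, p)), drop(crossprod(cs$X, cs$y)),
               tolerance = 1e-6)
})

test_that("structural separation is flagged with a profile bound", {
  # no nurse-nurse edges at all: differential nurse homophily -> -Inf
  nodes_occ <- c(rep("physician", 5), rep("nurse", 5))
  edges <- c(1,2, 1,3, 2,3, 3,4, 4,5, 1,6, 2,7, 3,8)  # no edge within nurses
  g <- attr_graph(edges, 10, occupation = nodes_occ)
  spec <- ergm_spec(term_edges(), term_nodematch("occupation", diff = TRUE))
  fit <- fit_ergm(g, spec)
  row <- fit$coefficients[fit$coefficients$term == "nodematch.occupation.nurse", ]
  expect_true(row$separated)
  expect_identical(row$estimate, -Inf)
  expect_true(is.finite(row$ci_upper))  # one-sided profile bound
  expect_true(fit$separated)
})

test_that("simulation from a fit is deterministic and moment-correct", {
  g <- attr_graph(c(1,2, 2,3, 3,4, 4,1), 6,
                  occupation = c("a", "a", "b", "b", "a", "b"))
  fit <- fit_ergm(g, ergm_spec(term_edges()))
  s1 <- simulate_from_fit(fit, n_sim = 5, seed = 77)
  s2 <- simulate_from_fit(fit, n_sim = 5, seed = 77)
  expect_identical(lapply(s1, igraph::as_edgelist),
                   lapply(s2, igraph::as_edgelist))
  # edges-only fit: simulated edge counts ~ Binomial(n_dyads, density)
  d <- 4 / 15
  sims <- simulate_from_fit(fit, n_sim = 200, seed = 3)
  counts <- vapply(sims, igraph::ecount, 0)
  expect_lt(abs(mean(counts) - 15 * d),
            3 * sqrt(15 * d * (1 - d) / 200))
  # attributes are carried over
  expect_identical(igraph::V(s1[[1]])$occupation, igraph::V(g)$occupation)
})

test_that("all-zero fitted probabilities give empty simulations", {
  g <- attr_graph(integer(), 4)
  fit <- fit_ergm(g, ergm_spec(term_edges()))
  # empty graph: edges MLE diverges to -Inf; probabilities underflow to 0
  sims <- simulate_from_fit(fit, n_sim = 3, seed = 1)
  expect_true(all(vapply(sims, igraph::ecount, 0) == 0L))
})

test_that("GOF distributions have the right closed forms", {
  tri <- attr_graph(c(1,2, 2,3, 1,3), 3, occupation = c("a", "a", "b"))
  expect_identical(psnet:::esp_values(tri), c(1L, 1L, 1L))
  fit <- fit_ergm(tri, ergm_spec(term_edges()))
  # observed = triangle itself; esp table must put all 3 edges in bin "1"
  rep <- gof(fit, tri, n_sim = 10, seed = 2)
  expect_equal(rep$esp$observed[rep$esp$bin == "1"], 3)
  # empty observed network: all degree mass at 0
  empty <- attr_graph(integer(), 3, occupation = c("a", "a", "b"))
  rep2 <- gof(fit, empty, n_sim = 5, seed = 2)
  expect_equal(rep2$degree$observed[rep2$degree$bin == "0"], 3)
})
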