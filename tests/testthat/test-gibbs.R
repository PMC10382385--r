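test_that("connection graph finds adduct and biochemical edges", {
  db <- toy_db(connections = data.frame(compound_id_a = "CPD1",
                                        compound_id_b = "CPD3"))
  annot <- structure(data.frame(
    feature_id = c("F1", "F1", "F2", "F3"),
    cluster_id = c(1L, 1L, 1L, 2L),
    compound_id = c("CPD1", "UNKNOWN", "CPD1", "CPD3"),
    adduct = c("[M+H]+", NA, "[M+Na]+", "[M+H]+"),
    prior = c(0.9, 0.1, 1, 1), posterior = NA_real_,
    stringsAsFactors = FALSE), class = c("ipa_annotations", "data.frame"))
  g <- build_connections(annot, db, bio_mode = "db_edges")
  # same compound, same cluster, different adducts -> one add edge
  expect_equal(nrow(g$add), 1)
  expect_setequal(as.vector(g$add), c(1L, 3L))
  # CPD1-CPD3 listed neighbours, across units -> bio edges (rows 1-4, 3-4)
  expect_equal(nrow(g$bio), 2)
  expect_false(any(g$bio == 2) || any(g$add == 2)) # unknown has no edges
  # single unit -> empty graph
  g1 <- build_connections(annot[1:2, ], db, bio_mode = "db_edges")
  expect_equal(nrow(g1$bio) + nrow(g1$add), 0)
  # missing sidecar instructs mass_diff mode
  expect_error(build_connections(annot, toy_db(), bio_mode = "db_edges"),
               "mass_diff")
})

test_that("mass-difference mode links glycosylated pairs", {
  cmp <- data.frame(
    compound_id = c("A", "B", "C"),
    name = c("aglycone", "glycoside", "unrelated"),
    formula = c("C10H12O2", "C16H22O7", "C9H11NO2"),
    stringsAsFactors = FALSE)
  db <- ipa_db(cmp) # mass from formula; B - A = C6H10O5 = 162.0528
  annot <- structure(data.frame(
    feature_id = c("F1", "F2", "F3"), cluster_id = 1:3,
    compound_id = c("A", "B", "C"),
    adduct = "[M+H]+", prior = 1, posterior = NA_real_,
    stringsAsFactors = FALSE), class = c("ipa_annotations", "data.frame"))
  g <- build_connections(annot, db, bio_mode = "mass_diff")
  expect_equal(nrow(g$bio), 1)
  expect_setequal(as.vector(g$bio), c(1L, 2L))
})

test_that("with no connections the posteriors reduce to the priors", {
  set.seed(21)
  sim <- simulate_dataset(n_compounds = 5L, decoys_per_compound = 1L,
                          seed = 21)
  f <- cluster_features(sim$features)
  f <- map_isotope_patterns(f)
  a <- compute_priors(f, sim$db)
  empty <- structure(list(bio = matrix(integer(0), ncol = 2),
                          add = matrix(integer(0), ncol = 2),
                          n_rows = nrow(a)), class = "connection_graph")
  n_iter <- 5000L
  burn_in <- 1000L
  p <- suppressMessages(
    gibbs_posterior(a, empty, n_iter = n_iter, burn_in = burn_in,
                    seed = 77))
  n_rec <- n_iter - burn_in
  bound <- 3 * sqrt(p$prior * (1 - p$prior) / n_rec) + 1e-9
  expect_true(all(abs(p$posterior - p$prior) <= bound))
})

test_that("two-unit posteriors match the product-form joint exactly", {
  # 2 units x 2 candidates, one bio edge between (u1,c1) and (u2,c1):
  # for two units the pseudo-count conditional is the full conditional of
  # P(x1,x2) proportional to p1(x1) p2(x2) (delta + [edge]) (delta)
  p1 <- c(0.7, 0.3)
  p2 <- c(0.4, 0.6)
  delta <- 1
  joint <- outer(p1, p2) * (delta + (outer(1:2, 1:2,
                                           function(i, j) i == 1 & j == 1)))
  joint <- joint / sum(joint)
  exp_u1 <- rowSums(joint)
  exp_u2 <- colSums(joint)
  inst <- list(priors = list(p1, p2), bio = matrix(c(1L, 3L), ncol = 2),
               add = NULL, sizes = c(2L, 2L), offsets = c(0L, 2L))
  post <- run_gibbs_on_instance(inst, n_iter = 50000L, seed = 5)
  expect_equal(post[[1]], exp_u1, tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(post[[2]], exp_u2, tolerance = 0.02, ignore_attr = TRUE)
  # the independent kernel-enumeration oracle agrees with the closed form
  oracle <- enumerate_gibbs_stationary(inst$priors, bio = inst$bio)
  expect_equal(oracle[[1]], exp_u1, tolerance = 1e-9, ignore_attr = TRUE)
  # the connected candidate gains posterior relative to its prior
  expect_gt(post[[1]][1], p1[1])
  expect_gt(post[[2]][1], p2[1])
})

test_that("sampler visit frequencies match the enumerated stationary law", {
  set.seed(31)
  for (rep in 1:6) {
    inst <- random_gibbs_instance()
    oracle <- enumerate_gibbs_stationary(inst$priors, bio = inst$bio,
                                         add = inst$add)
    post <- run_gibbs_on_instance(inst, n_iter = 50000L,
                                  seed = 1000 + rep)
    tv <- vapply(seq_along(oracle), function(f) {
      sum(abs(oracle[[f]] - post[[f]])) / 2
    }, numeric(1))
    expect_lt(max(tv), 0.02)
  }
})

test_that("the sampler is deterministic given a seed", {
  set.seed(41)
  inst <- random_gibbs_instance()
  a <- run_gibbs_on_instance(inst, n_iter = 2000L, burn_in = 200L,
                             seed = 9)
  b <- run_gibbs_on_instance(inst, n_iter = 2000L, burn_in = 200L,
                             seed = 9)
  expect_identical(a, b)
  c <- run_gibbs_on_instance(inst, n_iter = 2000L, burn_in = 200L,
                             seed = 10)
  expect_false(identical(a, c))
})

test_that("per-sweep cost in conditional evaluations is the candidate count", {
  set.seed(51)
  for (rep in 1:3) {
    inst <- random_gibbs_instance(max_units = 4L, max_cands = 3L)
    n_units <- length(inst$priors)
    annot <- data.frame(
      feature_id = rep(sprintf("U%02d", seq_len(n_units)), inst$sizes),
      cluster_id = 1L, compound_id = sprintf("X%d", seq_len(sum(inst$sizes))),
      prior = unlist(inst$priors), posterior = NA_real_)
    graph <- structure(list(bio = matrix(integer(0), ncol = 2),
                            add = matrix(integer(0), ncol = 2),
                            n_rows = nrow(annot)),
                       class = "connection_graph")
    n_iter <- 100L
    res <- suppressMessages(
      gibbs_posterior(annot, graph, n_iter = n_iter, burn_in = 10L,
                      seed = 1))
    expect_equal(attr(res, "n_cond_evals"), n_iter * sum(inst$sizes))
  }
})

test_that("posteriors stay normalized per unit", {
  sim <- simulate_dataset(seed = 61)
  f <- cluster_features(sim$features)
  f <- map_isotope_patterns(f)
  a <- compute_priors(f, sim$db)
  g <- build_connections(a, sim$db, bio_mode = "db_edges")
  p <- suppressMessages(gibbs_posterior(a, g, seed = 3))
  sums <- tapply(p$posterior, p$feature_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
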