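# Independent oracles used by the tests. These deliberately avoid the
# package's own computation paths: the isotope oracle enumerates every
# isotopologue combination explicitly, and the sampler oracle enumerates
# the full joint state space of the scan kernel.

# NIST principal/secondary isotope data, re-entered here independently of
# the package's table so a typo in either is caught.
ORACLE_ISOTOPES <- list(
  C  = list(mass = c(12, 13.00335484), ab = c(0.9893, 0.0107)),
  H  = list(mass = c(1.00782503, 2.01410178), ab = c(0.999885, 0.000115)),
  N  = list(mass = c(14.00307400, 15.00010890), ab = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491462, 16.99913176, 17.99915961),
            ab = c(0.99757, 0.00038, 0.00205)),
  S  = list(mass = c(31.97207117, 32.97145891, 33.96786700, 35.96708071),
            ab = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.96885268, 36.96590260), ab = c(0.7576, 0.2424)),
  P  = list(mass = 30.97376200, ab = 1)
)

# all compositions of n into k non-negative parts
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# exhaustive isotopologue enumeration: returns data frame
# (nominal shift k, abundance summed, abundance-weighted mean mass)
enumerate_isotopologues <- function(counts) {
  per_elem <- lapply(names(counts), function(el) {
    iso <- ORACLE_ISOTOPES[[el]]
    n <- counts[[el]]
    comp <- compositions(n, length(iso$mass))
    mass <- comp %*% iso$mass
    prob <- apply(comp, 1, function(k) stats::dmultinom(k, prob = iso$ab))
    data.frame(mass = as.numeric(mass), prob = prob)
  })
  total <- Reduce(function(a, b) {
    data.frame(mass = as.vector(outer(a$mass, b$mass, "+")),
               prob = as.vector(outer(a$prob, b$prob, "*")))
  }, per_elem)
  mono <- min(total$mass[total$prob > 1e-15])
  k <- round(total$mass - mono)
  data.frame(
    k = sort(unique(k)),
    abundance = as.numeric(tapply(total$prob, k, sum)),
    mass = as.numeric(tapply(total$prob * total$mass, k, sum) /
                        tapply(total$prob, k, sum))
  )
}

# exact stationary distribution of the systematic-scan sampler on the full
# joint state space; units: list of prior vectors, edges: list(bio=, add=)
# as 2-column matrices of (unit, candidate-within-unit) global indices
enumerate_gibbs_stationary <- function(priors, bio = NULL, add = NULL,
                                       delta_bio = 1, delta_add = 1) {
  n_units <- length(priors)
  sizes <- vapply(priors, length, integer(1))
  offsets <- cumsum(c(0L, sizes[-n_units]))
  states <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  ns <- nrow(states)
  glob <- function(s) offsets + s # global candidate ids of a joint state
  adj_count <- function(g_self, g_others, edges) {
    if (is.null(edges) || nrow(edges) == 0L) return(0)
    sum((edges[, 1] == g_self & edges[, 2] %in% g_others) |
          (edges[, 2] == g_self & edges[, 1] %in% g_others))
  }
  kernel_for_unit <- function(f) {
    K <- matrix(0, ns, ns)
    for (si in seq_len(ns)) {
      s <- states[si, ]
      others <- glob(s)[-f]
      w <- vapply(seq_len(sizes[f]), function(a) {
        g <- offsets[f] + a
        priors[[f]][a] *
          (adj_count(g, others, bio) + delta_bio) *
          (adj_count(g, others, add) + delta_add)
      }, numeric(1))
      w <- w / sum(w)
      for (a in seq_len(sizes[f])) {
        s2 <- s
        s2[f] <- a
        ti <- which(colSums(abs(t(states) - s2)) == 0)
        K[si, ti] <- K[si, ti] + w[a]
      }
    }
    K
  }
  K <- Reduce(`%*%`, lapply(seq_len(n_units), kernel_for_unit))
  pi <- rep(1 / ns, ns)
  repeat {
    pi2 <- as.vector(pi %*% K)
    if (max(abs(pi2 - pi)) < 1e-13) break
    pi <- pi2
  }
  # marginal visit probability per global candidate
  marg <- numeric(sum(sizes))
  for (si in seq_len(ns)) {
    marg[glob(states[si, ])] <- marg[glob(states[si, ])] + pi[si]
  }
  split(marg, rep(seq_len(n_units), sizes))
}

# random small sampler instance (for oracle-equivalence tests)
random_gibbs_instance <- function(max_units = 4L, max_cands = 3L) {
  n_units <- sample(2:max_units, 1)
  sizes <- sample(2:max_cands, n_units, replace = TRUE)
  priors <- lapply(sizes, function(k) {
    w <- stats::runif(k, 0.1, 1)
    w / sum(w)
  })
  offsets <- cumsum(c(0L, sizes[-n_units]))
  # random cross-unit edges
  all_pairs <- list()
  for (f in seq_len(n_units - 1L)) {
    for (g in seq(f + 1L, n_units)) {
      for (a in seq_len(sizes[f])) {
        for (b in seq_len(sizes[g])) {
          all_pairs[[length(all_pairs) + 1L]] <-
            c(offsets[f] + a, offsets[g] + b)
        }
      }
    }
  }
  pick <- function(p) {
    on <- stats::runif(length(all_pairs)) < p
    if (!any(on)) return(NULL)
    do.call(rbind, all_pairs[on])
  }
  list(priors = priors, bio = pick(0.2), add = pick(0.1),
       sizes = sizes, offsets = offsets)
}

# run the package sampler on such an instance and return per-unit posteriors
run_gibbs_on_instance <- function(inst, n_iter = 50000L, burn_in = 5000L,
                                  seed = 1L, delta_bio = 1, delta_add = 1) {
  n_units <- length(inst$priors)
  annot <- data.frame(
    feature_id = rep(sprintf("U%02d", seq_len(n_units)), inst$sizes),
    cluster_id = 1L,
    compound_id = sprintf("X%03d", seq_len(sum(inst$sizes))),
    prior = unlist(inst$priors),
    posterior = NA_real_, stringsAsFactors = FALSE)
  graph <- structure(list(
    bio = if (is.null(inst$bio)) matrix(integer(0), ncol = 2) else inst$bio,
    add = if (is.null(inst$add)) matrix(integer(0), ncol = 2) else inst$add,
    n_rows = nrow(annot)), class = "connection_graph")
  res <- suppressMessages(
    gibbs_posterior(annot, graph, delta_bio = delta_bio,
                    delta_add = delta_add, n_iter = n_iter,
                    burn_in = burn_in, seed = seed))
  split(res$posterior, rep(seq_len(n_units), inst$sizes))
}
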