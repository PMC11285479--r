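test_that("network construction counts directed acts within the group", {
  int <- make_interactions_df(
    list("2010-05-01 08:00:00", "a", "b", "agonistic", "loc1"),
    list("2010-05-02 08:00:00", "a", "b", "agonistic", "loc1"),
    list("2010-05-03 08:00:00", "a", "b", "agonistic", "loc1"),
    list("2010-05-04 08:00:00", "b", "a", "agonistic", "loc1"),
    list("2010-05-05 08:00:00", "a", "z", "agonistic", "loc1")) # cross-group
  net <- build_agonistic_network(int, members = c("a", "b", "c"))
  expect_equal(net$weights["a", "b"], 3L)
  expect_equal(net$weights["b", "a"], 1L)
  expect_equal(sum(net$weights), 4L)
  expect_equal(attr(net, "n_cross_group"), 1L)
  expect_true(net$eligible)
  # a dyad is not an eligible group
  expect_false(build_agonistic_network(int, members = c("a", "b"))$eligible)
})

test_that("a network without interactions has zero reach and zero GRC", {
  empty <- build_agonistic_network(make_interactions_df()[0, ],
                                   members = c("a", "b", "c", "d"))
  expect_equal(unname(local_reaching_centrality(empty)), rep(0, 4))
  expect_equal(grc(empty), 0)
})

test_that("local reaching centrality on canonical digraphs", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  expect_equal(unname(local_reaching_centrality(star)), c(1, 0, 0, 0))
  path <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  path["a", "b"] <- 1; path["b", "c"] <- 1
  expect_equal(local_reaching_centrality(path, "b"), 0.5)
  cyc <- matrix(0, 3, 3)
  cyc[cbind(1:3, c(2, 3, 1))] <- 1
  expect_equal(unname(local_reaching_centrality(cyc)), rep(1, 3))
  expect_error(local_reaching_centrality(path, "zz"), "not in network")
})

test_that("reach centralities match the transitive-closure oracle", {
  set.seed(31)
  for (rep in 1:120) {
    n <- sample(3:6, 1)
    a <- random_digraph(n, p = stats::runif(1, 0.1, 0.7))
    expect_equal(unname(local_reaching_centrality(a)), local_reach_oracle(a))
  }
})

test_that("GRC hits its analytic limits and the worked path value", {
  for (n in 3:6) {
    star <- matrix(0, n, n); star[1, 2:n] <- 1
    expect_equal(grc(star), 1)
    cyc <- matrix(0, n, n); cyc[cbind(1:n, c(2:n, 1))] <- 1
    expect_equal(grc(cyc), 0)
  }
  path <- matrix(0, 3, 3); path[1, 2] <- 1; path[2, 3] <- 1
  expect_equal(grc(path), 0.75) # C_R = (1, 0.5, 0)
  expect_error(grc(matrix(0, 2, 2)), "at least 3")
})

test_that("GRC is invariant to relabeling and weight rescaling, and equals 1
           exactly for out-star reach patterns", {
  set.seed(37)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    a <- random_digraph(n) * sample(1:5, n * n, replace = TRUE)
    perm <- sample(n)
    expect_equal(grc(a[perm, perm]), grc(a))
    expect_equal(grc(a * 7), grc(a)) # binarised reachability
  }
  # exhaustive over all digraphs on 3 nodes: GRC = 1 iff one node reaches
  # both others and neither of the others reaches anyone
  for (code in 0:(2^6 - 1)) {
    bits <- as.integer(intToBits(code))[1:6]
    a <- matrix(0, 3, 3)
    a[row(a) != col(a)] <- bits
    cr <- local_reach_oracle(a)
    star_like <- sum(cr == 1) == 1 && sum(cr == 0) == 2
    expect_equal(grc(a) == 1, star_like)
    expect_gte(grc(a), 0)
    expect_lte(grc(a), 1)
  }
})

test_that("the weighted reach variant reduces to the unweighted one on
           equal weights and stays bounded", {
  set.seed(41)
  for (rep in 1:10) {
    a <- random_digraph(sample(3:5, 1))
    expect_equal(local_reaching_centrality(a, weighted = TRUE),
                 local_reaching_centrality(a, weighted = FALSE))
    w <- a * sample(1:6, length(a), replace = TRUE)
    cr <- local_reaching_centrality(w, weighted = TRUE)
    expect_true(all(cr >= 0 & cr <= 1))
  }
})

test_that("rewiring an egalitarian cycle into an out-star never lowers GRC", {
  # fixed schedule: start from the 5-cycle and redirect non-hub edges to
  # hub-out edges one at a time
  n <- 5
  a <- matrix(0, n, n)
  a[cbind(1:n, c(2:n, 1))] <- 1
  vals <- grc(a)
  for (k in 2:n) {
    # remove node k's outgoing edge; add hub edge 1 -> k
    a[k, ] <- 0
    a[1, k] <- 1
    vals <- c(vals, grc(a))
  }
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[1], 0)
  expect_equal(vals[length(vals)], 1)
})

test_that("dyadic relations classify wins, ties and unknowns by majority", {
  w <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  w["a", "b"] <- 3; w["b", "a"] <- 1     # a wins
  w["b", "c"] <- 2; w["c", "b"] <- 2     # tie
  rel <- dominance_relations(w)
  expect_equal(rel["a", "b"], "win")
  expect_equal(rel["b", "a"], "loss")
  expect_equal(rel["b", "c"], "tie")
  expect_equal(rel["a", "c"], "unknown")
})

test_that("Landau's h matches its limits and the circular-triad oracle", {
  # transitive tournaments are perfectly linear
  for (n in 3:6) {
    wins <- (row(diag(n)) < col(diag(n))) * 1
    expect_equal(landau_h(relations_from_wins(wins)), 1)
  }
  # the 3-cycle is maximally intransitive
  cyc <- matrix(0, 3, 3); cyc[cbind(1:3, c(2, 3, 1))] <- 1
  expect_equal(landau_h(relations_from_wins(cyc)), 0)
  # N = 4 with scores (3,1,1,1): a beats all, b/c/d cycle
  wins <- matrix(0, 4, 4)
  wins[1, 2:4] <- 1
  wins[2, 3] <- 1; wins[3, 4] <- 1; wins[4, 2] <- 1
  expect_equal(landau_h(relations_from_wins(wins)), 0.6)
  # random complete tournaments agree with the circular-triad form of h
  set.seed(43)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    wins <- matrix(0, n, n)
    up <- which(upper.tri(wins), arr.ind = TRUE)
    dir <- stats::runif(nrow(up)) < 0.5
    wins[up[dir, , drop = FALSE]] <- 1
    wins[up[!dir, c(2, 1), drop = FALSE]] <- 1
    expect_equal(landau_h(relations_from_wins(wins)), landau_oracle(wins))
  }
  # incomplete tournaments must be routed to h'
  expect_error(landau_h(dominance_relations(matrix(0, 3, 3))), "h_prime")
})

test_that("h' equals h on complete tournaments and is seed-reproducible", {
  wins <- (row(diag(4)) < col(diag(4))) * 1
  rel <- relations_from_wins(wins)
  expect_equal(as.numeric(landau_h_prime(rel, n_perm = 7, seed = 1)),
               landau_h(rel))
  rel_u <- dominance_relations(matrix(0, 4, 4))
  expect_identical(landau_h_prime(rel_u, n_perm = 500, seed = 11),
                   landau_h_prime(rel_u, n_perm = 500, seed = 11))
  expect_error(landau_h_prime(rel_u, n_perm = 0), "n_perm")
})

test_that("h' converges to the exhaustive-completion mean and stays within
           the completion envelope", {
  # N = 3, all dyads unknown: 8 completions, 6 transitive (h = 1) and 2
  # cyclic (h = 0) -> exact mean 0.75
  rel <- dominance_relations(matrix(0, 3, 3))
  h_all <- sapply(0:7, function(code) {
    bits <- as.integer(intToBits(code))[1:3]
    wins <- matrix(0, 3, 3)
    wins[1, 2] <- bits[1]; wins[2, 1] <- 1 - bits[1]
    wins[1, 3] <- bits[2]; wins[3, 1] <- 1 - bits[2]
    wins[2, 3] <- bits[3]; wins[3, 2] <- 1 - bits[3]
    landau_oracle(wins)
  })
  expect_equal(mean(h_all), 0.75)
  hp <- landau_h_prime(rel, n_perm = 10000, seed = 4)
  se <- attr(hp, "sd") / sqrt(attr(hp, "n_permutations"))
  expect_lt(abs(as.numeric(hp) - 0.75), 3 * se)
  expect_gte(as.numeric(hp), min(h_all))
  expect_lte(as.numeric(hp), max(h_all))
})

test_that("h' Monte-Carlo error shrinks roughly as 1 / sqrt(n_perm)", {
  rel <- dominance_relations(matrix(0, 5, 5))
  reps <- function(n_perm) {
    vapply(1:20, function(s) as.numeric(landau_h_prime(rel, n_perm, seed = s)),
           numeric(1))
  }
  sd_small <- stats::sd(reps(100))
  sd_big <- stats::sd(reps(1600))
  # 16x the permutations should shrink the SE about 4-fold
  expect_lt(sd_big, sd_small / 2)
})

test_that("hierarchy_metrics bundles consistent per-network statistics", {
  int <- make_interactions_df(
    list("2010-05-01 08:00:00", "a", "b", "agonistic", "loc1"),
    list("2010-05-02 08:00:00", "b", "c", "agonistic", "loc1"),
    list("2010-05-03 08:00:00", "a", "c", "agonistic", "loc1"))
  net <- build_agonistic_network(int, members = c("a", "b", "c"),
                                 year = 2010, colony = "c1", group_id = "g1")
  hm <- hierarchy_metrics(net, n_perm = 200, seed = 3)
  expect_equal(hm$grc, grc(net))
  expect_equal(hm$h, 1) # complete transitive tournament
  expect_equal(hm$h_prime, 1)
  expect_equal(hm$n_undecided, 0)
  two <- build_agonistic_network(int, members = c("a", "b"))
  expect_error(hierarchy_metrics(two), "ineligible")
})
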