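# Independent oracles used to validate the package's implementations.
# These deliberately use different algorithms from the code under test.

# Transitive closure by repeated boolean matrix squaring (the implementation
# under test uses per-node breadth-first search instead).
closure_oracle <- function(adj) {
  r <- adj > 0
  repeat {
    r2 <- r | ((r %*% r) > 0)
    if (all(r2 == r)) break
    r <- r2
  }
  r
}

# Local reaching centralities straight from the closure.
local_reach_oracle <- function(adj) {
  n <- nrow(adj)
  r <- closure_oracle(adj)
  diag(r) <- FALSE
  rowSums(r) / (n - 1)
}

# Random directed adjacency matrix (binary), zero diagonal.
random_digraph <- function(n, p = 0.35) {
  a <- matrix(stats::runif(n * n) < p, n, n) * 1
  diag(a) <- 0
  a
}

# Random symmetric weighted graph for map-equation tests.
random_weighted_graph <- function(n, p = 0.5) {
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  vals <- ifelse(stats::runif(sum(up)) < p, stats::runif(sum(up), 0.2, 1), 0)
  a[up] <- vals
  a + t(a)
}

# Landau's h from the count of circular triads: h = 1 - 24 d / (N^3 - N).
# Independent of the score-variance form used by the implementation.
landau_oracle <- function(wins) {
  n <- nrow(wins)
  d <- 0
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        # a triad is circular iff each member wins exactly one of its two dyads
        s <- c(wins[i, j] + wins[i, k], wins[j, i] + wins[j, k],
               wins[k, i] + wins[k, j])
        if (all(s == 1)) d <- d + 1
      }
    }
  }
  1 - 24 * d / (n^3 - n)
}

# All set partitions of 1..n as a list of membership vectors (restricted
# growth strings); exhaustive search oracle for map-equation optimisation.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      recurse(c(prefix, b), max(maxblock, b))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Minimum codelength over every partition of the graph's nodes.
exhaustive_min_codelength <- function(w) {
  parts <- all_partitions(nrow(w))
  min(vapply(parts, function(p) map_equation_codelength(w, p), numeric(1)))
}

# Build a relation matrix from an explicit wins matrix (1 = row beats col).
relations_from_wins <- function(wins) {
  n <- nrow(wins)
  counts <- wins * 2 # any positive count works; winner has strictly more
  dominance_relations(counts)
}

# A tiny hand-enumerable interaction fixture: see test-records.R.
make_interactions_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(timestamp = as.POSIXct(r[[1]], tz = "UTC"),
               initiator_id = r[[2]], recipient_id = r[[3]],
               itype = r[[4]], location = r[[5]] %||% "loc1",
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
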