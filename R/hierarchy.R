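#' Build a directed, weighted agonistic network for one group-year
#'
#' Counts directed agonistic acts between members of one social group over
#' the season. Interactions involving a non-member are discarded (their count
#' is reported in the `"n_cross_group"` attribute). Networks with fewer than
#' three members are flagged ineligible: hierarchy metrics are not defined
#' for dyads.
#'
#' @param interactions interactions already passed through
#'   [filter_agonistic_study_set()].
#' @param members character vector of the group's adult females.
#' @param year,colony,group_id identifiers carried along.
#' @return An object of class `"agonistic_network"`: a list with `ids`,
#'   `weights` (square count matrix, entry \[i, j\] = acts initiated by i
#'   toward j, zero diagonal), `year`, `colony`, `group_id`, `eligible`.
#' @export
build_agonistic_network <- function(interactions, members, year = NA,
                                    colony = NA, group_id = NA) {
  members <- sort(unique(as.character(members)))
  n <- length(members)
  keep <- interactions$initiator_id %in% members &
    interactions$recipient_id %in% members
  n_cross <- sum(!keep)
  w <- matrix(0L, n, n, dimnames = list(members, members))
  if (any(keep)) {
    tab <- table(factor(interactions$initiator_id[keep], levels = members),
                 factor(interactions$recipient_id[keep], levels = members))
    w <- matrix(as.integer(tab), n, n, dimnames = list(members, members))
  }
  diag(w) <- 0L
  structure(list(ids = members, weights = w, year = year, colony = colony,
                 group_id = group_id, eligible = n >= 3),
            n_cross_group = n_cross,
            class = "agonistic_network")
}

#' @export
print.agonistic_network <- function(x, ...) {
  cat("Agonistic network:", x$group_id %||% "<unnamed>",
      sprintf("(%s females, %d acts%s)\n", length(x$ids), sum(x$weights),
              if (x$eligible) "" else ", INELIGIBLE: n < 3"))
  invisible(x)
}

# Accept either an agonistic_network or a bare weight matrix.
.as_weights <- function(net) {
  if (inherits(net, "agonistic_network")) net$weights else as.matrix(net)
}

# Directed reachability from node i on the binarised graph, by breadth-first
# search over out-neighbour lists.
.reachable_from <- function(adj, i) {
  n <- nrow(adj)
  visited <- logical(n)
  frontier <- which(adj[i, ] > 0)
  while (length(frontier) > 0) {
    frontier <- frontier[!visited[frontier]]
    visited[frontier] <- TRUE
    frontier <- which(adj[frontier, , drop = FALSE] > 0, arr.ind = TRUE)[, 2]
  }
  visited[i] <- FALSE
  visited
}

#' Local reaching centrality
#'
#' The fraction of the other `N - 1` individuals reachable from a node via
#' directed paths. By default the network is binarised (any aggression i to j
#' gives a directed edge) and reachability is unweighted. With
#' `weighted = TRUE` a generalised variant is used: each reachable node j
#' contributes the mean (max-normalised) edge weight along one shortest
#' directed path from i to j, so heavily used chains of aggression count for
#' more; it reduces to the unweighted version when all weights are equal.
#'
#' @param net an `agonistic_network` or a square weight matrix.
#' @param node a node id (or index); `NULL` returns all nodes.
#' @param weighted use the weighted variant (not the default).
#' @return Reaching centralities in \[0, 1\], named by node.
#' @export
local_reaching_centrality <- function(net, node = NULL, weighted = FALSE) {
  w <- .as_weights(net)
  n <- nrow(w)
  if (n < 2) stop("reaching centrality needs at least 2 nodes")
  ids <- rownames(w) %||% as.character(seq_len(n))
  if (!weighted) {
    cr <- vapply(seq_len(n), function(i) sum(.reachable_from(w, i)) / (n - 1),
                 numeric(1))
  } else {
    wmax <- max(w)
    if (wmax == 0) {
      cr <- numeric(n)
    } else {
      g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "directed")
      wn <- w / wmax
      cr <- vapply(seq_len(n), function(i) {
        # unreachable targets are expected and contribute 0
        sp <- suppressWarnings(
          igraph::shortest_paths(g, from = i, to = seq_len(n),
                                 mode = "out", output = "vpath"))$vpath
        contrib <- vapply(seq_len(n), function(j) {
          if (j == i) return(0)
          vp <- as.integer(sp[[j]])
          if (length(vp) < 2) return(0) # unreachable
          steps <- cbind(vp[-length(vp)], vp[-1])
          mean(wn[steps])
        }, numeric(1))
        sum(contrib) / (n - 1)
      }, numeric(1))
    }
  }
  names(cr) <- ids
  if (is.null(node)) return(cr)
  if (is.character(node) && !node %in% ids) stop("node '", node, "' not in network")
  cr[[node]]
}

#' Global reaching centrality
#'
#' The normalised total difference between the maximum local reaching
#' centrality and every node's local reaching centrality:
#' `GRC = sum_i (CRmax - CR_i) / (N - 1)`. GRC is 0 for egalitarian
#' structures such as a directed cycle (every node reaches everyone) and 1
#' for a despotic out-star (one individual reaches all, nobody reaches
#' anyone else). A network with no interactions has all reaches 0 and hence
#' GRC 0 (egalitarian by absence of evidence).
#'
#' @inheritParams local_reaching_centrality
#' @return GRC in \[0, 1\]. Errors for networks with fewer than 3 nodes,
#'   where the measure is not defined.
#' @export
grc <- function(net, weighted = FALSE) {
  w <- .as_weights(net)
  if (nrow(w) < 3) stop("GRC requires a group of at least 3 individuals")
  cr <- local_reaching_centrality(w, weighted = weighted)
  sum(max(cr) - cr) / (nrow(w) - 1)
}

#' Dyadic dominance relations
#'
#' Classifies every ordered pair by the directed act counts: the individual
#' with strictly more acts toward the other wins; equal non-zero counts are
#' a tie; no acts either way is unknown.
#'
#' @param net an `agonistic_network` or weight matrix.
#' @return A square character matrix with entries `"win"` (row beats
#'   column), `"loss"`, `"tie"`, `"unknown"`; diagonal is `""`.
#' @export
dominance_relations <- function(net) {
  w <- .as_weights(net)
  n <- nrow(w)
  rel <- matrix("", n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      rel[i, j] <- if (w[i, j] > w[j, i]) "win"
      else if (w[i, j] < w[j, i]) "loss"
      else if (w[i, j] > 0) "tie"
      else "unknown"
    }
  }
  rel
}

#' Landau's linearity index h
#'
#' For a complete dominance tournament (every dyad decided),
#' `h = (12 / (N^3 - N)) * sum_i (S_i - (N - 1) / 2)^2` where `S_i` is the
#' number of dyads individual i wins. h is 1 for a perfectly linear
#' hierarchy and 0 at maximal intransitivity. Matrices with tied or unknown
#' relationships are not a complete tournament; use [landau_h_prime()].
#'
#' @param relations a relation matrix from [dominance_relations()].
#' @return h in \[0, 1\].
#' @export
landau_h <- function(relations) {
  n <- nrow(relations)
  if (n < 3) stop("Landau's h requires at least 3 individuals")
  off <- relations[row(relations) != col(relations)]
  if (any(off %in% c("tie", "unknown"))) {
    stop("relations contain ties or unknowns: use landau_h_prime()")
  }
  s <- rowSums(relations == "win")
  (12 / (n^3 - n)) * sum((s - (n - 1) / 2)^2)
}

#' Landau's corrected linearity index h'
#'
#' Corrects [landau_h()] for incomplete dominance matrices: every unknown
#' dyad is assigned a random direction and every tied dyad a fair-coin
#' direction, h is computed on the completed tournament, and h' is the mean
#' over `n_perm` random completions. With no ties or unknowns h' equals h
#' exactly. One seeded generator fills dyads in fixed row-major order, so a
#' given seed is bit-reproducible.
#'
#' @param relations a relation matrix from [dominance_relations()].
#' @param n_perm number of random completions (the conventional choice is
#'   10,000).
#' @param seed RNG seed.
#' @return h' in \[0, 1\], with attributes `n_permutations` and `seed`.
#' @export
landau_h_prime <- function(relations, n_perm = 10000L, seed = 1L) {
  n <- nrow(relations)
  if (n < 3) stop("h' requires at least 3 individuals")
  if (n_perm < 1) stop("n_perm must be at least 1")
  s_known <- rowSums(relations == "win")
  # undecided dyads (i < j), in row-major order
  und <- which(upper.tri(relations) & (relations == "tie" | relations == "unknown"),
               arr.ind = TRUE)
  und <- und[order(und[, 1], und[, 2]), , drop = FALSE]
  d <- nrow(und)
  if (d == 0) {
    h <- (12 / (n^3 - n)) * sum((s_known - (n - 1) / 2)^2)
    return(structure(h, n_permutations = as.integer(n_perm), seed = as.integer(seed)))
  }
  h_vals <- with_seed(seed, {
    # column r = replicate r; draws fill dyads in row-major order within
    # each replicate because R fills matrices column-major
    draws <- matrix(stats::runif(d * n_perm) < 0.5, nrow = d)
    ii <- matrix(0L, d, n); ii[cbind(seq_len(d), und[, 1])] <- 1L
    jj <- matrix(0L, d, n); jj[cbind(seq_len(d), und[, 2])] <- 1L
    s_mat <- s_known + t(ii) %*% draws + t(jj) %*% (1 - draws)
    (12 / (n^3 - n)) * colSums((s_mat - (n - 1) / 2)^2)
  })
  structure(mean(h_vals), sd = stats::sd(h_vals),
            n_permutations = as.integer(n_perm), seed = as.integer(seed))
}

#' Hierarchy metrics for one agonistic network
#'
#' Bundles [grc()], per-node local reaching centralities, and the linearity
#' indices for one group-year network.
#'
#' @param net an `agonistic_network` (must be eligible: 3 or more members).
#' @param n_perm random completions for h'.
#' @param seed RNG seed for h'.
#' @param weighted passed to [grc()].
#' @return An object of class `"hierarchy_metrics"`: list with `grc`,
#'   `local_reach`, `h` (NA unless the tournament is complete), `h_prime`,
#'   `n_undecided`, `n_permutations`, `seed`, plus the network identifiers.
#' @export
hierarchy_metrics <- function(net, n_perm = 10000L, seed = 1L, weighted = FALSE) {
  if (!net$eligible) stop("network ineligible: fewer than 3 members")
  rel <- dominance_relations(net)
  off <- rel[row(rel) != col(rel)]
  complete <- !any(off %in% c("tie", "unknown"))
  hp <- landau_h_prime(rel, n_perm = n_perm, seed = seed)
  structure(list(
    grc = grc(net, weighted = weighted),
    local_reach = local_reaching_centrality(net, weighted = weighted),
    h = if (complete) landau_h(rel) else NA_real_,
    h_prime = as.numeric(hp),
    n_undecided = sum(off %in% c("tie", "unknown")) / 2,
    n_permutations = attr(hp, "n_permutations"),
    seed = as.integer(seed),
    n_females = length(net$ids),
    year = net$year, colony = net$colony, group_id = net$group_id
  ), class = "hierarchy_metrics")
}

#' @export
print.hierarchy_metrics <- function(x, digits = 3, ...) {
  cat("Hierarchy metrics for", x$group_id %||% "<unnamed>",
      sprintf("(N = %d)\n", x$n_females))
  cat(sprintf("  GRC = %.*f   h' = %.*f (%d completions, %g undecided dyads)\n",
              digits, x$grc, digits, x$h_prime, x$n_permutations, x$n_undecided))
  invisible(x)
}
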