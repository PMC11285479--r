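#' Simple-ratio association index for one dyad
#'
#' Association is scored by space-use overlap within a sampling period: two
#' individuals are "together" in a period if they were recorded at the same
#' location in that period. With `x` the number of periods both were seen
#' together, `y_A`/`y_B` the periods only one was seen, and `y_AB` the
#' periods both were seen but apart, the simple-ratio index is
#' `x / (x + y_A + y_B + y_AB)`.
#'
#' @param copresence a copresence record data frame (`individual_id`, `date`,
#'   `location`).
#' @param id_a,id_b individual ids.
#' @param sampling_period currently only `"day"`: records on the same
#'   calendar date fall in the same period.
#' @return A number in \[0, 1\], or `NA_real_` when neither individual was
#'   observed (undefined, as opposed to an observed index of 0).
#' @export
simple_ratio_index <- function(copresence, id_a, id_b, sampling_period = "day") {
  sampling_period <- match.arg(sampling_period)
  a <- copresence[copresence$individual_id == id_a, , drop = FALSE]
  b <- copresence[copresence$individual_id == id_b, , drop = FALSE]
  days_a <- unique(as.character(a$date))
  days_b <- unique(as.character(b$date))
  union_days <- union(days_a, days_b)
  if (length(union_days) == 0) return(NA_real_)
  both <- intersect(days_a, days_b)
  x <- 0L
  for (d in both) {
    loc_a <- a$location[as.character(a$date) == d]
    loc_b <- b$location[as.character(b$date) == d]
    if (length(intersect(loc_a, loc_b)) > 0) x <- x + 1L
  }
  # denominator = periods either was seen = x + y_A + y_B + y_AB
  x / length(union_days)
}

#' Simple-ratio association matrix
#'
#' Computes the simple-ratio index for every pair of the given ids from a
#' copresence table (see [simple_ratio_index()] for the definition).
#'
#' @param copresence a copresence record data frame.
#' @param ids ids to include; defaults to every id present.
#' @param year optional year tag carried in the `"year"` attribute.
#' @return A symmetric numeric matrix with `ids` as dimnames, zero diagonal,
#'   entries in \[0, 1\] (`NA` for pairs never observed).
#' @export
sri_matrix <- function(copresence, ids = NULL, year = NULL) {
  if (is.null(ids)) ids <- sort(unique(copresence$individual_id))
  n <- length(ids)
  cp <- copresence[copresence$individual_id %in% ids, , drop = FALSE]
  day <- as.character(cp$date)
  # periods each id was seen, and co-located pairs per period
  seen <- table(factor(cp$individual_id, levels = ids),
                factor(day, levels = unique(day))) > 0
  x <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (d in unique(day)) {
    sub <- cp[day == d, , drop = FALSE]
    inc <- table(factor(sub$individual_id, levels = ids), sub$location) > 0
    shared <- inc %*% t(inc) > 0 # pair shares >=1 location this period
    x <- x + (shared & !diag(TRUE, n))
  }
  n_seen <- rowSums(seen)
  both <- seen %*% t(seen) # periods both seen
  denom <- outer(n_seen, n_seen, `+`) - both # union of periods seen
  sri <- ifelse(denom > 0, x / denom, NA_real_)
  diag(sri) <- 0
  dimnames(sri) <- list(ids, ids)
  attr(sri, "year") <- year
  sri
}

#' Two-level map equation codelength
#'
#' Evaluates the description length, in bits, of a random walk on a weighted
#' undirected network under a two-level (index codebook + one codebook per
#' module) coding scheme. Node visit rates are proportional to node strength;
#' a module's exit rate is the total weight of its boundary edges over twice
#' the total edge weight. Lower codelength means the partition captures more
#' of the walk's flow structure.
#'
#' @param w symmetric non-negative weight matrix (diagonal ignored).
#' @param modules integer vector assigning every node to a module.
#' @return Codelength in bits (non-negative). A network with no edges has
#'   codelength 0 under any partition.
#' @export
map_equation_codelength <- function(w, modules) {
  w <- as.matrix(w)
  n <- nrow(w)
  if (n == 0) stop("empty network: codelength undefined")
  if (length(modules) != n || anyNA(modules)) {
    stop("partition must assign every node to a module")
  }
  diag(w) <- 0
  tot <- sum(w)
  if (tot <= 0) return(0)
  p <- rowSums(w) / tot # visit rates (strength-proportional)
  mods <- unique(modules)
  q <- numeric(length(mods))
  module_term <- 0
  for (k in seq_along(mods)) {
    in_m <- modules == mods[k]
    q[k] <- sum(w[in_m, !in_m, drop = FALSE]) / tot # exit rate
    p_circ <- q[k] + sum(p[in_m])
    if (p_circ > 0) {
      # p_circ * H(P_m) expanded in plogp form
      module_term <- module_term +
        plog2p(p_circ) - plog2p(q[k]) - sum(plog2p(p[in_m]))
    }
  }
  q_tot <- sum(q)
  index_term <- if (q_tot > 0) plog2p(q_tot) - sum(plog2p(q)) else 0
  index_term + module_term
}

#' Detect social groups by map-equation minimisation
#'
#' Partitions the nodes of an association matrix into social groups by
#' greedily minimising the two-level map-equation codelength
#' ([map_equation_codelength()]). The optimiser sweeps nodes in a seeded
#' random order, moving each node to the neighbouring module that most
#' lowers the codelength (ties broken by lowest module index), then
#' aggregates modules into super-nodes and repeats until no move helps.
#' Deterministic for a fixed seed.
#'
#' Nodes with zero strength (no association with anyone) become singleton
#' groups; an all-zero matrix yields all-singleton groups.
#'
#' @param assoc symmetric association matrix (e.g. from [sri_matrix()]);
#'   `NA` entries are treated as 0.
#' @param seed integer seed controlling the sweep order.
#' @return An integer membership vector named by the matrix's row names,
#'   with groups numbered 1..k in order of first appearance, and the
#'   achieved codelength in the `"codelength"` attribute.
#' @export
detect_groups <- function(assoc, seed = 1L) {
  w <- as.matrix(assoc)
  if (nrow(w) == 0) stop("empty association matrix")
  w[is.na(w)] <- 0
  diag(w) <- 0
  ids <- rownames(w) %||% as.character(seq_len(nrow(w)))
  membership <- with_seed(seed, .optimise_partition(w))
  # relabel 1..k in order of first appearance
  membership <- match(membership, unique(membership))
  names(membership) <- ids
  attr(membership, "codelength") <- map_equation_codelength(w, membership)
  membership
}

# One level of greedy node sweeps: move nodes between modules until no move
# lowers the codelength. Candidate modules are those of the node's
# neighbours plus a fresh singleton. Ties go to the lowest module index.
.sweep_moves <- function(w, modules) {
  n <- nrow(w)
  L <- map_equation_codelength(w, modules)
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      nb <- which(w[i, ] > 0)
      cand <- sort(unique(c(modules[nb], max(modules) + 1L)))
      cand <- setdiff(cand, modules[i])
      if (length(cand) == 0) next
      best_mod <- modules[i]
      best_L <- L
      for (m in cand) {
        trial <- modules
        trial[i] <- m
        Lt <- map_equation_codelength(w, trial)
        if (Lt < best_L - 1e-12) {
          best_L <- Lt
          best_mod <- m
        }
      }
      if (best_mod != modules[i]) {
        modules[i] <- best_mod
        L <- best_L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  modules
}

# Alternate node-move sweeps with whole-module merges (both evaluated as
# codelength on the original graph, so nothing is lost to aggregation)
# until neither improves.
.optimise_partition <- function(w) {
  modules <- .sweep_moves(w, seq_len(nrow(w)))
  repeat {
    labels <- match(modules, unique(modules))
    k <- max(labels)
    merged <- FALSE
    if (k > 1) {
      L <- map_equation_codelength(w, labels)
      best <- NULL
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          trial <- labels
          trial[trial == b] <- a
          Lt <- map_equation_codelength(w, trial)
          if (Lt < L - 1e-12) {
            L <- Lt
            best <- c(a, b)
            merged <- TRUE
          }
        }
      }
      if (merged) {
        labels[labels == best[2]] <- best[1]
        modules <- .sweep_moves(w, labels)
        next
      }
    }
    if (!merged) break
  }
  match(modules, unique(modules))
}

#' Detect social groups for every colony in a year
#'
#' Convenience wrapper running [sri_matrix()] + [detect_groups()] separately
#' within each colony (colonies are containers of social groups), restricted
#' to adult females with more than `min_traps` captures that year.
#'
#' @param copresence a copresence record data frame.
#' @param registry a registry record data frame.
#' @param year focal year.
#' @param seed seed passed to [detect_groups()].
#' @param min_traps trap-count eligibility threshold (strictly greater than).
#' @return A data frame with columns `year`, `colony`, `group_id`,
#'   `individual_id`; groups partition each colony's eligible females.
#' @export
detect_social_groups <- function(copresence, registry, year, seed = 1L,
                                 min_traps = 5) {
  reg <- registry[registry$year == as.integer(year) & registry$sex == "F" &
                    registry$age_class == "adult" & registry$n_traps > min_traps, ,
                  drop = FALSE]
  out <- list()
  for (col in sort(unique(reg$colony))) {
    ids <- sort(reg$individual_id[reg$colony == col])
    if (length(ids) == 0) next
    if (length(ids) == 1) {
      membership <- stats::setNames(1L, ids)
    } else {
      sri <- sri_matrix(copresence, ids = ids, year = year)
      membership <- detect_groups(sri, seed = seed)
    }
    out[[col]] <- data.frame(
      year = as.integer(year), colony = col,
      group_id = paste0(col, ".g", as.integer(membership)),
      individual_id = names(membership), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
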