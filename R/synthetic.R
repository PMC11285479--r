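#' Configuration for the synthetic colony generator
#'
#' Defaults emulate the study conditions of the long-term marmot data the
#' pipeline was designed around: 3 colonies followed over 11 years, 25
#' adult-female social groups of 3 to 11 females (a shifted, truncated
#' negative-binomial size law matched to an observed mean of about 4.7 and a
#' heavy right tail), rank-structured down-hierarchy aggression, and
#' reproduction whose concentration on high-ranking females is controlled by
#' the product of group despotism and the coupling parameter.
#'
#' @param n_groups total number of group-years to generate.
#' @param n_colonies,n_years number of colonies and study years the groups
#'   are spread over.
#' @param size_law `c(size =, mu =)` of the negative binomial drawn on
#'   0..8 and shifted by +3, giving group sizes in 3..11.
#' @param despotism despotism `delta >= 0`: a scalar gives every group the
#'   same despotism; a length-2 vector draws each group's delta uniformly
#'   from that range. The rate of aggression initiated by the female of rank
#'   r decays as `exp(-delta * (r - 1))`, so delta = 0 is egalitarian and
#'   large delta concentrates aggression in the top-ranked female.
#' @param coupling kappa linking despotism to reproductive concentration;
#'   0 decouples them (the null world).
#' @param interaction_rate lambda, mean down-hierarchy agonistic acts per
#'   dyad for a rank-1 initiator.
#' @param noise_frac up-hierarchy (retaliatory) aggression rate as a
#'   fraction of the initiator's down-hierarchy rate; keeps dominance
#'   matrices realistically full of ties and unknowns and makes delta = 0
#'   groups genuinely egalitarian (near-symmetric aggression).
#' @param colony_sd,year_sd,residual_sd standard deviations of the colony,
#'   year and group-level effects on the latent (log concentration) skew
#'   scale.
#' @param mean_litter mean offspring weaned per adult female; the group
#'   total is Poisson with mean `N * mean_litter`.
#' @param concentration baseline Dirichlet concentration per female; lower
#'   values give more baseline skew.
#' @param p_obs daily probability that a female is recorded at her group's
#'   home location.
#' @param p_roam daily probability of an additional sighting at the shared
#'   colony location (creates weak between-group association).
#' @param season_days length of the observation season in days.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_groups = 25L, n_colonies = 3L, n_years = 11L,
                             size_law = c(size = 0.3, mu = 20),
                             despotism = c(0, 2), coupling = 1,
                             interaction_rate = 4, noise_frac = 0.3,
                             colony_sd = 0.4, year_sd = 0.4, residual_sd = 0.3,
                             mean_litter = 3, concentration = 6,
                             p_obs = 0.35, p_roam = 0.05, season_days = 140L) {
  cfg <- as.list(environment())
  stopifnot(n_groups >= 1, n_colonies >= 1, n_years >= 1,
            all(despotism >= 0), interaction_rate >= 0, noise_frac >= 0,
            colony_sd >= 0, year_sd >= 0, residual_sd >= 0,
            mean_litter > 0, concentration > 0)
  class(cfg) <- "synthetic_config"
  cfg
}

# Group sizes 3..11: negative binomial on 0..8 shifted by +3, truncated.
.draw_group_sizes <- function(n, size_law) {
  k <- 0:8
  w <- stats::dnbinom(k, size = size_law[["size"]], mu = size_law[["mu"]])
  sample(k + 3L, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a full synthetic record set
#'
#' Simulates every input table the pipeline consumes -- registry,
#' copresence, interactions, reproduction -- plus a ground-truth sidecar
#' that the pipeline never reads. Per group: females get latent ranks 1..N;
#' directed agonistic acts i->j are Poisson with rate
#' `lambda * exp(-delta * (rank_i - 1))` when i outranks j, plus an
#' up-hierarchy noise rate `noise_frac * lambda`; daily copresence sightings
#' at the group's home burrow make within-group association far exceed
#' between-group association; offspring are Dirichlet-multinomial with
#' concentration `alpha_i` proportional to `exp(-kappa * delta * (rank_i - 1))`
#' scaled by colony-, year- and group-level lognormal effects, and group
#' total Poisson with mean `N * mean_litter`. Each record set also contains
#' a few males, yearlings and under-trapped transient females so the
#' eligibility filters have something to remove. Byte-identical output for
#' a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return A list with data frames `registry`, `copresence`, `interactions`,
#'   `reproduction`, `truth` (one row per group: delta, kappa, skew scale,
#'   true size) and `ranks` (one row per female), plus the config.
#' @export
generate_colony_data <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$interaction_rate == 0 && any(config$despotism > 0)) {
    warning("interaction_rate is 0: networks will be empty regardless of despotism")
  }
  with_seed(seed, .generate_colony_data(config))
}

.generate_colony_data <- function(cfg) {
  years <- 2003L + seq_len(cfg$n_years) - 1L
  colonies <- paste0("colony", seq_len(cfg$n_colonies))
  season_start <- function(y) as.Date(paste0(y, "-04-15"))

  g_colony <- colonies[(seq_len(cfg$n_groups) - 1L) %% cfg$n_colonies + 1L]
  g_year <- years[(seq_len(cfg$n_groups) - 1L) %% cfg$n_years + 1L]
  g_size <- .draw_group_sizes(cfg$n_groups, cfg$size_law)
  g_delta <- if (length(cfg$despotism) == 2) {
    stats::runif(cfg$n_groups, cfg$despotism[1], cfg$despotism[2])
  } else rep(cfg$despotism, cfg$n_groups)

  u_colony <- stats::setNames(stats::rnorm(cfg$n_colonies, 0, cfg$colony_sd), colonies)
  u_year <- stats::setNames(stats::rnorm(cfg$n_years, 0, cfg$year_sd), as.character(years))

  registry <- list(); copresence <- list(); interactions <- list()
  reproduction <- list(); truth <- list(); ranks_tab <- list()

  for (g in seq_len(cfg$n_groups)) {
    n <- g_size[g]; colony <- g_colony[g]; year <- g_year[g]; delta <- g_delta[g]
    fid <- sprintf("%s.y%d.g%d.f%d", colony, year, g, seq_len(n))
    home <- sprintf("%s_burrow_%d", colony, g)
    shared <- sprintf("%s_meadow", colony)

    # registry: focal adult females always pass the >5 traps filter; add one
    # transient female, one male and one yearling as filter fodder
    extra_id <- sprintf("%s.y%d.g%d.%s", colony, year, g, c("trans", "male", "yrl"))
    registry[[g]] <- data.frame(
      individual_id = c(fid, extra_id),
      year = year,
      sex = c(rep("F", n), "F", "M", "F"),
      age_class = c(rep("adult", n), "adult", "adult", "yearling"),
      colony = colony,
      n_traps = c(6L + stats::rpois(n, 6), sample(0:5, 1), 6L + stats::rpois(2, 6)),
      stringsAsFactors = FALSE)

    # copresence: daily sightings at the home burrow, occasional roaming
    days <- season_start(year) + sort(sample(0:(cfg$season_days - 1), cfg$season_days))
    seen <- matrix(stats::runif(n * cfg$season_days) < cfg$p_obs, n)
    roam <- matrix(stats::runif(n * cfg$season_days) < cfg$p_roam, n)
    idx <- which(seen, arr.ind = TRUE)
    ridx <- which(roam, arr.ind = TRUE)
    copresence[[g]] <- data.frame(
      individual_id = c(fid[idx[, 1]], fid[ridx[, 1]]),
      date = c(days[idx[, 2]], days[ridx[, 2]]),
      location = c(rep(home, nrow(idx)), rep(shared, nrow(ridx))),
      stringsAsFactors = FALSE)

    # interactions: the rate of acts initiated by rank r decays as
    # exp(-delta * (r - 1)) whether aimed down or up the hierarchy, with
    # up-hierarchy (retaliatory) aggression further damped by noise_frac;
    # at delta = 0 aggression is near-symmetric (egalitarian), at large
    # delta it concentrates in the top-ranked female (despotic)
    pairs <- which(outer(seq_len(n), seq_len(n), `!=`), arr.ind = TRUE)
    base <- cfg$interaction_rate * exp(-delta * (pairs[, 1] - 1))
    rate <- ifelse(pairs[, 1] < pairs[, 2], base, cfg$noise_frac * base)
    counts <- stats::rpois(nrow(pairs), rate)
    if (sum(counts) > 0) {
      init <- rep(pairs[, 1], counts); recip <- rep(pairs[, 2], counts)
      stamp <- as.POSIXct(sample(days, length(init), replace = TRUE), tz = "UTC") +
        stats::runif(length(init), 7 * 3600, 10 * 3600)
      interactions[[g]] <- data.frame(
        timestamp = stamp,
        initiator_id = fid[init], recipient_id = fid[recip],
        itype = "agonistic", location = home, stringsAsFactors = FALSE)
    }

    # reproduction: Dirichlet-multinomial; concentration decays with rank at
    # rate kappa * delta, scaled by colony/year/group effects on the log scale
    total <- stats::rpois(1, n * cfg$mean_litter)
    scale_g <- exp(-(u_colony[[colony]] + u_year[[as.character(year)]] +
                       stats::rnorm(1, 0, cfg$residual_sd)))
    alpha <- cfg$concentration * exp(-cfg$coupling * delta * (seq_len(n) - 1)) * scale_g
    gam <- stats::rgamma(n, shape = alpha, rate = 1)
    p <- if (sum(gam) > 0) gam / sum(gam) else rep(1 / n, n)
    offspring <- if (total > 0) as.integer(stats::rmultinom(1, total, p)) else integer(n)
    reproduction[[g]] <- data.frame(
      mother_id = fid, year = year, offspring = offspring, exposure = 1,
      stringsAsFactors = FALSE)

    truth[[g]] <- data.frame(
      group_id = sprintf("true.g%d", g), colony = colony, year = year,
      n_females = n, delta = delta, kappa = cfg$coupling,
      skew_scale = scale_g, stringsAsFactors = FALSE)
    ranks_tab[[g]] <- data.frame(
      individual_id = fid, group_id = sprintf("true.g%d", g),
      rank = seq_len(n), stringsAsFactors = FALSE)
  }

  list(registry = do.call(rbind, registry),
       copresence = do.call(rbind, copresence),
       interactions = do.call(rbind, interactions),
       reproduction = do.call(rbind, reproduction),
       truth = do.call(rbind, truth),
       ranks = do.call(rbind, ranks_tab),
       config = cfg)
}

#' Simulate group-year rows straight from the mixed-model data-generating
#' process
#'
#' Bypasses the behavioural simulation and draws standardised group-year
#' rows directly: predictors are standard normal, the response is
#' `beta_grc * grc_ls + beta_hprime * hprime_ls + beta_gsize * gsize_ls +
#' u_colony + u_year + e`. Used for parameter-recovery and type-I-error
#' checks of [fit_skew_model()].
#'
#' @param n number of group-years.
#' @param beta_grc,beta_hprime,beta_gsize true standardised coefficients.
#' @param n_colonies,n_years number of random-effect levels.
#' @param colony_sd,year_sd,residual_sd random-effect and residual SDs.
#' @param seed RNG seed.
#' @return A data frame ready for [fit_skew_model()].
#' @export
simulate_group_years <- function(n = 100L, beta_grc = 0.6, beta_hprime = 0,
                                 beta_gsize = 0, n_colonies = 3L, n_years = 11L,
                                 colony_sd = 0.4, year_sd = 0.4,
                                 residual_sd = 0.7, seed = 1L) {
  with_seed(seed, {
    colony <- factor(sample(paste0("colony", seq_len(n_colonies)), n, replace = TRUE))
    year_f <- factor(sample(2003L + seq_len(n_years) - 1L, n, replace = TRUE))
    u_c <- stats::setNames(stats::rnorm(n_colonies, 0, colony_sd),
                           paste0("colony", seq_len(n_colonies)))
    u_y <- stats::setNames(stats::rnorm(n_years, 0, year_sd),
                           as.character(2003L + seq_len(n_years) - 1L))
    grc_ls <- stats::rnorm(n); hprime_ls <- stats::rnorm(n); gsize_ls <- stats::rnorm(n)
    m_std <- beta_grc * grc_ls + beta_hprime * hprime_ls + beta_gsize * gsize_ls +
      u_c[as.character(colony)] + u_y[as.character(year_f)] +
      stats::rnorm(n, 0, residual_sd)
    data.frame(group_id = paste0("g", seq_len(n)), colony = colony,
               year_f = year_f, grc_ls = grc_ls, hprime_ls = hprime_ls,
               gsize_ls = gsize_ls, m_std = m_std, row.names = NULL)
  })
}

#' Bundled miniature fixtures
#'
#' Deterministic, human-readable datasets used in documentation and tests:
#'
#' * `toy_colony`: a tiny synthetic world (2 colonies, 2 years, 5 groups).
#' * `planted_partition`: a 15 x 15 association matrix with three planted
#'   blocks of 5 (within-block association 0.8, between 0.05).
#' * `skew_demo`: one group of four females with offspring (5, 3, 2, 0),
#'   whose M index is checkable by hand: `M_raw = 4 * ((0.5 - 0.25)^2 +
#'   (0.3 - 0.25)^2 + (0.2 - 0.25)^2 + (0 - 0.25)^2) = 0.52`, null
#'   expectation `(4 / 10) * (1 - 0.25) = 0.3`, so `M = 0.22`.
#'
#' @param name fixture name.
#' @return The fixture object (a record-set list, a matrix, or a data
#'   frame); unknown names error with the list of available fixtures.
#' @export
make_fixture <- function(name = c("toy_colony", "planted_partition", "skew_demo")) {
  registry <- c("toy_colony", "planted_partition", "skew_demo")
  if (!is.character(name) || !(name[1] %in% registry)) {
    stop("unknown fixture '", name[1], "'; available: ",
         paste(registry, collapse = ", "))
  }
  name <- match.arg(name)
  switch(name,
    toy_colony = generate_colony_data(
      synthetic_config(n_groups = 5L, n_colonies = 2L, n_years = 2L,
                       season_days = 30L), seed = 20030415L),
    planted_partition = {
      blocks <- rep(1:3, each = 5)
      m <- ifelse(outer(blocks, blocks, `==`), 0.8, 0.05)
      diag(m) <- 0
      dimnames(m) <- list(paste0("f", 1:15), paste0("f", 1:15))
      m
    },
    skew_demo = data.frame(
      mother_id = paste0("f", 1:4), year = 2010L,
      offspring = c(5L, 3L, 2L, 0L), exposure = 1, stringsAsFactors = FALSE)
  )
}
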