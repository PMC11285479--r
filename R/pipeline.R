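#' Run the full social-control / reproductive-skew pipeline
#'
#' Executes every stage in order on one record set: season + eligibility
#' filtering, per-colony group detection from simple-ratio association
#' indices, agonistic network construction per detected group, hierarchy
#' metrics (GRC, h'), the M skew index, table assembly, and the mixed-model
#' ladder. Writes tidy CSVs, a plain-text model report, and a JSON manifest
#' recording seeds, package version, and the row counts surviving every
#' filter (counts are non-increasing along the filter chain).
#'
#' @param data either a record-set list with elements `registry`,
#'   `copresence`, `interactions`, `reproduction` (e.g. from
#'   [generate_colony_data()]) or a named list/vector of four CSV paths with
#'   those names, read via [read_records()].
#' @param outdir output directory (created if needed).
#' @param seed root seed; group detection, h' permutations and the
#'   bootstrap each derive their seed from it.
#' @param n_perm random completions for h'.
#' @param n_boot parametric bootstrap iterations for the semi-partial
#'   R-squared.
#' @param min_traps trap-count eligibility threshold (strictly greater
#'   than).
#' @param weighted_grc use the weighted reaching-centrality variant.
#' @return Invisibly, a list with the per-stage tables (`groups`, `metrics`,
#'   `skew`, `table`), the fitted `ladder`, the `semi_partial` table for the
#'   full model, the `manifest`, and `outdir`.
#' @export
run_pipeline <- function(data, outdir, seed = 1L, n_perm = 10000L,
                         n_boot = 100L, min_traps = 5, weighted_grc = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(outdir, "pipeline.log")
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logf, append = TRUE)
  cat("", file = logf)

  if (is.character(data)) data <- as.list(data)
  if (!is.data.frame(data$registry)) {
    data <- list(
      registry = read_records(data$registry, "registry"),
      copresence = read_records(data$copresence, "copresence"),
      interactions = read_records(data$interactions, "interactions"),
      reproduction = read_records(data$reproduction, "reproduction"))
  }
  registry <- data$registry
  years <- sort(unique(registry$year))
  n_interactions <- nrow(data$interactions)
  log_line("loaded records:", n_interactions, "interactions,",
           nrow(registry), "registry rows,", length(years), "years")

  groups <- list(); metrics <- list(); skew <- list()
  n_filtered <- 0L; n_in_networks <- 0L
  for (y in years) {
    filt <- suppressWarnings(
      filter_agonistic_study_set(data$interactions, registry, y,
                                 min_traps = min_traps))
    n_filtered <- n_filtered + nrow(filt)
    gy <- detect_social_groups(data$copresence, registry, y,
                               seed = seed + y, min_traps = min_traps)
    if (is.null(gy) || nrow(gy) == 0) next
    groups[[as.character(y)]] <- gy
    for (gid in unique(gy$group_id)) {
      members <- gy$individual_id[gy$group_id == gid]
      net <- build_agonistic_network(filt, members, year = y,
                                     colony = gy$colony[gy$group_id == gid][1],
                                     group_id = gid)
      if (!net$eligible) {
        log_line("year", y, "group", gid, "ineligible (n =", length(members), ")")
        next
      }
      n_in_networks <- n_in_networks + sum(net$weights)
      hm <- hierarchy_metrics(net, n_perm = n_perm, seed = seed,
                              weighted = weighted_grc)
      metrics[[paste(y, gid)]] <- data.frame(
        group_id = gid, colony = net$colony, year = y,
        n_females = hm$n_females, grc = hm$grc, h = hm$h,
        h_prime = hm$h_prime, n_undecided = hm$n_undecided,
        stringsAsFactors = FALSE)
    }
    sk <- skew_by_group(data$reproduction, gy, y)
    if (!is.null(sk)) skew[[as.character(y)]] <- sk
  }
  rbind_all <- function(lst) if (length(lst) == 0) NULL else
    do.call(rbind, c(lst, list(make.row.names = FALSE)))
  groups <- rbind_all(groups)
  metrics <- rbind_all(metrics)
  skew <- rbind_all(skew)
  if (is.null(metrics) || is.null(skew)) {
    stop("pipeline produced no eligible group-years; nothing to model")
  }
  log_line("filter funnel:", n_interactions, "->", n_filtered, "->", n_in_networks)
  log_line("eligible group-years with metrics:", nrow(metrics))

  tab <- assemble_table(metrics, skew)
  ladder <- fit_model_ladder(tab)
  sp <- semi_partial_r2(ladder$fits$full, n_boot = n_boot, seed = seed + 1L)

  utils::write.csv(groups, file.path(outdir, "groups.csv"), row.names = FALSE)
  utils::write.csv(metrics, file.path(outdir, "hierarchy_metrics.csv"), row.names = FALSE)
  utils::write.csv(skew, file.path(outdir, "skew.csv"), row.names = FALSE)
  utils::write.csv(tab, file.path(outdir, "group_year_table.csv"), row.names = FALSE)
  utils::write.csv(ladder$comparison, file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(sp, file.path(outdir, "semi_partial_r2.csv"), row.names = FALSE)

  report <- file.path(outdir, "model_report.txt")
  sink(report); on.exit(if (sink.number() > 0) sink(), add = TRUE)
  cat("Group-level social control and reproductive skew\n")
  cat("================================================\n\n")
  print(ladder)
  cat("\nFull model\n----------\n")
  summary(ladder$fits$full)
  cat("\nSemi-partial marginal R2 (95% CI, parametric bootstrap)\n")
  print(sp, row.names = FALSE)
  sink()

  manifest <- list(
    package = "skewnet",
    version = as.character(utils::packageVersion("skewnet")),
    seed = seed, n_perm = n_perm, n_boot = n_boot, min_traps = min_traps,
    funnel = list(interactions_total = n_interactions,
                  interactions_study_set = n_filtered,
                  interactions_in_eligible_networks = n_in_networks),
    n_group_years = nrow(tab),
    years = years)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(groups = groups, metrics = metrics, skew = skew, table = tab,
                 ladder = ladder, semi_partial = sp, manifest = manifest,
                 outdir = outdir))
}
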