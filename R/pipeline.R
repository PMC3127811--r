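#' Pipeline configuration
#'
#' All tunable parameters of [run_pipeline()] in one validated list.
#'
#' @param thresholds A [classification_thresholds()] object.
#' @param reliability_rule `"and"` (annotation and reference set) or `"or"`.
#' @param score_min Minimum link confidence for network construction.
#' @param tau Similarity cut for [upgma_cluster()].
#' @param min_size Minimum module-candidate size.
#' @param alpha_module Significance level for both module enrichments.
#' @param k Number of concordance groups.
#' @param delta Dead-band for concordance centroid labelling.
#' @param kmeans_seed Seed for the k-means restarts.
#' @param path_alternative Mann-Whitney alternative for the path-length
#'   comparison (same-class vs opposite-class); the default `"less"` states
#'   that same-class pairs sit closer.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = classification_thresholds(),
                            reliability_rule = "and",
                            score_min = 0,
                            tau = 0.4, min_size = 3L, alpha_module = 0.01,
                            k = 5L, delta = log2(1.2), kmeans_seed = 1L,
                            path_alternative = "less") {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  if (!reliability_rule %in% c("and", "or")) {
    abort("`reliability_rule` must be 'and' or 'or'.")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the whole analysis pipeline
#'
#' Chains classification, reliability tiering, network construction and link
#' statistics, module detection with enrichment labelling, and
#' proteome-transcriptome concordance on a world (in-memory list from
#' [generate_world()]/[read_world()] or a directory serialized by
#' [write_world()]). Deterministic for a fixed input and config.
#'
#' @param input A `synthetic_world`, a list with the same components, or a
#'   directory path.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report`; see Details.
#'
#' @details The report contains `class_summary`, `reliability`,
#'   `network` (node/edge counts before and after component extraction,
#'   excluded ids), `links` (category summary), `link_fraction_test` and
#'   `path_length_test` (Mann-Whitney results), `modules` (module table,
#'   coverage), `concordance` (group sizes, centroids),
#'   `module_expression`, and `log` (dropped-record counts by stage).
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  world <- if (is.character(input)) read_world(input) else input
  needed <- c("abundance", "catalog", "links", "annotations", "expression")
  missing <- setdiff(needed, names(world))
  if (length(missing) > 0L) {
    abort(paste0("Input lacks component(s): ", paste(missing, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  records <- stage("classify",
                   classify_ratios(world$abundance, config$thresholds))
  class_summary <- summarize_classes(records)

  tiers <- stage("reliability", {
    ref <- assign_reference_tier(records, world$catalog,
                                 rule = config$reliability_rule)
    assign_link_tiers(records, ref, world$links)
  })
  reliability <- reliability_report(tiers)

  major <- stage("network", {
    net <- build_network(reliable_ids(tiers), world$links, records,
                         score_min = config$score_min)
    largest_component(net)
  })
  net <- major$network
  cat_links <- categorize_links(net)

  fractions <- link_fraction_samples(net)
  link_fraction_test <- if (nrow(fractions) > 0L) {
    mann_whitney_u(fractions$frac_intra, fractions$frac_inter,
                   alternative = "greater")
  } else tibble()
  paths <- stage("paths", shortest_path_samples(net))
  path_length_test <- mann_whitney_u(paths$same_class, paths$opposite_class,
                                     alternative = config$path_alternative)

  modules <- stage("modules", {
    sim <- similarity_from_network(net)
    clusters <- upgma_cluster(sim, tau = config$tau,
                              min_size = config$min_size)
    assemble_modules(clusters, world$annotations, records,
                     alpha = config$alpha_module)
  })

  concordance <- stage("concordance", {
    expr <- world$expression
    kept <- detection_filter(expr$mat, expr$detection_p, expr$condition)
    norm <- quantile_normalize(log2(kept$mat))
    mrna <- mrna_log2_ratios(norm, expr$condition)
    profiles <- profile_table(records, mrna)
    kmeans_partition(profiles, k = config$k, seed = config$kmeans_seed,
                     delta = config$delta)
  })
  module_expression <- module_expression_summary(modules,
                                                 concordance$profiles)

  structure(list(
    class_summary = class_summary,
    reliability = reliability,
    network = tibble(n_reliable = length(reliable_ids(tiers)),
                     n_component = nrow(net$nodes),
                     n_excluded = length(major$excluded),
                     n_edges = nrow(net$edges)),
    excluded_ids = major$excluded,
    links = cat_links$summary,
    link_fraction_test = link_fraction_test,
    path_length_test = path_length_test,
    modules = modules,
    concordance = concordance,
    module_expression = module_expression,
    config = config
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat("  classes:", x$class_summary$n_up, "up /", x$class_summary$n_down,
      "down /", x$class_summary$n_unchanged, "unchanged of",
      x$class_summary$n_total, "\n")
  rel <- x$reliability
  cat("  reliable:", rel$n[rel$tier == "reliable"], "(",
      rel$pct[rel$tier == "reliable"], "% )\n")
  cat("  network:", x$network$n_component, "nodes /", x$network$n_edges,
      "edges (", x$network$n_excluded, "excluded )\n")
  cat("  links:", x$links$n_intra, "intra /", x$links$n_inter, "inter (",
      x$links$pct_intra_of_regulatory, "% intra of regulatory )\n")
  cat("  modules:", nrow(x$modules$modules), "\n")
  print(glance(x$concordance))
  invisible(x)
}

#' Write a machine-readable pipeline report
#'
#' Serializes the report's tables to one JSON document (fixed key order and
#' number formatting, so identical analyses produce identical bytes).
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  payload <- list(
    class_summary = report$class_summary,
    reliability = report$reliability,
    network = report$network,
    excluded_ids = report$excluded_ids,
    links = report$links,
    link_fraction_test = report$link_fraction_test,
    path_length_test = report$path_length_test,
    modules = report$modules$modules,
    module_coverage = report$modules$coverage,
    concordance_groups = count(report$concordance$profiles, .data$group),
    concordance_centroids = report$concordance$centroids,
    module_expression = report$module_expression
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             path)
  invisible(path)
}
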