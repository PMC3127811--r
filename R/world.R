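#' Configuration for the synthetic-world generator
#'
#' Describes a synthetic mitochondrial-proteomics study: planted functional
#' modules (a stochastic block model with confidence-score weights),
#' regulation classes with log2 effect sizes, reference-catalog coverage,
#' flat term annotations with a dominant module term, and a replicated
#' two-condition expression matrix with planted proteome-transcriptome
#' concordance patterns.
#'
#' Defaults mirror the structure of an mtDNA-depletion study scaled to a
#' desk-size problem: five up- and eight down-regulated modules whose mRNAs
#' rise under depletion (protein falling in the down modules), a small
#' opposing fraction inside each module, regulated proteins outside any
#' module, an unchanged background, and sparsely linked contaminants that
#' never enter the reference catalog.
#'
#' @param n_up_modules,n_down_modules Number of planted up/down modules.
#' @param module_size Members per module (recycled to the module count).
#' @param opposing_fraction Fraction of members with the class opposite to
#'   their module's pattern (default 0.05).
#' @param protein_effect_log2,protein_sd Log2 mean effect (+/-) and sd of the
#'   planted protein ratios.
#' @param n_free_up,n_free_down Regulated proteins outside any module.
#' @param free_concordance_split Fraction of free regulated proteins whose
#'   mRNA moves with the protein (the rest oppose it).
#' @param n_background Unchanged, referenced background proteins.
#' @param n_contaminants Non-referenced proteins linked only at `p_out`.
#' @param p_in,p_out Within-module and background edge probabilities.
#' @param conf_within,conf_between Beta(a, b) parameters of the confidence
#'   scores on within-module and other edges.
#' @param physical_fraction Probability an edge is physical-channel.
#' @param n_reference_sets,cc_sensitivity,set_sensitivity,ref_fp_rate
#'   Reference-catalog structure: number of reference sets, probability a
#'   genuine protein carries the cellular-component annotation, per-set
#'   inclusion probability, and the false-positive rate for contaminants.
#' @param term_fraction Fraction of module members carrying the module's
#'   dominant term.
#' @param n_background_terms,terms_per_protein Uniform background annotation.
#' @param mrna_effect_log2,mrna_noise_sd Planted mRNA log2 effect and
#'   per-replicate noise sd.
#' @param base_mean,base_sd Log2 baseline intensity distribution.
#' @param n_replicates Replicates per condition (default 3).
#' @param n_array_extra,frac_undetected Array-only genes and the fraction of
#'   them undetected (high detection p) in every sample.
#' @param seed Mandatory integer seed.
#' @return An object of class `world_config` (a validated list).
#' @export
world_config <- function(n_up_modules = 5L, n_down_modules = 8L,
                         module_size = 15L, opposing_fraction = 0.05,
                         protein_effect_log2 = 1, protein_sd = 0.3,
                         n_free_up = 30L, n_free_down = 37L,
                         free_concordance_split = 0.5,
                         n_background = 300L, n_contaminants = 100L,
                         p_in = 0.3, p_out = 0.01,
                         conf_within = c(8, 2), conf_between = c(2, 8),
                         physical_fraction = 0.3,
                         n_reference_sets = 13L, cc_sensitivity = 0.9,
                         set_sensitivity = 0.3, ref_fp_rate = 0.02,
                         term_fraction = 0.8, n_background_terms = 30L,
                         terms_per_protein = 2L,
                         mrna_effect_log2 = 1, mrna_noise_sd = 0.3,
                         base_mean = 8, base_sd = 1,
                         n_replicates = 3L,
                         n_array_extra = 50L, frac_undetected = 0.3,
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  cfg <- as.list(environment())
  probs <- c(opposing_fraction, p_in, p_out, physical_fraction,
             cc_sensitivity, set_sensitivity, ref_fp_rate, term_fraction,
             free_concordance_split, frac_undetected)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0,1].")
  sizes <- c(n_up_modules, n_down_modules, module_size, n_background,
             n_replicates)
  if (any(sizes < 0) || module_size < 2L || n_replicates < 1L) {
    abort("Sizes must be positive (module_size >= 2, n_replicates >= 1).")
  }
  if (p_in < p_out) {
    warn("p_in < p_out: planted modules will not be recoverable.")
  }
  structure(cfg, class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("Synthetic world config:", x$n_up_modules, "up +", x$n_down_modules,
      "down modules of", x$module_size, "| p_in =", x$p_in, "p_out =", x$p_out,
      "| seed =", x$seed, "\n")
  invisible(x)
}

#' Recommended similarity cut for a synthetic world
#'
#' The expected average-linkage similarity between two sub-clusters of one
#' planted module is `p_in * E[within confidence]`, and between clusters of
#' different modules `p_out * E[between confidence]` (absent edges contribute
#' similarity 0). The recommended cut is the geometric mean of the two
#' expectations, computed analytically from the configuration alone. The two
#' levels typically differ by orders of magnitude, and greedy agglomeration
#' concentrates a module's densest pairs into early cores, so the observed
#' cross-core averages fluctuate well below the within-module expectation; a
#' log-scale midpoint keeps the cut under that fluctuation band while staying
#' far above the between-module level.
#'
#' @param config A [world_config()].
#' @return A single numeric cut value for [upgma_cluster()].
#' @export
suggest_tau <- function(config) {
  stopifnot(inherits(config, "world_config"))
  within <- config$p_in *
    config$conf_within[1L] / sum(config$conf_within)
  between <- config$p_out *
    config$conf_between[1L] / sum(config$conf_between)
  if (between <= 0) return(within / 10)
  sqrt(within * between)
}

# planted mRNA direction (+1/-1/0) for each concordance group
group_mrna_sign <- c(up_up = 1, down_up = 1, up_down = -1, down_down = -1,
                     unchanged = 0)

#' Generate a complete synthetic world
#'
#' Emits every input the pipeline consumes — abundance table, reference
#' catalog, link table, term annotations, replicated expression matrix with
#' detection p-values — plus the planted truth, deterministically from the
#' config seed.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world`: `abundance`, `catalog`,
#'   `links`, `annotations`, `expression` (list `mat`, `detection_p`,
#'   `condition`), `truth` (tibble with planted module, class, concordance
#'   group and referenced flag per protein), `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_modules <- config$n_up_modules + config$n_down_modules
  module_sizes <- rep_len(config$module_size, n_modules)
  module_pattern <- rep(c("up", "down"),
                        c(config$n_up_modules, config$n_down_modules))
  module_ids <- sprintf("MOD%02d", seq_len(n_modules))

  # --- planted truth -------------------------------------------------------
  rows <- list()
  for (m in seq_len(n_modules)) {
    size <- module_sizes[m]
    n_opp <- round(size * config$opposing_fraction)
    cls <- rep(module_pattern[m], size)
    if (n_opp > 0L) cls[seq_len(n_opp)] <- setdiff(c("up", "down"),
                                                   module_pattern[m])
    # mRNA follows the module pattern: up modules have mRNA up, and in down
    # modules the transcript also rises while the protein falls
    mrna_dir <- rep("up", size)
    grp <- ifelse(cls == "up", "up_up", "down_up")
    grp[mrna_dir == "up" & cls == "unchanged"] <- "unchanged"
    rows[[m]] <- tibble(module = module_ids[m], class = cls,
                        concordance_group = grp, contaminant = FALSE)
  }
  free_grp <- function(n, cls, split) {
    with_flow <- round(n * split)
    if (cls == "up") {
      c(rep("up_up", with_flow), rep("up_down", n - with_flow))
    } else {
      c(rep("down_down", with_flow), rep("down_up", n - with_flow))
    }
  }
  rows[[n_modules + 1L]] <- tibble(
    module = NA_character_, class = "up",
    concordance_group = free_grp(config$n_free_up, "up",
                                 config$free_concordance_split),
    contaminant = FALSE)
  rows[[n_modules + 2L]] <- tibble(
    module = NA_character_, class = "down",
    concordance_group = free_grp(config$n_free_down, "down",
                                 config$free_concordance_split),
    contaminant = FALSE)
  rows[[n_modules + 3L]] <- tibble(
    module = NA_character_, class = "unchanged",
    concordance_group = "unchanged", contaminant = FALSE,
    .rows = config$n_background)
  rows[[n_modules + 4L]] <- tibble(
    module = NA_character_, class = "unchanged",
    concordance_group = "unchanged", contaminant = TRUE,
    .rows = config$n_contaminants)
  truth <- bind_rows(rows)
  n <- nrow(truth)
  truth$protein_id <- sprintf("P%05d", seq_len(n))
  truth <- truth[, c("protein_id", "module", "class", "concordance_group",
                     "contaminant")]

  # --- abundance ratios ----------------------------------------------------
  mu <- c(up = config$protein_effect_log2,
          down = -config$protein_effect_log2, unchanged = 0)
  protein_log2 <- unname(mu[truth$class]) + rnorm(n, 0, config$protein_sd)
  abundance <- tibble(protein_id = truth$protein_id,
                      protein_ratio = 2^protein_log2)

  # --- reference catalog ---------------------------------------------------
  p_cc <- ifelse(truth$contaminant, config$ref_fp_rate, config$cc_sensitivity)
  in_cc <- runif(n) < p_cc
  cc_annotated <- truth$protein_id[in_cc]
  p_set <- ifelse(truth$contaminant, config$ref_fp_rate,
                  config$set_sensitivity)
  reference_sets <- lapply(seq_len(config$n_reference_sets), function(s) {
    truth$protein_id[runif(n) < p_set]
  })
  names(reference_sets) <- sprintf("REF%02d", seq_len(config$n_reference_sets))
  truth$referenced <- in_cc &
    truth$protein_id %in% unique(unlist(reference_sets, use.names = FALSE))
  catalog <- reference_catalog(cc_annotated, reference_sets)

  # --- link table (weighted planted-partition model) -----------------------
  pair_idx <- combn(n, 2L)
  ia <- pair_idx[1L, ]; ib <- pair_idx[2L, ]
  same_module <- !is.na(truth$module[ia]) &
    !is.na(truth$module[ib]) & truth$module[ia] == truth$module[ib]
  p_edge <- ifelse(same_module, config$p_in, config$p_out)
  has_edge <- runif(length(p_edge)) < p_edge
  ia <- ia[has_edge]; ib <- ib[has_edge]; same_module <- same_module[has_edge]
  n_e <- length(ia)
  confidence <- numeric(n_e)
  confidence[same_module] <- rbeta(sum(same_module), config$conf_within[1L],
                                   config$conf_within[2L])
  confidence[!same_module] <- rbeta(sum(!same_module), config$conf_between[1L],
                                    config$conf_between[2L])
  channel <- ifelse(runif(n_e) < config$physical_fraction,
                    "physical", "functional")
  links <- tibble(protein_a = truth$protein_id[ia],
                  protein_b = truth$protein_id[ib],
                  confidence = confidence, channel = channel)

  # --- term annotations ----------------------------------------------------
  ann <- list()
  for (m in seq_len(n_modules)) {
    members <- truth$protein_id[!is.na(truth$module) &
                                  truth$module == module_ids[m]]
    carriers <- members[runif(length(members)) < config$term_fraction]
    ann[[m]] <- tibble(protein_id = carriers,
                       term_id = sprintf("TERM_%s", module_ids[m]))
  }
  bg_terms <- sprintf("TERM_BG%03d", seq_len(config$n_background_terms))
  ann[[n_modules + 1L]] <- tibble(
    protein_id = rep(truth$protein_id, config$terms_per_protein),
    term_id = sample(bg_terms, n * config$terms_per_protein, replace = TRUE))
  annotations <- distinct(bind_rows(ann), .data$protein_id, .data$term_id)

  # --- expression matrix ---------------------------------------------------
  extra_ids <- if (config$n_array_extra > 0L) {
    sprintf("GX%04d", seq_len(config$n_array_extra))
  } else character()
  gene_ids <- c(truth$protein_id, extra_ids)
  n_g <- length(gene_ids)
  mrna_log2 <- c(config$mrna_effect_log2 *
                   unname(group_mrna_sign[truth$concordance_group]),
                 rep(0, length(extra_ids)))
  undetected <- c(rep(FALSE, n),
                  runif(length(extra_ids)) < config$frac_undetected)
  base <- rnorm(n_g, config$base_mean, config$base_sd)
  condition <- rep(c("rho0", "rho_plus"), each = config$n_replicates)
  n_s <- length(condition)
  log_int <- matrix(rnorm(n_g * n_s, 0, config$mrna_noise_sd), n_g, n_s)
  log_int <- log_int + base +
    outer(mrna_log2, as.numeric(condition == "rho0"))
  mat <- 2^log_int
  detection_p <- matrix(runif(n_g * n_s, 0, 0.01), n_g, n_s)
  if (any(undetected)) {
    detection_p[undetected, ] <- runif(sum(undetected) * n_s, 0.5, 1)
    mat[undetected, ] <- 2^rnorm(sum(undetected) * n_s,
                                 config$base_mean - 4, 0.5)
  }
  samples <- paste0(ifelse(condition == "rho0", "R0_", "RP_"),
                    rep(seq_len(config$n_replicates), 2L))
  dimnames(mat) <- list(gene_ids, samples)
  dimnames(detection_p) <- list(gene_ids, samples)

  structure(list(abundance = abundance, catalog = catalog, links = links,
                 annotations = annotations,
                 expression = list(mat = mat, detection_p = detection_p,
                                   condition = condition),
                 truth = truth, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$truth), "proteins,", nrow(x$links),
      "links,", nrow(x$expression$mat), "array genes (seed",
      x$config$seed, ")\n")
  invisible(x)
}

#' Planted-truth summary
#'
#' Per-class, per-module, and per-concordance-group planted counts, for test
#' assertions and world inspection.
#'
#' @param truth The `truth` tibble of a [generate_world()] result (or the
#'   world itself).
#' @return A tibble with columns `facet`, `level`, `n`.
#' @export
world_summary <- function(truth) {
  if (inherits(truth, "synthetic_world")) truth <- truth$truth
  truth <- as_tibble(truth)
  check_columns(truth, c("protein_id", "module", "class", "concordance_group",
                         "contaminant"), "planted truth")
  by_facet <- function(col, facet) {
    tab <- count(truth, level = as.character(.data[[col]]))
    tibble(facet = facet, level = ifelse(is.na(tab$level), "none", tab$level),
           n = tab$n)
  }
  bind_rows(
    by_facet("class", "class"),
    by_facet("module", "module"),
    by_facet("concordance_group", "concordance_group"),
    tibble(facet = "contaminant", level = c("FALSE", "TRUE"),
           n = c(sum(!truth$contaminant), sum(truth$contaminant)))
  )
}

#' Adjusted Rand index between detected clusters and planted modules
#'
#' Compares the detected partition with the planted module assignment over
#' the proteins that belong to a planted module; planted members missing from
#' every detected cluster are treated as singletons.
#'
#' @param clusters A `cluster_set`.
#' @param truth Planted-truth tibble (or `synthetic_world`).
#' @return The adjusted Rand index (needs the mclust package).
#' @export
planted_module_ari <- function(clusters, truth) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (inherits(truth, "synthetic_world")) truth <- truth$truth
  if (!requireNamespace("mclust", quietly = TRUE)) {
    abort("planted_module_ari requires the mclust package.")
  }
  planted <- truth[!is.na(truth$module), , drop = FALSE]
  detected <- tidy(clusters)
  lab <- setNames(detected$cluster, detected$protein_id)
  got <- lab[planted$protein_id]
  got[is.na(got)] <- paste0("singleton_",
                            planted$protein_id[is.na(got)])
  mclust::adjustedRandIndex(planted$module, unname(got))
}
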