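#' Construct a cluster set directly
#'
#' Builds a `cluster_set` from explicit member lists, for feeding
#' [assemble_modules()] with clusters obtained outside [upgma_cluster()]
#' (e.g. fixed partitions in worked examples).
#'
#' @param clusters Named list of disjoint character id vectors.
#' @param unassigned Ids outside every cluster.
#' @return An object of class `cluster_set`.
#' @export
cluster_set <- function(clusters, unassigned = character()) {
  if (!is.list(clusters)) abort("`clusters` must be a list of id vectors.")
  if (is.null(names(clusters)) && length(clusters) > 0L) {
    names(clusters) <- paste0("M", seq_along(clusters))
  }
  all_ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(c(all_ids, unassigned))) {
    abort("Clusters (and the unassigned pool) must be disjoint.")
  }
  structure(list(clusters = lapply(clusters, as.character),
                 unassigned = as.character(unassigned),
                 merges = tibble(step = integer(), height = numeric()),
                 tau = NA_real_, min_size = NA_integer_),
            class = "cluster_set")
}

#' Deterministic study-scale benchmark world
#'
#' A synthetic fixture whose marginal counts equal the printed tables of a
#' published mtDNA-depletion proteomics study: 1,121 identified proteins
#' (201 up / 313 down / 607 unchanged), a reference tier of 569 with 82
#' physically and 119 functionally rescued proteins (770 reliable, 351
#' non-referenced), a 726-node major component with 13,618 links of which
#' 4,854 are intra- and 859 inter-regulatory, a module universe where
#' modules capture 59 of 89 up- and 138 of 175 down-regulated proteins,
#' concordance clouds of sizes 127/147/78/218/118, and a 33-protein
#' platform-comparison panel agreeing on 30. Entirely deterministic (no
#' RNG); the pipeline operations recompute all derived counts and
#' percentages from these inputs.
#'
#' @return A list of class `study_world` with components `abundance`,
#'   `catalog`, `links`, `module_universe` (list `records`, `clusters`,
#'   `annotations`), `profiles`, `patterns` (list `a`, `b`).
#' @export
generate_study_world <- function() {
  id <- sprintf("S%04d", seq_len(1121L))
  up_ref <- id[1:122]; down_ref <- id[123:410]
  hub <- id[411]; unch_ref_other <- id[412:525]; isolated <- id[526:569]
  phys_resc <- id[570:651]; func_resc <- id[652:770]
  up_nonref <- id[771:849]; down_nonref <- id[850:874]
  unch_nonref <- id[875:1121]

  class_of <- rep("unchanged", 1121L)
  class_of[match(c(up_ref, up_nonref), id)] <- "up"
  class_of[match(c(down_ref, down_nonref), id)] <- "down"
  ratio_of <- c(up = 2, down = 0.5, unchanged = 1)[class_of]
  abundance <- tibble(protein_id = id, protein_ratio = unname(ratio_of))

  catalog <- reference_catalog(cc_annotated = id[1:569],
                               reference_sets = list(REF01 = id[1:569]))

  # rescue links: each rescued protein touches one down-class reference
  # protein; physical channel defines the physical tier, functional the rest
  rescue <- bind_rows(
    tibble(protein_a = phys_resc,
           protein_b = down_ref[(seq_along(phys_resc) - 1L) %% 288L + 1L],
           channel = "physical"),
    tibble(protein_a = func_resc,
           protein_b = down_ref[(seq_along(func_resc) - 1L) %% 288L + 1L],
           channel = "functional")
  )
  component <- setdiff(id[1:770], c(hub, isolated))
  spokes <- tibble(protein_a = hub, protein_b = component,
                   channel = "functional")

  first_pairs <- function(ids_a, ids_b = NULL, k) {
    # first k unordered pairs in enumeration order; within one set when
    # ids_b is NULL, across the two sets otherwise
    if (is.null(ids_b)) {
      m <- length(ids_a)
      need <- k
      a <- character(k); b <- character(k); pos <- 1L
      for (i in seq_len(m - 1L)) {
        take <- min(m - i, need)
        if (take <= 0L) break
        a[pos:(pos + take - 1L)] <- ids_a[i]
        b[pos:(pos + take - 1L)] <- ids_a[(i + 1L):(i + take)]
        pos <- pos + take
        need <- need - take
      }
      tibble(protein_a = a, protein_b = b)
    } else {
      g <- expand.grid(bi = seq_along(ids_b), ai = seq_along(ids_a))
      g <- g[order(g$ai, g$bi), , drop = FALSE][seq_len(k), , drop = FALSE]
      tibble(protein_a = ids_a[g$ai], protein_b = ids_b[g$bi])
    }
  }
  intra <- first_pairs(down_ref, k = 4854L)
  inter <- first_pairs(up_ref, down_ref, k = 859L)
  unch_component <- c(unch_ref_other, phys_resc, func_resc)
  filler <- first_pairs(unch_component,
                        k = 13618L - nrow(rescue) - nrow(spokes) -
                          nrow(intra) - nrow(inter))
  links <- bind_rows(rescue, spokes,
                     mutate(intra, channel = "functional"),
                     mutate(inter, channel = "functional"),
                     mutate(filler, channel = "functional")) %>%
    mutate(confidence = 0.9) %>%
    select("protein_a", "protein_b", "confidence", "channel")

  # --- module universe: 5 up modules covering 59/89, 8 down covering 138/175
  up_ids <- sprintf("U%03d", 1:89)
  down_ids <- sprintf("D%03d", 1:175)
  unch_ids <- sprintf("N%03d", 1:100)
  up_sizes <- c(12L, 12L, 12L, 12L, 11L)
  down_sizes <- c(18L, 18L, 17L, 17L, 17L, 17L, 17L, 17L)
  carve <- function(ids, sizes, prefix) {
    out <- list(); pos <- 1L
    for (i in seq_along(sizes)) {
      out[[sprintf("%s%02d", prefix, i)]] <- ids[pos:(pos + sizes[i] - 1L)]
      pos <- pos + sizes[i]
    }
    out
  }
  mods <- c(carve(up_ids, up_sizes, "UPM"), carve(down_ids, down_sizes, "DNM"))
  assigned <- unlist(mods, use.names = FALSE)
  universe <- c(up_ids, down_ids, unch_ids)
  clusters <- cluster_set(mods, unassigned = setdiff(universe, assigned))
  records <- tibble(
    protein_id = universe,
    protein_ratio = c(rep(2, 89), rep(0.5, 175), rep(1, 100))
  ) %>% classify_ratios()
  annotations <- bind_rows(
    tibble(protein_id = universe, term_id = "T_ALL"),
    bind_rows(lapply(names(mods), function(nm) {
      tibble(protein_id = mods[[nm]], term_id = paste0("T_", nm))
    }))
  )

  # --- concordance clouds at the printed group sizes -----------------------
  centers <- list(up_up = c(1.5, 1.5), down_down = c(-1.5, -1.5),
                  up_down = c(1.5, -1.5), down_up = c(-1.5, 1.5),
                  unchanged = c(0, 0))
  sizes <- c(up_up = 127L, down_down = 147L, up_down = 78L,
             down_up = 218L, unchanged = 118L)
  profiles <- bind_rows(lapply(names(sizes), function(g) {
    m <- sizes[[g]]
    theta <- 2 * pi * (seq_len(m) - 1L) / m
    tibble(protein_id = sprintf("C_%s_%03d", g, seq_len(m)),
           protein_log2 = centers[[g]][1L] + 0.1 * cos(theta),
           mrna_log2 = centers[[g]][2L] + 0.1 * sin(theta),
           planted_group = g)
  }))

  # --- two-platform regulation panel: 30 of 33 agree -----------------------
  vid <- sprintf("V%02d", 1:33)
  pat_a <- tibble(protein_id = vid,
                  regulation = c(rep("down", 20), rep("up", 10),
                                 rep("unchanged", 3)))
  pat_b <- pat_a
  pat_b$regulation[31:33] <- c("down", "down", "up")

  structure(list(abundance = abundance, catalog = catalog, links = links,
                 module_universe = list(records = records,
                                        clusters = clusters,
                                        annotations = annotations),
                 profiles = profiles,
                 patterns = list(a = pat_a, b = pat_b)),
            class = "study_world")
}
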