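#' Build a functional network over reliable proteins
#'
#' Induces a simple, undirected, weighted graph on the reliable protein set
#' from a link table. Link rows touching a non-reliable id are dropped
#' (counted in a message); duplicate unordered pairs are collapsed keeping
#' the maximum confidence (physical channel preferred on ties); links below
#' `score_min` are discarded. Every reliable id becomes a node, including
#' isolated ones, carrying its regulation class.
#'
#' @param reliable Character vector of reliable ids, or a `reliability_tiers`
#'   object.
#' @param links Link tibble (`protein_a`, `protein_b`, `confidence`,
#'   `channel`).
#' @param records Classified abundance tibble supplying `regulation` per node.
#' @param score_min Minimum confidence score retained (default 0).
#' @return An object of class `functional_network` with tibbles `nodes`
#'   (`protein_id`, `regulation`) and `edges` (`protein_a`, `protein_b`,
#'   `confidence`, `channel`).
#' @export
build_network <- function(reliable, links, records, score_min = 0) {
  if (inherits(reliable, "reliability_tiers")) reliable <- reliable_ids(reliable)
  reliable <- unique(as.character(reliable))
  if (length(reliable) == 0L) abort("`reliable` must be non-empty.")
  links <- validate_links(links)
  records <- as_tibble(records)
  check_columns(records, c("protein_id", "regulation"), "classified records")

  keep <- links$protein_a %in% reliable & links$protein_b %in% reliable &
    links$confidence >= score_min
  if (any(!keep)) {
    inform(paste0("Dropping ", sum(!keep),
                  " link rows (non-reliable endpoint or confidence < score_min)."))
  }
  links <- links[keep, , drop = FALSE]

  # canonical unordered orientation, then collapse duplicates keeping the
  # highest-confidence row (physical wins ties so the channel is deterministic)
  a <- pmin(links$protein_a, links$protein_b)
  b <- pmax(links$protein_a, links$protein_b)
  edges <- tibble(protein_a = a, protein_b = b,
                  confidence = links$confidence, channel = links$channel) %>%
    arrange(.data$protein_a, .data$protein_b,
            dplyr::desc(.data$confidence),
            .data$channel != "physical") %>%
    distinct(.data$protein_a, .data$protein_b, .keep_all = TRUE)

  reg <- setNames(as.character(records$regulation), records$protein_id)
  node_reg <- reg[reliable]
  if (anyNA(node_reg)) {
    abort("Every reliable id must appear in the classified records.")
  }
  nodes <- tibble(protein_id = reliable,
                  regulation = factor(node_reg, levels = regulation_levels)) %>%
    arrange(.data$protein_id)

  structure(list(nodes = nodes, edges = edges), class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat("Functional network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
tidy.functional_network <- function(x, ...) x$edges

#' @export
glance.functional_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_up = sum(x$nodes$regulation == "up"),
         n_down = sum(x$nodes$regulation == "down"),
         n_unchanged = sum(x$nodes$regulation == "unchanged"))
}

# igraph view of a functional_network; isolated nodes retained
as_igraph <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("protein_a", "protein_b", "confidence", "channel")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes$protein_id,
                          regulation = as.character(net$nodes$regulation))
  )
}

#' Extract the largest connected component
#'
#' Returns the subnetwork induced on the largest connected node set, plus the
#' excluded node ids. Size ties are broken toward the component containing
#' the lexicographically smallest member id.
#'
#' @param net A `functional_network`.
#' @return A list with `network` (the major component) and `excluded`
#'   (character vector of dropped ids).
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  if (nrow(net$nodes) == 0L) abort("Network has no nodes.")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1L]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  excluded <- sort(setdiff(net$nodes$protein_id, keep))
  nodes <- net$nodes[net$nodes$protein_id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$protein_a %in% keep &
                       net$edges$protein_b %in% keep, , drop = FALSE]
  list(network = structure(list(nodes = nodes, edges = edges),
                           class = "functional_network"),
       excluded = excluded)
}

#' Categorise network links by the regulation of their endpoints
#'
#' Labels every edge `intra` (up-up or down-down), `inter` (up-down), or
#' `other` (at least one endpoint unchanged), and summarises the counts.
#' The intraregulatory percentage is taken over regulatory links only
#' (intra + inter) and is `NA` when there are none.
#'
#' @param net A `functional_network`.
#' @return A list with `edges` (edge tibble plus `category`) and `summary`
#'   (one-row tibble: `n_intra`, `n_inter`, `n_other`, `n_regulatory`,
#'   `n_total`, `pct_intra_of_regulatory`).
#' @export
categorize_links <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  reg <- setNames(as.character(net$nodes$regulation), net$nodes$protein_id)
  ra <- reg[net$edges$protein_a]
  rb <- reg[net$edges$protein_b]
  category <- ifelse(ra == "unchanged" | rb == "unchanged", "other",
                     ifelse(ra == rb, "intra", "inter"))
  edges <- mutate(net$edges, category = factor(category,
                                               levels = c("intra", "inter", "other")))
  n_intra <- sum(category == "intra")
  n_inter <- sum(category == "inter")
  n_other <- sum(category == "other")
  n_reg <- n_intra + n_inter
  summary <- tibble(
    n_intra = n_intra, n_inter = n_inter, n_other = n_other,
    n_regulatory = n_reg, n_total = nrow(edges),
    pct_intra_of_regulatory = if (n_reg == 0L) NA_real_ else
      round(100 * n_intra / n_reg, 2)
  )
  list(edges = edges, summary = summary)
}

#' Per-protein fractions of intra- and inter-regulatory links
#'
#' For every up- or down-regulated node with at least one regulatory edge,
#' computes the fraction of its regulatory edges that are intraregulatory and
#' the fraction that are interregulatory (they sum to one per node; edges to
#' unchanged proteins are excluded from the denominator). Nodes with no
#' regulatory edge are excluded.
#'
#' @param net A `functional_network`.
#' @return A tibble with `protein_id`, `regulation`, `n_regulatory`,
#'   `frac_intra`, `frac_inter`.
#' @export
link_fraction_samples <- function(net) {
  cat_net <- categorize_links(net)
  edges <- cat_net$edges[cat_net$edges$category != "other", , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(tibble(protein_id = character(), regulation = character(),
                  n_regulatory = integer(), frac_intra = numeric(),
                  frac_inter = numeric()))
  }
  incident <- bind_rows(
    tibble(protein_id = edges$protein_a, category = as.character(edges$category)),
    tibble(protein_id = edges$protein_b, category = as.character(edges$category))
  )
  reg <- setNames(as.character(net$nodes$regulation), net$nodes$protein_id)
  incident %>%
    group_by(.data$protein_id) %>%
    summarise(n_regulatory = dplyr::n(),
              frac_intra = mean(.data$category == "intra"),
              frac_inter = mean(.data$category == "inter"),
              .groups = "drop") %>%
    mutate(regulation = unname(reg[.data$protein_id])) %>%
    select("protein_id", "regulation", "n_regulatory",
           "frac_intra", "frac_inter")
}

#' Shortest-path-length samples for regulated protein pairs
#'
#' Breadth-first (unweighted) shortest path lengths over all edges of the
#' major component for every unordered pair of regulated (up/down) nodes,
#' binned into same-class (up-up, down-down) and opposite-class (up-down)
#' samples. Only connected pairs contribute. With
#' `pair_set = "regulatory_subgraph"`, distances are instead computed in the
#' subgraph of intraregulatory edges (same-class sample) and of
#' interregulatory edges (opposite-class sample) — an alternative reading of
#' "connected within intraregulatory links".
#'
#' @param net A `functional_network`, normally the major component.
#' @param pair_set `"all"` (default) or `"regulatory_subgraph"`.
#' @return A list with integer vectors `same_class` and `opposite_class`.
#' @export
shortest_path_samples <- function(net, pair_set = c("all", "regulatory_subgraph")) {
  pair_set <- match.arg(pair_set)
  stopifnot(inherits(net, "functional_network"))
  reg <- setNames(as.character(net$nodes$regulation), net$nodes$protein_id)
  up_ids <- sort(names(reg)[reg == "up"])
  down_ids <- sort(names(reg)[reg == "down"])
  if (length(up_ids) + length(down_ids) < 2L) {
    abort("Need at least two regulated nodes to form pairs.")
  }

  pair_lengths <- function(g, from_ids, to_ids, same) {
    from_ids <- intersect(from_ids, igraph::V(g)$name)
    to_ids <- intersect(to_ids, igraph::V(g)$name)
    if (length(from_ids) == 0L || length(to_ids) == 0L) return(integer())
    d <- igraph::distances(g, v = from_ids, to = to_ids)
    if (same) d[lower.tri(d, diag = TRUE)] <- Inf  # each unordered pair once
    as.integer(d[is.finite(d)])
  }

  if (pair_set == "all") {
    g <- as_igraph(net)
    same <- c(pair_lengths(g, up_ids, up_ids, TRUE),
              pair_lengths(g, down_ids, down_ids, TRUE))
    opposite <- pair_lengths(g, up_ids, down_ids, FALSE)
  } else {
    cat_net <- categorize_links(net)
    sub <- function(cat) {
      e <- cat_net$edges[cat_net$edges$category == cat, , drop = FALSE]
      igraph::graph_from_data_frame(
        e[, c("protein_a", "protein_b")], directed = FALSE,
        vertices = data.frame(name = net$nodes$protein_id))
    }
    g_intra <- sub("intra")
    g_inter <- sub("inter")
    same <- c(pair_lengths(g_intra, up_ids, up_ids, TRUE),
              pair_lengths(g_intra, down_ids, down_ids, TRUE))
    opposite <- pair_lengths(g_inter, up_ids, down_ids, FALSE)
  }
  list(same_class = same, opposite_class = opposite)
}

#' Mann-Whitney U rank-sum test
#'
#' Rank-sum U with mid-rank ties. The p-value uses the normal approximation
#' with tie-corrected variance and a continuity correction; when
#' `n_x + n_y <= exact_max` (default 12) an exact permutation distribution is
#' enumerated instead. `alternative = "greater"` means x tends to exceed y.
#'
#' @param x,y Numeric samples.
#' @param alternative `"two_sided"`, `"less"`, or `"greater"`.
#' @param exact_max Total sample size up to which the exact permutation
#'   distribution is used.
#' @return A one-row tibble: `U`, `p_value`, `alternative`, `method`,
#'   `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4), alternative = "less")
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "less", "greater"),
                           exact_max = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) abort("Both samples must be non-empty.")
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  pooled <- c(x, y)

  u_stat <- function(lab_x) {
    r <- rank(pooled)  # mid-ranks
    sum(r[lab_x]) - n_x * (n_x + 1) / 2
  }
  U <- u_stat(seq_len(n_x))

  if (length(unique(pooled)) == 1L) {
    warn("Pooled sample is constant; p-value is 1.")
    return(tibble(U = U, p_value = 1, alternative = alternative,
                  method = "degenerate", n_x = n_x, n_y = n_y))
  }

  if (n <= exact_max) {
    # exact permutation: U for every assignment of n_x labels to the pool
    r <- rank(pooled)
    combos <- combn(n, n_x)
    u_all <- colSums(matrix(r[combos], nrow = n_x)) - n_x * (n_x + 1) / 2
    mu <- n_x * n_y / 2
    eps <- 1e-9
    p <- switch(alternative,
      greater = mean(u_all >= U - eps),
      less = mean(u_all <= U + eps),
      two_sided = mean(abs(u_all - mu) >= abs(U - mu) - eps)
    )
    method <- "exact_permutation"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    mu <- n_x * n_y / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    z <- switch(alternative,
      greater = (U - mu - 0.5) / sigma,
      less = (U - mu + 0.5) / sigma,
      two_sided = (abs(U - mu) - 0.5) / sigma
    )
    p <- switch(alternative,
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z),
      two_sided = 2 * pnorm(z, lower.tail = FALSE)
    )
    p <- min(max(p, 0), 1)
    method <- "normal_approximation"
  }
  tibble(U = U, p_value = p, alternative = alternative, method = method,
         n_x = n_x, n_y = n_y)
}

#' Link-statistics plot for a categorised network
#'
#' Bar chart of link counts by category, mirroring the usual presentation of
#' intra/inter-regulatory link tallies.
#'
#' @param object A `functional_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.functional_network <- function(object, ...) {
  cats <- categorize_links(object)$edges
  df <- count(cats, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "link category", y = "number of links") +
    ggplot2::theme_minimal()
}
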