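#' Confidence-score similarity matrix of a network
#'
#' Symmetric matrix over the network's nodes whose entries are the edge
#' confidence scores (0 where no edge, 1 on the diagonal). Confidence is used
#' directly as a similarity measure for average-linkage clustering.
#'
#' @param net A `functional_network`.
#' @return A numeric matrix with node ids as dimnames.
#' @export
similarity_from_network <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  ids <- net$nodes$protein_id
  n <- length(ids)
  if (n == 0L) abort("Network has no nodes.")
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(net$edges) > 0L) {
    ia <- match(net$edges$protein_a, ids)
    ib <- match(net$edges$protein_b, ids)
    s[cbind(ia, ib)] <- net$edges$confidence
    s[cbind(ib, ia)] <- net$edges$confidence
  }
  diag(s) <- 1
  s
}

#' Average-linkage (UPGMA) clustering on a similarity matrix
#'
#' Agglomerative clustering that repeatedly merges the pair of clusters with
#' the greatest average inter-cluster similarity — the unweighted mean over
#' all cross pairs — and stops when the best average similarity falls below
#' `tau`. Clusters with fewer than `min_size` members are returned in an
#' `unassigned` pool rather than as module candidates.
#'
#' @param sim Symmetric similarity matrix in \[0,1\] with id dimnames.
#' @param tau Similarity cut in (0, 1]; merging stops below it.
#' @param min_size Minimum cluster size kept as a candidate (>= 2).
#' @return An object of class `cluster_set`: `clusters` (named list of id
#'   vectors), `unassigned` (ids), `merges` (tibble of merge heights in
#'   order), `tau`, `min_size`.
#' @examples
#' s <- matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma_cluster(s, tau = 0.5, min_size = 2)
#' @export
upgma_cluster <- function(sim, tau = 0.4, min_size = 3L) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    abort("`sim` must be a square matrix.")
  }
  if (is.null(rownames(sim))) {
    dimnames(sim) <- list(paste0("n", seq_len(nrow(sim))),
                          paste0("n", seq_len(nrow(sim))))
  }
  if (max(abs(sim - t(sim))) > 1e-8) abort("`sim` must be symmetric.")
  if (any(sim < -1e-12) || any(sim > 1 + 1e-12)) {
    abort("Similarities must lie in [0,1].")
  }
  if (!is.numeric(tau) || length(tau) != 1L || !(tau > 0 && tau <= 1)) {
    abort("`tau` must lie in (0, 1].")
  }
  if (min_size < 2L) abort("`min_size` must be at least 2.")

  ids <- rownames(sim)
  n <- length(ids)
  members <- as.list(ids)
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  s <- sim
  diag(s) <- -Inf
  heights <- numeric(0)

  while (sum(active) > 1L) {
    best <- max(s)  # inactive rows/cols and the diagonal sit at -Inf
    if (best < tau) break
    idx <- which(s == best, arr.ind = TRUE)
    # deterministic tie-break: smallest row then column index
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    i <- min(idx[1L, ]); j <- max(idx[1L, ])
    heights <- c(heights, best)
    # running UPGMA update: new average is the size-weighted mean, which
    # equals the unweighted mean over all cross pairs
    new_row <- (sizes[i] * s[i, ] + sizes[j] * s[j, ]) / (sizes[i] + sizes[j])
    s[i, ] <- new_row
    s[, i] <- new_row
    s[i, i] <- -Inf
    active[j] <- FALSE
    s[j, ] <- -Inf
    s[, j] <- -Inf
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    members[j] <- list(NULL)
  }

  groups <- members[active]
  groups <- lapply(groups, sort)
  big <- vapply(groups, length, integer(1)) >= min_size
  clusters <- groups[big]
  ord <- order(-vapply(clusters, length, integer(1)),
               vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  if (length(clusters) > 0L) {
    names(clusters) <- paste0("M", seq_along(clusters))
  }
  unassigned <- sort(unlist(groups[!big], use.names = FALSE)) %||% character()

  structure(list(clusters = clusters,
                 unassigned = as.character(unassigned),
                 merges = tibble(step = seq_along(heights), height = heights),
                 tau = tau, min_size = as.integer(min_size)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster set:", length(x$clusters), "clusters (min_size =", x$min_size,
      "), ", length(x$unassigned), "unassigned; tau =", x$tau, "\n")
  invisible(x)
}

#' @export
tidy.cluster_set <- function(x, ...) {
  if (length(x$clusters) == 0L) {
    return(tibble(protein_id = character(), cluster = character()))
  }
  bind_rows(lapply(names(x$clusters), function(nm) {
    tibble(protein_id = x$clusters[[nm]], cluster = nm)
  }))
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' `k` annotated members in a size-`n` draw without replacement from a
#' background of `N` containing `K` annotated. Computed through the
#' survival function, so it is stable for extreme tails.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the background.
#' @param n Draw (cluster) size.
#' @param N Background size.
#' @return The upper-tail probability (vectorised).
#' @examples
#' hypergeometric_tail(2, 4, 3, 10)  # 1/3
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & k <= n & n <= N & K <= N & k <= K
  if (any(!ok)) {
    abort("Inconsistent hypergeometric counts: need 0 <= k <= min(n, K), n <= N, K <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term enrichment of a cluster
#'
#' One-sided (upper-tail) hypergeometric enrichment, term for term, over a
#' flat protein-to-term annotation table. Only terms annotating at least two
#' cluster members are tested. The background defaults to the annotated
#' proteins among `background_ids`.
#'
#' @param cluster Character vector of member ids.
#' @param annotations Tibble with columns `protein_id`, `term_id`.
#' @param background_ids Ids of the clustered universe; the effective
#'   background is its annotated subset.
#' @param min_annotated Minimum cluster members carrying a term for it to be
#'   tested (default 2).
#' @return Tibble `term_id`, `k`, `K`, `n`, `N`, `p_value`, sorted ascending
#'   by `p_value`; zero rows when no cluster member is annotated.
#' @export
term_enrichment <- function(cluster, annotations, background_ids,
                            min_annotated = 2L) {
  annotations <- as_tibble(annotations)
  check_columns(annotations, c("protein_id", "term_id"), "annotation table")
  annotations <- distinct(annotations, .data$protein_id, .data$term_id)
  background <- intersect(unique(background_ids), unique(annotations$protein_id))
  N <- length(background)
  members <- intersect(unique(cluster), background)
  n <- length(members)
  empty <- tibble(term_id = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric())
  if (n == 0L || N == 0L) return(empty)

  ann_bg <- annotations[annotations$protein_id %in% background, , drop = FALSE]
  K_tab <- count(ann_bg, .data$term_id, name = "K")
  k_tab <- count(ann_bg[ann_bg$protein_id %in% members, , drop = FALSE],
                 .data$term_id, name = "k")
  res <- inner_join(k_tab, K_tab, by = "term_id") %>%
    filter(.data$k >= min_annotated)
  if (nrow(res) == 0L) return(empty)
  res %>%
    mutate(n = n, N = N,
           p_value = hypergeometric_tail(.data$k, .data$K, n, N)) %>%
    arrange(.data$p_value, .data$term_id) %>%
    select("term_id", "k", "K", "n", "N", "p_value")
}

#' Regulation-class enrichment of a cluster
#'
#' Upper-tail hypergeometric enrichment of up- and of down-regulated members
#' against the clustered universe. The label is the direction with the
#' smaller p-value when that p-value is below `alpha`; ties are broken
#' toward the direction with more members (logged).
#'
#' @param cluster Character vector of member ids.
#' @param records Classified abundance tibble covering the universe.
#' @param background_ids Ids of the clustered universe.
#' @param alpha Significance level for labelling (default 0.01).
#' @return One-row tibble `label` (`"up"`, `"down"`, or `NA`), `p_value`,
#'   `p_up`, `p_down`, `n_up`, `n_down`, `n`, `N`.
#' @export
regulation_enrichment <- function(cluster, records, background_ids,
                                  alpha = 0.01) {
  records <- as_tibble(records)
  check_columns(records, c("protein_id", "regulation"), "classified records")
  reg <- setNames(as.character(records$regulation), records$protein_id)
  background <- intersect(unique(background_ids), names(reg))
  members <- intersect(unique(cluster), background)
  N <- length(background)
  n <- length(members)
  if (n == 0L) {
    return(tibble(label = NA_character_, p_value = NA_real_, p_up = NA_real_,
                  p_down = NA_real_, n_up = 0L, n_down = 0L, n = 0L, N = N))
  }
  K_up <- sum(reg[background] == "up")
  K_down <- sum(reg[background] == "down")
  k_up <- sum(reg[members] == "up")
  k_down <- sum(reg[members] == "down")
  p_up <- if (K_up == 0L) 1 else hypergeometric_tail(k_up, K_up, n, N)
  p_down <- if (K_down == 0L) 1 else hypergeometric_tail(k_down, K_down, n, N)

  label <- NA_character_
  p_value <- NA_real_
  if (min(p_up, p_down) < alpha) {
    if (p_up < p_down) {
      label <- "up"; p_value <- p_up
    } else if (p_down < p_up) {
      label <- "down"; p_value <- p_down
    } else {
      label <- if (k_up >= k_down) "up" else "down"
      p_value <- p_up
      inform(paste0("Equal enrichment p for both directions; labelled '",
                    label, "' by member count."))
    }
  }
  tibble(label = label, p_value = p_value, p_up = p_up, p_down = p_down,
         n_up = k_up, n_down = k_down, n = n, N = N)
}

#' Assemble functional modules from clusters and enrichment tests
#'
#' A cluster becomes a functional module when it passes both the term
#' enrichment and the regulation enrichment at `alpha`. Each module carries
#' its representative (minimum-p) term, regulation label, and the count of
#' members whose class opposes the label. Aggregate coverage reports, per
#' regulation class, the fraction of regulated proteins of the clustered
#' universe captured by modules labelled with that class.
#'
#' @param clusters A `cluster_set`.
#' @param annotations Protein-to-term annotation tibble.
#' @param records Classified abundance tibble.
#' @param alpha Significance level for both tests (default 0.01).
#' @param adjust If `TRUE`, Benjamini-Hochberg-adjust the term p-values
#'   within each cluster before selection (off by default).
#' @return An object of class `module_set`: `modules` (tibble), `members`
#'   (tibble), `coverage` (tibble), `alpha`.
#' @export
assemble_modules <- function(clusters, annotations, records, alpha = 0.01,
                             adjust = FALSE) {
  stopifnot(inherits(clusters, "cluster_set"))
  records <- as_tibble(records)
  universe <- c(unlist(clusters$clusters, use.names = FALSE),
                clusters$unassigned)
  reg <- setNames(as.character(records$regulation), records$protein_id)

  rows <- list()
  member_rows <- list()
  for (nm in names(clusters$clusters)) {
    members <- clusters$clusters[[nm]]
    te <- term_enrichment(members, annotations, universe)
    if (nrow(te) == 0L) next
    if (adjust) te$p_value <- p.adjust(te$p_value, method = "BH")
    te <- arrange(te, .data$p_value, .data$term_id)
    if (te$p_value[1L] >= alpha) next
    re <- regulation_enrichment(members, records, universe, alpha = alpha)
    if (is.na(re$label)) next
    opposing <- if (re$label == "up") "down" else "up"
    rows[[nm]] <- tibble(
      module_id = nm, n_members = length(members),
      regulation_label = re$label, regulation_p = re$p_value,
      representative_term = te$term_id[1L], term_p = te$p_value[1L],
      n_opposing = sum(reg[members] == opposing, na.rm = TRUE)
    )
    member_rows[[nm]] <- tibble(module_id = nm, protein_id = members,
                                regulation = unname(reg[members]))
  }
  modules <- if (length(rows) > 0L) bind_rows(rows) else
    tibble(module_id = character(), n_members = integer(),
           regulation_label = character(), regulation_p = numeric(),
           representative_term = character(), term_p = numeric(),
           n_opposing = integer())
  members <- if (length(member_rows) > 0L) bind_rows(member_rows) else
    tibble(module_id = character(), protein_id = character(),
           regulation = character())

  coverage <- lapply(c("up", "down"), function(cl) {
    univ_cl <- sum(reg[universe] == cl, na.rm = TRUE)
    mods_cl <- modules$module_id[modules$regulation_label == cl]
    in_mod <- members$protein_id[members$module_id %in% mods_cl &
                                   members$regulation == cl]
    tibble(class = cl, n_in_modules = length(unique(in_mod)),
           n_universe = univ_cl,
           pct = if (univ_cl == 0L) NA_real_ else
             round(100 * length(unique(in_mod)) / univ_cl, 2))
  })
  structure(list(modules = modules, members = members,
                 coverage = bind_rows(coverage), alpha = alpha),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("Module set:", nrow(x$modules), "modules (",
      sum(x$modules$regulation_label == "up"), "up /",
      sum(x$modules$regulation_label == "down"), "down ) at alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' @export
tidy.module_set <- function(x, ...) {
  left_join(x$members, x$modules, by = "module_id")
}

#' @export
glance.module_set <- function(x, ...) {
  tibble(n_modules = nrow(x$modules),
         n_up_modules = sum(x$modules$regulation_label == "up"),
         n_down_modules = sum(x$modules$regulation_label == "down"),
         pct_up_covered = x$coverage$pct[x$coverage$class == "up"],
         pct_down_covered = x$coverage$pct[x$coverage$class == "down"])
}

#' Module-size plot
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_set <- function(object, ...) {
  df <- object$modules
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$module_id,
                                                      -.data$n_members),
                                   y = .data$n_members,
                                   fill = .data$regulation_label)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#2e7d32", down = "#c62828")) +
    ggplot2::labs(x = "module", y = "members", fill = "label") +
    ggplot2::theme_minimal()
}
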