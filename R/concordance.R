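#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) of a log2-scale intensity matrix to share the
#' same empirical distribution: each column's sorted values are replaced by
#' the across-column rank means, with ties receiving the mean of their target
#' quantiles. Delegates to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param mat Numeric genes-by-samples matrix, typically log2 intensities.
#' @return The normalized matrix (dimnames preserved).
#' @examples
#' quantile_normalize(cbind(a = c(1, 3), b = c(2, 4)))
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) abort("`mat` must be a numeric matrix.")
  if (anyNA(mat)) abort("`mat` must not contain NA.")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Filter genes by detection p-value
#'
#' Removes genes that are undetected (detection p-value > `alpha`) in every
#' sample of either condition; a gene detected in at least one sample of each
#' condition is kept.
#'
#' @param mat Genes-by-samples intensity matrix.
#' @param detection_p Matrix of the same shape with per-entry detection
#'   p-values.
#' @param condition Character/factor vector over columns with values
#'   `"rho0"` and `"rho_plus"`.
#' @param alpha Detection threshold (default 0.05).
#' @return A list: `mat` and `detection_p` restricted to surviving genes,
#'   and `removed` (character vector of dropped gene ids).
#' @export
detection_filter <- function(mat, detection_p, condition, alpha = 0.05) {
  if (!all(dim(mat) == dim(detection_p))) {
    abort("`mat` and `detection_p` must have identical dimensions.")
  }
  condition <- as.character(condition)
  if (length(condition) != ncol(mat) ||
      !all(condition %in% c("rho0", "rho_plus"))) {
    abort("`condition` must label every column as 'rho0' or 'rho_plus'.")
  }
  if (nrow(mat) == 0L) {
    return(list(mat = mat, detection_p = detection_p, removed = character()))
  }
  undetected_all <- function(cond) {
    cols <- which(condition == cond)
    apply(detection_p[, cols, drop = FALSE] > alpha, 1L, all)
  }
  drop <- undetected_all("rho0") | undetected_all("rho_plus")
  removed <- rownames(mat)[drop] %||% as.character(which(drop))
  if (any(drop)) {
    inform(paste0("Detection filter removed ", sum(drop), " genes."))
  }
  list(mat = mat[!drop, , drop = FALSE],
       detection_p = detection_p[!drop, , drop = FALSE],
       removed = removed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone after sorting, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0,1] with no NA.")
  }
  p.adjust(p, method = "BH")
}

#' Per-gene mRNA log2 ratios from a replicated expression matrix
#'
#' The mRNA log2 ratio is the mean over all rho0 x rho_plus replicate pairs
#' of the difference in normalized log2 intensity, which equals the
#' difference of the per-condition replicate means.
#'
#' @param mat Normalized log2 genes-by-samples matrix with gene rownames.
#' @param condition Column condition labels (`"rho0"` / `"rho_plus"`).
#' @return Tibble `protein_id`, `mrna_log2`.
#' @export
mrna_log2_ratios <- function(mat, condition) {
  condition <- as.character(condition)
  if (length(condition) != ncol(mat) ||
      !all(c("rho0", "rho_plus") %in% condition)) {
    abort("`condition` must cover every column and include both conditions.")
  }
  if (is.null(rownames(mat))) abort("`mat` must carry gene rownames.")
  m0 <- rowMeans(mat[, condition == "rho0", drop = FALSE])
  mp <- rowMeans(mat[, condition == "rho_plus", drop = FALSE])
  tibble(protein_id = rownames(mat), mrna_log2 = unname(m0 - mp))
}

#' Join protein and mRNA ratios into expression profiles
#'
#' Inner join on `protein_id`; proteins lacking an mRNA measurement are
#' excluded with a logged count. Protein ratios enter on the linear scale and
#' are log2-transformed here.
#'
#' @param records Classified abundance tibble (`protein_id`, `protein_ratio`,
#'   `regulation`).
#' @param mrna Tibble `protein_id`, `mrna_log2` (see [mrna_log2_ratios()]).
#' @return Tibble `protein_id`, `protein_log2`, `mrna_log2`, `regulation`.
#' @export
profile_table <- function(records, mrna) {
  records <- as_tibble(records)
  check_columns(records, c("protein_id", "protein_ratio"), "records table")
  mrna <- as_tibble(mrna)
  check_columns(mrna, c("protein_id", "mrna_log2"), "mRNA ratio table")
  joined <- inner_join(
    mutate(records, protein_log2 = log2(.data$protein_ratio)),
    distinct(mrna, .data$protein_id, .keep_all = TRUE),
    by = "protein_id"
  )
  n_dropped <- nrow(records) - nrow(joined)
  if (n_dropped > 0L) {
    inform(paste0(n_dropped, " proteins lack mRNA measurements and were excluded."))
  }
  cols <- c("protein_id", "protein_log2", "mrna_log2",
            intersect("regulation", names(joined)))
  joined[, cols]
}

concordance_levels <- c("up_up", "down_down", "up_down", "down_up", "unchanged")

#' K-means concordance partition of expression profiles
#'
#' Partitions the 2-D (protein log2 ratio, mRNA log2 ratio) points into `k`
#' groups with `stats::kmeans` (10 restarts, best inertia kept, deterministic
#' given `seed`), then labels clusters by centroid geometry: the centroid with
#' the smallest norm is `unchanged`; the rest are labelled by quadrant using a
#' dead-band `delta` (default `log2(1.2)`): both coordinates above `+delta`
#' is `up_up`, both below `-delta` is `down_down`, protein above and mRNA
#' below is `up_down`, protein below and mRNA above is `down_up`.
#'
#' @param profiles Tibble from [profile_table()].
#' @param k Number of groups (default 5).
#' @param seed Integer seed for the k-means restarts.
#' @param delta Dead-band on the centroid coordinates (default `log2(1.2)`).
#' @param nstart Random restarts (default 10).
#' @return An object of class `concordance_partition`: `profiles` (input plus
#'   `group`), `centroids` (tibble with `group`, coordinates, `size`),
#'   `inertia`, `seed`.
#' @export
kmeans_partition <- function(profiles, k = 5L, seed = 1L,
                             delta = log2(1.2), nstart = 10L) {
  profiles <- as_tibble(profiles)
  check_columns(profiles, c("protein_id", "protein_log2", "mrna_log2"),
                "profile table")
  if (nrow(profiles) < k) abort("Need at least `k` profiles.")
  pts <- as.matrix(profiles[, c("protein_log2", "mrna_log2")])
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  # Hartigan-Wong flags its Quick-TRANSfer stage on highly regular point
  # layouts; the fit is still valid, so only that warning is muffled
  km <- withCallingHandlers(
    kmeans(pts, centers = k, nstart = nstart, iter.max = 100L),
    warning = function(w) {
      if (grepl("Quick-TRANSfer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })

  centers <- km$centers
  norms <- sqrt(rowSums(centers^2))
  labels <- rep(NA_character_, k)
  labels[which.min(norms)] <- "unchanged"
  for (i in seq_len(k)) {
    if (!is.na(labels[i])) next
    p <- centers[i, 1L]; m <- centers[i, 2L]
    labels[i] <-
      if (p > delta && m > delta) "up_up"
      else if (p < -delta && m < -delta) "down_down"
      else if (p > delta && m < -delta) "up_down"
      else if (p < -delta && m > delta) "down_up"
      else NA_character_
  }
  if (anyNA(labels) || anyDuplicated(labels)) {
    abort(paste0("Centroid geometry is not labelable with delta = ",
                 signif(delta, 3), "; centroids: ",
                 paste(apply(round(centers, 3), 1L, paste, collapse = ","),
                       collapse = " | ")))
  }
  group <- factor(labels[km$cluster], levels = concordance_levels)
  centroids <- tibble(group = factor(labels, levels = concordance_levels),
                      protein_log2 = centers[, 1L],
                      mrna_log2 = centers[, 2L],
                      size = as.integer(km$size)) %>%
    arrange(.data$group)
  structure(list(profiles = mutate(profiles, group = group),
                 centroids = centroids,
                 inertia = km$tot.withinss, seed = seed),
            class = "concordance_partition")
}

#' @export
print.concordance_partition <- function(x, ...) {
  cat("Concordance partition (seed", x$seed, "):\n")
  print(count(x$profiles, .data$group))
  invisible(x)
}

#' @export
tidy.concordance_partition <- function(x, ...) x$profiles

#' @export
glance.concordance_partition <- function(x, ...) {
  sizes <- table(x$profiles$group)
  tibble(n = nrow(x$profiles),
         n_up_up = as.integer(sizes[["up_up"]]),
         n_down_down = as.integer(sizes[["down_down"]]),
         n_up_down = as.integer(sizes[["up_down"]]),
         n_down_up = as.integer(sizes[["down_up"]]),
         n_unchanged = as.integer(sizes[["unchanged"]]),
         n_positive = as.integer(sizes[["up_up"]] + sizes[["down_down"]]),
         n_negative = as.integer(sizes[["up_down"]] + sizes[["down_up"]]),
         inertia = x$inertia)
}

#' Concordance scatter plot
#'
#' @param object A `concordance_partition`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_partition <- function(object, ...) {
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$protein_log2, y = .data$mrna_log2,
                               colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = object$centroids, shape = 4, size = 3,
                        colour = "black") +
    ggplot2::labs(x = "protein log2 ratio", y = "mRNA log2 ratio") +
    ggplot2::theme_minimal()
}

#' Per-module expression summaries
#'
#' Mean and standard deviation (n - 1 denominator) of the linear-scale
#' protein and mRNA abundance ratios over each module's profiled members,
#' with direction flags for the module-level pattern (protein/mRNA mean
#' above or below 1). Modules with no profiled member are omitted with a log.
#'
#' @param modules A `module_set`.
#' @param profiles Tibble from [profile_table()].
#' @return Tibble `module_id`, `regulation_label`, `n_profiled`,
#'   `protein_mean`, `protein_sd`, `mrna_mean`, `mrna_sd`,
#'   `protein_direction`, `mrna_direction`.
#' @export
module_expression_summary <- function(modules, profiles) {
  stopifnot(inherits(modules, "module_set"))
  profiles <- as_tibble(profiles)
  check_columns(profiles, c("protein_id", "protein_log2", "mrna_log2"),
                "profile table")
  joined <- inner_join(modules$members, profiles, by = "protein_id")
  omitted <- setdiff(modules$modules$module_id, unique(joined$module_id))
  if (length(omitted) > 0L) {
    inform(paste0("Modules with no profiled member omitted: ",
                  paste(omitted, collapse = ", ")))
  }
  joined %>%
    mutate(protein_ratio = 2^.data$protein_log2,
           mrna_ratio = 2^.data$mrna_log2) %>%
    group_by(.data$module_id) %>%
    summarise(n_profiled = dplyr::n(),
              protein_mean = mean(.data$protein_ratio),
              protein_sd = sd(.data$protein_ratio),
              mrna_mean = mean(.data$mrna_ratio),
              mrna_sd = sd(.data$mrna_ratio),
              .groups = "drop") %>%
    left_join(modules$modules[, c("module_id", "regulation_label")],
              by = "module_id") %>%
    mutate(protein_direction = ifelse(.data$protein_mean > 1, "elevated",
                                      "depressed"),
           mrna_direction = ifelse(.data$mrna_mean > 1, "elevated",
                                   "depressed")) %>%
    select("module_id", "regulation_label", "n_profiled",
           "protein_mean", "protein_sd", "mrna_mean", "mrna_sd",
           "protein_direction", "mrna_direction")
}

#' Agreement between two regulation-pattern calls
#'
#' Percentage (two decimals) of shared proteins given the same regulation
#' class by two independent calls (e.g. two quantification platforms), plus
#' an exact binomial test of the agreement count against a null agreement
#' probability. The original study's comparison statistic is not specified;
#' the binomial test here is an explicit assumption of this implementation.
#'
#' @param patterns_a,patterns_b Tibbles with `protein_id` and `regulation`
#'   columns (or named character vectors).
#' @param p_null Null agreement probability for the binomial test
#'   (default 0.5).
#' @return One-row tibble `n_shared`, `n_agree`, `pct_agree`, `binom_p`.
#' @export
pattern_agreement <- function(patterns_a, patterns_b, p_null = 0.5) {
  as_map <- function(x) {
    if (is.data.frame(x)) {
      check_columns(x, c("protein_id", "regulation"), "pattern table")
      setNames(as.character(x$regulation), x$protein_id)
    } else {
      setNames(as.character(x), names(x))
    }
  }
  a <- as_map(patterns_a)
  b <- as_map(patterns_b)
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) abort("The two pattern sets share no proteins.")
  n_agree <- sum(a[shared] == b[shared])
  n <- length(shared)
  tibble(n_shared = n, n_agree = n_agree,
         pct_agree = round(100 * n_agree / n, 2),
         binom_p = binom.test(n_agree, n, p = p_null)$p.value)
}
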