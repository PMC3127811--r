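#' Regulation-classification thresholds
#'
#' Fold-change thresholds on the linear rho0/rho+ abundance-ratio scale.
#' A protein is called up-regulated when its ratio is at least `up_min`
#' (default 1.5, a 1.5-fold increase) and down-regulated when its ratio is
#' at most `down_max` (default 0.67, the conventional printed value for a
#' 1.5-fold decrease). Both boundaries are inclusive; everything strictly
#' between them is "unchanged".
#'
#' @param up_min Positive real; lower bound (inclusive) for the up class.
#' @param down_max Positive real; upper bound (inclusive) for the down class.
#' @return An object of class `classification_thresholds`.
#' @examples
#' classification_thresholds()
#' classification_thresholds(up_min = 2, down_max = 0.5)
#' @export
classification_thresholds <- function(up_min = 1.5, down_max = 0.67) {
  if (!is.numeric(up_min) || length(up_min) != 1L || !is.finite(up_min) ||
      !is.numeric(down_max) || length(down_max) != 1L || !is.finite(down_max)) {
    abort("`up_min` and `down_max` must be single finite numbers.")
  }
  if (!(down_max > 0 && down_max < up_min)) {
    abort("Thresholds must satisfy 0 < down_max < up_min.")
  }
  structure(list(up_min = up_min, down_max = down_max),
            class = "classification_thresholds")
}

#' @export
print.classification_thresholds <- function(x, ...) {
  cat("Regulation thresholds: up if ratio >=", x$up_min,
      "| down if ratio <=", x$down_max, "\n")
  invisible(x)
}

regulation_levels <- c("up", "down", "unchanged")

#' Classify abundance ratios into regulation classes
#'
#' Vectorised three-way classification of linear-scale rho0/rho+ ratios.
#'
#' @param ratio Numeric vector of positive, finite abundance ratios.
#' @param thresholds A [classification_thresholds()] object.
#' @param protein_id Optional identifiers used in error messages.
#' @return A factor with levels `up`, `down`, `unchanged`.
#' @examples
#' classify_abundance(c(1.5, 0.67, 1.0))
#' @export
classify_abundance <- function(ratio, thresholds = classification_thresholds(),
                               protein_id = NULL) {
  stopifnot(inherits(thresholds, "classification_thresholds"))
  bad <- !is.finite(ratio) | ratio <= 0
  if (any(bad)) {
    who <- if (!is.null(protein_id)) {
      paste(head(protein_id[bad], 5L), collapse = ", ")
    } else {
      paste(head(which(bad), 5L), collapse = ", ")
    }
    abort(paste0("Abundance ratios must be positive and finite; offending ",
                 if (is.null(protein_id)) "positions: " else "proteins: ", who))
  }
  out <- rep("unchanged", length(ratio))
  out[ratio >= thresholds$up_min] <- "up"
  out[ratio <= thresholds$down_max] <- "down"
  factor(out, levels = regulation_levels)
}

#' Classify an abundance table
#'
#' Takes a data frame with `protein_id` and `protein_ratio` columns (the
#' quantitative proteomics output), drops rows with missing ratios (logged),
#' and appends a `regulation` column.
#'
#' @param abundance Data frame with columns `protein_id`, `protein_ratio`.
#' @param thresholds A [classification_thresholds()] object.
#' @return A tibble with the input columns plus `regulation`.
#' @examples
#' classify_ratios(tibble::tibble(protein_id = c("A", "B", "C"),
#'                                protein_ratio = c(2, 0.5, 1)))
#' @export
classify_ratios <- function(abundance, thresholds = classification_thresholds()) {
  abundance <- as_tibble(abundance)
  check_columns(abundance, c("protein_id", "protein_ratio"), "abundance table")
  if (anyDuplicated(abundance$protein_id)) {
    dup <- unique(abundance$protein_id[duplicated(abundance$protein_id)])
    abort(paste0("Duplicate protein_id in abundance table: ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  missing_ratio <- is.na(abundance$protein_ratio)
  if (any(missing_ratio)) {
    inform(paste0("Dropping ", sum(missing_ratio),
                  " rows with missing protein_ratio."))
    abundance <- abundance[!missing_ratio, , drop = FALSE]
  }
  abundance %>%
    mutate(regulation = classify_abundance(.data$protein_ratio, thresholds,
                                           protein_id = .data$protein_id))
}

#' Summarise regulation classes
#'
#' Counts (and percentages of the total, two decimals) per regulation class
#' for a classified abundance table.
#'
#' @param records A classified abundance tibble (see [classify_ratios()]).
#' @return A one-row tibble with `n_up`, `n_down`, `n_unchanged`, `n_total`
#'   and the matching `pct_*` columns.
#' @examples
#' summarize_classes(classify_ratios(
#'   tibble::tibble(protein_id = letters[1:3], protein_ratio = c(2, 0.5, 1))))
#' @export
summarize_classes <- function(records) {
  records <- as_tibble(records)
  check_columns(records, c("protein_id", "regulation"), "classified records")
  if (anyDuplicated(records$protein_id)) {
    abort("Duplicate protein_id in classified records.")
  }
  reg <- factor(records$regulation, levels = regulation_levels)
  if (anyNA(reg)) abort("Unknown regulation class in records.")
  counts <- table(reg)
  n_total <- nrow(records)
  pct <- function(k) if (n_total == 0L) NA_real_ else round(100 * k / n_total, 2)
  tibble(
    n_up = as.integer(counts[["up"]]),
    n_down = as.integer(counts[["down"]]),
    n_unchanged = as.integer(counts[["unchanged"]]),
    n_total = n_total,
    pct_up = pct(.data$n_up),
    pct_down = pct(.data$n_down),
    pct_unchanged = pct(.data$n_unchanged)
  )
}

# shared column-presence check used by every table-consuming function
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(paste0("The ", what, " is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}
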