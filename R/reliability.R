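#' Reference catalog of organelle proteins
#'
#' Bundles the cellular-component annotation set with one or more named
#' reference protein sets (mirroring curated mitochondrial databases and
#' published mitochondrial proteomics datasets).
#'
#' @param cc_annotated Character vector of protein ids carrying the
#'   mitochondrial cellular-component annotation.
#' @param reference_sets Named list of character vectors, one per reference
#'   dataset. Names must be unique and must not include `"CC"` (reserved).
#' @return An object of class `reference_catalog`.
#' @export
reference_catalog <- function(cc_annotated, reference_sets) {
  cc_annotated <- unique(as.character(cc_annotated))
  if (!is.list(reference_sets) || length(reference_sets) == 0L) {
    abort("`reference_sets` must be a non-empty named list of id vectors.")
  }
  nm <- names(reference_sets)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "") || "CC" %in% nm) {
    abort("Reference set names must be unique, non-empty, and not 'CC'.")
  }
  reference_sets <- lapply(reference_sets, function(x) unique(as.character(x)))
  structure(list(cc_annotated = cc_annotated, reference_sets = reference_sets),
            class = "reference_catalog")
}

#' @export
print.reference_catalog <- function(x, ...) {
  cat("Reference catalog:", length(x$cc_annotated), "CC-annotated ids;",
      length(x$reference_sets), "reference sets\n")
  invisible(x)
}

#' Assign the reference tier
#'
#' Selects identified proteins supported by the reference evidence: with
#' `rule = "and"` (default) a protein must carry the cellular-component
#' annotation AND occur in at least one reference set; with `rule = "or"`
#' either line of evidence suffices.
#'
#' @param records Classified abundance tibble (the identified universe).
#' @param catalog A [reference_catalog()].
#' @param rule `"and"` or `"or"`.
#' @return Character vector of protein ids in the reference tier.
#' @export
assign_reference_tier <- function(records, catalog, rule = c("and", "or")) {
  rule <- match.arg(rule)
  records <- as_tibble(records)
  check_columns(records, "protein_id", "records table")
  if (!inherits(catalog, "reference_catalog")) {
    abort("`catalog` must be a reference_catalog object.")
  }
  ids <- records$protein_id
  in_cc <- ids %in% catalog$cc_annotated
  in_any_set <- ids %in% unique(unlist(catalog$reference_sets, use.names = FALSE))
  keep <- if (rule == "and") in_cc & in_any_set else in_cc | in_any_set
  ids[keep]
}

#' Rescue non-referenced proteins through links to the reference tier
#'
#' Proteins outside the reference tier are rescued if they carry at least one
#' physical-channel link to a reference-tier protein (tier `physical`);
#' of the remainder, those with at least one functional-channel link to the
#' reference tier form tier `functional`. Physical evidence takes precedence,
#' so the tiers are disjoint. Rescue is single-hop: links to rescued proteins
#' do not propagate.
#'
#' @param records Classified abundance tibble (the identified universe).
#' @param tier_reference Ids returned by [assign_reference_tier()].
#' @param links Link tibble with columns `protein_a`, `protein_b`,
#'   `confidence`, `channel` (see [read_links()]).
#' @return An object of class `reliability_tiers` with components
#'   `tier_reference`, `tier_physical`, `tier_functional`, `non_referenced`,
#'   and `universe`.
#' @export
assign_link_tiers <- function(records, tier_reference, links) {
  records <- as_tibble(records)
  check_columns(records, "protein_id", "records table")
  links <- validate_links(links)
  universe <- records$protein_id
  tier_reference <- intersect(unique(tier_reference), universe)

  known <- links$protein_a %in% universe & links$protein_b %in% universe
  if (any(!known)) {
    inform(paste0("Ignoring ", sum(!known),
                  " link rows with endpoints outside the identified universe."))
    links <- links[known, , drop = FALSE]
  }

  touches_ref <- function(channel) {
    lk <- links[links$channel == channel, , drop = FALSE]
    a_ref <- lk$protein_a %in% tier_reference
    b_ref <- lk$protein_b %in% tier_reference
    unique(c(lk$protein_b[a_ref & !b_ref], lk$protein_a[b_ref & !a_ref]))
  }
  candidates <- setdiff(universe, tier_reference)
  tier_physical <- intersect(candidates, touches_ref("physical"))
  tier_functional <- setdiff(intersect(candidates, touches_ref("functional")),
                             tier_physical)
  non_referenced <- setdiff(candidates, c(tier_physical, tier_functional))

  structure(list(tier_reference = tier_reference,
                 tier_physical = tier_physical,
                 tier_functional = tier_functional,
                 non_referenced = non_referenced,
                 universe = universe),
            class = "reliability_tiers")
}

#' Reliable protein ids from a tier object
#'
#' The reliable set is the union of the reference, physically-linked and
#' functionally-linked tiers.
#'
#' @param tiers A `reliability_tiers` object.
#' @return Character vector of reliable protein ids.
#' @export
reliable_ids <- function(tiers) {
  stopifnot(inherits(tiers, "reliability_tiers"))
  c(tiers$tier_reference, tiers$tier_physical, tiers$tier_functional)
}

#' Tier counts and percentages
#'
#' Per-tier counts, percentages of the identified universe (two decimals),
#' and the reliable total.
#'
#' @param tiers A `reliability_tiers` object.
#' @return A tibble with one row per tier plus a `reliable` summary row.
#' @export
reliability_report <- function(tiers) {
  stopifnot(inherits(tiers, "reliability_tiers"))
  n_univ <- length(tiers$universe)
  rows <- tibble(
    tier = c("reference", "physical", "functional", "non_referenced", "reliable"),
    n = c(length(tiers$tier_reference), length(tiers$tier_physical),
          length(tiers$tier_functional), length(tiers$non_referenced),
          length(reliable_ids(tiers)))
  )
  rows$pct <- if (n_univ == 0L) NA_real_ else round(100 * rows$n / n_univ, 2)
  rows$n_universe <- n_univ
  rows
}

#' @export
print.reliability_tiers <- function(x, ...) {
  print(reliability_report(x))
  invisible(x)
}

#' @export
tidy.reliability_tiers <- function(x, ...) {
  tier_of <- c(
    setNames(rep("reference", length(x$tier_reference)), x$tier_reference),
    setNames(rep("physical", length(x$tier_physical)), x$tier_physical),
    setNames(rep("functional", length(x$tier_functional)), x$tier_functional),
    setNames(rep("non_referenced", length(x$non_referenced)), x$non_referenced)
  )
  tibble(protein_id = x$universe,
         tier = unname(tier_of[x$universe]),
         reliable = unname(tier_of[x$universe]) != "non_referenced")
}

#' @export
glance.reliability_tiers <- function(x, ...) {
  r <- reliability_report(x)
  tibble(n_universe = length(x$universe),
         n_reference = r$n[r$tier == "reference"],
         n_physical = r$n[r$tier == "physical"],
         n_functional = r$n[r$tier == "functional"],
         n_non_referenced = r$n[r$tier == "non_referenced"],
         n_reliable = r$n[r$tier == "reliable"],
         pct_reliable = r$pct[r$tier == "reliable"])
}

# validates the link-table contract shared by reliability and funcnet
validate_links <- function(links) {
  links <- as_tibble(links)
  check_columns(links, c("protein_a", "protein_b", "confidence", "channel"),
                "link table")
  if (any(links$protein_a == links$protein_b)) {
    abort("Link table contains self-links.")
  }
  bad_conf <- !is.finite(links$confidence) | links$confidence < 0 |
    links$confidence > 1
  if (any(bad_conf)) {
    abort(paste0("Link confidences outside [0,1] at rows: ",
                 paste(head(which(bad_conf), 5L), collapse = ", ")))
  }
  if (!all(links$channel %in% c("physical", "functional"))) {
    abort("Link channel must be 'physical' or 'functional'.")
  }
  links
}
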