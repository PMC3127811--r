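#' @name table-io
#' @title Readers and writers for the pipeline's table dialects
#'
#' @description
#' Every table travels as tab-delimited UTF-8 text with a header row. Readers
#' validate the schema strictly and report offending data rows by line number
#' (header = line 1). Writers emit the same dialect.
#'
#' * abundance: `protein_id`, `protein_ratio` (writer appends `regulation`
#'   when present)
#' * catalog: `protein_id`, `set_name` (`"CC"` reserved for the
#'   cellular-component annotation)
#' * links: `protein_a`, `protein_b`, `confidence`, `channel`
#' * annotations: `protein_id`, `term_id`
#' * expression: genes x samples intensity matrix with a `gene_id` first
#'   column, plus a detection-p matrix of identical shape and a two-column
#'   condition map (`sample`, `condition`)
#'
#' @param path,mat_path,detection_path,condition_path File paths.
#' @param x Object to write.
#' @return Readers return tibbles (or the expression list); writers return
#'   the path invisibly.
NULL

read_tsv_strict <- function(path, col_names) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  if (!identical(names(df), col_names)) {
    abort(paste0(path, ": expected columns ", paste(col_names, collapse = ", "),
                 " but found ", paste(names(df), collapse = ", ")))
  }
  df
}

bad_rows <- function(path, cond, what) {
  if (any(cond)) {
    abort(paste0(path, ": ", what, " at line(s) ",
                 paste(head(which(cond) + 1L, 5L), collapse = ", ")))
  }
}

#' @rdname table-io
#' @export
read_abundance <- function(path) {
  df <- read_tsv_strict(path, c("protein_id", "protein_ratio"))
  ratio <- suppressWarnings(as.numeric(df$protein_ratio))
  bad_rows(path, is.na(ratio) & !is.na(df$protein_ratio), "non-numeric ratio")
  tibble(protein_id = df$protein_id, protein_ratio = ratio)
}

#' @rdname table-io
#' @export
write_abundance <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, c("protein_id", "set_name"))
  cc <- df$protein_id[df$set_name == "CC"]
  rest <- df[df$set_name != "CC", , drop = FALSE]
  if (nrow(rest) == 0L) abort(paste0(path, ": no reference sets beside CC."))
  reference_catalog(cc, split(rest$protein_id, rest$set_name))
}

#' @rdname table-io
#' @export
write_catalog <- function(x, path) {
  stopifnot(inherits(x, "reference_catalog"))
  df <- bind_rows(
    tibble(protein_id = x$cc_annotated, set_name = "CC"),
    bind_rows(lapply(names(x$reference_sets), function(nm) {
      tibble(protein_id = x$reference_sets[[nm]], set_name = nm)
    }))
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_links <- function(path) {
  df <- read_tsv_strict(path, c("protein_a", "protein_b", "confidence",
                                "channel"))
  conf <- suppressWarnings(as.numeric(df$confidence))
  bad_rows(path, is.na(conf), "non-numeric confidence")
  bad_rows(path, conf < 0 | conf > 1, "confidence outside [0,1]")
  bad_rows(path, !df$channel %in% c("physical", "functional"),
           "unknown channel")
  bad_rows(path, df$protein_a == df$protein_b, "self-link")
  tibble(protein_a = df$protein_a, protein_b = df$protein_b,
         confidence = conf, channel = df$channel)
}

#' @rdname table-io
#' @export
write_links <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_annotations <- function(path) {
  read_tsv_strict(path, c("protein_id", "term_id"))
}

#' @rdname table-io
#' @export
write_annotations <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_expression <- function(mat_path, detection_path, condition_path) {
  read_mat <- function(p) {
    df <- readr::read_tsv(p, progress = FALSE, show_col_types = FALSE)
    if (names(df)[1L] != "gene_id") {
      abort(paste0(p, ": first column must be gene_id."))
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) abort(paste0(p, ": non-numeric entries."))
    rownames(m) <- df$gene_id
    m
  }
  mat <- read_mat(mat_path)
  detection_p <- read_mat(detection_path)
  if (!identical(dim(mat), dim(detection_p)) ||
      !identical(dimnames(mat), dimnames(detection_p))) {
    abort("Intensity and detection-p matrices must have identical shape.")
  }
  cond <- read_tsv_strict(condition_path, c("sample", "condition"))
  if (!identical(cond$sample, colnames(mat))) {
    abort("Condition map must list the matrix columns in order.")
  }
  if (!all(cond$condition %in% c("rho0", "rho_plus"))) {
    abort("Conditions must be 'rho0' or 'rho_plus'.")
  }
  list(mat = mat, detection_p = detection_p, condition = cond$condition)
}

#' @rdname table-io
#' @export
write_expression <- function(x, mat_path, detection_path, condition_path) {
  write_mat <- function(m, p) {
    df <- as_tibble(m, rownames = "gene_id")
    readr::write_tsv(df, p)
  }
  write_mat(x$mat, mat_path)
  write_mat(x$detection_p, detection_path)
  readr::write_tsv(tibble(sample = colnames(x$mat), condition = x$condition),
                   condition_path)
  invisible(mat_path)
}

#' Serialize a synthetic world to a directory
#'
#' Writes the exact table dialects the pipeline consumes, plus the planted
#' truth and a manifest (paths, seed, config hash). Byte-identical for a
#' fixed config.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_abundance(world$abundance, p("abundance.tsv"))
  write_catalog(world$catalog, p("catalog.tsv"))
  write_links(world$links, p("links.tsv"))
  write_annotations(world$annotations, p("annotations.tsv"))
  write_expression(world$expression, p("expression.tsv"),
                   p("detection_p.tsv"), p("condition.tsv"))
  readr::write_tsv(world$truth, p("truth.tsv"))
  manifest <- list(
    files = c("abundance.tsv", "catalog.tsv", "links.tsv", "annotations.tsv",
              "expression.tsv", "detection_p.tsv", "condition.tsv",
              "truth.tsv"),
    seed = world$config$seed,
    config_hash = rlang::hash(unclass(world$config))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             p("manifest.json"))
  invisible(dir)
}

#' Read a serialized world directory
#'
#' @param dir Directory written by [write_world()].
#' @return A list with the same data components as [generate_world()]
#'   (`truth` included; `config` is not reconstructed).
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  list(
    abundance = read_abundance(p("abundance.tsv")),
    catalog = read_catalog(p("catalog.tsv")),
    links = read_links(p("links.tsv")),
    annotations = read_annotations(p("annotations.tsv")),
    expression = read_expression(p("expression.tsv"), p("detection_p.tsv"),
                                 p("condition.tsv")),
    truth = readr::read_tsv(p("truth.tsv"), progress = FALSE,
                            show_col_types = FALSE)
  )
}

#' Write a module report
#'
#' One row per module member: module id, member id, regulation label,
#' representative term and both enrichment p-values.
#'
#' @param modules A `module_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  stopifnot(inherits(modules, "module_set"))
  readr::write_tsv(tidy(modules)[, c("module_id", "protein_id",
                                     "regulation_label", "representative_term",
                                     "term_p", "regulation_p")], path)
  invisible(path)
}

#' Write concordance profiles
#'
#' @param partition A `concordance_partition`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(partition, path) {
  stopifnot(inherits(partition, "concordance_partition"))
  readr::write_tsv(partition$profiles, path)
  invisible(path)
}
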