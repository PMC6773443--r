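#' Assemble a validated count dataset
#'
#' Bundles a gene-by-sample matrix of raw read counts with its sample
#' metadata. All differential-expression functions in the package take this
#' container. Counts must be non-negative integers; metadata must describe
#' every sample exactly once and carry `sex` (F/M), `diet` (C/P, i.e.
#' carbohydrate- vs protein-rich) and `replicate` columns.
#'
#' @param counts integer matrix (genes in rows, unique rownames) or a tibble
#'   with a `gene` column followed by one column per sample.
#' @param samples data frame with columns `sample`, `sex`, `diet`,
#'   `replicate`.
#' @return An object of class `count_data`: a list with elements `counts`
#'   (integer matrix) and `samples` (tibble, one row per column of
#'   `counts`, in column order).
#' @export
count_data <- function(counts, samples) {
  if (is.data.frame(counts)) {
    if (!"gene" %in% names(counts)) {
      abort_format("tabular counts need a `gene` column.")
    }
    m <- as.matrix(counts[setdiff(names(counts), "gene")])
    rownames(m) <- counts$gene
    counts <- m
  }
  if (!is.matrix(counts) || is.null(rownames(counts))) {
    abort_format("`counts` must be a matrix with gene identifiers as rownames.")
  }
  if (anyDuplicated(rownames(counts))) abort_format("duplicate gene identifiers.")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort_format("counts must be finite non-negative integers.")
  }
  storage.mode(counts) <- "double"

  samples <- as_tibble(samples)
  required <- c("sample", "sex", "diet", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort_format(paste0("sample metadata is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  samples$sample <- as.character(samples$sample)
  samples$sex <- as.character(samples$sex)
  samples$diet <- as.character(samples$diet)
  if (anyDuplicated(samples$sample)) abort_data("duplicate sample identifiers in metadata.")
  if (!all(samples$sex %in% c("F", "M"))) abort_data("`sex` must be 'F' or 'M'.")
  if (!all(samples$diet %in% c("C", "P"))) abort_data("`diet` must be 'C' or 'P'.")

  if (is.null(colnames(counts))) {
    if (ncol(counts) != nrow(samples)) {
      abort_data("metadata does not describe the same samples as the count matrix.")
    }
    colnames(counts) <- samples$sample
  }
  if (!setequal(colnames(counts), samples$sample) ||
      ncol(counts) != nrow(samples)) {
    abort_data("metadata does not describe the same samples as the count matrix.")
  }
  samples <- samples[match(colnames(counts), samples$sample), ]

  structure(list(counts = counts, samples = samples), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("<count_data> %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  print(dplyr::count(x$samples, .data$sex, .data$diet))
  invisible(x)
}

#' @export
dim.count_data <- function(x) dim(x$counts)

#' Read counts and sample metadata from TSV
#'
#' Readers reject malformed input rather than coercing it: counts must be
#' integer-valued and non-negative, gene identifiers unique, and the
#' metadata must cover exactly the samples present in the count table.
#'
#' @param counts_path TSV with a `gene` column then one column per sample.
#' @param metadata_path TSV with columns `sample`, `sex`, `diet`, `replicate`.
#' @return A [count_data] object with samples ordered as in the count table.
#' @export
read_counts <- function(counts_path, metadata_path) {
  ct <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE,
                        na = character())
  if (!"gene" %in% names(ct)) abort_format("count table must have a `gene` column.")
  num <- ct[setdiff(names(ct), "gene")]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad)) abort_format("non-numeric count column(s) found.")
  md <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  count_data(ct, md)
}

#' Write counts and metadata as TSV
#'
#' @param x a [count_data] object.
#' @param counts_path,metadata_path output file paths.
#' @return Invisibly, the input (so the call can sit mid-pipe).
#' @export
write_counts <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "count_data"))
  tb <- bind_cols(tibble(gene = rownames(x$counts)),
                  as_tibble(x$counts, .name_repair = "minimal"))
  readr::write_tsv(tb, counts_path, progress = FALSE)
  readr::write_tsv(x$samples, metadata_path, progress = FALSE)
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members within a set are dropped with a logged warning.
#'
#' @param gmt_path path to a GMT file.
#' @return A named list of character vectors with a `description` attribute
#'   (named character vector), class `gene_set_collection`.
#' @export
read_gene_sets <- function(gmt_path) {
  lines <- readr::read_lines(gmt_path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      abort_format("GMT line with fewer than 3 fields (name, description, >=1 gene).")
    }
    nm <- fields[1]
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      nd_log(sprintf("gene set '%s': %d duplicate member(s) removed.",
                     nm, sum(duplicated(members))))
      members <- unique(members)
    }
    sets[[nm]] <- members
    descs[nm] <- fields[2]
  }
  if (anyDuplicated(names(sets))) abort_format("duplicate set names in GMT file.")
  gene_set_collection(sets, descs)
}

gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(sets, description = descriptions, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection named list of character vectors (as from
#'   [read_gene_sets()]).
#' @param gmt_path output path.
#' @export
write_gene_sets <- function(collection, gmt_path) {
  descs <- attr(collection, "description") %||%
    setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descs[[nm]] %||% "", collection[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, gmt_path)
  invisible(collection)
}

#' Read / write a term hierarchy (parent -> child edge list)
#'
#' The hierarchy is a two-column TSV of directed `parent`, `child` edges
#' over term names; it must be acyclic.
#'
#' @param path TSV path with columns `parent` and `child`.
#' @return A tibble with columns `parent`, `child`.
#' @export
read_hierarchy <- function(path) {
  h <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("parent", "child") %in% names(h))) {
    abort_format("hierarchy TSV needs `parent` and `child` columns.")
  }
  h <- as_tibble(h[c("parent", "child")])
  assert_acyclic(h)
  h
}

#' @rdname read_hierarchy
#' @param hierarchy tibble of `parent`, `child` edges.
#' @export
write_hierarchy <- function(hierarchy, path) {
  readr::write_tsv(as_tibble(hierarchy[c("parent", "child")]), path, progress = FALSE)
  invisible(hierarchy)
}

assert_acyclic <- function(edges) {
  # Kahn's algorithm; leftover edges imply a cycle
  e <- edges
  repeat {
    leaves <- setdiff(e$child, e$parent)
    keep <- !(e$child %in% leaves)
    if (all(keep)) break
    e <- e[keep, ]
    if (nrow(e) == 0L) break
  }
  if (nrow(e) > 0L) abort_format("term hierarchy contains a cycle.")
  invisible(edges)
}

#' Write result tables with a manifest
#'
#' Writes each tibble in `tables` to `<out_dir>/<name>.tsv` and a
#' `manifest.json` recording file names, row counts, and any parameters and
#' seeds supplied. Serialisation is deterministic: identical inputs give
#' byte-identical files.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if missing).
#' @param params optional named list recorded verbatim in the manifest.
#' @return The manifest as a list, invisibly.
#' @export
write_results <- function(tables, out_dir, params = list()) {
  if (!is.list(tables) || is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort_usage("`tables` must be a named list of data frames.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort_data(sprintf("cannot create directory '%s'.", out_dir))
  files <- list()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(as_tibble(tables[[nm]]), path, progress = FALSE)
    files[[nm]] <- list(file = basename(path), rows = nrow(tables[[nm]]))
  }
  manifest <- list(files = files, params = params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
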