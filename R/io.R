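#' @name io
#' @title Readers and writers for the upload dialect, gene sets, GMT and
#'   results
#'
#' @description
#' Datasets travel as a pair of plain-text files: a metadata table
#' describing the samples and their attributes, and a normalised data
#' file (probes x samples). Inputs are tab-separated by default with
#' delimiter auto-detection (comma accepted); exports are CSV. Every
#' writer's output is accepted by its paired reader.
NULL

# auto-detect tab vs comma from the first line
detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0L) "\t" else ","
}

read_table_file <- function(path, sep = NULL) {
  check_that(file.exists(path), "file not found: %s", path)
  sep <- sep %||% detect_sep(path)
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a metadata + normalized-data file pair
#'
#' Performs an itemized validation: required metadata columns, duplicate
#' sample IDs, samples present in only one of the two files, and
#' non-positive intensities are all reported by name. Dose levels outside
#' Control/Low/Middle/High are accepted as free text with a warning (new
#' tissues, compounds and time points may be freely defined).
#'
#' @param metadata_path path to the sample metadata table (TSV/CSV).
#' @param data_path path to the expression matrix (first column probe
#'   IDs, one column per sample).
#' @param sep optional explicit field separator for both files.
#' @return A [tox_dataset()].
#' @export
read_upload_pair <- function(metadata_path, data_path, sep = NULL) {
  meta <- read_table_file(metadata_path, sep)
  missing_cols <- setdiff(META_COLUMNS, names(meta))
  check_that(length(missing_cols) == 0L,
             "metadata is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  data <- read_table_file(data_path, sep)
  check_that(ncol(data) >= 2L,
             "data file needs a probe ID column plus sample columns")
  probes <- as.character(data[[1L]])
  m <- as.matrix(data[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probes
  nonstandard <- setdiff(unique(meta$dose_level), STANDARD_DOSE_LEVELS)
  if (length(nonstandard) > 0L) {
    warning(sprintf("non-standard dose level(s) accepted as free text: %s",
                    paste(nonstandard, collapse = ", ")), call. = FALSE)
  }
  tox_dataset(m, meta)
}

#' Write a dataset as a metadata + data file pair
#'
#' Emits `metadata.tsv` and `expression.tsv` under `dir`, in the exact
#' dialect [read_upload_pair()] consumes (round-trip safe).
#'
#' @param dataset a [tox_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tox_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta_path <- file.path(dir, "metadata.tsv")
  data_path <- file.path(dir, "expression.tsv")
  write.table(dataset$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  df <- data.frame(probe_id = dataset$probes,
                   dataset$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, data_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(metadata = meta_path, data = data_path))
}

#' Read / write a gene set as plain text
#'
#' One ID per line; leading lines starting with `#` carry the name
#' (`# name: ...`) and provenance (`# provenance: ...`).
#'
#' @param path file path.
#' @rdname geneset-io
#' @return `read_geneset()`: a [gene_set()].
#' @export
read_geneset <- function(path) {
  check_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  headers <- grep("^#", lines, value = TRUE)
  ids <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  ids <- ids[nzchar(ids)]
  name <- sub("^#\\s*name:\\s*", "",
              grep("^#\\s*name:", headers, value = TRUE))
  prov <- sub("^#\\s*provenance:\\s*", "",
              grep("^#\\s*provenance:", headers, value = TRUE))
  gene_set(if (length(name)) name[1L] else basename(path), ids,
           provenance = prov)
}

#' @param geneset a [gene_set()].
#' @rdname geneset-io
#' @export
write_geneset <- function(geneset, path) {
  stopifnot(inherits(geneset, "tox_geneset"))
  lines <- c(sprintf("# name: %s", geneset$name),
             sprintf("# provenance: %s", geneset$provenance),
             geneset$members)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one category per line, tab-separated fields name,
#' description, then member IDs.
#'
#' @param path file path.
#' @param feature_type collection feature type (see
#'   [annotation_collection()]).
#' @param name collection name; defaults to the file name.
#' @rdname gmt-io
#' @return `read_gmt()`: an [annotation_collection()].
#' @export
read_gmt <- function(path, feature_type = "other", name = NULL) {
  check_that(file.exists(path), "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  check_that(length(lines) > 0L, "empty GMT file: %s", path)
  cats <- list()
  for (line in lines) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    check_that(length(fields) >= 3L,
               "malformed GMT line (need name, description, members)")
    cats[[fields[1L]]] <- list(description = fields[2L],
                               members = fields[-(1:2)])
  }
  annotation_collection(name %||% basename(path), cats,
                        feature_type = feature_type)
}

#' @param collection an [annotation_collection()], or a list of
#'   [gene_set()]s for multi-set interchange.
#' @rdname gmt-io
#' @export
write_gmt <- function(collection, path) {
  if (inherits(collection, "tox_collection")) {
    lines <- vapply(names(collection$categories), function(id) {
      cat <- collection$categories[[id]]
      paste(c(id, cat$description, cat$members), collapse = "\t")
    }, character(1L))
  } else {
    lines <- vapply(collection, function(gs) {
      stopifnot(inherits(gs, "tox_geneset"))
      desc <- if (length(gs$provenance)) gs$provenance[1L] else ""
      paste(c(gs$name, desc, gs$members), collapse = "\t")
    }, character(1L))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a table as CSV
#'
#' Two export flavours exist: `"grouped"` writes the probes x groups
#' log2 table; `"individual"` writes the probes x samples fold values
#' prior to the log2 transform, so per-sample statistics can be
#' recomputed downstream (re-aggregating the individual export reproduces
#' the grouped export).
#'
#' @param x a [build_group_matrix()] result (`mode = "grouped"`) or a
#'   [build_fold_matrix()] result (`mode = "individual"`).
#' @param path output CSV path.
#' @param mode `"grouped"` or `"individual"`.
#' @return Invisibly, `path`.
#' @export
export_table <- function(x, path, mode = c("grouped", "individual")) {
  mode <- match.arg(mode)
  if (mode == "grouped") {
    check_that(inherits(x, "tox_group_table"),
               "grouped export needs a group table")
    m <- x$values
  } else {
    check_that(inherits(x, "tox_fold_matrix"),
               "individual export needs a fold matrix")
    m <- x$folds
  }
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probes x columns table export back into a matrix
#'
#' @param path CSV/TSV with a leading probe-ID column.
#' @param sep optional explicit separator.
#' @return Numeric matrix with probe row names.
#' @export
read_table_matrix <- function(path, sep = NULL) {
  df <- read_table_file(path, sep)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write a clustering result: partition TSV + JSON sidecar
#'
#' The TSV maps `probe_id` to `cluster_id`; the JSON sidecar carries the
#' merge list, heights at full double precision, the configuration and
#' the cutoff, so the dendrogram can be reconstructed bit-exactly.
#'
#' @param clustering a [cluster_table()] result with a partition.
#' @param prefix output path prefix (writes `<prefix>.tsv` and
#'   `<prefix>.json`).
#' @return Invisibly, the two paths.
#' @export
write_partition <- function(clustering, prefix) {
  stopifnot(inherits(clustering, "tox_clustering"))
  check_that(!is.null(clustering$partition),
             "clustering has no cutoff partition to write")
  part <- clustering$partition
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- data.frame(probe_id = names(part$assignment),
                   cluster_id = paste0("cluster", part$assignment),
                   stringsAsFactors = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  dend <- clustering$row_dendrogram
  # %.17g keeps the heights bit-exact across the JSON round trip
  heights_json <- structure(
    sprintf("[%s]", paste(sprintf("%.17g", dend$height), collapse = ",")),
    class = "json")
  payload <- list(
    config = list(method = clustering$config$method,
                  distance = clustering$config$distance,
                  max_genes = clustering$config$max_genes),
    cutoff = clustering$cutoff,
    labels = dend$labels,
    merges = dend$merge,
    heights = heights_json)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       json_verbatim = TRUE)
  invisible(c(partition = tsv, sidecar = json))
}

#' Read / write an ortholog map
#'
#' Tab-separated columns `set_id`, `platform`, `probe_id`.
#'
#' @param path file path.
#' @rdname ortho-io
#' @return `read_ortholog_map()`: an [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  df <- read_table_file(path, "\t")
  ortholog_map(df, provenance = sprintf("read from %s", basename(path)))
}

#' @param map an [ortholog_map()].
#' @rdname ortho-io
#' @export
write_ortholog_map <- function(map, path) {
  stopifnot(inherits(map, "tox_ortho_map"))
  write.table(map$sets, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an enrichment result as TSV
#'
#' @param result a [enrich()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "tox_enrichment"))
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a compound ranking as TSV
#'
#' @param ranking a [rank_compounds()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "tox_ranking"))
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
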