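#' @name pipeline
#' @title Declarative analysis pipeline
#'
#' @description
#' [run_pipeline()] chains the analysis stages in a fixed, documented
#' order driven by a single declarative JSON configuration: load (and
#' optionally median-normalize) a dataset, define sample groups, build
#' the group table, filter it into a gene set, cluster with a dendrogram
#' cutoff, enrich the clusters, add a statistical test column and filter
#' by it, re-cluster the resulting DEG set, extract consistently
#' down-regulated probes and rank compounds against them. Every
#' intermediate gene set is written with provenance; any stage failure
#' aborts with a stage-tagged error. The pipeline itself draws no random
#' numbers, so a rerun on the same inputs is byte-identical.
NULL

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    check_that(file.exists(config), "config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  }
  check_that(is.list(config), "`config` must be a list or a JSON path")
  check_that(!is.null(config$output_dir), "config needs `output_dir`")
  check_that(!is.null(config$data$metadata) &&
             !is.null(config$data$expression),
             "config needs data$metadata and data$expression paths")
  config
}

pipe_log <- function(state, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  state$log <- c(state$log, line)
  state
}

pipe_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# build per-column filters from a config filter spec
config_filters <- function(spec, table) {
  cols <- spec$columns %||% "*"
  if (identical(cols, "*") || identical(cols, list("*")))
    cols <- colnames(table$values)
  filters <- lapply(unlist(cols), function(cl)
    column_filter(spec$kind, spec$threshold))
  names(filters) <- unlist(cols)
  filters
}

# OR-combination across per-column masks (the per-time-point extraction
# used by dose/time-course workflows); AND is filter_table()'s native rule
filter_stage <- function(table, spec, name) {
  filters <- config_filters(spec, table)
  combine <- spec$combine %||% "and"
  if (combine == "and") return(filter_table(table, filters, name = name))
  masks <- lapply(names(filters), function(cl)
    apply_filter(table$values[, cl], filters[[cl]]))
  mask <- Reduce(`|`, masks)
  if (!any(mask)) warning("filter result is empty", call. = FALSE)
  gene_set(name, rownames(table$values)[mask],
           provenance = sprintf("filter (%s over %d columns): %s %s",
                                combine, length(filters), spec$kind,
                                format(spec$threshold)))
}

find_group <- function(groups, name) {
  check_that(name %in% names(groups), "unknown group '%s'", name)
  groups[[name]]
}

#' Run the declarative analysis pipeline
#'
#' @param config path to a JSON configuration file, or an equivalent
#'   list. Fields: `output_dir`; `data` (`metadata`, `expression`,
#'   optional `median_normalize`); optional `groups` scope (`compounds`,
#'   `dose_levels`, `times`); optional stages `filter` (`columns`,
#'   `kind`, `threshold`, `combine`), `cluster` (`method`, `distance`,
#'   `cutoff`), `enrich` (`gmt`, `adjust`), `stats` (`test`, `group_a`,
#'   `group_b`, `threshold`), `recluster` (`cutoff`, optional `method`,
#'   `distance`, plus column scope `compounds`/`dose_levels`/`times`),
#'   `consistent` (`compound`, `dose_level`, `ratio`, `direction`),
#'   `rank` (`mode`, `dose_level`, optional `geneset` path - default is
#'   the `consistent` stage result).
#' @return Invisibly, a list with the in-memory stage results (`dataset`,
#'   `groups`, `table`, `filtered`, `clustering`, `enrichment`,
#'   `stat_degs`, `reclustering`, `consistent`, `ranking`) and the
#'   artifact directory.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  state <- list(log = character())
  res <- list(output_dir = out)

  state <- pipe_log(state, "load", sprintf("reading %s + %s",
                                           config$data$metadata,
                                           config$data$expression))
  dataset <- pipe_stage("load",
    read_upload_pair(config$data$metadata, config$data$expression))
  if (isTRUE(config$data$median_normalize %||% TRUE)) {
    dataset <- pipe_stage("normalize", median_normalize(dataset))
    state <- pipe_log(state, "normalize", "median-normalized all columns")
  }
  res$dataset <- dataset

  gscope <- config$groups %||% list()
  groups <- pipe_stage("groups",
    make_groups(dataset, compounds = unlist(gscope$compounds),
                dose_levels = unlist(gscope$dose_levels),
                times = unlist(gscope$times)))
  state <- pipe_log(state, "groups", sprintf("%d sample group(s) defined",
                                             length(groups)))
  res$groups <- groups

  table <- pipe_stage("table", build_group_matrix(dataset, groups))
  export_table(table, file.path(out, "grouped_table.csv"), "grouped")
  folds <- pipe_stage("table", build_fold_matrix(dataset, groups))
  export_table(folds, file.path(out, "individual_folds.csv"),
               "individual")
  state <- pipe_log(state, "table",
                    sprintf("group table: %d probes x %d groups",
                            nrow(table$values), ncol(table$values)))
  res$table <- table

  current_set <- NULL
  if (!is.null(config$filter)) {
    current_set <- pipe_stage("filter",
      filter_stage(table, config$filter, "filtered"))
    write_geneset(current_set, file.path(out, "filtered.txt"))
    state <- pipe_log(state, "filter",
                      sprintf("%d probe(s) pass", length(current_set)))
    res$filtered <- current_set
  }

  if (!is.null(config$cluster)) {
    cl_conf <- clustering_config(
      method = config$cluster$method %||% "ward_d2",
      distance = config$cluster$distance %||% "pearson")
    sub <- table
    if (!is.null(current_set)) {
      check_that(length(current_set) >= 2L,
                 "filter result too small to cluster (%d probe(s))",
                 length(current_set))
      sub <- table$values[current_set$members, , drop = FALSE]
    }
    clustering <- pipe_stage("cluster",
      cluster_table(sub, cl_conf, cutoff = config$cluster$cutoff))
    if (!is.null(clustering$partition)) {
      write_partition(clustering, file.path(out, "clusters"))
      write_gmt(clustering$genesets, file.path(out, "clusters.gmt"))
      state <- pipe_log(state, "cluster",
                        sprintf("cutoff %s -> %d cluster(s)",
                                format(config$cluster$cutoff),
                                length(clustering$genesets)))
    } else {
      state <- pipe_log(state, "cluster", "dendrogram built (no cutoff)")
    }
    res$clustering <- clustering

    if (!is.null(config$enrich) && !is.null(clustering$partition)) {
      collection <- pipe_stage("enrich",
        read_gmt(config$enrich$gmt))
      universe <- dataset$probes
      top <- pipe_stage("enrich",
        top_feature_per_cluster(clustering$partition, universe,
                                collection))
      write.table(top, file.path(out, "cluster_top_features.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr <- pipe_stage("enrich", suppressWarnings(
        enrich(unlist(clustering$partition$clusters), universe,
               collection, adjust = config$enrich$adjust %||% "bh")))
      write_enrichment(enr, file.path(out, "enrichment.tsv"))
      state <- pipe_log(state, "enrich",
                        sprintf("%d categories tested", nrow(enr)))
      res$enrichment <- enr
    }
  }

  if (!is.null(config$stats)) {
    ga <- pipe_stage("stats", find_group(groups, config$stats$group_a))
    gb <- pipe_stage("stats", find_group(groups, config$stats$group_b))
    col <- pipe_stage("stats", suppressWarnings(
      stat_column(dataset, ga, gb,
                  test = config$stats$test %||% "welch_t")))
    degs <- pipe_stage("stats", suppressWarnings(
      filter_table(table,
                   list(p = column_filter("upper",
                                          config$stats$threshold %||% 0.01)),
                   extra = list(p = col$p.value), name = "stat_degs")))
    write_geneset(degs, file.path(out, "stat_degs.txt"))
    state <- pipe_log(state, "stats",
                      sprintf("%s %s vs %s: %d probe(s) at p <= %s",
                              col$test, ga$name, gb$name, length(degs),
                              format(config$stats$threshold %||% 0.01)))
    res$stat_degs <- degs

    if (!is.null(config$recluster)) {
      check_that(length(degs) >= 2L,
                 "DEG set too small to re-cluster (%d probe(s))",
                 length(degs))
      rc <- config$recluster
      cl_conf <- clustering_config(method = rc$method %||% "ward_d2",
                                   distance = rc$distance %||% "pearson")
      scope_groups <- if (!is.null(rc$compounds) || !is.null(rc$dose_levels) ||
                          !is.null(rc$times)) {
        pipe_stage("recluster",
          make_groups(dataset, compounds = unlist(rc$compounds),
                      dose_levels = unlist(rc$dose_levels),
                      times = unlist(rc$times)))
      } else groups
      rtab <- pipe_stage("recluster",
        build_group_matrix(dataset, scope_groups))
      sub <- rtab$values[degs$members, , drop = FALSE]
      reclustering <- pipe_stage("recluster",
        cluster_table(sub, cl_conf, cutoff = rc$cutoff))
      write_partition(reclustering, file.path(out, "recluster"))
      write_gmt(reclustering$genesets, file.path(out, "recluster.gmt"))
      state <- pipe_log(state, "recluster",
                        sprintf("cutoff %s -> %d cluster(s)",
                                format(rc$cutoff),
                                length(reclustering$genesets)))
      res$reclustering <- reclustering
    }
  }

  if (!is.null(config$consistent)) {
    cs <- config$consistent
    cgroups <- pipe_stage("consistent",
      make_groups(dataset, compounds = cs$compound,
                  dose_levels = cs$dose_level %||% "Middle"))
    ctab <- pipe_stage("consistent", build_group_matrix(dataset, cgroups))
    con_set <- pipe_stage("consistent",
      extract_consistent(ctab, ratio = cs$ratio %||% 0.5,
                         direction = cs$direction %||% "down"))
    write_geneset(con_set, file.path(out, "consistent.txt"))
    state <- pipe_log(state, "consistent",
                      sprintf("%d probe(s) consistently %s-regulated",
                              length(con_set), cs$direction %||% "down"))
    res$consistent <- con_set
  }

  if (!is.null(config$rank)) {
    rk <- config$rank
    query_set <- if (!is.null(rk$geneset)) {
      pipe_stage("rank", read_geneset(rk$geneset))
    } else {
      check_that(!is.null(res$consistent),
                 "rank stage needs a `geneset` path or a consistent stage")
      res$consistent
    }
    query <- pipe_stage("rank",
      ranking_query(query_set, mode = rk$mode %||% "total_downregulation",
                    dose_level = rk$dose_level %||% "Middle"))
    rank_groups <- pipe_stage("rank",
      make_groups(dataset, dose_levels = query$dose_level))
    rank_table <- pipe_stage("rank",
      build_group_matrix(dataset, rank_groups))
    ranking <- pipe_stage("rank", suppressWarnings(
      rank_compounds(rank_table, query)))
    write_ranking(ranking, file.path(out, "ranking.tsv"))
    state <- pipe_log(state, "rank",
                      sprintf("top compound: %s (score %.4g)",
                              ranking$compound[1L], ranking$score[1L]))
    res$ranking <- ranking
  }

  writeLines(state$log, file.path(out, "run.log"))
  invisible(res)
}
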