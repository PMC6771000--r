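## Pipeline orchestration: a flat key=value run configuration, TSV report
## writers with a "#" header line, a functional-category tally, and the
## end-to-end driver used by the command-line interface.

#' Build or read a run configuration
#'
#' Defaults equal the printed pipeline parameters: clustering c = 0.8,
#' s = 0.9; unique-cluster filter and pathway screen at e-value 1e-5 and
#' identity 50; 100 accumulation permutations. The file format is flat
#' `key = value` lines ('#' comments allowed); explicit arguments override
#' file values.
#'
#' @param file optional config file.
#' @param ... overrides (proteome_dir, genome_dir, tree, refdb, out_dir,
#'   c, s, evalue_max, identity_min, R, seed, fragment_len, ...).
#' @return list of class `run_config`.
#' @export
run_config <- function(file = NULL, ...) {
  cfg <- list(proteome_dir = NULL, genome_dir = NULL, tree = NULL,
              refdb = NULL, annotation = NULL, out_dir = "panlin_out",
              c = 0.8, s = 0.9, evalue_max = 1e-5, identity_min = 50,
              R = 100, seed = 1L, fragment_len = 1020)
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    lines <- grep("^\\s*(#|$)", readLines(file), value = TRUE, invert = TRUE)
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("bad config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a report TSV with a one-line '#' header naming the columns
#'
#' @param df data frame.
#' @param path output file.
#' @param params optional named list echoed as '#' comment lines.
#' @export
write_report_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# param %s=%s", names(params),
                       vapply(params, format, "")), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Tally functional categories for core and unique clusters
#'
#' Counts user-supplied functional categories (for example COG letters)
#' over the representatives of core clusters and of unique clusters;
#' representatives without an annotation are counted under "unassigned".
#' The assignment itself is out of scope — this consumes a finished
#' gene-to-category table.
#'
#' @param p a [partition_pangenome()] result.
#' @param cs the underlying `cluster_set`.
#' @param annotation data frame (gene_id, category) or named vector.
#' @return data frame (class, category, count, percent) with percentages
#'   per class to 1 decimal place in the `percent_label` column.
#' @export
category_tally <- function(p, cs, annotation) {
  if (inherits(annotation, "data.frame")) {
    ann <- setNames(as.character(annotation[[2]]),
                    as.character(annotation[[1]]))
  } else ann <- annotation
  reps <- setNames(vapply(cs$clusters, `[[`, "", "representative"),
                   vapply(cs$clusters, `[[`, 0L, "cluster_id"))
  tally_one <- function(ids, label) {
    g <- unname(reps[as.character(ids)])
    cat_of <- ifelse(is.na(ann[g]) | !g %in% names(ann), "unassigned",
                     ann[g])
    t <- table(cat_of)
    data.frame(class = label, category = names(t),
               count = as.integer(t),
               percent = 100 * as.integer(t) / length(g),
               stringsAsFactors = FALSE)
  }
  uniq_ids <- unlist(p$unique_by_genome, use.names = FALSE)
  out <- rbind(
    if (length(p$core)) tally_one(p$core, "core"),
    if (length(uniq_ids)) tally_one(uniq_ids, "unique"))
  if (is.null(out))
    out <- data.frame(class = character(0), category = character(0),
                      count = integer(0), percent = numeric(0))
  out$percent_label <- sprintf("%.1f%%", out$percent)
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the pangenome pipeline end to end
#'
#' stats -> cluster -> partition -> unique filter -> accumulation ->
#' Heaps fit -> (with a tree) unique-vs-distance correlation -> reports.
#' Outputs are written with a ".partial" suffix and renamed on success;
#' the JSON manifest records parameters, seed, input checksums and
#' package version, which suffices to re-run bit-identically.
#'
#' @param config a [run_config()].
#' @return the manifest (invisibly also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- .stage("inputs", {
    if (is.null(config$proteome_dir)) stop("proteome_dir is not set")
    if (!dir.exists(config$proteome_dir) &&
        !file.exists(config$proteome_dir))
      stop("proteome path does not exist: ", config$proteome_dir)
    p <- if (dir.exists(config$proteome_dir))
      list.files(config$proteome_dir, "\\.(fa|faa|fasta)$",
                 full.names = TRUE) else config$proteome_dir
    if (length(p) == 0) stop("no proteome FASTA files in ",
                             config$proteome_dir)
    sort(p)
  })
  prote <- .stage("read_proteomes", read_proteomes(paths))
  params <- list(c = config$c, s = config$s, evalue_max = config$evalue_max,
                 identity_min = config$identity_min, R = config$R,
                 seed = config$seed)
  outfile <- function(name) file.path(config$out_dir, name)
  partials <- character(0)
  emit <- function(df, name, ...) {
    tmp <- paste0(outfile(name), ".partial")
    write_report_tsv(df, tmp, params = params)
    partials <<- c(partials, tmp)
    tmp
  }
  cs <- .stage("cluster",
               greedy_cluster(prote, cluster_params(config$c, config$s)))
  emit(cluster_table(cs), "clusters.tsv")
  p <- .stage("partition", partition_pangenome(cs))
  p <- .stage("filter_unique",
              filter_unique(p, cs, prote, evalue_max = config$evalue_max,
                            identity_min = config$identity_min))
  part_tab <- data.frame(
    cluster_id = as.integer(names(p$presence)),
    class = ifelse(as.integer(names(p$presence)) %in% p$core, "core",
                   ifelse(as.integer(names(p$presence)) %in% p$accessory,
                          "accessory", "unique")),
    presence_count = as.integer(p$presence), stringsAsFactors = FALSE)
  emit(part_tab, "partition.tsv")
  emit(data.frame(genome = p$genome_ids,
                  n_unique = vapply(p$unique_by_genome, length, 0L)),
       "unique_counts.tsv")
  emit(attr(p, "reclassified"), "unique_filter_log.tsv")
  curve <- .stage("accumulation",
                  accumulation(cs, R = config$R, seed = as.integer(config$seed)))
  emit(as.data.frame(curve), "accumulation.tsv")
  hf <- if (p$n_genomes >= 3) .stage("heaps", heaps_fit(curve)) else NULL
  corr <- NULL
  if (!is.null(config$tree)) {
    tree <- .stage("tree", read_newick(config$tree))
    corr <- .stage("correlation", unique_vs_distance(p, tree))
    emit(corr$table, "unique_vs_distance.tsv")
  }
  ctally <- NULL
  if (!is.null(config$annotation)) {
    ann <- .stage("annotation", read.delim(config$annotation,
                                           header = FALSE,
                                           comment.char = "#",
                                           stringsAsFactors = FALSE))
    ctally <- category_tally(p, cs, ann)
    emit(ctally, "category_tally.tsv")
  }
  manifest <- list(
    package = "panlin",
    version = as.character(utils::packageVersion("panlin")),
    parameters = params,
    inputs = as.list(setNames(unname(tools::md5sum(paths)), paths)),
    n_genomes = p$n_genomes,
    n_clusters = length(cs$clusters),
    n_core = length(p$core),
    n_accessory = length(p$accessory),
    n_unique = sum(vapply(p$unique_by_genome, length, 0L)),
    heaps = if (!is.null(hf)) hf[c("kappa", "alpha", "gamma", "verdict")],
    correlation = if (!is.null(corr)) corr[c("rho", "pvalue", "n")],
    outputs = basename(sub("\\.partial$", "", partials)))
  for (f in partials) file.rename(f, sub("\\.partial$", "", f))
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
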