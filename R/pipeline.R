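# One-command orchestration: catalog -> scan -> matrix -> screens ---------

#' Assemble and validate a pipeline run configuration
#'
#' @param catalog Path(s) to mature miRNA FASTA file(s).
#' @param genomes Named list/vector mapping genome id to genome FASTA
#'   path.
#' @param tree Path to a Newick species tree over the genome ids.
#' @param labels Path to a trait-label TSV (`genome_id`, `label`).
#' @param clades Named list of clade member vectors to bind on the
#'   tree.
#' @param outdir Output directory.
#' @param precedence Species-prefix precedence for [dedup_catalog()].
#' @param max_mismatches,min_positive,min_inside,tolerance Scanner and
#'   screen thresholds (defaults 0, 1, 1, 0).
#' @param seed Integer recorded in the run report (the pipeline itself
#'   is deterministic).
#' @return A validated `run_config` list.
#' @export
run_config <- function(catalog, genomes, tree, labels, clades = list(),
                       outdir, precedence = c("ame", "nvi", "dme"),
                       max_mismatches = 0L, min_positive = 1L,
                       min_inside = 1L, tolerance = 0L, seed = 0L) {
  genomes <- unlist(genomes)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    stop("genomes must be a named genome_id -> FASTA path map")
  }
  paths <- c(catalog, unname(genomes), tree, labels)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input path(s) do not exist: ", paste(missing, collapse = ", "))
  }
  structure(list(catalog = catalog, genomes = genomes, tree = tree,
                 labels = labels, clades = clades, outdir = outdir,
                 precedence = precedence,
                 max_mismatches = as.integer(max_mismatches),
                 min_positive = as.integer(min_positive),
                 min_inside = as.integer(min_inside),
                 tolerance = as.integer(tolerance),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [run_config()]; relative
#'   paths are resolved against the YAML file's directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  args <- list(catalog = rel(unlist(y$catalog)),
               genomes = lapply(y$genomes, rel),
               tree = rel(y$tree), labels = rel(y$labels),
               clades = y$clades %||% list(),
               outdir = rel(y$outdir %||% "socmir_out"))
  for (f in c("precedence", "max_mismatches", "min_positive", "min_inside",
              "tolerance", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full profiling pipeline
#'
#' Executes catalog construction, genome scanning, matrix assembly and
#' filtering/ordering, the trait-exclusive and clade screens, and
#' parsimony reconstruction, writing every stage product under
#' `config$outdir`. Rerunning with identical inputs reproduces
#' identical outputs. Any stage error aborts with the stage name
#' prefixed to the message.
#'
#' @param config A `run_config` (or YAML path).
#' @return The run report (also written as `run_report.json`),
#'   invisibly a list with stage products attached in
#'   `attr(report, "products")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)

  catalog <- stage("catalog", {
    entries <- do.call(rbind, lapply(config$catalog, load_mature_fasta))
    if (nrow(entries) == 0L) stop("catalog is empty after loading")
    cat <- dedup_catalog(entries, precedence = config$precedence)
    write_catalog_tsv(cat, out("catalog.tsv"))
    cat
  })

  hits <- stage("scan", {
    panel <- lapply(names(config$genomes), function(g) {
      read_genome_fasta(config$genomes[[g]], g)
    })
    h <- scan_panel(catalog, panel, config$max_mismatches)
    write_hits_bed(h, out("hits.bed"), out("hits.tsv"))
    h
  })

  tree <- stage("tree", {
    tr <- parse_newick(paste(readLines(config$tree), collapse = ""))
    if (length(config$clades)) tr <- bind_clades(tr, config$clades)
    tr
  })
  labels <- stage("labels", read_labels_tsv(config$labels))

  matrices <- stage("matrix", {
    raw <- call_presence(hits, catalog, names(config$genomes))
    informative <- filter_informative(raw)
    ordered <- order_by_tree(informative, tree)
    write_pa_tsv(raw, out("matrix_raw.tsv"))
    write_pa_tsv(informative, out("matrix_informative.tsv"))
    write_pa_tsv(ordered, out("matrix_ordered.tsv"))
    list(raw = raw, informative = informative, ordered = ordered)
  })

  screens <- stage("screens", {
    sc <- list(trait_exclusive = trait_exclusive(matrices$informative,
                                                 labels,
                                                 config$min_positive))
    for (cl in names(attr(tree, "clades") %||% list())) {
      sc[[paste0("clade_exclusive_", cl)]] <-
        clade_exclusive(matrices$informative, tree, cl, config$min_inside)
      sc[[paste0("clade_universal_", cl)]] <-
        clade_universal(matrices$informative, tree, cl, config$tolerance)
    }
    for (nm in names(sc)) {
      utils::write.table(sc[[nm]], out(paste0("candidates_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    sc
  })

  parsimony <- stage("reconstruct", {
    summ <- convergence_summary(matrices$informative, tree, labels)
    recon <- reconstruct_matrix(matrices$informative, tree)
    utils::write.table(summ, out("convergence_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(recon, out("parsimony_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(convergence = summ, reconstruction = recon)
  })

  report <- list(
    tool = "socmir",
    version = as.character(utils::packageVersion("socmir")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = list(max_mismatches = config$max_mismatches,
                      min_positive = config$min_positive,
                      min_inside = config$min_inside,
                      tolerance = config$tolerance),
    counts = list(
      catalog_queries = nrow(catalog),
      genomes = length(config$genomes),
      hits = nrow(hits),
      matrix_rows_raw = nrow(matrices$raw$values),
      matrix_rows_informative = nrow(matrices$informative$values),
      candidates = lapply(screens, nrow)
    ),
    complete = TRUE
  )
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  attr(report, "products") <- list(catalog = catalog, hits = hits,
                                   matrices = matrices, screens = screens,
                                   parsimony = parsimony, tree = tree,
                                   labels = labels, config = config)
  invisible(report)
}

#' Render a human-readable run summary and heatmap
#'
#' Writes `summary.txt` (a single timestamp header line followed by a
#' deterministic body) and a tree-ordered presence/absence heatmap
#' with trait-exclusive rows framed black and clade-exclusive rows
#' framed red.
#'
#' @param report A completed report from [run_pipeline()].
#' @param outdir Output directory (defaults to the run's).
#' @return Paths written, invisibly.
#' @export
render_report <- function(report, outdir = NULL) {
  if (!isTRUE(report$complete)) {
    stop("run is incomplete; fix the failed stage before rendering")
  }
  prod <- attr(report, "products")
  if (is.null(prod)) stop("report carries no stage products")
  outdir <- outdir %||% prod$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    paste("# generated:", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("socmir %s run summary (seed %d)", report$version, report$seed),
    sprintf("catalog: %d unique queries", report$counts$catalog_queries),
    sprintf("panel: %d genomes, %d hits", report$counts$genomes,
            report$counts$hits),
    sprintf("matrix: %d rows raw, %d informative",
            report$counts$matrix_rows_raw,
            report$counts$matrix_rows_informative),
    vapply(names(prod$screens), function(nm) {
      n <- nrow(prod$screens[[nm]])
      hits <- if (n == 0) "none" else
        paste(prod$screens[[nm]]$mirna_name, collapse = ", ")
      sprintf("screen %s: %d candidate(s)%s", nm, n,
              if (n == 0) "" else paste0(" [", hits, "]"))
    }, character(1))
  )
  summary_path <- file.path(outdir, "summary.txt")
  writeLines(lines, summary_path)
  heat_path <- file.path(outdir, "heatmap.png")
  clade_rows <- unlist(lapply(
    grep("^clade_exclusive_", names(prod$screens), value = TRUE),
    function(nm) prod$screens[[nm]]$mirna_name))
  plot_pa_heatmap(prod$matrices$ordered, labels = prod$labels,
                  frame_black = prod$screens$trait_exclusive$mirna_name,
                  frame_red = setdiff(clade_rows,
                                      prod$screens$trait_exclusive$mirna_name),
                  file = heat_path, main = "presence/absence profile")
  invisible(c(summary = summary_path, heatmap = heat_path))
}
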