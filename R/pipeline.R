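# File-driven pipeline: extract -> assign -> abc -> eval, plus a small
# argv dispatcher so every stage is scriptable with Rscript. Configuration
# is a plain-text "key: value" file, echoed into the log for
# reproducibility.

#' Path to a bundled example or fixture file
#'
#' @param name file name under the package's `extdata` directory; omit to
#'   list the available files.
#' @return a file path (or a character vector of file names).
#' @export
abc_example <- function(name = NULL) {
  if (is.null(name))
    return(list.files(system.file("extdata", package = "abcontext")))
  path <- system.file("extdata", name, package = "abcontext")
  if (!nzchar(path)) stop("no bundled file '", name, "'", call. = FALSE)
  path
}

#' Read a plain-text pipeline configuration
#'
#' One `key: value` pair per line; blank lines and `#` comments are
#' skipped. Recognized keys: `sentences` or `relations` (input), `mode`
#' (`annotated`/`heuristic`), `model`, `threshold`, `a`, `c`,
#' `vocab.<type>`, `max_distance.<type>`, `gold`, `universe`,
#' `normalization`, `out_dir`, `seed`.
#'
#' @param path config file path.
#' @return named list of strings.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regexec("^([^:]+):(.*)$", lines)
  parts <- regmatches(lines, m)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0)
    stop("malformed config line: '", lines[bad[1]], "'", call. = FALSE)
  stats::setNames(lapply(parts, function(p) trimws(p[3])),
                  vapply(parts, function(p) trimws(p[2]), character(1)))
}

load_config_vocabs <- function(config) {
  vocabs <- list()
  for (type in CONTEXT_SLOTS) {
    key <- paste0("vocab.", type)
    if (is.null(config[[key]])) next
    md_key <- paste0("max_distance.", type)
    md <- if (is.null(config[[md_key]])) NULL
          else as.numeric(config[[md_key]])
    vocabs[[type]] <- load_hierarchy(config[[key]], type, md)
  }
  vocabs
}

#' Run the full closed-discovery pipeline from a configuration file
#'
#' Stages: read (or extract from sentences) the relation table; for the
#' context-assignment model, assign abstract-level contexts; build A-B-C
#' paths under the configured model and threshold; deduplicate B entities;
#' evaluate against gold labels when provided. Each stage's output is
#' written under `out_dir` in the dialect the next stage reads
#' (`relations_extracted.tsv`, `relations_assigned.tsv`, `paths.tsv`,
#' `b_entities.txt`, `evaluation.tsv`) and per-stage counts are logged.
#' Missing input files are a configuration error raised before any stage
#' runs.
#'
#' @param config path to a config file, or an equivalent named list.
#' @param quiet suppress log messages.
#' @return invisibly, a list with `relations`, `paths`, `b_entities`,
#'   `evaluation` (or `NULL`) and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  say <- function(...) if (!quiet) message(...)
  for (key in names(config)) say("config ", key, ": ", config[[key]])

  model <- match.arg(gsub("-", "_", config$model %||% "cooccurrence"),
                     ABC_MODELS)
  needed <- c(config$sentences, config$relations, config$gold,
              config$universe,
              unlist(config[paste0("vocab.", CONTEXT_SLOTS)]))
  absent <- needed[!file.exists(needed)]
  if (length(absent) > 0)
    stop("configured input file(s) not found: ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (is.null(config$sentences) && is.null(config$relations))
    stop("config must name 'sentences' or 'relations'", call. = FALSE)
  if (is.null(config$a) || is.null(config$c))
    stop("config must name the fixed endpoints 'a' and 'c'", call. = FALSE)

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vocabs <- load_config_vocabs(config)
  threshold <- as.numeric(config$threshold %||% "1")
  mode <- config$mode %||% "annotated"

  if (!is.null(config$sentences)) {
    sentences <- read_annotated_sentences(config$sentences)
    relations <- extract_relations(sentences, mode = mode)
    say("extracted ", nrow(relations), " relations from ",
        length(sentences), " sentences")
  } else {
    relations <- read_relation_table(config$relations)
    say("read ", nrow(relations), " relations")
  }
  write_relation_table(relations,
                       file.path(out_dir, "relations_extracted.tsv"))

  if (model == "context_assignment") {
    relations <- assign_contexts(relations)
    write_relation_table(relations,
                         file.path(out_dir, "relations_assigned.tsv"))
    say("assigned abstract-level contexts across ",
        length(unique(relations$pmid)), " abstracts")
  }

  paths <- build_paths(relations, config$a, config$c, model = model,
                       threshold = threshold, vocabs = vocabs,
                       normalization = config$normalization %||% "all")
  write_path_table(paths, file.path(out_dir, "paths.tsv"))
  b <- dedup_b_entities(paths)
  writeLines(b, file.path(out_dir, "b_entities.txt"))
  say(model, " model at threshold ", threshold, ": ", nrow(paths),
      " paths, ", length(b), " B entities after deduplication")

  evaluation <- NULL
  if (!is.null(config$gold)) {
    gold <- read_gold_labels(config$gold, config$universe)
    evaluation <- evaluate_b_entities(b, gold)
    utils::write.table(
      data.frame(metric = names(evaluation),
                 value = unlist(evaluation, use.names = FALSE)),
      file.path(out_dir, "evaluation.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    say(sprintf("precision %.3f, recall %.3f",
                evaluation$precision, evaluation$recall))
  }
  invisible(list(relations = relations, paths = paths, b_entities = b,
                 evaluation = evaluation, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `extract`, `assign`, `abc`,
#' `eval`, `sweep` and `run` over `--flag value` arguments, e.g.
#' `Rscript -e 'abcontext::abc_cli()' run --config pipeline.conf` or
#' `... abc --relations rel.tsv --model context --a apoe --c mapt
#' --threshold 1 --vocab-disease mesh.tsv --out paths.tsv`.
#'
#' @param args character vector of arguments; defaults to the command
#'   line's trailing arguments.
#' @return exit-style integer status, invisibly (0 on success).
#' @export
abc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: abc_cli <simulate|extract|assign|abc|eval|sweep|run> ",
            "[--flag value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_flags(args[-1])
  vocabs_from <- function(opts) {
    vocabs <- list()
    for (type in CONTEXT_SLOTS) {
      key <- paste0("vocab-", type)
      if (!is.null(opts[[key]]))
        vocabs[[type]] <- load_hierarchy(opts[[key]], type)
    }
    vocabs
  }
  status <- switch(
    cmd,
    run = {
      run_pipeline(opts$config %||% stop("run needs --config",
                                         call. = FALSE))
      0L
    },
    extract = {
      sentences <- read_annotated_sentences(opts$sentences)
      rel <- extract_relations(sentences, mode = opts$mode %||% "annotated")
      write_relation_table(rel, opts$out %||% "relations.tsv")
      message("extracted ", nrow(rel), " relations")
      0L
    },
    assign = {
      rel <- assign_contexts(read_relation_table(opts$relations))
      write_relation_table(rel, opts$out %||% "relations_assigned.tsv")
      0L
    },
    abc = {
      rel <- read_relation_table(opts$relations)
      paths <- build_paths(rel, opts$a, opts$c,
                           model = gsub("-", "_", opts$model %||% "context"),
                           threshold = as.numeric(opts$threshold %||% "1"),
                           vocabs = vocabs_from(opts))
      write_path_table(paths, opts$out %||% "paths.tsv")
      message(nrow(paths), " paths, ",
              length(dedup_b_entities(paths)), " B entities")
      0L
    },
    eval = {
      b <- readLines(opts$b)
      gold <- read_gold_labels(opts$gold, opts$universe)
      res <- evaluate_b_entities(b, gold)
      message(sprintf("precision %.3f recall %.3f f %.3f",
                      res$precision, res$recall, res$f_measure))
      0L
    },
    sweep = {
      rel <- read_relation_table(opts$relations)
      grid <- as.numeric(strsplit(opts$grid %||% "0:1:0.1", ":")[[1]])
      thresholds <- seq(grid[1], grid[2], by = grid[3])
      gold <- if (is.null(opts$gold)) NULL
              else read_gold_labels(opts$gold, opts$universe)
      tab <- threshold_sweep(rel, opts$a, opts$c,
                             model = gsub("-", "_",
                                          opts$model %||% "context"),
                             thresholds = thresholds,
                             vocabs = vocabs_from(opts), gold = gold)
      utils::write.table(tab, opts$out %||% "sweep.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
      0L
    },
    simulate = {
      chains <- utils::read.delim(opts$chains, colClasses = "character")
      chains$matched <- toupper(chains$matched) %in% c("TRUE", "T", "1")
      sim <- simulate_corpus(
        chains,
        n_abstracts = as.integer(opts[["n-abstracts"]] %||% "200"),
        context_rate = as.numeric(opts[["context-rate"]] %||% "0.3"),
        seed = as.integer(opts$seed %||% "1"))
      out_dir <- opts[["out-dir"]] %||% "."
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_annotated_sentences(sim$sentences,
                                file.path(out_dir, "sentences.tsv"))
      write_hierarchy(sim$vocabs$disease,
                      file.path(out_dir, "disease_hierarchy.tsv"))
      write_hierarchy(sim$vocabs$drug,
                      file.path(out_dir, "drug_hierarchy.tsv"))
      writeLines(c(paste(sim$gold$relevant, "O", sep = "\t")),
                 file.path(out_dir, "gold.tsv"))
      writeLines(sim$gold$universe, file.path(out_dir, "universe.txt"))
      message("wrote ", length(sim$sentences), " sentences to ", out_dir)
      0L
    },
    {
      message("unknown subcommand: ", cmd)
      1L
    }
  )
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --flag, got '", args[i], "'", call. = FALSE)
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- "true"
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}
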