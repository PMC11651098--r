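#' Read a simulation/analysis config from YAML or JSON
#'
#' Any subset of the [sim_config()] fields may be given; the rest keep their
#' defaults. Analysis-level keys (`n_perm`, `n_null`, `rarefy_depth`,
#' `abundance_floor`, `beta_threshold`, `alpha`, `K`, `score_mode`, `cycles`)
#' are carried through in attribute `"analysis"`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` with attribute `"analysis"`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sim_keys <- names(formals(sim_config))
  cfg <- do.call(sim_config, raw[intersect(names(raw), sim_keys)])
  attr(cfg, "analysis") <- raw[setdiff(names(raw), sim_keys)]
  cfg
}

#' Write the tables and bulk measurements of an experiment to disk
#'
#' One TSV per cycle (`C0.tsv`, ...), the bulk measurements as
#' `bulk_measurements.tsv`, and a provenance JSON holding the config and seed.
#'
#' @param experiment A `melo_experiment`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_experiment <- function(experiment, outdir) {
  stopifnot(inherits(experiment, "melo_experiment"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(experiment$tables)) {
    p <- file.path(outdir, paste0(id, ".tsv"))
    write_abundance_table(experiment$tables[[id]], p)
    paths[id] <- p
  }
  p <- file.path(outdir, "bulk_measurements.tsv")
  utils::write.table(experiment$bulk, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["bulk"] <- p
  p <- file.path(outdir, "provenance.json")
  jsonlite::write_json(list(config = unclass(experiment$config),
                            coalescence_cycle = experiment$coalescence_cycle),
                       p, auto_unbox = TRUE, pretty = TRUE, null = "null")
  paths["provenance"] <- p
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Chains the stages of the metacommunity analysis on a simulated experiment
#' (or on user-supplied per-cycle tables): rarefaction, alpha/gamma diversity,
#' the Raup-Crick null model with its three-bin classification, community
#' typing, CUE, the multiplayer Elo trajectory with per-genus trends, and the
#' neutral-versus-competitiveness classification of the post-coalescence
#' cycle. All stage outputs are written under `outdir` and listed (with
#' checksums) in a run manifest; two runs with the same config and seed give
#' identical summaries.
#'
#' @param config A [sim_config()] (simulation mode); ignored for the
#'   simulation when `tables` is given.
#' @param outdir Output directory; `NULL` skips writing files.
#' @param tables Data mode: named list of abundance tables or TSV paths
#'   (`C0`, `C1`, ..., last entry = post-coalescence cycle).
#' @param cell_counts Data mode: named per-microcosm cell counts of the final
#'   pre-coalescence cycle (simulation mode takes them from the bulk
#'   measurements).
#' @param cycles Cycles to Elo-rate (default `c(0, 1, 4, 6)` clipped to the
#'   available pre-coalescence cycles).
#' @param n_perm,n_null Permutation/null-replicate counts (defaults 1000).
#' @param rarefy_depth Rarefaction depth (default: minimum column sum across
#'   all cycles).
#' @param abundance_floor Elo inclusion floor (default 0.001).
#' @param beta_threshold Raup-Crick bin threshold (default 0.95).
#' @param alpha Significance level for trends and classification (default
#'   0.05).
#' @param score_mode `"rating"` or `"uniform"` expected-score mode.
#' @param K Elo update budget (default 32).
#' @param seed Seed for every stochastic stage (overrides `config$seed`).
#' @return An object of class `melo_run`: list with `summary` (per-cycle
#'   diversity and beta bins, trends, classification summary, CUE series),
#'   `results` (the full stage objects) and `manifest`.
#' @export
run_full_analysis <- function(config = sim_config(), outdir = NULL,
                              tables = NULL, cell_counts = NULL,
                              cycles = c(0, 1, 4, 6), n_perm = 1000,
                              n_null = 1000, rarefy_depth = NULL,
                              abundance_floor = 0.001, beta_threshold = 0.95,
                              alpha = 0.05, score_mode = c("rating", "uniform"),
                              K = 32, seed = NULL) {
  score_mode <- match.arg(score_mode)
  t0 <- Sys.time()
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(seed)) config$seed <- seed
  experiment <- NULL
  if (is.null(tables)) {
    if (is.null(config$seed)) config$seed <- 1L
    experiment <- stage("simulate", simulate_experiment(config))
    tables <- experiment$tables
    coal_id <- paste0("C", experiment$coalescence_cycle)
    bulk <- experiment$bulk
  } else {
    tables <- lapply(tables, function(x) if (is.character(x)) read_abundance_table(x) else x)
    if (is.null(names(tables))) stop("data mode: `tables` must be named C0, C1, ...", call. = FALSE)
    coal_id <- names(tables)[length(tables)]
    bulk <- NULL
  }
  pre_ids <- setdiff(names(tables), coal_id)
  final_pre <- pre_ids[length(pre_ids)]

  # --- diversity stage: rarefy, alpha/gamma, Raup-Crick bins per cycle
  depth <- rarefy_depth %||% min(vapply(tables, function(t) min(colSums(count_matrix(t))),
                                        numeric(1)))
  seed_base <- (config$seed %||% 1L) %% 100000L
  div <- stage("diversity", {
    purrr::imap(tables, function(tab, id) {
      i <- match(id, names(tables))
      rt <- withCallingHandlers(
        rarefy(tab, depth = depth, seed = seed_base + i),
        warning = function(w) { note("rarefy ", id, ": ", conditionMessage(w))
                                invokeRestart("muffleWarning") })
      ag <- alpha_gamma(rt)
      rc <- raup_crick_matrix(rt, n_null = n_null, seed = seed_base + 1000L + i)
      list(rarefied = rt, alpha = ag, raup_crick = rc,
           bins = classify_beta(rc, threshold = beta_threshold))
    })
  })
  types <- stage("community_types", assign_community_types(div[[final_pre]]$rarefied))

  # --- elo stage
  cycles <- intersect(cycles, as.integer(sub("^C", "", pre_ids)))
  if (length(cycles) < 1L) stop("no rated cycle available", call. = FALSE)
  elo <- stage("elo", rate_experiment(tables, cycles = cycles, n_perm = n_perm,
                                      abundance_floor = abundance_floor,
                                      mode = score_mode, K = K,
                                      seed = seed_base + 2000L))
  trends <- if (length(cycles) >= 3) {
    stage("elo_trend", elo_trend(elo, alpha = alpha))
  } else {
    note("fewer than 3 rated cycles; per-genus trends skipped")
    NULL
  }

  # --- coalescence stage
  if (is.null(cell_counts)) {
    if (!is.null(bulk)) {
      fb <- dplyr::filter(bulk, .data$cycle == as.integer(sub("^C", "", final_pre)))
      cell_counts <- stats::setNames(fb$cells, fb$microcosm)
    } else {
      note("no cell counts supplied; neutral model weighs microcosms equally")
      cell_counts <- stats::setNames(rep(1, ncol(count_matrix(tables[[final_pre]]))),
                                     colnames(count_matrix(tables[[final_pre]])))
    }
  }
  coal <- stage("coalescence", {
    pn <- predict_neutral(tables[[final_pre]], cell_counts)
    pc <- predict_competitive(elo, cell_counts)
    cls <- classify_genera(tables[[coal_id]], pn, pc, alpha = alpha)
    list(neutral = pn, competitive = pc, classified = cls,
         outcomes = summarize_outcomes(cls, tables[[coal_id]]))
  })

  cue <- if (!is.null(bulk)) {
    dplyr::summarise(dplyr::group_by(bulk, .data$cycle),
                     mean_cue = mean(.data$cue, na.rm = TRUE),
                     sd_cue = stats::sd(.data$cue, na.rm = TRUE), .groups = "drop")
  } else NULL

  summary <- list(
    cycles = purrr::imap(div, function(d, id) {
      list(cycle = id, richness_mean = mean(d$alpha$richness),
           richness_sd = stats::sd(d$alpha$richness),
           evenness_mean = mean(d$alpha$evenness, na.rm = TRUE),
           gamma = attr(d$alpha, "gamma"),
           beta_bins = stats::setNames(as.list(d$bins$fraction), as.character(d$bins$bin)))
    }),
    rarefy_depth = depth,
    community_types = attr(types, "types"),
    score_function = list(a = elo$score_function$a, b = elo$score_function$b,
                          r_squared = elo$score_function$r_squared),
    elo_trends = if (!is.null(trends)) table(trends$direction) else NULL,
    coalescence = stats::setNames(as.list(coal$outcomes$n_genera), coal$outcomes$category),
    cue = cue
  )

  manifest <- list(config = unclass(config),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("metaelo")),
                   parameters = list(n_perm = n_perm, n_null = n_null,
                                     rarefy_depth = depth,
                                     abundance_floor = abundance_floor,
                                     beta_threshold = beta_threshold,
                                     alpha = alpha, score_mode = score_mode, K = K),
                   started = format(t0), warnings = warnings_log, files = list())

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(experiment)) write_experiment(experiment, file.path(outdir, "tables"))
    for (id in names(div)) {
      bp <- file.path(outdir, paste0("beta_rc_", id, ".tsv"))
      utils::write.table(div[[id]]$raup_crick$beta_rc, bp, sep = "\t", quote = FALSE,
                         col.names = NA)
    }
    utils::write.table(elo$trajectory, file.path(outdir, "elo_trajectory.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(trends)) {
      utils::write.table(trends, file.path(outdir, "elo_trends.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(coal$classified, file.path(outdir, "coalescence_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
                         force = TRUE)
    files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(outdir, "manifest.json"))
    manifest$files <- purrr::map(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  structure(list(summary = summary, manifest = manifest,
                 results = list(experiment = experiment, diversity = div,
                                community_types = types, elo = elo,
                                trends = trends, coalescence = coal, cue = cue)),
            class = "melo_run")
}

#' @export
print.melo_run <- function(x, ...) {
  cat("<melo_run>", length(x$summary$cycles), "cycles analysed; categories:",
      paste(names(x$summary$coalescence), unlist(x$summary$coalescence),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# command-line entry point (kept in-package so it is testable in-process; the
# inst/exec wrapper just forwards commandArgs)

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", sub("^--", "", a))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic experiment), `diversity`
#' (rarefaction + alpha/gamma + Raup-Crick bins for one table), `elo`
#' (trajectory + trends from per-cycle tables in a directory), `coalescence`
#' (classify a post-coalescence table) and `run-all` (the whole pipeline).
#' Shared flags: `--config`, `--seed`, `--outdir`, `--n-perm`, `--n-null`,
#' `--rarefy-depth`, `--score-mode`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   process arguments).
#' @return Exit status, invisibly: 0 success, 1 user error, 2 internal error.
#' @export
metaelo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: metaelo <simulate|diversity|elo|coalescence|run-all>",
                 "[--config F] [--seed N] [--outdir D] [--table F] [--indir D]",
                 "[--cycles 0,1,4,6] [--n-perm N] [--n-null N] [--rarefy-depth N]",
                 "[--score-mode rating|uniform] [--c6 F] [--c7 F] [--cells F]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  status <- tryCatch({
    fl <- parse_flags(args[-1])
    cfg <- if (!is.null(fl$config)) read_sim_config(fl$config) else sim_config()
    if (!is.null(fl$seed)) cfg$seed <- as.integer(fl$seed)
    outdir <- fl$outdir %||% "."
    num <- function(x, d) if (is.null(x)) d else as.numeric(x)
    switch(cmd,
      simulate = {
        exp <- simulate_experiment(cfg)
        write_experiment(exp, outdir)
        message("wrote ", length(exp$tables), " cycle tables to ", outdir)
        0L
      },
      diversity = {
        if (is.null(fl$table)) stop("diversity needs --table", call. = FALSE)
        tab <- read_abundance_table(fl$table)
        rt <- rarefy(tab, depth = if (is.null(fl$rarefy_depth)) NULL else num(fl$rarefy_depth),
                     seed = cfg$seed)
        ag <- alpha_gamma(rt)
        rc <- raup_crick_matrix(rt, n_null = num(fl$n_null, 1000), seed = cfg$seed)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(ag, file.path(outdir, "alpha_gamma.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(rc$beta_rc, file.path(outdir, "beta_rc.tsv"), sep = "\t",
                           quote = FALSE, col.names = NA)
        jsonlite::write_json(classify_beta(rc), file.path(outdir, "beta_bins.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        0L
      },
      elo = {
        if (is.null(fl$indir)) stop("elo needs --indir with C<i>.tsv tables", call. = FALSE)
        paths <- list.files(fl$indir, pattern = "^C[0-9]+\\.tsv$", full.names = TRUE)
        if (length(paths) == 0) stop("no C<i>.tsv tables in ", fl$indir, call. = FALSE)
        tabs <- stats::setNames(lapply(paths, read_abundance_table),
                                sub("\\.tsv$", "", basename(paths)))
        cyc <- if (is.null(fl$cycles)) c(0, 1, 4, 6) else
          as.integer(strsplit(fl$cycles, ",")[[1]])
        cyc <- intersect(cyc, as.integer(sub("^C", "", names(tabs))))
        tr <- rate_experiment(tabs, cycles = cyc, n_perm = num(fl$n_perm, 1000),
                              mode = fl$score_mode %||% "rating", seed = cfg$seed)
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(tr$trajectory, file.path(outdir, "elo_trajectory.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(elo_trend(tr), file.path(outdir, "elo_trends.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        0L
      },
      coalescence = {
        if (is.null(fl$c6) || is.null(fl$c7)) stop("coalescence needs --c6 and --c7", call. = FALSE)
        c6 <- read_abundance_table(fl$c6)
        c7 <- read_abundance_table(fl$c7)
        cells <- if (!is.null(fl$cells)) {
          cb <- utils::read.delim(fl$cells)
          stats::setNames(cb$cells, cb$microcosm)
        } else {
          stats::setNames(rep(1, ncol(count_matrix(c6))),
                          setdiff(names(c6), "genus"))
        }
        tr <- rate_experiment(list(C6 = c6), cycles = 6, n_perm = num(fl$n_perm, 1000),
                              seed = cfg$seed)
        cls <- classify_genera(c7, predict_neutral(c6, cells),
                               predict_competitive(tr, cells))
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        utils::write.table(cls, file.path(outdir, "coalescence_classification.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summarize_outcomes(cls, c7),
                             file.path(outdir, "coalescence_summary.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
        0L
      },
      `run-all` = {
        an <- attr(cfg, "analysis") %||% list()
        run_full_analysis(cfg, outdir = outdir,
                          n_perm = num(fl$n_perm, an$n_perm %||% 1000),
                          n_null = num(fl$n_null, an$n_null %||% 1000),
                          rarefy_depth = if (is.null(fl$rarefy_depth)) an$rarefy_depth
                                         else num(fl$rarefy_depth),
                          score_mode = fl$score_mode %||% (an$score_mode %||% "rating"))
        message("analysis written to ", outdir)
        0L
      },
      { message(usage); 1L }
    )
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    user <- grepl("needs|not found|usage|invalid|no microcosm|no genera|--", msg)
    if (user) 1L else 2L
  })
  invisible(status)
}
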