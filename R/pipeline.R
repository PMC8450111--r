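#' Read / write a flat key-value configuration file
#'
#' Format: `key = value` lines, with optional `[section]` headers
#' grouping stage settings; `#` starts a comment. Values are returned as
#' strings; numeric conversion happens at the point of use. Keys outside
#' any section land in the `global` section.
#'
#' @param path file path.
#' @return Named list of sections, each a named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "global"
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- character(0)
    } else if (grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      out[[section]] <- c(out[[section]], stats::setNames(val, key))
    } else {
      stop("config ", path, " line ", k, ": expected 'key = value' or '[section]', got: ", ln)
    }
  }
  out
}

#' @rdname read_config
#' @param config named list of sections (named character vectors).
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, paste0("[", sec, "]"),
               paste(names(config[[sec]]), "=", config[[sec]]), "")
  }
  writeLines(lines, path)
  invisible(path)
}

cfg_num <- function(section, key, default = NULL) {
  if (!is.null(section) && key %in% names(section))
    as.numeric(section[[key]]) else default
}
cfg_chr <- function(section, key, default = NULL) {
  if (!is.null(section) && key %in% names(section))
    section[[key]] else default
}

#' Run the simulate / analyse / report pipeline
#'
#' Executes the stages named in the config file, in dependency order:
#' `simulate` (gamma-renewal focus dataset), `coc` (CoC curve TSV),
#' `gamma` (interference fit TSV), `metrics` (per-strain summary TSV),
#' `tetrads` (simulated tetrad table) and `missegregation` (scored
#' frequency TSV). Each stage reads its input from the file produced by
#' an earlier stage (or a `foci` / `tetrads` path given in its section)
#' and writes a TSV next to the manifest. A run manifest recording the
#' config snapshot, seeds, output paths and their MD5 digests is written
#' last; re-running an identical config reproduces identical outputs.
#'
#' @param config_path path to a config file (see [read_config()]).
#' @param outdir output directory (created if absent).
#' @return Named list of output paths (including `manifest`), invisibly.
#' @export
run_pipeline <- function(config_path, outdir = dirname(config_path)) {
  cfg <- read_config(config_path)
  known <- c("global", "simulate", "coc", "gamma", "metrics", "tetrads",
             "missegregation")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown pipeline stage(s) in ", config_path, ": ",
         paste(unknown, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  foci_path <- cfg_chr(cfg$global, "foci")
  if ("simulate" %in% names(cfg)) {
    s <- cfg$simulate
    config <- simulation_config(
      shape = cfg_num(s, "shape", 2),
      mean_spacing = cfg_num(s, "mean_spacing", 1),
      axis_length_mean = cfg_num(s, "axis_length_mean", 3),
      axis_length_cv = cfg_num(s, "axis_length_cv", 0.15),
      n_nuclei = cfg_num(s, "n_nuclei", 200),
      chromosomes_per_nucleus = cfg_num(s, "chromosomes_per_nucleus", 1),
      seed = cfg_num(s, "seed", 1),
      strain = cfg_chr(s, "strain", "sim"))
    sim <- simulate_focus_dataset(config)
    foci_path <- file.path(outdir, "foci.tsv")
    write_focus_table(sim, foci_path)
    outputs["foci"] <- foci_path
    note("simulate: %d chromosomes, seed %d -> %s", nrow(sim),
         config$seed, foci_path)
  }

  need_foci <- intersect(c("coc", "gamma", "metrics"), names(cfg))
  chroms <- NULL
  if (length(need_foci)) {
    if (is.null(foci_path))
      stop("stages ", paste(need_foci, collapse = "/"),
           " need a focus table: add a [simulate] stage or 'foci =' in [global]")
    if (!file.exists(foci_path)) stop("missing input: ", foci_path)
    bad <- validate_focus_table(foci_path)
    if (nrow(bad))
      stop("focus table ", foci_path, " failed validation: row ",
           bad$row[1], ": ", bad$problem[1])
    chroms <- read_focus_table(foci_path)
  }

  if ("coc" %in% names(cfg)) {
    cur <- coc_curve(chroms,
                     n_intervals = cfg_num(cfg$coc, "intervals", 30),
                     by_experiment = !identical(cfg_chr(cfg$coc, "by_experiment"), "false"))
    p <- file.path(outdir, "coc_curve.tsv")
    write_coc_curve(cur, p)
    outputs["coc"] <- p
    note("coc: %d distances, %d undefined pairs excluded -> %s",
         nrow(cur), attr(cur, "n_undefined_pairs"), p)
  }
  if ("gamma" %in% names(cfg)) {
    g <- cfg$gamma
    fit <- fit_interference(
      chroms,
      normalized = !identical(cfg_chr(g, "units"), "micron"),
      bootstrap = cfg_num(g, "bootstrap", 1000),
      seed = cfg_num(g, "seed", 1))
    p <- file.path(outdir, "gamma_fit.tsv")
    write_gamma_fit(fit, p)
    outputs["gamma"] <- p
    note("gamma: shape %.3f on %d distances -> %s", fit$shape, fit$n, p)
  }
  if ("metrics" %in% names(cfg)) {
    p <- file.path(outdir, "strain_summary.tsv")
    utils::write.table(strain_summary(chroms), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs["metrics"] <- p
    note("metrics -> %s", p)
  }

  tetrad_path <- cfg_chr(cfg$global, "tetrads")
  if ("tetrads" %in% names(cfg)) {
    t <- cfg$tetrads
    tet <- simulate_tetrads(cfg_num(t, "n", 1000),
                            cfg_num(t, "missegregation_rate", 0),
                            cfg_num(t, "blank_rate", 0),
                            cfg_num(t, "seed", 1))
    tetrad_path <- file.path(outdir, "tetrads.tsv")
    write_tetrad_table(tet, tetrad_path)
    outputs["tetrads"] <- tetrad_path
    note("tetrads: %d simulated -> %s", nrow(tet), tetrad_path)
  }
  if ("missegregation" %in% names(cfg)) {
    if (is.null(tetrad_path)) stop("missegregation stage needs a tetrad table")
    if (!file.exists(tetrad_path)) stop("missing input: ", tetrad_path)
    res <- missegregation_frequency(read_tetrad_table(tetrad_path))
    p <- file.path(outdir, "missegregation.tsv")
    utils::write.table(
      data.frame(frequency = res$frequency,
                 n_missegregated = res$n_missegregated,
                 n_scored = res$n_scored, n_excluded = res$n_excluded),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs["missegregation"] <- p
    note("missegregation: %.4f over %d scored (%d excluded) -> %s",
         res$frequency, res$n_scored, res$n_excluded, p)
  }

  manifest <- file.path(outdir, "manifest.txt")
  digests <- tools::md5sum(unname(outputs))
  writeLines(c(
    paste0("meicoc_version = ", as.character(utils::packageVersion("meicoc"))),
    paste0("config = ", normalizePath(config_path)),
    paste0("config_md5 = ", unname(tools::md5sum(config_path))),
    "", "[outputs]",
    paste0(names(outputs), " = ", unname(outputs)),
    "", "[md5]",
    paste0(basename(names(digests)), " = ", unname(digests)),
    "", "[log]", log
  ), manifest)
  outputs["manifest"] <- manifest
  invisible(as.list(outputs))
}
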