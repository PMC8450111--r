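#' Construct a single focus-bearing chromosome record
#'
#' The atom of all interference analyses: one chromosome's axis length
#' (in micrometres, e.g. traced along Rec8 or Zip1 lines) and the ordered
#' positions of its crossover-marker foci measured from a marked end.
#'
#' @param strain strain label.
#' @param nucleus_id nucleus identifier (unique within strain).
#' @param chromosome_id chromosome identifier (unique within nucleus).
#' @param axis_length positive axis length in micrometres.
#' @param foci numeric vector of focus positions in micrometres from the
#'   marked end; may be empty (a chromosome lacking foci). Positions are
#'   sorted ascending and must lie in `[0, axis_length]`.
#' @return A one-row `focus_data` data frame.
#' @seealso [focus_data()], [simulate_focus_dataset()]
#' @export
focus_chromosome <- function(strain, nucleus_id, chromosome_id,
                             axis_length, foci = numeric(0)) {
  focus_data(data.frame(
    strain = as.character(strain),
    nucleus_id = as.character(nucleus_id),
    chromosome_id = as.character(chromosome_id),
    axis_length_um = as.numeric(axis_length),
    stringsAsFactors = FALSE
  ), foci = list(as.numeric(foci)))
}

#' Assemble a focus dataset from per-chromosome records
#'
#' A `focus_data` object is a data frame with one row per chromosome:
#' columns `strain`, `nucleus_id`, `chromosome_id`, `axis_length_um`, an
#' optional `experiment` label, and a list column `foci` holding each
#' chromosome's sorted focus positions (micrometres). Zero-focus
#' chromosomes carry an empty vector, not a dropped row: the obligatory-
#' crossover analyses depend on them being present.
#'
#' @param df data frame with the scalar columns above.
#' @param foci list of numeric vectors, one per row of `df`.
#' @return A `focus_data` object.
#' @export
focus_data <- function(df, foci) {
  stopifnot(is.data.frame(df), is.list(foci), length(foci) == nrow(df))
  need <- c("strain", "nucleus_id", "chromosome_id", "axis_length_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("focus_data: missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$axis_length_um)) || any(df$axis_length_um <= 0))
    stop("focus_data: axis_length_um must be positive and finite")
  foci <- lapply(foci, function(p) sort(as.numeric(p)))
  for (i in seq_along(foci)) {
    p <- foci[[i]]
    if (length(p) && (any(p < 0) || any(p > df$axis_length_um[i])))
      stop(sprintf(
        "focus_data: focus position outside [0, axis length] for row %d (%s/%s/%s)",
        i, df$strain[i], df$nucleus_id[i], df$chromosome_id[i]))
  }
  df$foci <- foci
  class(df) <- c("focus_data", "data.frame")
  df
}

#' @export
print.focus_data <- function(x, ...) {
  nfoci <- lengths(x$foci)
  cat(sprintf(
    "Focus dataset: %d chromosomes, %d nuclei, %d strain(s)\n",
    nrow(x), length(unique(paste(x$strain, x$nucleus_id))),
    length(unique(x$strain))))
  cat(sprintf("  foci per chromosome: mean %.2f (range %d-%d); %d with none\n",
              mean(nfoci), min(nfoci), max(nfoci), sum(nfoci == 0)))
  cat(sprintf("  axis length (um): mean %.2f, sd %.2f\n",
              mean(x$axis_length_um), stats::sd(x$axis_length_um)))
  invisible(x)
}

n_foci <- function(chroms) lengths(chroms$foci)

#' Read a focus table
#'
#' Tab-separated, header
#' `strain nucleus_id chromosome_id axis_length_um focus_pos_um`
#' (an optional `experiment` column is carried through), one row per focus;
#' a chromosome without foci appears once with an empty `focus_pos_um`
#' field.
#'
#' @param path file path.
#' @return A `focus_data` object.
#' @export
read_focus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("strain", "nucleus_id", "chromosome_id", "axis_length_um",
            "focus_pos_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("focus table ", path, ": missing column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(tab)) stop("focus table ", path, ": no records")
  key <- paste(tab$strain, tab$nucleus_id, tab$chromosome_id, sep = "\r")
  idx <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  df <- data.frame(
    strain = tab$strain[first],
    nucleus_id = tab$nucleus_id[first],
    chromosome_id = tab$chromosome_id[first],
    axis_length_um = as.numeric(tab$axis_length_um[first]),
    stringsAsFactors = FALSE
  )
  if ("experiment" %in% names(tab)) df$experiment <- tab$experiment[first]
  foci <- lapply(idx, function(i) {
    p <- suppressWarnings(as.numeric(tab$focus_pos_um[i]))
    p[!is.na(p)]
  })
  focus_data(df, foci)
}

#' Write a focus table
#'
#' @param chroms a `focus_data` object.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_focus_table <- function(chroms, path) {
  k <- lengths(chroms$foci)
  rep_idx <- rep(seq_len(nrow(chroms)), pmax(k, 1L))
  pos <- unlist(lapply(chroms$foci, function(p) if (length(p)) p else NA_real_))
  out <- data.frame(
    strain = chroms$strain[rep_idx],
    nucleus_id = chroms$nucleus_id[rep_idx],
    chromosome_id = chroms$chromosome_id[rep_idx],
    axis_length_um = chroms$axis_length_um[rep_idx],
    focus_pos_um = pos,
    stringsAsFactors = FALSE
  )
  if ("experiment" %in% names(chroms)) out$experiment <- chroms$experiment[rep_idx]
  out$focus_pos_um <- ifelse(is.na(out$focus_pos_um), "",
                             format(out$focus_pos_um, trim = TRUE, digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a focus table file
#'
#' Schema, numeric parsing, position bounds and duplicate checks with
#' row-level diagnostics.
#'
#' @param path file path.
#' @return Data frame with columns `row`, `problem`; zero rows when clean.
#' @export
validate_focus_table <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("unreadable focus table ", path, ": ",
                             conditionMessage(e)))
  report <- data.frame(row = integer(0), problem = character(0),
                       stringsAsFactors = FALSE)
  flag <- function(row, problem)
    rbind(report, data.frame(row = row, problem = problem,
                             stringsAsFactors = FALSE))
  need <- c("strain", "nucleus_id", "chromosome_id", "axis_length_um",
            "focus_pos_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    return(flag(0L, paste("missing column(s):", paste(miss, collapse = ", "))))
  if (!nrow(tab)) return(flag(0L, "no records"))
  axis <- suppressWarnings(as.numeric(tab$axis_length_um))
  pos <- suppressWarnings(as.numeric(tab$focus_pos_um))
  empty <- !nzchar(trimws(tab$focus_pos_um))
  for (i in seq_len(nrow(tab))) {
    if (is.na(axis[i]) || axis[i] <= 0)
      report <- flag(i, "axis_length_um not a positive number")
    else if (!empty[i] && is.na(pos[i]))
      report <- flag(i, "focus_pos_um not numeric")
    else if (!empty[i] && (pos[i] < 0 || pos[i] > axis[i]))
      report <- flag(i, "focus position outside [0, axis length]")
  }
  key <- paste(tab$strain, tab$nucleus_id, tab$chromosome_id, tab$focus_pos_um)
  dup <- which(duplicated(key) & !empty)
  for (i in dup) report <- flag(i, "duplicate focus record")
  chrom_key <- paste(tab$strain, tab$nucleus_id, tab$chromosome_id)
  bad_empty <- which(empty & chrom_key %in% chrom_key[!empty])
  for (i in bad_empty)
    report <- flag(i, "empty-focus row for a chromosome that also has foci")
  report
}
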