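# Readers and writers for the plain-text formats the pipeline speaks:
# FASTA (via Biostrings), two-column peak-list TSV, a minimal MGF
# dialect, the violations report, and the YAML run configuration.
# Every writer's output round-trips through the matching reader.

#' Read sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' Single-line headers, sequence wrapped at 60 columns.
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a two-column peak list TSV
#'
#' Columns `mz` and `intensity`; '#' comments allowed.
#'
#' @param path TSV path.
#' @return Data frame with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak list must have 'mz' and 'intensity' columns: ", path)
  }
  df[, c("mz", "intensity")]
}

#' Write a two-column peak list TSV
#'
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(peaks[, c("mz", "intensity")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a minimal MGF peak list
#'
#' Understands the BEGIN IONS / TITLE / PEPMASS / END IONS dialect with
#' one space- or tab-separated (m/z, intensity) pair per peak line; one
#' spectrum per file.
#'
#' @param path MGF path.
#' @return List with `title`, `pepmass` and `peaks` (data frame).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != 1L || length(end) != 1L || end < begin) {
    stop("malformed MGF (need one BEGIN IONS / END IONS block): ", path)
  }
  body <- lines[(begin + 1L):(end - 1L)]
  title <- sub("^TITLE=", "", grep("^TITLE=", body, value = TRUE))
  pep <- sub("^PEPMASS=", "", grep("^PEPMASS=", body, value = TRUE))
  peak_lines <- body[!grepl("=", body) & nzchar(body)]
  parts <- strsplit(peak_lines, "[ \t]+")
  peaks <- data.frame(
    mz = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    intensity = vapply(parts, function(p) as.numeric(p[2]), numeric(1)))
  list(title = if (length(title)) title else NA_character_,
       pepmass = if (length(pep)) as.numeric(strsplit(pep, " ")[[1]][1])
                 else NA_real_,
       peaks = peaks)
}

#' Write a minimal MGF peak list
#'
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param path Output path.
#' @param title Spectrum title.
#' @param pepmass Precursor m/z.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(peaks, path, title = "spectrum", pepmass = NA) {
  lines <- c("BEGIN IONS",
             paste0("TITLE=", title),
             if (!is.na(pepmass)) paste0("PEPMASS=", format(pepmass,
                                                            digits = 10)),
             paste(format(peaks$mz, digits = 10, trim = TRUE),
                   format(peaks$intensity, digits = 10, trim = TRUE)),
             "END IONS")
  writeLines(lines, path)
  invisible(path)
}

#' Write a codon-violation report TSV
#'
#' @param violations Result of [validate_syn61()].
#' @param seq_id Sequence identifier written in the first column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_violations <- function(violations, seq_id, path) {
  df <- cbind(seq_id = rep(seq_id, nrow(violations)), violations)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.RUN_CONFIG_KEYS <- c("registry", "templates", "schemes", "active_min",
                      "inactive_max", "tolerance", "mass_mode", "seed",
                      "output_dir")

#' Load a YAML run configuration
#'
#' Known keys: `registry`, `templates`, `schemes` (paths; must exist when
#' given), `active_min`, `inactive_max`, `tolerance`, `mass_mode`,
#' `seed`, `output_dir`. Unknown keys are rejected rather than ignored.
#'
#' @param path YAML path.
#' @return Named list of configuration values with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("registry", "templates", "schemes")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config file for ", sQuote(key), " does not exist: ", cfg[[key]])
    }
  }
  defaults <- list(active_min = 10000, inactive_max = 2500,
                   tolerance = 0.1, mass_mode = "monoisotopic", seed = 1L)
  for (key in names(defaults)) {
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  }
  cfg$mass_mode <- match.arg(cfg$mass_mode, .MASS_MODES)
  cfg
}

#' Read macrocycle templates from YAML
#'
#' Expected layout: a top-level `templates` map of name to slot list,
#' e.g. `templates: {demo: [L, A, V, B, C]}`.
#'
#' @param path YAML path.
#' @return Named list of [macrocycle_template()]s.
#' @export
read_templates <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$templates)) stop("no 'templates' key in ", path)
  out <- lapply(names(y$templates), function(nm) {
    macrocycle_template(nm, as.character(y$templates[[nm]]))
  })
  stats::setNames(out, names(y$templates))
}

#' Write an orthogonal-pair table to TSV
#'
#' @param pairs Result of [find_pairs()] or [unique_pairings()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
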