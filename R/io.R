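## Readers and writers: energy-matrix TSV, MEME minimal motif format,
## probability-matrix TSV, results tables.

#' Write / read an energy matrix as TSV
#'
#' Layout: an optional comment line `#offset <E0>`, a header `pos 1 ... m`,
#' then four rows labeled A, C, G, T with energies in kT. Numbers are
#' serialized at full double precision so write-then-read is an identity.
#' On read, rows may appear in any label order; a violated zero gauge is
#' repaired (residue moved into the offset) with a warning.
#'
#' @param model an [energy_matrix()].
#' @param path file path.
#' @return `write_energy_matrix` returns `path` invisibly;
#'   `read_energy_matrix` returns an [energy_matrix()].
#' @export
write_energy_matrix <- function(model, path) {
  stopifnot(inherits(model, "energy_matrix"))
  m <- ncol(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#offset\t%.17g", attr(model, "offset")), con)
  writeLines(paste(c("pos", seq_len(m)), collapse = "\t"), con)
  for (b in BASES)
    writeLines(paste(c(b, sprintf("%.17g", unclass(model)[b, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  lines <- readLines(path)
  offset <- 0
  is_off <- grepl("^#offset\\b", lines)
  if (any(is_off)) {
    off_parts <- strsplit(lines[which(is_off)[1L]], "\t| +")[[1L]]
    offset <- as.numeric(off_parts[2L])
    if (is.na(offset)) stop("malformed #offset line in ", path)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 5L)
    stop("expected a header plus 4 base rows in ", path,
         "; found ", length(lines), " non-comment lines")
  parts <- strsplit(lines, "\t")
  if (tolower(parts[[1L]][1L]) != "pos")
    stop("line 1: expected header starting with 'pos' in ", path)
  m <- length(parts[[1L]]) - 1L
  eps <- matrix(NA_real_, 4L, m, dimnames = list(BASES, NULL))
  for (i in 2:5) {
    lab <- toupper(parts[[i]][1L])
    if (!lab %in% BASES)
      stop(sprintf("line %d: unknown base label '%s' in %s", i, lab, path))
    vals <- suppressWarnings(as.numeric(parts[[i]][-1L]))
    if (length(vals) != m || any(is.na(vals)))
      stop(sprintf("line %d (base %s): expected %d numeric entries in %s",
                   i, lab, m, path))
    eps[lab, ] <- vals
  }
  if (any(is.na(eps))) stop("missing base rows in ", path)
  energy_matrix(eps, offset = offset, regauge = TRUE)
}

#' Write / read a probability matrix
#'
#' Two formats. `format = "meme"` (default) is the MEME minimal motif format:
#' version header, `ALPHABET= ACGT`, background frequencies, then a
#' `letter-probability matrix: alength= 4 w= m` block with one row per
#' position in A, C, G, T column order. `format = "tsv"` mirrors the
#' energy-matrix layout (header `pos 1..m`, four labeled base rows).
#'
#' On read, columns whose sums deviate from 1 by at most `1e-6` are silently
#' renormalized; larger deviations are an error.
#'
#' @param pm a [prob_matrix()].
#' @param path file path.
#' @param format `"meme"` or `"tsv"`.
#' @param name motif name written into the MEME file.
#' @return `write_pm` returns `path` invisibly; `read_pm` a [prob_matrix()].
#' @export
write_pm <- function(pm, path, format = c("meme", "tsv"), name = "motif1") {
  stopifnot(inherits(pm, "prob_matrix"))
  format <- match.arg(format)
  m <- ncol(pm)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "meme") {
    bg <- attr(pm, "background")
    writeLines(c(
      "MEME version 4", "",
      "ALPHABET= ACGT", "",
      "Background letter frequencies",
      paste(sprintf("%s %.6f", BASES, bg), collapse = " "), "",
      sprintf("MOTIF %s", name),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= 1 E= 0", m)
    ), con)
    for (j in seq_len(m))
      writeLines(paste(sprintf("%.17g", unclass(pm)[, j]), collapse = " "),
                 con)
  } else {
    writeLines(paste(c("pos", seq_len(m)), collapse = "\t"), con)
    for (b in BASES)
      writeLines(paste(c(b, sprintf("%.17g", unclass(pm)[b, ])),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pm
#' @export
read_pm <- function(path, format = c("meme", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "meme") {
    hdr <- grep("^letter-probability matrix:", lines)
    if (length(hdr) == 0)
      stop("no 'letter-probability matrix' block in ", path)
    hdr <- hdr[1L]
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr])))
    if (is.na(w)) stop("could not parse motif width from ", path)
    rows <- lines[(hdr + 1L):(hdr + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    if (any(vapply(vals, length, 1L) != 4L) || any(is.na(unlist(vals))))
      stop("malformed probability rows in ", path)
    pm <- matrix(unlist(vals), nrow = 4L, dimnames = list(BASES, NULL))
    bg <- rep(0.25, 4)
    bgl <- grep("^Background letter frequencies", lines)
    if (length(bgl) > 0 && bgl[1L] + 1L <= length(lines)) {
      toks <- strsplit(trimws(lines[bgl[1L] + 1L]), "\\s+")[[1L]]
      if (length(toks) == 8L) {
        b <- as.numeric(toks[c(2, 4, 6, 8)])
        if (!any(is.na(b))) bg <- b / sum(b)
      }
    }
  } else {
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    m <- length(parts[[1L]]) - 1L
    pm <- matrix(NA_real_, 4L, m, dimnames = list(BASES, NULL))
    for (i in 2:5) {
      lab <- toupper(parts[[i]][1L])
      if (!lab %in% BASES)
        stop(sprintf("line %d: unknown base label '%s' in %s", i, lab, path))
      pm[lab, ] <- as.numeric(parts[[i]][-1L])
    }
    bg <- rep(0.25, 4)
  }
  cs <- colSums(pm)
  dev <- abs(cs - 1)
  if (any(dev > 1e-6))
    stop(sprintf(
      "column %d of %s sums to %.8f; beyond the 1e-6 renormalization tolerance",
      which.max(dev), path, cs[which.max(dev)]))
  pm <- sweep(pm, 2L, cs, "/")
  prob_matrix(pm, background = bg)
}

#' Display a probability matrix as rounded percentages
#'
#' Returns `round(100 * PM)` for compact display of base frequencies
#' (display only; stored matrices are never rounded).
#'
#' @param pm a [prob_matrix()].
#' @return 4 x m integer matrix of percentages.
#' @export
pm_percent <- function(pm) {
  stopifnot(inherits(pm, "prob_matrix"))
  round(100 * unclass(pm))
}

#' Write per-replicate results and summary tables as TSV
#'
#' @param x an `experiment_summary` (from [run_experiment()] or
#'   [run_noise_experiment()]).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written: `<prefix>results.tsv` (per
#'   replicate), `<prefix>summary.tsv`, and one `mean (sd)` table per
#'   evaluation subset rounded to 3 decimals.
#' @export
write_results <- function(x, dir, prefix = "") {
  stopifnot(inherits(x, "experiment_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, paste0(prefix, "results.tsv"))
  utils::write.table(x$results, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "summary.tsv"))
  utils::write.table(x$summary, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  for (ss in unique(x$summary$subset)) {
    tab <- correlation_table(x, subset = ss)
    p <- file.path(dir, sprintf("%stable_%s.tsv", prefix, ss))
    utils::write.table(cbind(pm_method = rownames(tab), tab), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a run-metadata file sufficient to reproduce a run
#'
#' @param config an `experiment_config` or `noise_config`.
#' @param path output file.
#' @param files character vector of output files produced by the run.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, files = character(0)) {
  lines <- c(
    sprintf("tool\tbindsim %s",
            as.character(utils::packageVersion("bindsim"))),
    sprintf("timestamp\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(config), function(k)
      sprintf("config.%s\t%s", k, paste(config[[k]], collapse = ",")),
      character(1)),
    sprintf("replicate_seeds\t%s",
            paste(config$base_seed + seq_len(config$replicates),
                  collapse = ",")),
    if (length(files)) sprintf("output\t%s", files)
  )
  writeLines(lines, path)
  invisible(path)
}
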