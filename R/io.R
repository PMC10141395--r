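#' Write a recording to a plain-text file
#'
#' File format: UTF-8 text with header comment lines `# key: value`
#' (`sampling_interval_s` always present, other metadata and passthrough
#' keys in sorted order) followed by one current sample per line in
#' scientific notation with 17 significant digits, which round-trips IEEE
#' doubles exactly through their decimal representation.
#'
#' @param r a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(r, path) {
  stopifnot(inherits(r, "recording"))
  if (length(r$current) < 2L) {
    stop("recording must contain at least 2 samples", call. = FALSE)
  }
  fmt_val <- function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }
  meta <- list(sampling_interval_s = r$dt)
  if (!is.na(r$voltage_mV)) meta$voltage_mV <- r$voltage_mV
  if (!all(is.na(r$replicate))) meta$replicate <- r$replicate
  if (!is.na(r$condition)) meta$condition <- r$condition
  if (!is.na(r$incubation_min)) meta$incubation_min <- r$incubation_min
  for (k in names(r$extra)) meta[[k]] <- r$extra[[k]]
  meta <- meta[order(names(meta))]
  header <- vapply(names(meta),
                   function(k) paste0("# ", k, ": ", fmt_val(meta[[k]])),
                   character(1))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17e", r$current), con)
  invisible(path)
}

#' Read a recording from a plain-text file
#'
#' Accepts the header + one-sample-per-line format written by
#' [write_recording()], or a two-column time/current TSV (sampling interval
#' inferred from the time column when no `sampling_interval_s` header is
#' present). Unknown header keys are preserved in the recording's `extra`
#' metadata. Malformed sample lines are reported with their line number.
#'
#' @param path input file path.
#' @return a [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  is_header <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  meta <- list()
  for (hl in lines[is_header]) {
    m <- regmatches(hl, regexec("^\\s*#\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", hl))[[1]]
    if (length(m) == 3L) {
      val <- m[3L]
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2L]]] <- if (!is.na(num)) num else val
    }
  }
  data_idx <- which(!is_header & !is_blank)
  if (!length(data_idx)) stop("no data lines in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[data_idx]), "[\t,[:space:]]+")
  n_fields <- lengths(fields)
  two_col <- all(n_fields == 2L)
  if (!two_col && !all(n_fields == 1L)) {
    bad <- data_idx[which(n_fields != n_fields[1L])[1L]]
    stop("inconsistent number of columns at line ", bad, " of ", path,
         call. = FALSE)
  }
  parse_col <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", j)))
    if (anyNA(v)) {
      bad <- data_idx[which(is.na(v))[1L]]
      stop("non-numeric sample at line ", bad, " of ", path, call. = FALSE)
    }
    v
  }
  if (two_col) {
    time <- parse_col(1L)
    current <- parse_col(2L)
    dt <- meta[["sampling_interval_s"]]
    if (is.null(dt)) {
      if (length(time) < 2L) stop("cannot infer sampling interval from a ",
                                  "single sample", call. = FALSE)
      dt <- stats::median(diff(time))
    }
  } else {
    current <- parse_col(1L)
    dt <- meta[["sampling_interval_s"]]
    if (is.null(dt)) {
      stop("missing required header `# sampling_interval_s: ...` in ", path,
           call. = FALSE)
    }
  }
  known <- c("sampling_interval_s", "voltage_mV", "replicate", "condition",
             "incubation_min")
  extra <- meta[setdiff(names(meta), known)]
  recording(
    current, dt = dt,
    voltage_mV = if (is.null(meta$voltage_mV)) NA_real_ else meta$voltage_mV,
    replicate = if (is.null(meta$replicate)) NA else meta$replicate,
    condition = if (is.null(meta$condition)) NA_character_ else meta$condition,
    incubation_min = if (is.null(meta$incubation_min)) NA_real_ else
      meta$incubation_min,
    extra = extra
  )
}

#' Write a protocol study as a bundle of text artifacts
#'
#' Writes, under `dir`: per-condition H(q) curves (`hurst_curves.tsv`:
#' condition, q, mean H, sd H), singularity spectra (`spectrum_curves.tsv`:
#' condition, replicate-mean alpha and f), the two summary tables
#' (`width_table.tsv`, `endpoint_table.tsv`) and a JSON manifest
#' (`manifest.json`) recording every parameter and seed needed to reproduce
#' the run.
#'
#' @param study a `"protocol_study"`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(study, dir) {
  stopifnot(inherits(study, "protocol_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, name) {
    utils::write.table(d, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  hurst_curves <- do.call(rbind, lapply(study$sets, function(s) {
    data.frame(condition = s$condition, q = s$q,
               mean_H = unname(s$mean_H), sd_H = unname(s$sd_H))
  }))
  spectrum_curves <- do.call(rbind, lapply(study$sets, function(s) {
    alpha <- rowMeans(vapply(s$spectra, function(sp) sp$alpha,
                             numeric(length(s$q))))
    f_alpha <- rowMeans(vapply(s$spectra, function(sp) sp$f_alpha,
                               numeric(length(s$q))))
    data.frame(condition = s$condition, q = s$q,
               alpha = alpha, f_alpha = f_alpha)
  }))
  tsv(hurst_curves, "hurst_curves.tsv")
  tsv(spectrum_curves, "spectrum_curves.tsv")
  tsv(study$tables$width, "width_table.tsv")
  tsv(study$tables$endpoint, "endpoint_table.tsv")
  manifest <- list(
    package = "mfpatch",
    package_version = as.character(utils::packageVersion("mfpatch")),
    schema_version = 1L,
    arm = study$config$arm,
    conditions = study$config$conditions,
    n_replicates = study$config$n_replicates,
    master_seed = study$config$master_seed,
    replicate_seeds = study$config$seeds,
    memory_a = study$config$memory_a,
    dt = study$config$dt,
    mfdfa_args = study$config$mfdfa_args
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}
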