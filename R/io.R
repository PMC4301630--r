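# File-based interfaces: trace TSV reader/writer, per-stage artifact
# writers, and the end-to-end file-driven pipeline with a run manifest.

trace_header <- c("molecule_id", "frame", "time_s", "donor", "acceptor")

#' Write a dataset's intensity traces to TSV files
#'
#' One tab-separated file per pH condition (`traces_pH<value>.tsv`) with
#' columns `molecule_id`, `frame`, `time_s`, `donor`, `acceptor` and a
#' mandatory header line.  Ground truth, when present, goes to a sidecar
#' `<basename>.truth.tsv` with the per-frame true state and per-molecule
#' flags (donor-only, bleach times).
#'
#' @param dataset a `fret_dataset` (or list of `intensity_trace`).
#' @param dir output directory (created if needed).
#' @param truth write truth sidecars when available.
#' @return Character vector of trace file paths, invisibly.
#' @export
write_traces <- function(dataset, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- split_by_ph(dataset)
  paths <- character(0)
  for (g in names(groups)) {
    traces <- groups[[g]]
    base <- file.path(dir, sprintf("traces_pH%s", g))
    tab <- do.call(rbind, lapply(traces, function(tr) {
      n <- length(tr$donor)
      data.frame(molecule_id = tr$molecule_id, frame = seq_len(n),
                 time_s = sprintf("%.4f", (seq_len(n) - 1L) * tr$dt),
                 donor = sprintf("%.4f", tr$donor),
                 acceptor = sprintf("%.4f", tr$acceptor))
    }))
    path <- paste0(base, ".tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
    if (truth && !is.null(traces[[1L]]$truth)) {
      ttab <- do.call(rbind, lapply(traces, function(tr) {
        n <- length(tr$donor)
        data.frame(molecule_id = tr$molecule_id, frame = seq_len(n),
                   state = tr$truth$states,
                   donor_only = as.integer(tr$truth$donor_only),
                   acceptor_bleach_s = sprintf("%.4f", tr$truth$acceptor_bleach_time),
                   donor_bleach_s = sprintf("%.4f", tr$truth$donor_bleach_time))
      }))
      write.table(ttab, paste0(base, ".truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(paths)
}

#' Read intensity traces from TSV files
#'
#' Accepts a single trace file or a directory of `traces_pH*.tsv` files.
#' The header line is mandatory; malformed rows and non-monotonic frame
#' indices are reported with line numbers.  pH is parsed from the file
#' name when it follows the `traces_pH<value>.tsv` convention.
#'
#' @param path a trace TSV file or a directory containing them.
#' @return A `fret_dataset` with `config = NULL` (the file contract does
#'   not carry the generator configuration).
#' @export
read_traces <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "^traces_pH.*\\.tsv$", full.names = TRUE))
  } else path
  files <- files[!grepl("\\.truth\\.tsv$", files)]
  if (length(files) == 0L) stop("no trace files found at ", path)
  traces <- list()
  for (f in files) {
    lines <- readLines(f)
    if (length(lines) == 0L || !identical(strsplit(lines[1L], "\t")[[1L]], trace_header))
      stop("format error in ", f, ": missing or malformed header line ",
           "(expected: ", paste(trace_header, collapse = "\\t"), ")")
    nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
    bad <- which(nf != length(trace_header))
    if (length(bad) > 0L)
      stop("format error in ", f, ": malformed row at line ", bad[1L],
           " (last good line: ", bad[1L] - 1L, ")")
    tab <- read.table(f, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer", "numeric",
                                     "numeric", "numeric"))
    if (anyNA(tab$donor) || anyNA(tab$acceptor) || anyNA(tab$frame))
      stop("format error in ", f, ": non-numeric values at line ",
           min(which(!complete.cases(tab))) + 1L)
    pH <- NA_real_
    m <- regmatches(basename(f), regexec("traces_pH([0-9.]+)\\.tsv$", basename(f)))[[1L]]
    if (length(m) == 2L) pH <- as.numeric(m[2L])
    for (id in unique(tab$molecule_id)) {
      sub <- tab[tab$molecule_id == id, ]
      if (is.unsorted(sub$frame, strictly = TRUE))
        stop("format error in ", f, ": non-monotonic frame index for molecule ", id)
      dt <- if (nrow(sub) > 1L) stats::median(diff(sub$time_s)) else NA_real_
      traces[[length(traces) + 1L]] <-
        structure(list(molecule_id = id, donor = sub$donor,
                       acceptor = sub$acceptor, dt = dt, pH = pH,
                       truth = NULL),
                  class = "intensity_trace")
    }
  }
  structure(list(traces = traces, config = NULL), class = "fret_dataset")
}

#' Run the full file-based analysis pipeline
#'
#' Executes simulate -> histogram -> idealize -> rates -> trend, writing
#' every intermediate as a plain-text artifact so each stage is
#' independently inspectable and re-runnable, plus a JSON run manifest
#' with the configuration snapshot, seed, package version and MD5 digests
#' of every artifact.  Each stage reads only files written by earlier
#' stages.
#'
#' @param config a [simulation_config()] (or path to a YAML config file).
#' @param out_dir output directory.
#' @param seed root seed; overrides the config's seed when given.
#' @param rates run the HMM/kinetics branch (slower).
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, rates = TRUE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # stage 1: simulate and persist traces
  trace_dir <- file.path(out_dir, "traces")
  stage("simulate", {
    ds <- simulate_dataset(config)
    write_traces(ds, trace_dir)
  })

  # stage 2..5 operate on the files only; the analysis-stage RNG
  # (HMM restarts, bootstrap SEs) is derived from the manifest seed so
  # re-running a manifest reproduces every artifact
  result <- stage("analysis", {
    ds <- read_traces(trace_dir)
    ds$config <- config
    set.seed(molecule_seed(config$seed, 1000003L))
    fret_kinetics(ds, rates = rates)
  })

  stage("write-artifacts", {
    write.table(result$table, file.path(out_dir, "summary.csv"),
                sep = ",", quote = FALSE, row.names = FALSE)
    for (g in names(result$histogram_fits)) {
      fit <- result$histogram_fits[[g]]
      h <- fit$hist
      write.table(data.frame(bin_center = bin_centers(h), count = h$counts),
                  file.path(out_dir, sprintf("histogram_pH%s.tsv", g)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(peaks = fit$peaks, residual = fit$residual),
        file.path(out_dir, sprintf("histogram_fit_pH%s.json", g)),
        auto_unbox = TRUE, digits = NA)
    }
    trends <- list(
      n_average = list(slope = result$trend_n_average$slope,
                       stderr = result$trend_n_average$stderr_slope,
                       r_squared = result$trend_n_average$r_squared))
    if (!is.null(result$trend_bind)) {
      trends$k_bind <- list(slope = result$trend_bind$slope,
                            stderr = result$trend_bind$stderr_slope)
      trends$k_diss <- list(slope = result$trend_diss$slope,
                            stderr = result$trend_diss$stderr_slope)
      trends$slope_ratio <- result$slope_ratio
    }
    jsonlite::write_json(trends, file.path(out_dir, "trends.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", out_dir), "/?"),
                        "", names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("recafret")),
    seed = config$seed,
    condition = config$condition,
    n_molecules = config$n_molecules,
    n_frames = config$n_frames,
    dt = config$dt,
    pH_values = config$pH_values,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    exclusions = as.list(result$exclusions),
    digests = as.list(digests))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
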