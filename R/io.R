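# File formats: CSV (comma separated, '.' decimal, UTF-8, mandatory header),
# YAML/JSON parameter files, JSON fit results. Times in ms, currents in pA.
# All writers are deterministic: stable key order, 12 significant digits.

.fmt_num <- function(x) sprintf("%.12g", x)

#' Read a spike raster
#'
#' Expects a CSV with header \code{cell_id,I_pA,spike_time_ms}. Spike times
#' out of order within a current are sorted with a warning; duplicated times
#' raise a warning.
#'
#' @param path CSV file path.
#' @return A raster data.frame sorted by cell, current, time.
#' @export
load_raster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "I_pA", "spike_time_ms")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("raster schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  for (col in c("I_pA", "spike_time_ms")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop("raster schema error: non-numeric ", col, " at row ", bad[1])
  }
  key <- interaction(df$cell_id, df$I_pA, drop = TRUE)
  unsortedness <- vapply(split(df$spike_time_ms, key), is.unsorted, logical(1))
  if (any(unsortedness)) {
    warning("spike times out of order; sorting within each current")
  }
  if (any(vapply(split(df$spike_time_ms, key),
                 function(s) anyDuplicated(s) > 0, logical(1))))
    warning("duplicated spike times in the raster")
  df[order(df$cell_id, df$I_pA, df$spike_time_ms), , drop = FALSE]
}

#' Write a spike raster
#' @param raster data.frame with columns \code{cell_id, I_pA, spike_time_ms}.
#' @param path output CSV path.
#' @export
write_raster <- function(raster, path) {
  out <- data.frame(cell_id = raster$cell_id,
                    I_pA = .fmt_num(raster$I_pA),
                    spike_time_ms = .fmt_num(raster$spike_time_ms))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulation protocol (JSON or CSV)
#'
#' CSV columns / JSON keys: \code{t_begin_ms, t_end_ms, I_pA}.
#' @param path file path (format chosen by extension).
#' @return An \code{"aglif_protocol"}.
#' @export
read_protocol <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    as.data.frame(jsonlite::fromJSON(path))
  else utils::read.csv(path)
  missing <- setdiff(c("t_begin_ms", "t_end_ms", "I_pA"), names(df))
  if (length(missing))
    stop("protocol schema error: missing ", paste(missing, collapse = ", "))
  stimulus_protocol(df$t_begin_ms, df$t_end_ms, df$I_pA)
}

#' Write a stimulation protocol
#' @param protocol an \code{"aglif_protocol"}.
#' @param path output path (.json or .csv).
#' @export
write_protocol <- function(protocol, path) {
  df <- as.data.frame(unclass(protocol))[c("t_begin_ms", "t_end_ms", "I_pA")]
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, digits = NA, pretty = TRUE)
  else utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load cell parameters from YAML or JSON
#'
#' Keys are the field names of [aglif_parameters()]; the file is validated
#' and completed through [complete_parameters()].
#' @param path file path (.yaml/.yml or .json).
#' @return An \code{"aglif_parameters"} object.
#' @export
load_parameters <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path)
  complete_parameters(lapply(raw, as.numeric))
}

#' Write cell parameters to YAML or JSON
#' @param p an \code{"aglif_parameters"}.
#' @param path output path (.yaml/.yml or .json).
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "aglif_parameters"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(p), path, precision = 12)
  else jsonlite::write_json(unclass(p), path, digits = NA, auto_unbox = TRUE,
                            pretty = TRUE)
  invisible(path)
}

.fit_schema_version <- 1L

.monod_to_list <- function(m) list(a = m$a, b = m$b, c = m$c, d = m$d)

.block_to_list <- function(b) {
  if (is.null(b)) return(NULL)
  list(lines = lapply(b$lines, function(ln)
         list(A = ln$A, B = ln$B, validity = ln$validity,
              threshold = ln$threshold,
              P1 = as.list(ln$P1), P2 = as.list(ln$P2))),
       block_intervals = b$block_intervals,
       I_fire = b$I_fire,
       blocking_currents = b$blocking_currents)
}

.block_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  structure(list(
    lines = lapply(x$lines, function(ln)
      list(A = as.numeric(ln$A), B = as.numeric(ln$B),
           validity = as.character(ln$validity),
           threshold = as.numeric(ln$threshold),
           P1 = vapply(ln$P1, as.numeric, numeric(1)),
           P2 = vapply(ln$P2, as.numeric, numeric(1)))),
    block_intervals = lapply(x$block_intervals,
                             function(v) as.numeric(unlist(v))),
    I_fire = as.numeric(unlist(x$I_fire)),
    blocking_currents = as.numeric(unlist(x$blocking_currents))),
    class = "aglif_block_rule")
}

#' Save / load a fit result (JSON)
#'
#' The file carries an explicit \code{schema_version}; loading a file with an
#' unknown version is an error, never a silent reinterpretation. The
#' round trip \code{load_fit(save_fit(x))} reproduces every numeric field to
#' full precision.
#'
#' @param fit an \code{"aglif_fit"}.
#' @param path output path.
#' @return \code{save_fit} returns the path invisibly; \code{load_fit}
#'   returns the reconstructed \code{"aglif_fit"}.
#' @export
save_fit <- function(fit, path) {
  stopifnot(inherits(fit, "aglif_fit"))
  payload <- list(schema_version = .fit_schema_version,
                  params = unclass(fit$params),
                  sequences = fit$sequences,
                  monod = .monod_to_list(fit$monod),
                  block = .block_to_list(fit$block),
                  cost = fit$cost,
                  diagnostics = fit$diagnostics)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_fit
#' @export
load_fit <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$schema_version) || x$schema_version != .fit_schema_version)
    stop("unknown fit schema version: ",
         if (is.null(x$schema_version)) "<absent>" else x$schema_version)
  params <- do.call(aglif_parameters, lapply(x$params, as.numeric))
  monod <- monod_coefficients(x$monod$a, x$monod$b, x$monod$c, x$monod$d)
  block <- .block_from_list(x$block)
  seqs <- if (length(x$sequences))
    do.call(rbind, lapply(x$sequences, function(r)
      data.frame(I_pA = r$I_pA, chi_ms = r$chi_ms, I_adap0 = r$I_adap0,
                 clipped = r$clipped)))
  else data.frame(I_pA = numeric(0), chi_ms = numeric(0),
                  I_adap0 = numeric(0), clipped = logical(0))
  diagnostics <- list(
    generations = x$diagnostics$generations,
    best_history = as.numeric(unlist(x$diagnostics$best_history)),
    seed = x$diagnostics$seed)
  structure(list(params = params, sequences = seqs, monod = monod,
                 block = block, cost = x$cost, diagnostics = diagnostics,
                 cell = aglif_cell(params, monod, block, id = "fitted")),
            class = "aglif_fit")
}

#' Write a run manifest
#'
#' Records the command, configuration hash, seeds, package version,
#' timestamp and input/output digests of a command-line run; every CLI
#' invocation writes exactly one manifest next to its outputs.
#'
#' @param command subcommand name.
#' @param args named list of arguments.
#' @param seed seed(s) used.
#' @param inputs,outputs character vectors of file paths (digested when they
#'   exist).
#' @param path manifest output path.
#' @export
write_manifest <- function(command, args, seed, inputs = character(0),
                           outputs = character(0), path) {
  digest <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    # small stable digest: size + sum of bytes
    bytes <- readBin(f, "raw", file.info(f)$size)
    sprintf("%d-%08x", length(bytes), sum(as.integer(bytes)) %% 0xFFFFFFF)
  }
  manifest <- list(command = command,
                   args = args,
                   config_hash = digest_args <- sprintf("%08x",
                     sum(utf8ToInt(paste(names(args), unlist(args),
                                         collapse = ";"))) %% 0xFFFFFFF),
                   seed = seed,
                   package_version = as.character(utils::packageVersion("aglif")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   inputs = stats::setNames(lapply(inputs, digest), inputs),
                   outputs = stats::setNames(lapply(outputs, digest), outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
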