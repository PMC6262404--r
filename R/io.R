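# Plain-text (and optional binary) file formats. Every result file carries
# the population layout in its header so a raster or matrix is
# self-describing.

layout_to_json <- function(layout) {
  if (is.null(layout)) return(NULL)
  as.character(jsonlite::toJSON(
    list(population = layout$population, start = layout$start,
         size = layout$size),
    auto_unbox = FALSE))
}

layout_from_json <- function(txt) {
  if (is.null(txt) || !nzchar(txt)) return(NULL)
  l <- jsonlite::fromJSON(txt)
  population_layout(stats::setNames(as.integer(l$size), l$population))
}

#' Write a spike raster to disk
#'
#' The text format is two tab-separated columns (`time_ms`,
#' `neuron_index`, 0-based) preceded by `#` header lines recording the
#' network size, duration and population layout. The binary format is an RDS
#' container. Both round-trip through [read_raster()].
#'
#' @param raster A [spike_raster()].
#' @param path Output file path.
#' @param format `"tsv"` (plain text) or `"rds"` (binary container).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(raster, "spike_raster"))
  if (format == "rds") {
    saveRDS(list(time = raster$time, neuron = raster$neuron,
                 n_neurons = attr(raster, "n_neurons"),
                 duration = attr(raster, "duration"),
                 layout = attr(raster, "layout")), path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# serialmem spike raster",
               paste0("# n_neurons: ", attr(raster, "n_neurons")),
               paste0("# duration_ms: ",
                      format(attr(raster, "duration"), digits = 15)),
               paste0("# layout: ",
                      layout_to_json(attr(raster, "layout")) %||% ""),
               "# time_ms\tneuron_index"), con)
  if (nrow(raster))
    writeLines(paste(format(raster$time, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     raster$neuron, sep = "\t"), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a spike raster written by [write_raster()]
#'
#' @param path File path (`.tsv` text or `.rds` binary; sniffed from the
#'   content).
#' @return A [spike_raster()].
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # RDS files start with a serialization magic, text files with '#'
  first <- readBin(path, "raw", 2)
  if (!identical(rawToChar(first[1]), "#")) {
    l <- readRDS(path)
    return(spike_raster(l$time, l$neuron, l$n_neurons, l$duration, l$layout))
  }
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- lines[hdr]
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(m)) stop("malformed raster file ", path,
                         ": missing header '", key, "'")
    sub(paste0("^# ", key, ": "), "", m[1])
  }
  n_neurons <- as.integer(get_meta("n_neurons"))
  duration <- as.numeric(get_meta("duration_ms"))
  layout <- layout_from_json(get_meta("layout"))
  body <- lines[!hdr]
  body <- body[nzchar(body)]
  if (!length(body))
    return(spike_raster(numeric(0), integer(0), n_neurons, duration, layout))
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed raster file ", path, ": expected two tab-separated ",
         "columns at line ", sum(hdr) + bad[1])
  tm <- as.numeric(vapply(parts, `[[`, "", 1L))
  nr <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(tm) || anyNA(nr))
    stop("malformed raster file ", path, ": non-numeric entry at line ",
         sum(hdr) + which(is.na(tm) | is.na(nr))[1])
  spike_raster(tm, nr, n_neurons, duration, layout)
}

#' Write a connectivity or probe matrix
#'
#' Dense numeric CSV (no header; sign encodes synapse type) plus, when a
#' layout is supplied, a JSON sidecar `<path>.layout.json` describing the
#' population index ranges. The binary format is RDS.
#'
#' @param w Numeric matrix.
#' @param path Output file path.
#' @param layout Optional [population_layout()], written to the sidecar.
#' @param format `"csv"` or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(w, path, layout = NULL, format = c("csv", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(w = w, layout = layout), path)
    return(invisible(path))
  }
  utils::write.table(w, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(layout))
    writeLines(layout_to_json(layout), paste0(path, ".layout.json"))
  invisible(path)
}

#' Read a matrix written by [write_matrix()]
#'
#' @param path File path.
#' @return The numeric matrix; if a layout sidecar exists, it is attached as
#'   the `layout` attribute.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readChar(path, 1, useBytes = TRUE)
  if (!grepl("[-0-9.]", first)) {
    l <- readRDS(path)
    w <- l$w
    attr(w, "layout") <- l$layout
    return(w)
  }
  w <- tryCatch(
    as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    error = function(e) stop("malformed matrix file ", path, ": ",
                             conditionMessage(e)))
  dimnames(w) <- NULL
  if (!is.numeric(w)) stop("malformed matrix file ", path,
                           ": non-numeric entries")
  side <- paste0(path, ".layout.json")
  if (file.exists(side))
    attr(w, "layout") <- layout_from_json(paste(readLines(side),
                                                collapse = ""))
  w
}

# ---- experiment configuration (YAML) ---------------------------------------

plainify <- function(x) {
  if (inherits(x, "population_layout"))
    return(list(.class = "population_layout",
                sizes = stats::setNames(as.list(x$size), x$population)))
  if (is.list(x)) {
    out <- lapply(unclass(x), plainify)
    cls <- class(x)[1]
    if (cls != "list") out$.class <- cls
    return(out)
  }
  x
}

unplainify <- function(x) {
  if (!is.list(x)) return(x)
  cls <- x$.class
  x$.class <- NULL
  x <- lapply(x, unplainify)
  if (is.null(cls)) return(x)
  ctor <- switch(cls,
                 neuron_params = neuron_params,
                 plasticity_params = plasticity_params,
                 static_weight_table = static_weight_table,
                 serial_order_config = serial_order_config,
                 teaching_protocol = teaching_protocol,
                 sim_config = sim_config,
                 wta_config = wta_config,
                 laser_script = NULL,
                 population_layout = NULL,
                 stop("unknown configuration class '", cls, "'"))
  if (cls == "population_layout")
    return(population_layout(unlist(x$sizes)))
  if (cls == "laser_script")
    return(do.call(laser_script, x))
  args <- x[intersect(names(x), names(formals(ctor)))]
  args <- args[!vapply(args, is.null, logical(1))]
  # vectors serialized as lists come back as plain (classless) lists;
  # reconstructed configuration objects must be left intact
  args <- lapply(args, function(a)
    if (is.list(a) && is.null(attr(a, "class")) &&
        all(vapply(a, is.atomic, logical(1)))) unlist(a) else a)
  do.call(ctor, args)
}

#' Write an experiment configuration to a YAML file
#'
#' Any collection of the package's configuration objects (neuron and
#' plasticity parameters, weight tables, serial-order and WTA
#' configurations, protocols, simulation configs) and plain scalars can be
#' stored; class tags let [read_config()] reconstruct and re-validate the
#' objects. One config file plus one seed fully describes an experiment.
#'
#' @param config Named list of configuration objects / values.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(plainify(config), path)
  invisible(path)
}

#' Read an experiment configuration written by [write_config()]
#'
#' @param path YAML file path.
#' @return The reconstructed named list; tagged objects are rebuilt through
#'   their constructors (re-running all validity checks).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("malformed config file ", path,
                                           ": ", conditionMessage(e)))
  unplainify(raw)
}

#' Write a run manifest
#'
#' Records what produced a set of result files: a hash of the canonical
#' configuration, the seed, the package and R versions and a timestamp.
#' Two runs of the same configuration and seed differ only in the timestamp.
#'
#' @param path Output JSON path.
#' @param config Named list of configuration objects (hashed canonically).
#' @param seed Integer seed of the run.
#' @param extra Optional named list of additional fields.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, extra = list()) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  manifest <- c(list(
    artifact = "serialmem",
    version = as.character(utils::packageVersion("serialmem")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = as.integer(seed),
    config_hash = unname(tools::md5sum(tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a run manifest
#' @param path JSON file path.
#' @return Named list.
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path)
}
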