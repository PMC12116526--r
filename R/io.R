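# Tabular and bundle I/O. CSV is the interchange dialect (RFC 4180, UTF-8,
# '.' decimal); floats are written with 17 significant digits so numeric
# round-trips are lossless.

format_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
}

#' Write a per-zone table as CSV
#'
#' Standard dialect: `zone_id` is a 0-based integer key; numeric columns
#' are written at 17 significant digits (lossless round-trip for doubles).
#'
#' @param table data.frame with at least a `zone_id` column.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_zone_table <- function(table, path) {
  if (!("zone_id" %in% names(table)))
    af_stop("zone table must contain a 'zone_id' column",
            class = "agrifusion_io_error")
  if (anyDuplicated(table$zone_id))
    af_stop(sprintf("duplicate zone_id: %s",
                    paste(unique(table$zone_id[duplicated(table$zone_id)]),
                          collapse = ", ")),
            class = "agrifusion_io_error")
  out <- table
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- format_num(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-zone table from CSV
#'
#' @param path CSV file in the dialect of [write_zone_table()].
#' @param required character vector of required column names
#'   (default `"zone_id"`).
#' @return data.frame; `zone_id` as integer.
#' @export
read_zone_table <- function(path, required = "zone_id") {
  if (!file.exists(path))
    af_stop(sprintf("zone table not found: %s", path),
            class = "agrifusion_io_error")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    af_stop(paste0("missing required column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "agrifusion_io_error")
  if ("zone_id" %in% names(tab)) {
    if (anyDuplicated(tab$zone_id))
      af_stop(sprintf("duplicate zone_id: %s",
                      paste(unique(tab$zone_id[duplicated(tab$zone_id)]),
                            collapse = ", ")),
              class = "agrifusion_io_error")
    tab$zone_id <- as.integer(tab$zone_id)
  }
  tab
}

#' Write a multimodal observation as a text bundle
#'
#' One CSV per modality (spatial arrays flattened row-major with their
#' dimensions recorded) plus a JSON manifest, so the bundle is plain text
#' and loss-free.
#'
#' @param obs a [multimodal_observation].
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_observation_bundle <- function(obs, dir) {
  stopifnot(inherits(obs, "multimodal_observation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dims <- list()
  for (nm in c("x_sat", "x_uav", "x_sens", "x_weather")) {
    a <- obs[[nm]]
    dims[[nm]] <- dim(a)
    flat <- if (length(dim(a)) == 3L)
      matrix(a, nrow = dim(a)[1L] * dim(a)[2L]) else a
    utils::write.table(apply(flat, 2L, format_num),
                       file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  jsonlite::write_json(dims, file.path(dir, "bundle.json"), digits = NA)
  invisible(dir)
}

#' Read a multimodal observation bundle
#'
#' @param dir directory written by [write_observation_bundle()].
#' @return a [multimodal_observation].
#' @export
read_observation_bundle <- function(dir) {
  manifest <- file.path(dir, "bundle.json")
  if (!file.exists(manifest))
    af_stop(sprintf("not an observation bundle (no bundle.json): %s", dir),
            class = "agrifusion_io_error")
  dims <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  get_mat <- function(nm) {
    m <- as.matrix(utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                                   header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    if (length(dims[[nm]]) == 3L) array(m, dim = dims[[nm]]) else m
  }
  multimodal_observation(get_mat("x_sat"), get_mat("x_uav"),
                         get_mat("x_sens"), get_mat("x_weather"))
}

# Run manifest: everything needed to reproduce a run bit-exactly. No
# timestamps, so repeated runs are byte-identical.
write_manifest <- function(dir, command, seed, cfg, outputs) {
  jsonlite::write_json(
    list(command = command, seed = seed,
         config_hash = config_hash(cfg),
         package = "agrifusion",
         version = as.character(utils::packageVersion("agrifusion")),
         outputs = outputs),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
}
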