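#' Write indentation curves as per-site CSV files with a manifest
#'
#' Each site's curve goes to its own CSV (`time_s`, `load_mN`, `depth_nm`);
#' a `manifest.csv` lists specimen, compartment, trabecula, site, and file;
#' a JSON sidecar records the seed and generation metadata.
#'
#' @param curves A long tibble of curve samples with id columns `specimen`,
#'   `compartment`, optionally `trabecula`, `site`.
#' @param dir Output directory (created if needed).
#' @param metadata A list written to `metadata.json` (seed, spec, version).
#'
#' @return The manifest tibble, invisibly.
#' @export
write_curves <- function(curves, dir, metadata = list()) {
  check_columns(curves, c("specimen", "compartment", "site",
                          "time_s", "load_mN", "depth_nm"), "write_curves")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!"trabecula" %in% names(curves)) curves$trabecula <- NA_integer_
  ids <- dplyr::distinct(curves, .data$specimen, .data$compartment,
                         .data$trabecula, .data$site)
  ids$file <- sprintf("curve_%s_%s_%s_%03d.csv", ids$specimen, ids$compartment,
                      ifelse(is.na(ids$trabecula), "x", ids$trabecula), ids$site)
  for (i in seq_len(nrow(ids))) {
    sel <- curves$specimen == ids$specimen[i] &
      curves$compartment == ids$compartment[i] &
      (is.na(ids$trabecula[i]) | curves$trabecula %in% ids$trabecula[i]) &
      curves$site == ids$site[i]
    readr::write_csv(curves[sel, c("time_s", "load_mN", "depth_nm")],
                     file.path(dir, ids$file[i]))
  }
  readr::write_csv(ids, file.path(dir, "manifest.csv"))
  meta <- c(list(package_version = as.character(packageVersion("ossindent"))),
            metadata)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(ids)
}

#' Read curves written by [write_curves()]
#'
#' @param dir Directory containing `manifest.csv` and the per-site CSVs.
#'   Column-name aliases (e.g. `time`, `load`, `depth`) are accepted.
#' @return A long tibble of curve samples with id columns.
#' @export
read_curves <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest)) {
    abort(sprintf("read_curves: no manifest at %s", manifest),
          class = "ossindent_error_io")
  }
  ids <- readr::read_csv(manifest, show_col_types = FALSE)
  aliases <- c(time = "time_s", t = "time_s", time_s = "time_s",
               load = "load_mN", p = "load_mN", load_mn = "load_mN",
               load_mN = "load_mN",
               depth = "depth_nm", h = "depth_nm", depth_nm = "depth_nm")
  purrr::pmap_dfr(ids, function(specimen, compartment, trabecula, site, file, ...) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      abort(sprintf("read_curves: missing curve file %s", path),
            class = "ossindent_error_io")
    }
    d <- readr::read_csv(path, show_col_types = FALSE)
    hit <- aliases[names(d)]
    names(d)[!is.na(hit)] <- hit[!is.na(hit)]
    check_columns(d, c("time_s", "load_mN", "depth_nm"), "read_curves")
    dplyr::bind_cols(
      tibble::tibble(specimen = specimen, compartment = compartment,
                     trabecula = trabecula, site = site),
      d[, c("time_s", "load_mN", "depth_nm")])
  })
}

# list-columns of numeric readings <-> semicolon-joined strings
pack_readings <- function(col) {
  vapply(col, function(x) paste(format(as.numeric(x), digits = 15, trim = TRUE,
                                       scientific = FALSE),
                                collapse = ";"),
         character(1))
}
unpack_readings <- function(col) {
  lapply(strsplit(ifelse(is.na(col), "", col), ";", fixed = TRUE),
         function(x) as.numeric(x[nzchar(x)]))
}

#' Write a primitives table (flattening reading lists)
#'
#' Reading list-columns (`o_th_um`, `w_th_um`, `interlabel_um`, `ct_th_um`)
#' are serialized as semicolon-joined values inside a single CSV field;
#' [read_primitives()] reverses this. Missing values are written as empty
#' fields.
#'
#' @param data A primitives tibble.
#' @param path Output CSV path.
#' @export
write_primitives <- function(data, path) {
  out <- data
  for (col in intersect(c("o_th_um", "w_th_um", "interlabel_um", "ct_th_um"),
                        names(out))) {
    if (is.list(out[[col]])) out[[col]] <- pack_readings(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a primitives table written by [write_primitives()]
#'
#' @param path CSV path.
#' @return A tibble with reading list-columns restored.
#' @export
read_primitives <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()))
  for (col in intersect(c("o_th_um", "w_th_um", "interlabel_um", "ct_th_um"),
                        names(d))) {
    d[[col]] <- unpack_readings(as.character(d[[col]]))
  }
  d
}
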