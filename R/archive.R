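layer_names <- c("Raw", "TOF", "BGO", "All")
array_names <- c("bins", "counts", "smoothed_counts", "baseline",
                 "calibration")
expected_records <- c(main = 23L, reference = 10L, validation = 10L)

#' Construct a campaign dataset
#'
#' A campaign is a named list of spectrum records, one per beam energy;
#' names are the energies formatted to two decimals (`"115.55"`) to avoid
#' float-key pitfalls. Each record holds the delivered proton count and the
#' four suppression layers, each layer a 2048-row tibble with the five
#' archive arrays (`bins`, `counts`, `smoothed_counts`, `baseline`,
#' `calibration`).
#'
#' @param campaign_name `"main"`, `"reference"`, `"validation"`, or any
#'   other label for ad-hoc datasets.
#' @param records named list of `pg_record` objects (see
#'   [simulate_spectrum_record()]).
#' @return object of class `pg_campaign`.
#' @export
new_pg_campaign <- function(campaign_name, records) {
  structure(list(campaign_name = campaign_name, records = records),
            class = "pg_campaign")
}

#' @export
print.pg_campaign <- function(x, ...) {
  cat(sprintf("<pg_campaign> %s: %d records\n", x$campaign_name,
              length(x$records)))
  cat("energies:", paste(names(x$records), collapse = " "), "\n")
  invisible(x)
}

#' Validate a campaign dataset's structure
#'
#' Checks the archive invariants: at least one record; every record has a
#' positive proton count and all four layers; every layer carries the five
#' arrays with exactly `n_bins` elements, non-negative counts, and a
#' strictly increasing calibration. When `campaign_name` is one of the three
#' study campaigns and `check_size` is `TRUE`, the record count must match
#' the campaign table (23/10/10). Errors name the offending energy and
#' layer.
#'
#' @param dataset a `pg_campaign`.
#' @param campaign_name expected campaign name, or `NULL` to accept any.
#' @param check_size enforce the study's record counts for the three named
#'   campaigns.
#' @param n_bins required array length.
#' @return `dataset`, invisibly.
#' @export
validate_campaign <- function(dataset, campaign_name = NULL,
                              check_size = FALSE, n_bins = 2048L) {
  if (!inherits(dataset, "pg_campaign")) abort("not a pg_campaign")
  if (!is.null(campaign_name) && dataset$campaign_name != campaign_name)
    abort(sprintf("campaign name is '%s', expected '%s'",
                  dataset$campaign_name, campaign_name))
  if (length(dataset$records) == 0)
    abort("a campaign must contain at least one record")
  if (check_size && dataset$campaign_name %in% names(expected_records)) {
    want <- expected_records[[dataset$campaign_name]]
    if (length(dataset$records) != want)
      abort(sprintf("campaign '%s' must have %d records, found %d",
                    dataset$campaign_name, want, length(dataset$records)))
  }
  for (key in names(dataset$records)) {
    rec <- dataset$records[[key]]
    if (is.null(rec$protons) || rec$protons <= 0)
      abort(sprintf("record %s: protons must be > 0", key))
    missing <- setdiff(layer_names, names(rec$layers))
    if (length(missing) > 0)
      abort(sprintf("record %s: missing layer %s", key,
                    paste(missing, collapse = ", ")))
    for (layer in layer_names) {
      la <- rec$layers[[layer]]
      for (arr in array_names) {
        if (is.null(la[[arr]]))
          abort(sprintf("record %s layer %s: missing array '%s'", key,
                        layer, arr))
        if (length(la[[arr]]) != n_bins)
          abort(sprintf(
            "record %s layer %s: array '%s' has %d elements, expected %d",
            key, layer, arr, length(la[[arr]]), n_bins))
      }
      if (any(la$counts < 0))
        abort(sprintf("record %s layer %s: negative counts", key, layer))
      if (any(diff(la$calibration) <= 0))
        abort(sprintf(
          "record %s layer %s: calibration is not strictly increasing",
          key, layer))
    }
  }
  invisible(dataset)
}

#' Flatten a campaign to a long tibble
#'
#' @param x a `pg_campaign`.
#' @param ... unused.
#' @return tibble with `beam_energy`, `protons`, `layer` and the five
#'   per-bin arrays.
#' @export
as_tibble.pg_campaign <- function(x, ...) {
  purrr::map_dfr(names(x$records), function(key) {
    rec <- x$records[[key]]
    purrr::map_dfr(layer_names, function(layer) {
      rec$layers[[layer]] |>
        dplyr::mutate(beam_energy = rec$beam_energy, protons = rec$protons,
                      layer = layer, .before = 1)
    })
  })
}

#' Write a campaign to the portable archive format
#'
#' One directory per campaign: a `manifest.yaml` (campaign name, energies as
#' two-decimal strings, proton counts, file map) plus one CSV per
#' energy/layer holding the five arrays as columns. The dataset is validated
#' before writing.
#'
#' @param dataset a `pg_campaign`.
#' @param path directory to create (must not be an existing non-empty file).
#' @return `path`, invisibly.
#' @export
write_campaign_archive <- function(dataset, path) {
  validate_campaign(dataset)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory '%s'", path))
  files <- list()
  for (key in names(dataset$records)) {
    rec <- dataset$records[[key]]
    for (layer in layer_names) {
      fname <- sprintf("E%s_%s.csv", key, layer)
      readr::write_csv(rec$layers[[layer]][array_names],
                       file.path(path, fname), progress = FALSE)
      files[[key]][[layer]] <- fname
    }
  }
  manifest <- list(
    campaign_name = dataset$campaign_name,
    energies = as.list(names(dataset$records)),
    protons = as.list(setNames(
      purrr::map_dbl(dataset$records, "protons"), names(dataset$records))),
    files = files
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"))
  invisible(path)
}

#' Read a campaign from the portable archive format
#'
#' Inverse of [write_campaign_archive()]; the result is validated and
#' value-identical to the written dataset. Unknown manifest keys are kept in
#' the `extra` attribute but otherwise ignored.
#'
#' @param path archive directory.
#' @param campaign_name expected campaign name, or `NULL`.
#' @param check_size see [validate_campaign()].
#' @return a `pg_campaign`.
#' @export
read_campaign_archive <- function(path, campaign_name = NULL,
                                  check_size = FALSE) {
  mf_path <- file.path(path, "manifest.yaml")
  if (!file.exists(mf_path)) abort(sprintf("no manifest at '%s'", mf_path))
  mf <- yaml::read_yaml(mf_path)
  records <- list()
  for (key in unlist(mf$energies)) {
    layers <- list()
    for (layer in layer_names) {
      fname <- mf$files[[key]][[layer]]
      if (is.null(fname))
        abort(sprintf("record %s: manifest lists no file for layer %s",
                      key, layer))
      layers[[layer]] <- readr::read_csv(
        file.path(path, fname), show_col_types = FALSE, progress = FALSE)
    }
    records[[key]] <- structure(
      list(beam_energy = as.numeric(key),
           protons = as.numeric(mf$protons[[key]]), layers = layers),
      class = "pg_record")
  }
  dataset <- new_pg_campaign(mf$campaign_name, records)
  known <- c("campaign_name", "energies", "protons", "files")
  attr(dataset, "extra") <- mf[setdiff(names(mf), known)]
  validate_campaign(dataset, campaign_name, check_size)
  dataset
}

python_bin <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") abort("no python interpreter found for the pickle bridge")
  py
}

#' Read or write the deposited pickle archive format
#'
#' The deposited archives are Python pickles with a three-layer nesting:
#' energy label, then `proton` plus the four suppression layers, then the
#' five arrays (`_counts`, `baseline`, `bins`, `calibration`, `counts`).
#' These functions bridge to that format through the system Python
#' interpreter via JSON, tolerating byte-string keys and numpy-array leaves
#' from older pickles. `_counts` (the smoothed spectrum) maps to
#' `smoothed_counts`. Whether the deposited `counts` are dead-time-corrected
#' is not documented; they are passed through as-is.
#'
#' @param dataset a `pg_campaign`.
#' @param path pickle file path.
#' @param campaign_name expected campaign name, or `NULL`.
#' @param check_size see [validate_campaign()].
#' @return `read_campaign_pickle()` returns a `pg_campaign`;
#'   `write_campaign_pickle()` returns `path` invisibly.
#' @export
read_campaign_pickle <- function(path, campaign_name = NULL,
                                 check_size = FALSE) {
  if (!file.exists(path)) abort(sprintf("no file at '%s'", path))
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path))
  script <- paste(
    "import pickle, json, sys",
    "def clean(o):",
    "    if isinstance(o, bytes): return o.decode('utf-8', 'replace')",
    "    if isinstance(o, dict):",
    "        return {clean(k): clean(v) for k, v in o.items()}",
    "    if hasattr(o, 'tolist'): return o.tolist()",
    "    if isinstance(o, (list, tuple)): return [clean(v) for v in o]",
    "    return o",
    "with open(sys.argv[1], 'rb') as fh: d = pickle.load(fh)",
    "with open(sys.argv[2], 'w') as fh: json.dump(clean(d), fh)",
    sep = "\n")
  status <- system2(python_bin(), c("-c", shQuote(script), shQuote(path),
                                    shQuote(json_path)))
  if (status != 0) abort("python pickle bridge failed while reading")
  raw <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  records <- list()
  for (key in names(raw)) {
    node <- raw[[key]]
    layers <- list()
    for (layer in layer_names) {
      la <- node[[layer]]
      if (is.null(la))
        abort(sprintf("record %s: missing layer %s", key, layer))
      layers[[layer]] <- tibble::tibble(
        bins = as.numeric(la[["bins"]]),
        counts = as.numeric(la[["counts"]]),
        smoothed_counts = as.numeric(la[["_counts"]]),
        baseline = as.numeric(la[["baseline"]]),
        calibration = as.numeric(la[["calibration"]])
      )
    }
    records[[sprintf("%.2f", as.numeric(key))]] <- structure(
      list(beam_energy = as.numeric(key),
           protons = as.numeric(node[["proton"]]), layers = layers),
      class = "pg_record")
  }
  dataset <- new_pg_campaign(
    if (is.null(campaign_name)) "unknown" else campaign_name, records)
  validate_campaign(dataset, campaign_name, check_size)
  dataset
}

#' @rdname read_campaign_pickle
#' @export
write_campaign_pickle <- function(dataset, path) {
  validate_campaign(dataset)
  out <- list()
  for (key in names(dataset$records)) {
    rec <- dataset$records[[key]]
    node <- list(proton = rec$protons)
    for (layer in layer_names) {
      la <- rec$layers[[layer]]
      node[[layer]] <- list(`_counts` = la$smoothed_counts,
                            baseline = la$baseline, bins = la$bins,
                            calibration = la$calibration,
                            counts = la$counts)
    }
    out[[key]] <- node
  }
  json_path <- tempfile(fileext = ".json")
  on.exit(unlink(json_path))
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  script <- paste(
    "import pickle, json, sys",
    "with open(sys.argv[1]) as fh: d = json.load(fh)",
    "with open(sys.argv[2], 'wb') as fh: pickle.dump(d, fh)",
    sep = "\n")
  status <- system2(python_bin(), c("-c", shQuote(script), shQuote(json_path),
                                    shQuote(path)))
  if (status != 0) abort("python pickle bridge failed while writing")
  invisible(path)
}

#' Per-layer event retention of a campaign
#'
#' Fraction of Raw-layer counts retained by each suppression layer, per
#' record: `sum(counts[layer]) / sum(counts[Raw])`. The Raw fraction is 1 by
#' construction; with the study's cuts the TOF layer keeps about 13%, BGO
#' about 32% and both together about 6%.
#'
#' @param dataset a `pg_campaign`.
#' @return tibble with `beam_energy`, `layer`, `retained_fraction`.
#' @export
layer_retention <- function(dataset) {
  validate_campaign(dataset)
  purrr::map_dfr(names(dataset$records), function(key) {
    rec <- dataset$records[[key]]
    raw_total <- sum(rec$layers$Raw$counts)
    if (raw_total <= 0)
      abort(sprintf("record %s: zero Raw counts, retention undefined", key))
    tibble::tibble(
      beam_energy = rec$beam_energy,
      layer = layer_names,
      retained_fraction = purrr::map_dbl(
        layer_names, ~ sum(rec$layers[[.x]]$counts) / raw_total)
    )
  })
}
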