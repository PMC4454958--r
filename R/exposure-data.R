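#' Construct a workplace exposure dataset
#'
#' An exposure dataset is a data frame of individual air-concentration
#' measurements, one row per sample, with the workplace it came from and
#' whether it was a personal (breathing-zone) or area sample. Values at or
#' below the detection limit are flagged and carried at the detection-limit
#' surrogate value (simple substitution); the flag is preserved so that
#' alternative censoring policies can be layered on later.
#'
#' @param workplace_id character vector of workplace labels.
#' @param sample_kind character vector, `"personal"` or `"area"`.
#' @param concentration numeric vector of concentrations in mg/m3,
#'   non-negative and finite.
#' @param detection_limit analytical detection limit in mg/m3.
#' @return a data frame of class `exposure_dataset` with columns
#'   `workplace_id`, `sample_kind`, `concentration`, `below_detection`
#'   and attribute `detection_limit`.
#' @export
exposure_dataset <- function(workplace_id, sample_kind, concentration,
                             detection_limit = 0.001) {
  n <- length(concentration)
  if (n == 0) stop("exposure dataset must contain at least one sample", call. = FALSE)
  stopifnot(length(workplace_id) == n, length(sample_kind) == n)
  sample_kind <- as.character(sample_kind)
  if (!all(sample_kind %in% c("personal", "area"))) {
    bad <- which(!sample_kind %in% c("personal", "area"))[1]
    stop(sprintf("unknown sample_kind in row %d: '%s'", bad, sample_kind[bad]),
         call. = FALSE)
  }
  if (any(!is.finite(concentration)))
    stop("all concentrations must be finite", call. = FALSE)
  if (any(concentration < 0)) {
    bad <- which(concentration < 0)[1]
    stop(sprintf("negative concentration in row %d (%g mg/m3)", bad,
                 concentration[bad]), call. = FALSE)
  }
  stopifnot(is.numeric(detection_limit), detection_limit >= 0)
  below <- concentration <= detection_limit
  concentration[below] <- detection_limit
  out <- data.frame(workplace_id = as.character(workplace_id),
                    sample_kind = sample_kind,
                    concentration = concentration,
                    below_detection = below,
                    stringsAsFactors = FALSE)
  attr(out, "detection_limit") <- detection_limit
  class(out) <- c("exposure_dataset", "data.frame")
  out
}

#' Convert an air concentration from ppm to mg/m3
#'
#' Uses the ideal-gas relation `mg/m3 = ppm * MW / Vm`, with the molar
#' volume `Vm` defaulting to 24.45 L/mol (25 degrees C, 1 atm). Note that
#' regulatory limit pairs are sometimes set by convention rather than by
#' this formula; a [substance_dossier()] therefore stores the ppm and
#' mg/m3 limit values independently.
#'
#' @param c concentration in ppm (non-negative).
#' @param mw molecular weight in g/mol.
#' @param molar_volume molar volume in L/mol.
#' @return concentration in mg/m3.
#' @examples
#' convert_ppm_to_mgm3(0.2, 154.21)  # biphenyl, 0.2 ppm -> ~1.26 mg/m3
#' @export
convert_ppm_to_mgm3 <- function(c, mw, molar_volume = 24.45) {
  if (!is.numeric(mw) || any(mw <= 0)) stop("'mw' must be positive", call. = FALSE)
  if (!is.numeric(molar_volume) || any(molar_volume <= 0))
    stop("'molar_volume' must be positive", call. = FALSE)
  if (any(c < 0, na.rm = TRUE)) stop("'c' must be non-negative", call. = FALSE)
  c * mw / molar_volume
}

#' @rdname convert_ppm_to_mgm3
#' @export
convert_mgm3_to_ppm <- function(c, mw, molar_volume = 24.45) {
  if (!is.numeric(mw) || any(mw <= 0)) stop("'mw' must be positive", call. = FALSE)
  if (!is.numeric(molar_volume) || any(molar_volume <= 0))
    stop("'molar_volume' must be positive", call. = FALSE)
  if (any(c < 0, na.rm = TRUE)) stop("'c' must be non-negative", call. = FALSE)
  c * molar_volume / mw
}

#' Read a workplace measurement table from delimited text
#'
#' The file is CSV or TSV (chosen by extension; `.tsv`/`.txt` are read as
#' tab-separated) with columns `workplace_id`, `sample_kind`,
#' `concentration` and an optional leading pragma comment declaring the
#' unit, e.g. `# units: mg/m3` or `# units: ppm`. Files in ppm are
#' converted to mg/m3 on load, which requires `molecular_weight`.
#'
#' @param path file path.
#' @param detection_limit detection limit in mg/m3; rows at or below it are
#'   flagged `below_detection`.
#' @param molecular_weight g/mol; required only when the file declares ppm.
#' @param molar_volume L/mol used for the ppm conversion.
#' @return an [exposure_dataset()].
#' @export
load_exposure_table <- function(path, detection_limit = 0.001,
                                molecular_weight = NULL, molar_volume = 24.45) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  units <- "mg/m3"
  pragma <- grep("^\\s*#", lines)
  if (length(pragma)) {
    m <- regmatches(lines[pragma],
                    regexpr("units\\s*:\\s*\\S+", lines[pragma], ignore.case = TRUE))
    if (length(m)) {
      units <- tolower(trimws(sub("(?i)units\\s*:\\s*", "", m[[1]], perl = TRUE)))
      if (!units %in% c("mg/m3", "ppm"))
        stop(sprintf("unknown unit in header pragma: '%s'", units), call. = FALSE)
    }
    lines <- lines[-pragma]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop("no data rows found below the header", call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  required <- c("workplace_id", "sample_kind", "concentration")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  conc <- suppressWarnings(as.numeric(tab$concentration))
  if (any(is.na(conc))) {
    bad <- which(is.na(conc))[1]
    stop(sprintf("non-numeric concentration in row %d: '%s'", bad,
                 tab$concentration[bad]), call. = FALSE)
  }
  if (any(conc < 0)) {
    bad <- which(conc < 0)[1]
    stop(sprintf("negative concentration in row %d (%g)", bad, conc[bad]),
         call. = FALSE)
  }
  if (identical(units, "ppm")) {
    if (is.null(molecular_weight))
      stop("file is in ppm: 'molecular_weight' is required for conversion",
           call. = FALSE)
    conc <- convert_ppm_to_mgm3(conc, molecular_weight, molar_volume)
  }
  exposure_dataset(tab$workplace_id, tab$sample_kind, conc,
                   detection_limit = detection_limit)
}

#' Descriptive summary of an exposure dataset by workplace
#'
#' Computes, per workplace and overall, the sample count N, arithmetic mean
#' (AM), sample standard deviation (SD, `n - 1` denominator, the
#' industrial-hygiene convention) and observed range. Groups with a single
#' sample report SD = 0 and are flagged `sd_degenerate`, with a warning.
#'
#' @param dataset an [exposure_dataset()].
#' @param by grouping column, default `"workplace_id"`.
#' @param total_label label for the pooled overall row.
#' @return data frame with columns `workplace_id`, `n`, `am`, `sd`,
#'   `range_lo`, `range_hi`, `sd_degenerate`.
#' @export
summarize_exposure <- function(dataset, by = "workplace_id",
                               total_label = "Total") {
  stopifnot(inherits(dataset, "exposure_dataset"), nrow(dataset) >= 1)
  g <- dataset[[by]]
  one <- function(x, label) {
    n <- length(x)
    data.frame(workplace_id = label, n = n, am = mean(x),
               sd = if (n > 1) stats::sd(x) else 0,
               range_lo = min(x), range_hi = max(x),
               sd_degenerate = n == 1, stringsAsFactors = FALSE)
  }
  groups <- lapply(sort(unique(g)), function(k)
    one(dataset$concentration[g == k], k))
  out <- do.call(rbind, c(groups,
                          list(one(dataset$concentration, total_label))))
  rownames(out) <- NULL
  if (any(out$sd_degenerate))
    warning("group(s) with a single sample: SD reported as 0", call. = FALSE)
  out
}

#' Write a Table-style exposure summary
#'
#' Renders the [summarize_exposure()] output either as CSV or as an aligned
#' plain-text table in the conventional column order (N, AM, SD, Range).
#'
#' @param summary data frame from [summarize_exposure()].
#' @param path output path, or `NULL` to return the text invisibly printed.
#' @param format `"text"` or `"csv"`.
#' @return the formatted lines, invisibly.
#' @export
format_exposure_summary <- function(summary, path = NULL, format = c("text", "csv")) {
  format <- match.arg(format)
  if (identical(format, "csv")) {
    out <- utils::capture.output(
      utils::write.csv(summary[c("workplace_id", "n", "am", "sd",
                                 "range_lo", "range_hi")],
                       row.names = FALSE))
  } else {
    rng <- sprintf("%.3f-%.3f", summary$range_lo, summary$range_hi)
    m <- rbind(c("Workplace", "N", "AM", "SD", "Range"),
               cbind(summary$workplace_id, summary$n,
                     sprintf("%.3f", round_half_up(summary$am, 3)),
                     sprintf("%.3f", round_half_up(summary$sd, 3)), rng))
    for (j in seq_len(ncol(m)))
      m[, j] <- formatC(m[, j], width = max(nchar(m[, j])), flag = "-")
    out <- trimws(apply(m, 1, paste, collapse = "  "), "right")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Substance dossier
#'
#' Bundle of per-substance regulatory and toxicological inputs: molecular
#' weight, occupational exposure limit (OEL), cancer slope factor and
#' points of departure. The OEL is stored both in ppm and in mg/m3 as two
#' independent regulatory values: limit pairs are set by convention and do
#' not necessarily satisfy the molar-volume conversion, so the mg/m3 value
#' is never recomputed from the ppm value.
#'
#' @param name substance name.
#' @param molecular_weight g/mol.
#' @param oel_ppm regulatory OEL in ppm.
#' @param oel_mgm3 regulatory OEL in mg/m3, stored verbatim.
#' @param slope_factor cancer slope factor, per mg/kg-day, or `NULL`.
#' @param pods named list of [point_of_departure()] objects keyed by
#'   endpoint.
#' @return object of class `substance_dossier`.
#' @seealso [biphenyl_dossier()] for the built-in example dossier,
#'   [read_dossier()] to load one from a YAML config file.
#' @export
substance_dossier <- function(name, molecular_weight, oel_ppm, oel_mgm3,
                              slope_factor = NULL, pods = list()) {
  stopifnot(is.character(name), molecular_weight > 0, oel_ppm > 0, oel_mgm3 > 0)
  if (!is.null(slope_factor)) stopifnot(slope_factor > 0)
  structure(list(name = name, molecular_weight = molecular_weight,
                 oel_ppm = oel_ppm, oel_mgm3 = oel_mgm3,
                 slope_factor = slope_factor, pods = pods),
            class = "substance_dossier")
}

#' Read a substance dossier from a YAML config file
#'
#' The file holds one document per substance with keys `name`,
#' `molecular_weight`, `oel_ppm`, `oel_mgm3`, optional `slope_factor`, and
#' a `pods` mapping of endpoint name to `{value, pod_type, route, species,
#' study_duration_weeks}`. See `system.file("extdata", "biphenyl.yaml",
#' package = "workrisk")` for the shipped example.
#'
#' @param path YAML file path.
#' @return a [substance_dossier()].
#' @export
read_dossier <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  pods <- lapply(names(cfg$pods), function(ep) {
    p <- cfg$pods[[ep]]
    point_of_departure(value = p$value, pod_type = p$pod_type, route = p$route,
                       endpoint = ep, species = p$species %||% "unknown",
                       study_duration_weeks = p$study_duration_weeks)
  })
  names(pods) <- names(cfg$pods)
  substance_dossier(name = cfg$name, molecular_weight = cfg$molecular_weight,
                    oel_ppm = cfg$oel_ppm, oel_mgm3 = cfg$oel_mgm3,
                    slope_factor = cfg$slope_factor, pods = pods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
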