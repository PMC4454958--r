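# Writes a small measurement table to a temp file in the package's CSV/TSV
# dialect and returns the path.
write_exposure_file <- function(concentration,
                                workplace_id = rep("A", length(concentration)),
                                sample_kind = rep("personal", length(concentration)),
                                units = "mg/m3", ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext == "csv") "," else "\t"
  lines <- c(sprintf("# units: %s", units),
             paste(c("workplace_id", "sample_kind", "concentration"),
                   collapse = sep),
             paste(workplace_id, sample_kind, concentration, sep = sep))
  writeLines(lines, path)
  path
}

kosha <- correction_schema("KOSHA")

biphenyl_rfcs <- function(schema = kosha) {
  d <- biphenyl_dossier()
  lapply(d$pods, rfc_work, schema = schema)
}
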