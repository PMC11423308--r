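#' Read and write crosspeak intensity tables
#'
#' The on-disk format is a long CSV with columns `label`, `spectrum_kind`,
#' `time_s`, `S`, `S0`, `noise_sigma` and optional `site`,
#' `ambiguity_group`; one row per (crosspeak, dephasing time).
#'
#' @param path CSV file path.
#' @return `read_intensity_csv()`: a list of [crosspeak_record()].
#' @export
read_intensity_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read intensity table: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "spectrum_kind", "time_s", "S", "S0", "noise_sigma")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("intensity table lacks column(s): ", paste(missing, collapse = ", "))
  if (is.null(d$site)) d$site <- NA_character_
  if (is.null(d$ambiguity_group)) d$ambiguity_group <- NA_character_
  lapply(split(d, d$label), function(sub) {
    sub <- sub[order(sub$time_s), ]
    crosspeak_record(label = sub$label[1], times = sub$time_s,
                     S = sub$S, S0 = sub$S0,
                     noise_sigma = sub$noise_sigma[1],
                     spectrum_kind = sub$spectrum_kind[1],
                     site = sub$site[1],
                     ambiguity_group = sub$ambiguity_group[1])
  })
}

#' @rdname read_intensity_csv
#' @param records List of [crosspeak_record()].
#' @export
write_intensity_csv <- function(records, path) {
  rows <- lapply(records, function(r)
    data.frame(label = r$label, spectrum_kind = r$spectrum_kind,
               time_s = r$times, S = r$S, S0 = r$S0,
               noise_sigma = r$noise_sigma, site = r$site,
               ambiguity_group = r$ambiguity_group))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export a buildup curve as CSV
#'
#' Columns `time_s`, `fraction`, `sigma`.
#'
#' @param curve A [assemble_buildup()] result.
#' @param path Output path.
#' @export
write_buildup_csv <- function(curve, path) {
  utils::write.csv(data.frame(time_s = curve$time, fraction = curve$fraction,
                              sigma = curve$sigma),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a per-site dynamics table as CSV
#'
#' @param table A [build_site_table()] result.
#' @param path Output path.
#' @export
write_site_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' Records the package version, seed, configuration (with an md5 hash) and
#' any result fields as JSON next to the run's outputs.
#'
#' @param path Output JSON path.
#' @param config List of configuration values used for the run.
#' @param seed Integer seed used for the run (NA if deterministic).
#' @param ... Further named result fields to record.
#' @export
write_run_summary <- function(path, config = list(), seed = NA_integer_,
                              ...) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  out <- list(tool = "redordyn",
              version = as.character(utils::packageVersion("redordyn")),
              seed = seed, config = config, config_md5 = hash, ...)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
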