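# Delimited-table I/O. All tables are comma-separated with a header row,
# UTF-8, one row per sample; delta values in permil vs air N2, water
# concentrations in uM, droplet concentrations in mM. Missing measurements
# are empty cells (read back as NA), never sentinel zeros.

.read_table <- function(path, required, label) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s",
                                       label, path), call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s table lacks column(s): %s", label,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x
}

#' Read and write field-sample tables
#'
#' Readers validate the presence of the required columns for each sample
#' kind and return plain data.frames; writers emit the same dialect the
#' readers consume. Water tables require `site_id`, `distance_m`, `pH`,
#' `temp_C`, `nhx_uM` (optional: `no3_uM`, `d15N_TDN_permil`,
#' `d15N_NO3_permil`, `sulfide_uM`); droplet tables require `site_id`,
#' `distance_m`, `droplet_type`, `pH`, `nh4_mM`, `d15N_nh4_permil`; air
#' tables require `site_id`, `sampler`, `distance_m`, `nh3_ppbv`,
#' `d15N_permil`, `quality_flag`.
#'
#' @param path file path of a CSV table.
#' @return A data.frame (readers) or the path, invisibly (writers).
#' @name sample_tables
NULL

#' @rdname sample_tables
#' @export
read_water_samples <- function(path) {
  .read_table(path, c("site_id", "distance_m", "pH", "temp_C", "nhx_uM"),
              "water")
}

#' @rdname sample_tables
#' @export
read_droplet_samples <- function(path) {
  .read_table(path, c("site_id", "distance_m", "droplet_type", "pH",
                      "nh4_mM", "d15N_nh4_permil"), "droplet")
}

#' @rdname sample_tables
#' @export
read_air_samples <- function(path) {
  .read_table(path, c("site_id", "sampler", "distance_m", "nh3_ppbv",
                      "d15N_permil", "quality_flag"), "air")
}

#' @rdname sample_tables
#' @param x a data.frame to write.
#' @export
write_sample_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Write a synthetic campaign to a directory
#'
#' Emits `water.csv`, `droplets.csv` and `air.csv` in the shared table
#' dialect.
#'
#' @param campaign an `nhx_campaign` from [generate_campaign()].
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "nhx_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sample_table(campaign$water, file.path(dir, "water.csv"))
  write_sample_table(campaign$droplets, file.path(dir, "droplets.csv"))
  write_sample_table(campaign$air, file.path(dir, "air.csv"))
  invisible(dir)
}
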