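#' Export simulation tables
#'
#' Plain-text writers for the simulator's standard outputs: a lineage table
#' consumable by Muller-plot tools, the per-cell metaphenotype table, long-
#' format field values, and agent snapshots.
#'
#' @param sim An `mp_sim`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name exports
NULL

#' @rdname exports
#' @export
write_lineage_csv <- function(sim, path) {
  utils::write.csv(sim$lineage, path, row.names = FALSE)
  invisible(path)
}

#' @rdname exports
#' @export
write_mp_csv <- function(sim, path) {
  mp <- dplyr::bind_cols(tibble::tibble(time = max(sim$timeseries$time)),
                         sim$mp_final)
  utils::write.csv(mp, path, row.names = FALSE)
  invisible(path)
}

#' Long-format field export
#'
#' @param fields An `mp_fields`.
#' @param path Output CSV path.
#' @param time Time stamp column value.
#' @return `path`, invisibly. Columns: `t`, `x`, `y`, `field`, `value`
#'   (protons are additionally reported as `pH`).
#' @export
write_fields_csv <- function(fields, path, time = NA_real_) {
  nx <- nrow(fields$oxygen); ny <- ncol(fields$oxygen)
  grid <- tidyr::expand_grid(y = seq_len(ny), x = seq_len(nx))
  long <- purrr::map_dfr(c("oxygen", "glucose", "protons", "drug"),
                         function(f) {
                           tibble::tibble(t = time, x = grid$x, y = grid$y,
                                          field = f,
                                          value = as.vector(fields[[f]]))
                         })
  ph <- tibble::tibble(t = time, x = grid$x, y = grid$y, field = "pH",
                       value = as.vector(pH_of(fields$protons)))
  utils::write.csv(dplyr::bind_rows(long, ph), path, row.names = FALSE)
  invisible(path)
}

#' Snapshot container
#'
#' Writes a directory of plain CSV tables (`timeseries.csv`,
#' `metaphenotypes.csv`, `lineage.csv`, `cells.csv`, `tcells.csv`,
#' `vessels.csv`, `kills.csv`, `fields.csv`) plus the run's configuration as
#' YAML, keyed by the final recorded time.
#'
#' @param sim An `mp_sim`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_snapshot_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(sim$timeseries, "timeseries.csv")
  w(sim$mp_timeseries, "metaphenotypes.csv")
  w(sim$lineage, "lineage.csv")
  w(sim$cells, "cells.csv")
  w(sim$tcells, "tcells.csv")
  w(sim$vessels, "vessels.csv")
  w(sim$kill_log, "kills.csv")
  write_fields_csv(sim$fields, file.path(dir, "fields.csv"),
                   time = max(sim$timeseries$time))
  write_sim_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
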