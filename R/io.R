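#' Write a trajectory to TSV with a JSON metadata sidecar
#'
#' The event table is written as tab-separated text with a documented header
#' (`time_s`, `event`, `n_me0`..`n_me3`, `tx_cum`, `promoter`, `alpha`,
#' `n_exchange`); run metadata (variant, seed, full parameter snapshot with
#' primitive fields only) goes to `<path>.json`.
#'
#' @param traj a `chromatin_trajectory` with recorded events.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "chromatin_trajectory"), !is.null(traj$events))
  utils::write.table(traj$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(
    variant = traj$variant,
    seed = traj$seed,
    t_end_s = traj$t_end,
    params = params_primitives(traj$params),
    burst = if (!is.null(traj$burst)) {
      traj$burst[c("k_on_max", "k_off", "f_min", "fold_change")]
    }
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory TSV written by [write_trajectory_tsv()]
#'
#' @param path TSV path.
#' @return A data frame of events; the parsed sidecar (if present) is
#'   attached as attribute `meta`.
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    attr(df, "meta") <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  df
}

# primitive (serializable) parameter fields, derived fields never serialized
params_primitives <- function(params) {
  params[c("N", "cell_cycle_hr", "beta", "k_me", "rho_me2", "f_min", "f_max",
           "P_T", "p_dem", "p_ex", "f_cap", "alpha", "replication_survival")]
}

#' Serialize chromatin parameters to JSON or YAML
#'
#' Only primitive fields are written; derived quantities are recomputed on
#' read.
#'
#' @param params a [chromatin_params()] object.
#' @param path output path; format chosen by extension (`.json`, `.yaml` /
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  prim <- params_primitives(params)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to write YAML parameter files")
    }
    yaml::write_yaml(prim, path)
  } else {
    jsonlite::write_json(prim, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read chromatin parameters from JSON or YAML
#'
#' @param path file written by [write_params()] (or hand-authored with the
#'   same primitive fields; missing fields take their defaults).
#' @return A [chromatin_params()] object with derived fields recomputed.
#' @export
read_params <- function(path) {
  prim <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read YAML parameter files")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(chromatin_params, prim)
}

#' Write / read a SILAC measurement table as CSV
#'
#' Columns: `time_hr`, `pool`, `replicate`, `me3_fraction`.
#'
#' @param silac_table data frame, e.g. from [synthetic_silac()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_silac_csv <- function(silac_table, path) {
  stopifnot(all(c("time_hr", "pool", "replicate", "me3_fraction") %in%
                  names(silac_table)))
  utils::write.csv(silac_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_silac_csv
#' @export
read_silac_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_hr", "pool", "replicate", "me3_fraction") %in%
                  names(df)),
            all(df$me3_fraction >= 0 & df$me3_fraction <= 1))
  df
}

#' Export a regulator trace as TSV
#'
#' Columns `time_s`, `mRNA`, `protein`, `alpha`; reusable as a replayable
#' input record.
#'
#' @param trace data frame from [simulate_regulator()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_regulator_tsv <- function(trace, path) {
  stopifnot(all(c("time_s", "mRNA", "protein", "alpha") %in% names(trace)))
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
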