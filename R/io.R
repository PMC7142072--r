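#' Read and write the study's file formats
#'
#' Plain-text dialects shared by all stages (UTF-8, '.' decimal separator,
#' mandatory headers):
#' * forcing CSV: `t_day,T_surface_C,T_deep_C,F_gC_per_L` (`T_deep_C`
#'   optional);
#' * tunnel CSV: `t_day,lower,upper,variable`;
#' * trajectory CSV: `t_day,cm_gC,bd_cm,wm_g,P,I,A,R_O2,R_C,Ex,Re,Eg,dG`;
#' * results TSV: the [evaluate_space()] table.
#'
#' Readers validate structure and report the offending file; writers refuse
#' to write malformed objects.
#'
#' @param path file path.
#' @param forcing a [forcing_series()].
#' @param tunnels a [tunnel_set()].
#' @param trajectory a [simulate_jelly()] trajectory.
#' @param results an [evaluate_space()] table.
#' @name study_io
NULL

#' @rdname study_io
#' @export
read_forcing_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_day", "T_surface_C", "F_gC_per_L")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("forcing file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  forcing_series(df$t_day, df$T_surface_C,
                 if ("T_deep_C" %in% names(df)) df$T_deep_C else NA,
                 df$F_gC_per_L)
}

#' @rdname study_io
#' @export
write_forcing_csv <- function(forcing, path) {
  stopifnot(inherits(forcing, "jelly_forcing"))
  write.csv(as.data.frame(forcing), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_tunnels_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_day", "lower", "upper", "variable")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("tunnel file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  variable <- unique(df$variable)
  if (length(variable) != 1)
    stop("tunnel file '", path, "' mixes compared variables")
  tunnel_set(df$t_day, df$lower, df$upper, variable)
}

#' @rdname study_io
#' @export
write_tunnels_csv <- function(tunnels, path) {
  stopifnot(inherits(tunnels, "jelly_tunnel"))
  df <- as.data.frame(tunnels)
  df$variable <- attr(tunnels, "variable")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "jelly_trajectory"))
  write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t_day", "cm_gC", "bd_cm", "wm_g", "Eg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trajectory file '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  attr(df, "n_valid") <- sum(!is.na(df$cm_gC))
  attr(df, "status") <- if (anyNA(df$cm_gC)) "exhausted" else "ok"
  class(df) <- c("jelly_trajectory", "data.frame")
  df
}

#' @rdname study_io
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_results_tsv <- function(path) {
  read.delim(path)
}

#' Run manifest
#'
#' A YAML snapshot of a run: configuration, seeds and produced files, so a
#' deterministic stage can be reproduced bit-for-bit from the manifest
#' alone.
#'
#' @param path manifest path.
#' @param config named list of configuration values (should include seeds).
#' @param files named list describing every produced file.
#' @return `write_run_manifest()` returns the path invisibly;
#'   `read_run_manifest()` the manifest list.
#' @export
write_run_manifest <- function(path, config, files) {
  yaml::write_yaml(list(package = "jellysmc",
                        version = as.character(utils::packageVersion("jellysmc")),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                        config = config, files = files),
                   path)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  yaml::read_yaml(path)
}
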