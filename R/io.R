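#' Read a binary SLE dataset from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row naming at least
#' the columns `x1`, `T_K` and `branch`. Rows are validated (mole fractions
#' in `[0, 1]`, positive temperatures, branch 1 or 2); malformed rows are
#' reported by line number in a typed parse error.
#'
#' @param path path to the CSV file.
#' @param name1,name2 optional component labels (default from the file name).
#' @return An [sle_dataset()].
#' @export
read_sle_csv <- function(path, name1 = "Component 1", name2 = "Component 2") {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  missing_cols <- setdiff(c("x1", "T_K", "branch"), names(raw))
  if (length(missing_cols))
    stop_parse(sprintf("missing required column(s): %s",
                       paste(missing_cols, collapse = ", ")))
  # report offending data lines (+1 for the header) before constructing
  x1 <- suppressWarnings(as.numeric(raw$x1))
  T_K <- suppressWarnings(as.numeric(raw$T_K))
  br <- suppressWarnings(as.integer(raw$branch))
  bad <- which(!is.finite(x1) | x1 < 0 | x1 > 1 |
                 !is.finite(T_K) | T_K <= 0 | !br %in% c(1L, 2L))
  if (length(bad))
    stop_parse(sprintf("invalid row(s) at file line(s): %s",
                       paste(bad + 1L, collapse = ", ")))
  sle_dataset(data.frame(x1 = x1, T_K = T_K, branch = br),
              name1 = name1, name2 = name2,
              provenance = sprintf("read from %s", path))
}

#' Write a binary SLE dataset to CSV
#'
#' Writes the `(x1, T_K, branch)` dialect that [read_sle_csv()] reads back,
#' with 10 significant digits so round trips are stable.
#'
#' @param dataset an [sle_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sle_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "sle_dataset"))
  d <- as.data.frame(dataset)
  d$x1 <- sprintf("%.10g", d$x1)
  d$T_K <- sprintf("%.10g", d$T_K)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sweep configuration from YAML
#'
#' The config file mirrors [sweep_config()]: keys `mode`, `Tm1`, `Tm2`,
#' `dSm1`, `dSm2`, `dHm1`, `dHm2`, `a1`, `a2`. Energies may be given in
#' kJ/mol by setting `units: kJ/mol` (they are converted to J/mol on read;
#' temperatures are always K).
#'
#' @param path path to the YAML file.
#' @return A [sweep_config()].
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse(sprintf(
                    "cannot parse %s: %s", path, conditionMessage(e))))
  scale <- 1
  if (!is.null(cfg$units)) {
    scale <- switch(cfg$units,
                    `J/mol` = 1, `kJ/mol` = 1000,
                    stop_parse(sprintf("unknown units '%s'", cfg$units)))
  }
  energy <- function(v) if (is.null(v)) NULL else unlist(v) * scale
  sweep_config(mode = cfg$mode %||% "ideal",
               Tm1 = unlist(cfg$Tm1) %||% 600, Tm2 = unlist(cfg$Tm2) %||% 300,
               dSm1 = unlist(cfg$dSm1) %||% "walden",
               dSm2 = unlist(cfg$dSm2) %||% "walden",
               dHm1 = energy(cfg$dHm1), dHm2 = energy(cfg$dHm2),
               a1 = energy(cfg$a1) %||% 0, a2 = energy(cfg$a2) %||% 0)
}

#' Write a eutectic-point summary as JSON
#'
#' Machine-readable summary with keys `x1_e`, `Te_K`, `norm_depression`,
#' `gamma1_e`, `gamma2_e`.
#'
#' @param ep an [eutectic_point()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eutectic_json <- function(ep, path) {
  stopifnot(inherits(ep, "eutectic_point"))
  jsonlite::write_json(
    list(x1_e = ep$x1_e, Te_K = ep$Te, norm_depression = ep$norm_depression,
         gamma1_e = ep$gamma1_e, gamma2_e = ep$gamma2_e),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of artifacts: the subcommand (or calling
#' function), an md5 digest of the configuration inputs, the seed(s), the
#' package version and a timestamp. Re-running with an identical manifest's
#' inputs reproduces the outputs.
#'
#' @param path output JSON path.
#' @param subcommand name of the operation run.
#' @param config any serializable configuration object (digested, not stored).
#' @param seed integer seed(s) used, or `NULL` for deterministic runs.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, config = NULL, seed = NULL) {
  digest <- {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(utils::capture.output(utils::str(config)), tmp)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(
    subcommand = subcommand,
    config_digest = digest,
    seed = seed,
    package = "slekit",
    version = as.character(utils::packageVersion("slekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
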