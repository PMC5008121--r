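# Delimited-text I/O and run manifests.
#
# All tabular files are comma-separated with a header row; empty cells
# encode missing values.

.read_csv <- function(path) {
  if (!file.exists(path)) stop_sspm("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"))
}

.check_numeric <- function(df, cols, path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         na.strings = c("", "NA"))
  for (cn in intersect(cols, names(raw))) {
    v <- raw[[cn]]
    bad <- which(!is.na(v) & is.na(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop_sspm("non-numeric value '", v[bad[1]], "' in ", basename(path),
                ", row ", bad[1], ", column '", cn, "'")
  }
}

#' Read a counts file
#'
#' Expects columns `year`, `pairs`, `chicks`; validates that every cell is
#' numeric and names the offending row and column otherwise.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_counts <- function(path) {
  df <- .read_csv(path)
  need <- c("year", "pairs", "chicks")
  if (!all(need %in% names(df)))
    stop_sspm(basename(path), " needs columns: ",
              paste(need, collapse = ", "))
  .check_numeric(df, need, path)
  df
}

#' Read a survival-estimates file
#'
#' Expects columns `year`, `age_class`, `estimate`, `ci_low`, `ci_high`.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_survival <- function(path) {
  df <- .read_csv(path)
  need <- c("year", "age_class", "estimate", "ci_low", "ci_high")
  if (!all(need %in% names(df)))
    stop_sspm(basename(path), " needs columns: ",
              paste(need, collapse = ", "))
  .check_numeric(df, setdiff(need, "age_class"), path)
  df
}

#' Read a raw covariate file
#'
#' Expects columns `year`, `P`, `S`, `M`, `E`, `A`, `D` (raw scales, empty
#' cells = missing), suitable for [covariate_matrix()].
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  df <- .read_csv(path)
  need <- c("year", "P", "S", "M", "E", "A", "D")
  if (!all(need %in% names(df)))
    stop_sspm(basename(path), " needs columns: ",
              paste(need, collapse = ", "))
  .check_numeric(df, need, path)
  df
}

#' Write the files of a simulated scenario
#'
#' Writes `counts.csv`, `replicates.csv`, `survival.csv`,
#' `covariates.csv` (raw scales with missing cells empty),
#' `truth_rates.csv`, `truth_states.csv` and a `config.yaml` snapshot.
#'
#' @param sim output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                        row.names = FALSE, na = "")
  w(sim$counts, "counts.csv")
  w(sim$replicates, "replicates.csv")
  w(sim$survival, "survival.csv")
  w(sim$raw_covariates, "covariates.csv")
  years <- sim$counts$year
  w(data.frame(year = years, phi_f = sim$truth$phi_f,
               phi_a = sim$truth$phi_a, b = sim$truth$b), "truth_rates.csv")
  st <- as.data.frame(t(sim$truth$N))
  names(st) <- paste0("stage", 1:6)
  w(cbind(year = years, st, chicks_f = sim$truth$chicks),
    "truth_states.csv")
  cfg <- sim$config
  cfg$surv_coef <- unclass(cfg$surv_coef)
  cfg$prod_coef <- lapply(unclass(cfg$prod_coef), as.list)
  yaml::write_yaml(list(scenario = lapply(cfg, function(z)
    if (is.numeric(z)) as.numeric(z) else z), seed = sim$seed),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a run manifest
#'
#' Every pipeline output directory gets exactly one `manifest.yaml`
#' recording the configuration snapshot, input-file checksums, seeds,
#' package version and a timestamp, so any output is reconstructible.
#'
#' @param dir output directory.
#' @param config named list (configuration snapshot).
#' @param inputs character vector of input file paths (checksummed).
#' @param seeds named list or vector of seeds.
#' @return invisibly, the manifest path.
#' @export
write_manifest <- function(dir, config = list(), inputs = character(),
                           seeds = list()) {
  inputs <- inputs[file.exists(inputs)]
  man <- list(
    package = "sspopdyn",
    version = as.character(utils::packageVersion("sspopdyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds,
    config = config,
    inputs = if (length(inputs))
      as.list(stats::setNames(as.character(tools::md5sum(inputs)),
                              basename(inputs))) else list())
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param dir directory containing `manifest.yaml`.
#' @return named list.
#' @export
read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.yaml")
  if (!file.exists(p)) stop_sspm("no manifest.yaml in ", dir)
  yaml::read_yaml(p)
}
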