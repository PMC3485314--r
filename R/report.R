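#' Report writers
#'
#' Machine-readable outputs for a run: per-draw CSV dumps, a JSON + plain
#' text summary table (one row per quantity: `M_0`, `W_bpr`, `alpha`,
#' `r`, `h`), and a manifest tying the outputs to the configuration hash,
#' seed and scenario.
#'
#' @name report
NULL

#' Write the summary table
#'
#' @param ens an `ensemble_result`.
#' @param path output path for the JSON document; a sibling `.txt` with
#'   the aligned table is written next to it.
#' @return the summary data frame, invisibly.
#' @export
write_summary <- function(ens, path) {
  if (!nrow(ens$draws) || !nrow(ens$pops)) stop("empty ensemble")
  s <- summarize_ensemble(ens)
  sp <- attr(s, "spearman")
  payload <- list(
    scenario = ens$scenario,
    seed = ens$seed,
    n_draws = nrow(ens$draws),
    n_pops = nrow(ens$pops),
    filtered = ens$filtered,
    rho = ens$rho,
    quantile_method = attr(s, "quantile_method"),
    quantities = lapply(stats::setNames(rownames(s), rownames(s)),
                        function(q) as.list(s[q, ])),
    spearman = list(M0_r = unname(sp$draws["M0", "r"]),
                    M0_h = unname(sp$pops["M0", "h"]),
                    M0_alpha = unname(sp$pops["M0", "alpha"]))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(c(
    sprintf("scenario: %s  (n_draws = %d, n_pops = %d%s)", ens$scenario,
            nrow(ens$draws), nrow(ens$pops),
            if (ens$filtered) ", accept-reject filtered" else ""),
    utils::capture.output(print(s))
  ), txt)
  invisible(s)
}

#' Write the per-draw tables
#'
#' `draws.csv` has one row per Leslie draw (`M0`, `r`, `W_bpr`, `h`);
#' `pops.csv` one row per replicate population (`M0`, `alpha`, `W_bpr`,
#' `h`).
#'
#' @param ens an `ensemble_result`.
#' @param dir output directory (created if missing).
#' @return character vector of the files written.
#' @export
write_draws <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "draws.csv")
  f2 <- file.path(dir, "pops.csv")
  utils::write.csv(ens$draws[, c("draw", "M0", "r", "W_bpr", "h")], f1,
                   row.names = FALSE)
  utils::write.csv(ens$pops[, c("pop", "M0", "alpha", "W_bpr", "h")], f2,
                   row.names = FALSE)
  c(f1, f2)
}

# 32-bit FNV-1a over the serialized normalized configuration.
config_hash <- function(cfg) {
  bytes <- as.integer(serialize(config_as_list(cfg), connection = NULL,
                                version = 2))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; multiply in 16-bit halves to stay
    # exact in double arithmetic
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest
#'
#' @param ens an `ensemble_result`.
#' @param files output files the manifest covers.
#' @return named list (config hash, seed, scenario, draw counts, package
#'   version, file list).
#' @export
run_manifest <- function(ens, files = character()) {
  list(
    package = "demopriors",
    version = as.character(utils::packageVersion("demopriors")),
    config_hash = config_hash(ens$cfg),
    seed = ens$seed,
    scenario = ens$scenario,
    rho = ens$rho,
    n_draws = nrow(ens$draws),
    n_pops = nrow(ens$pops),
    pop_size = ens$pop_size,
    filtered = ens$filtered,
    files = as.list(basename(files))
  )
}

#' Write a complete run directory
#'
#' `draws.csv`, `pops.csv`, `summary.json`, `summary.txt` and
#' `manifest.json`.
#'
#' @param ens an `ensemble_result`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_run <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_draws(ens, dir)
  sj <- file.path(dir, "summary.json")
  write_summary(ens, sj)
  files <- c(files, sj, file.path(dir, "summary.txt"))
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(run_manifest(ens, c(files, mf)), mf,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(dir)
}

#' Observed young-of-the-year mortality rates (reference table)
#'
#' Published instantaneous and cumulative mortality-rate observations for
#' young-of-the-year tunas and small pelagic species, bundled for
#' comparison plots and magnitude checks against the simulated daily
#' rates.  Ages are days post-hatching or post exogenous feeding, as
#' recorded in the `age_unit` column.
#'
#' @return data frame with columns `species`, `age_days`, `age_unit`,
#'   `type` (`instantaneous` or `cumulative`), `rate` and `reference`.
#' @export
observed_yoy_mortality <- function() {
  path <- system.file("extdata", "observed_yoy_mortality.csv",
                      package = "demopriors", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
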