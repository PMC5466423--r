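# 32-bit FNV-1a hash of a character scalar; used to fingerprint the
# configuration recorded in output headers
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # h * 16777619 mod 2^32 in 16-bit halves (stays within double precision)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# '#'-prefixed metadata header lines: tool version, seed, config fingerprint
metadata_header <- function(seed = NULL, config = NULL) {
  version <- tryCatch(
    as.character(utils::packageVersion("vibriopassage")),
    error = function(e) "unknown")
  lines <- c(sprintf("# vibriopassage %s", version))
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %s", seed))
  if (!is.null(config)) {
    cfg <- paste(names(config), vapply(config, function(v)
      paste(format(v, trim = TRUE), collapse = ","), character(1)),
      sep = "=", collapse = "; ")
    lines <- c(lines, sprintf("# config: %s", cfg),
               sprintf("# config_hash: %s", fnv1a32(cfg)))
  }
  lines
}

#' Write a table as TSV with a commented metadata header
#'
#' Writes a data frame as tab-separated values preceded by `#`-prefixed
#' metadata lines (package version, RNG seed, configuration fingerprint).
#' Column order is preserved; output is deterministic for identical inputs
#' (no timestamps).
#'
#' @param data Data frame.
#' @param path Output path.
#' @param seed Optional seed to record in the header.
#' @param config Optional named list of configuration values to record
#'   (with an FNV-1a fingerprint).
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, seed = NULL, config = NULL) {
  stopifnot(is.data.frame(data))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(metadata_header(seed, config), con)
  utils::write.table(data, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a survival surface as TSV
#'
#' Header row of selection coefficients, first column the origin
#' generation `t`, body the survival probabilities; preceded by the
#' standard metadata header.
#'
#' @param surface A [survival_surface()] object.
#' @param path Output path.
#' @inheritParams write_table
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, seed = NULL) {
  stopifnot(inherits(surface, "survival_surface"))
  wide <- data.frame(t = surface$t_values, surface$survival,
                     check.names = FALSE)
  names(wide) <- c("t", paste0("s=", as.character(surface$s_values)))
  write_table(wide, path, seed = seed,
              config = list(tau = surface$tau, label = surface$label))
}

#' Write a passage trajectory as TSV
#'
#' Long-format trajectory (`passage`, `cycle`, `generation`,
#' `genotype_id`, `s`, `count`) with the standard metadata header. An empty
#' trajectory writes a header-only file.
#'
#' @param trajectory A [run_passage_series()] result, or a data frame in
#'   the trajectory schema.
#' @param path Output path.
#' @inheritParams write_table
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, seed = NULL, config = NULL) {
  if (inherits(trajectory, "passage_trajectory")) {
    if (is.null(seed)) seed <- trajectory$seed
    trajectory <- trajectory$trajectory
  }
  if (is.null(trajectory))
    trajectory <- data.frame(passage = integer(), cycle = integer(),
                             generation = integer(),
                             genotype_id = character(), s = numeric(),
                             count = numeric())
  write_table(trajectory, path, seed = seed, config = config)
}

#' Read a competition-observation table
#'
#' Reads a TSV of per-host competition observations (schema of
#' [estimate_selection()]; `#`-prefixed header lines are ignored),
#' validates column presence, numeric types, count non-negativity, and
#' frequency/density domains, and reports offending rows by number.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame of observations.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  obs <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_observations(obs, where = path)
  obs
}

#' Write a competition-observation table
#'
#' Inverse of [read_observations()]: writes the observation schema as TSV
#' with the standard metadata header, in deterministic column order.
#'
#' @param obs Observation data frame.
#' @param path Output path.
#' @inheritParams write_table
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path, seed = NULL, config = NULL) {
  validate_observations(obs, "obs")
  write_table(obs[, observation_columns()], path, seed = seed,
              config = config)
}
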