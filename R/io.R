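# Readers and writers. Tables are comma-delimited UTF-8 text with a
# header row; connectivity uses a long edge-list format (one row per
# unordered region pair per participant); fitted chains are stored in an
# output directory with a JSON manifest recording seed and config.

#' Read connectivity from a long-format edge list
#'
#' Expects columns `participant_id,region_u,region_v,value` with 1-based
#' region labels. Rows may appear in either orientation; duplicate
#' (u,v)/(v,u) entries must agree within 1e-9 or an error names the
#' offending line. Participants are ordered as first encountered. Pairs
#' absent from the file are missing entries.
#'
#' @param path CSV file path.
#' @param n_regions Optional V (default: the largest region label seen).
#' @return A `connectivity_data`.
#' @export
read_connectivity <- function(path, n_regions = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "region_u", "region_v", "value")
  if (!all(need %in% names(df))) {
    stop("missing header column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  }
  u <- as.integer(df$region_u); v <- as.integer(df$region_v)
  if (any(is.na(u) | is.na(v)) || any(u < 1L) || any(v < 1L) || any(u == v)) {
    bad <- which(is.na(u) | is.na(v) | u < 1L | v < 1L | u == v)[1L]
    stop("invalid region pair at line ", bad + 1L)
  }
  V <- if (is.null(n_regions)) max(u, v) else as.integer(n_regions)
  if (max(u, v) > V) {
    bad <- which(pmax(u, v) > V)[1L]
    stop("unknown region label at line ", bad + 1L, ": exceeds V = ", V)
  }
  ids <- unique(df$participant_id)
  N <- length(ids)
  pairs <- edge_pairs(V)
  M <- nrow(pairs)
  E <- matrix(NA_real_, N, M)
  row_i <- match(df$participant_id, ids)
  col_j <- pair_index(u, v, V)
  for (r in seq_len(nrow(df))) {
    cur <- E[row_i[r], col_j[r]]
    val <- df$value[r]
    if (!is.na(cur)) {
      if (is.na(val) || abs(cur - val) > 1e-9) {
        stop("conflicting duplicate edge at line ", r + 1L, " (participant ",
             df$participant_id[r], ", pair ", u[r], ",", v[r], ")")
      }
    } else {
      E[row_i[r], col_j[r]] <- val
    }
  }
  connectivity_data(E, n_regions = V, participant_ids = ids)
}

#' Write connectivity as a long-format edge list
#'
#' @param conn A `connectivity_data`.
#' @param path Output CSV path.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_data"))
  N <- conn$n_participants; M <- nrow(conn$pairs)
  vals <- as.numeric(t(conn$edges))
  obs <- as.logical(t(conn$mask))
  df <- data.frame(
    participant_id = rep(conn$participant_ids, each = M),
    region_u = rep(conn$pairs[, "u"], N),
    region_v = rep(conn$pairs[, "v"], N),
    value = vals
  )[obs, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read behavior outcomes aligned to a connectivity object
#'
#' One row per participant; `participant_id` must be the first column and
#' every connectivity participant must appear exactly once. Remaining
#' columns are outcome items.
#'
#' @param path CSV file path.
#' @param conn Optional `connectivity_data` whose participant order the
#'   rows are aligned to.
#' @return A `behavior_data`.
#' @export
read_behavior <- function(path, conn = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1L] != "participant_id") {
    stop("first column must be participant_id")
  }
  ids <- df$participant_id
  if (!is.null(conn)) {
    extra <- setdiff(ids, conn$participant_ids)
    if (length(extra)) {
      stop("behavior rows for unknown participant(s): ",
           paste(extra, collapse = ", "))
    }
    missing_ <- setdiff(conn$participant_ids, ids)
    if (length(missing_)) {
      stop("no behavior row for participant(s): ",
           paste(missing_, collapse = ", "))
    }
    df <- df[match(conn$participant_ids, ids), , drop = FALSE]
    ids <- df$participant_id
  }
  Y <- as.matrix(df[, -1L, drop = FALSE])
  behavior_data(Y, item_labels = colnames(Y), participant_ids = ids)
}

#' Read a participant covariate table
#'
#' One row per participant, `participant_id` first, remaining columns
#' numeric covariates. An intercept column of ones is prepended, giving
#' a matrix usable as the `covariates` slot of [connectivity_data()] or
#' [behavior_data()].
#'
#' @param path CSV file path.
#' @param conn Optional `connectivity_data` whose participant order the
#'   rows are aligned to.
#' @return Numeric matrix with first column identically 1.
#' @export
read_covariates <- function(path, conn = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1L] != "participant_id") {
    stop("first column must be participant_id")
  }
  ids <- df$participant_id
  if (!is.null(conn)) {
    extra <- setdiff(ids, conn$participant_ids)
    if (length(extra)) {
      stop("covariate rows for unknown participant(s): ",
           paste(extra, collapse = ", "))
    }
    missing_ <- setdiff(conn$participant_ids, ids)
    if (length(missing_)) {
      stop("no covariate row for participant(s): ",
           paste(missing_, collapse = ", "))
    }
    df <- df[match(conn$participant_ids, ids), , drop = FALSE]
  }
  X <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("covariates must be numeric")
  cbind(intercept = 1, X)
}

#' Write behavior outcomes
#'
#' @param behav A `behavior_data`.
#' @param path Output CSV path.
#' @export
write_behavior <- function(behav, path) {
  stopifnot(inherits(behav, "behavior_data"))
  Y <- behav$outcomes
  Y[!behav$mask] <- NA
  df <- data.frame(participant_id = behav$participant_ids, Y)
  names(df)[-1L] <- behav$item_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.RUN_CONFIG_KEYS <- c(
  "connectivity", "behavior", "covariates", "out",
  "n_iterations", "burn_in", "thinning", "n_starts", "seed",
  "store_latents", "region_marginal_prior", "verbose",
  "n_participants", "n_regions", "snr", "signal_proportion",
  "cross_cov_value", "behavior_noise_var", "n_behavior_items",
  "mode", "test", "test_size", "n_repeats", "p_threshold",
  "iterations", "burnin", "n", "regions", "prop", "grid", "log_level"
)

#' Read a run configuration file
#'
#' Accepts YAML or JSON. The schema is strict: unknown keys are rejected
#' so a typo cannot silently change a run.
#'
#' @param path Config file path (`.yaml`, `.yml` or `.json`).
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.list(cfg)) stop("config must be a mapping of key: value pairs")
  unknown <- setdiff(names(cfg), .RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

.FIT_SCHEMA <- 1L

#' Persist a fitted chain to a directory
#'
#' Writes the draws container (`samples.rds`), the biomarker report as
#' CSV, and a JSON manifest recording the schema version, seed, sampler
#' settings and a config hash. [read_fit()] restores the draws
#' bit-exactly.
#'
#' @param samples A `posterior_samples`.
#' @param out_dir Output directory (created if absent).
#' @param report Optional `biomarker_report` to include.
#' @export
write_fit <- function(samples, out_dir, report = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rds <- file.path(out_dir, "samples.rds")
  saveRDS(samples, rds)
  cfg <- list(n_iterations = samples$n_iterations, burn_in = samples$burn_in,
              thinning = samples$thinning, seed = samples$seed,
              n_retained = samples$n_retained)
  manifest <- list(
    schema_version = .FIT_SCHEMA,
    config = cfg,
    config_hash = unname(tools::md5sum(rds)),
    n_regions = ncol(samples$cross_cov)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(report)) {
    write_biomarker_report(report, file.path(out_dir, "biomarkers.csv"))
  }
  invisible(out_dir)
}

#' Restore a fitted chain from a directory
#'
#' @param out_dir Directory written by [write_fit()].
#' @return The `posterior_samples` object.
#' @export
read_fit <- function(out_dir) {
  mf <- file.path(out_dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version), .FIT_SCHEMA)) {
    stop("fit schema version ", manifest$schema_version,
         " not supported (expected ", .FIT_SCHEMA, ")")
  }
  readRDS(file.path(out_dir, "samples.rds"))
}
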