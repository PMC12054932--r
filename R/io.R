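#' Read a linear-method count table
#'
#' One row per sample.  Required columns: `sample_id`, `x`, `n`, `N1`,
#' `Ybar1`, `s1`, `mass`; optional: `unit` (default `"g"`) and `Ybar3x`
#' (mean targets per field of view, needed for the effort model; `NA`
#' effort otherwise).  Malformed rows are reported by row number and field.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default `","`; use `"\t"` for TSV).
#' @return A validated `data.frame` of class `"linear_count_table"`.
#' @export
read_linear_counts <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("sample_id", "x", "n", "N1", "Ybar1", "s1", "mass")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!"unit" %in% names(df)) df$unit <- "g"
  if (!"Ybar3x" %in% names(df)) df$Ybar3x <- NA_real_
  check_rows(df, c("x", "n", "N1"), integer_valued = TRUE)
  check_rows(df, c("Ybar1", "s1", "mass"))
  bad <- which(df$n < 1)
  if (length(bad))
    stop("zero markers counted in row(s) ", paste(bad, collapse = ", "),
         ": concentration unbounded", call. = FALSE)
  class(df) <- c("linear_count_table", "data.frame")
  df
}

#' Read FOVS-method count tables
#'
#' Two delimited files describe a batch of FOVS counts:
#' * `calib_path` — long format, one row per calibration field of view:
#'   `sample_id`, `fov_index`, `count`.
#' * `extrap_path` — one row per sample: `sample_id`, `N3E`, `rare_count`,
#'   `N1`, `Ybar1`, `s1`, `mass`; optional `unit` and `role`
#'   (`"targets_common"`, the default, or `"markers_common"`).
#'
#' Every sample must have at least two calibration fields of view.
#'
#' @param calib_path,extrap_path Paths to the two files.
#' @param sep Field separator.
#' @return A list of class `"fovs_count_table"` with elements `calib` and
#'   `extrap`.
#' @export
read_fovs_counts <- function(calib_path, extrap_path, sep = ",") {
  calib <- utils::read.csv(calib_path, sep = sep, stringsAsFactors = FALSE)
  extrap <- utils::read.csv(extrap_path, sep = sep, stringsAsFactors = FALSE)
  need_c <- c("sample_id", "fov_index", "count")
  need_e <- c("sample_id", "N3E", "rare_count", "N1", "Ybar1", "s1", "mass")
  if (length(miss <- setdiff(need_c, names(calib))))
    stop("calibration table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (length(miss <- setdiff(need_e, names(extrap))))
    stop("extrapolation table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"unit" %in% names(extrap)) extrap$unit <- "g"
  if (!"role" %in% names(extrap)) extrap$role <- "targets_common"
  check_rows(calib, c("fov_index", "count"), integer_valued = TRUE)
  check_rows(extrap, c("N3E", "rare_count", "N1"), integer_valued = TRUE)
  check_rows(extrap, c("Ybar1", "s1", "mass"))
  n_fov <- table(calib$sample_id)
  thin <- names(n_fov)[n_fov < 2]
  if (length(thin))
    stop("fewer than 2 calibration fields of view for sample(s): ",
         paste(thin, collapse = ", "), call. = FALSE)
  orphan <- setdiff(extrap$sample_id, calib$sample_id)
  if (length(orphan))
    stop("no calibration counts for sample(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  structure(list(calib = calib, extrap = extrap),
            class = "fovs_count_table")
}

check_rows <- function(df, cols, integer_valued = FALSE) {
  for (col in cols) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 |
                   (integer_valued & v != round(v)))
    if (length(bad))
      stop(sprintf("invalid value in column `%s`, row(s) %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Batch concentration estimation
#'
#' Applies the appropriate estimator to every sample of a count table,
#' isolating per-row failures (reported in the `errors` attribute) so one
#' bad sample does not abort a batch.  Returns one row per sample plus a
#' `summary` attribute with the across-sample means of concentration, total
#' error and effort — the quantities usually tabulated when comparing the
#' two methods over an assemblage suite.
#'
#' @param table A `"linear_count_table"` or `"fovs_count_table"`.
#' @param omega Transition effort factor (default 2).
#' @param conf_level Confidence level for the normal-approximation interval.
#' @param method_choice If `TRUE` (linear tables with `Ybar3x` available, or
#'   FOVS tables), append the recommended method per sample via
#'   [choose_method()].
#' @param ... Unused.
#' @return A `data.frame` with one row per successfully estimated sample;
#'   attributes `summary` (list of means) and `errors` (named character
#'   vector of per-sample failures).
#' @export
estimate_batch <- function(table, omega = 2, conf_level = 0.95,
                           method_choice = FALSE, ...) {
  UseMethod("estimate_batch")
}

#' @export
estimate_batch.linear_count_table <- function(table, omega = 2,
                                              conf_level = 0.95,
                                              method_choice = FALSE, ...) {
  rows <- list()
  errors <- character()
  for (i in seq_len(nrow(table))) {
    row <- table[i, ]
    res <- tryCatch({
      spike <- marker_spike(row$N1, row$Ybar1, row$s1)
      est <- estimate_linear(
        linear_tally(row$x, row$n), spike, sample_spec(row$mass, row$unit),
        omega = omega,
        mean_targets_per_fov = if (is.na(row$Ybar3x)) 1 else row$Ybar3x,
        conf_level = conf_level)
      out <- as.data.frame(est)
      if (is.na(row$Ybar3x)) out$effort <- NA_real_
      out$sample_id <- row$sample_id
      out$u_hat <- row$x / row$n
      if (method_choice && !is.na(row$Ybar3x) && out$u_hat >= 1) {
        mc <- choose_method(design_point(out$u_hat, row$Ybar3x, omega,
                                         spike$dose_error_term))
        out$recommended <- mc$recommended
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(row$sample_id)] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  finish_batch(rows, errors)
}

#' @export
estimate_batch.fovs_count_table <- function(table, omega = 2,
                                            conf_level = 0.95,
                                            method_choice = FALSE, ...) {
  rows <- list()
  errors <- character()
  calib_split <- split(table$calib$count, table$calib$sample_id)
  for (i in seq_len(nrow(table$extrap))) {
    row <- table$extrap[i, ]
    res <- tryCatch({
      calib <- calibration_stats(calib_split[[as.character(row$sample_id)]],
                                 role = row$role)
      extrap <- fov_extrapolation(row$N3E, row$rare_count)
      spike <- marker_spike(row$N1, row$Ybar1, row$s1)
      est <- estimate_fovs(calib, extrap, spike,
                           sample_spec(row$mass, row$unit),
                           omega = omega, conf_level = conf_level)
      out <- as.data.frame(est)
      out$sample_id <- row$sample_id
      rare_per_fov <- row$rare_count / row$N3E
      out$u_hat <- calib$mean_per_fov / rare_per_fov
      if (method_choice && out$u_hat >= 1) {
        mc <- choose_method(design_point(out$u_hat, calib$mean_per_fov,
                                         omega, spike$dose_error_term))
        out$recommended <- mc$recommended
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(row$sample_id)] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  finish_batch(rows, errors)
}

finish_batch <- function(rows, errors) {
  if (!length(rows))
    stop("no sample could be estimated",
         if (length(errors)) paste0(": ", errors[[1]]) else "",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_samples = nrow(out),
    mean_concentration = mean(out$concentration),
    mean_error_pct = mean(out$total_error_pct),
    mean_effort = mean(out$effort))
  attr(out, "errors") <- errors
  out
}

#' Write batch results with a reproducibility manifest
#'
#' Writes the per-sample results as CSV and, optionally, a JSON file
#' containing the across-sample summary plus a run manifest (package
#' version, seed, timestamp, input-file digests) sufficient to reproduce the
#' run.
#'
#' @param results A result of [estimate_batch()].
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON summary path.
#' @param seed The seed used for any randomness in the run (recorded only).
#' @param inputs Character vector of input file paths to digest.
#' @return Invisibly, the manifest list.
#' @export
write_results <- function(results, csv_path, json_path = NULL,
                          seed = NA_integer_, inputs = character()) {
  utils::write.csv(results, csv_path, row.names = FALSE)
  manifest <- list(
    package = "fovs",
    version = as.character(utils::packageVersion("fovs")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    inputs = as.list(tools::md5sum(inputs)))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = attr(results, "summary"),
           errors = as.list(attr(results, "errors")),
           manifest = manifest),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest)
}

#' Generate count-table fixtures with known truth
#'
#' Simulates one virtual study area per sample from a [sim_config()]
#' scenario and writes the resulting counts in the package's interchange
#' formats (a linear count table and a FOVS calibration/extrapolation
#' pair), together with a JSON truth sidecar recording the known
#' concentration and scenario.  Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of samples (study areas) to emit.
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of the file paths written.
#' @export
generate_fixtures <- function(cfg, n_samples = 3, outdir, prefix = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dp <- design_point(cfg$u_true, cfg$design_density, cfg$omega,
                     cfg$dose_error)
  alloc <- optimal_allocation(dp, cfg$effort_budget)
  lin <- list(); cal <- list(); ext <- list()
  for (i in seq_len(n_samples)) {
    area <- generate_study_area(cfg, replicate = i)
    lr <- linear_window_count(area, cfg$x_stop, cfg)
    set.seed((cfg$seed + 104729L * i) %% 2147483647L)
    fr <- fov_replicate(area, alloc$n3c, alloc$n3e, cfg)
    sid <- sprintf("%s%02d", prefix, i)
    lin[[i]] <- data.frame(sample_id = sid, x = lr$counts[["x"]],
                           n = lr$counts[["n"]], N1 = 1,
                           Ybar1 = cfg$n_markers, s1 = cfg$dose_sd,
                           mass = 1, unit = "arbitrary",
                           Ybar3x = cfg$density)
    counts <- tabulate(cell_index(area$target_coords, cfg$grid_side),
                       cfg$grid_side^2)
    # replay the calibration cells actually used by fov_replicate
    set.seed((cfg$seed + 104729L * i) %% 2147483647L)
    cells <- sample.int(cfg$grid_side^2, alloc$n3c + alloc$n3e)
    cal[[i]] <- data.frame(sample_id = sid,
                           fov_index = seq_len(alloc$n3c),
                           count = counts[cells[seq_len(alloc$n3c)]])
    ext[[i]] <- data.frame(sample_id = sid, N3E = alloc$n3e,
                           rare_count = fr$counts[["n"]], N1 = 1,
                           Ybar1 = cfg$n_markers, s1 = cfg$dose_sd,
                           mass = 1, unit = "arbitrary",
                           role = "targets_common")
  }
  paths <- list(
    linear = file.path(outdir, paste0(prefix, "_linear.csv")),
    calib = file.path(outdir, paste0(prefix, "_fov_calibration.csv")),
    extrap = file.path(outdir, paste0(prefix, "_fov_extrapolation.csv")),
    truth = file.path(outdir, paste0(prefix, "_truth.json")))
  utils::write.csv(do.call(rbind, lin), paths$linear, row.names = FALSE)
  utils::write.csv(do.call(rbind, cal), paths$calib, row.names = FALSE)
  utils::write.csv(do.call(rbind, ext), paths$extrap, row.names = FALSE)
  jsonlite::write_json(
    list(true_concentration = cfg$n_targets,
         n_markers = cfg$n_markers, u_true = cfg$u_true,
         density = cfg$density, omega = cfg$omega,
         x_stop = cfg$x_stop, n3c = alloc$n3c, n3e = alloc$n3e,
         seed = cfg$seed, n_samples = n_samples),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
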