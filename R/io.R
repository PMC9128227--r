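# Readers and writers for the package's tabular and config formats.
# All files are UTF-8 CSV with a header row and a versioned schema comment
# line ("# tetherdrive <schema> v1") that readers verify.

CROSS_SCHEMA <- c("vial_id", "mother_genotype", "father_genotype",
                  "n_egfp", "n_dsred", "n_both", "n_neither",
                  "n_eggs", "n_pupae")
CAGE_SCHEMA <- c("generation", "census", "n_egfp_only", "n_dsred_only",
                 "n_both", "n_neither")

write_with_header <- function(df, path, tag) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# tetherdrive ", tag, " v1"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_with_header <- function(path, tag, schema) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, paste0("# tetherdrive ", tag)))
    stop(path, ": not a tetherdrive ", tag, " file (missing schema header)",
         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(schema, names(df))
  if (length(missing))
    stop(path, ": missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  df[, schema]
}

#' Read and write cross count tables
#'
#' Cross CSV schema: `vial_id`, `mother_genotype`, `father_genotype`,
#' `n_egfp`, `n_dsred`, `n_both`, `n_neither`, `n_eggs`, `n_pupae` (the egg
#' and pupa columns may be `NA`). Counts are validated to be non-negative
#' integers; offending rows are named in the error.
#'
#' @param path file path.
#' @param x a cross data frame (as from [gen_cross_dataset()]).
#' @return `read_cross_csv` returns the validated data frame;
#'   `write_cross_csv` returns `path` invisibly.
#' @export
read_cross_csv <- function(path) {
  df <- read_with_header(path, "cross", CROSS_SCHEMA)
  cnt <- c("n_egfp", "n_dsred", "n_both", "n_neither")
  for (nm in c("n_eggs", "n_pupae")) df[[nm]] <- as.integer(df[[nm]])
  for (nm in cnt) {
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0 |
                   df[[nm]] != round(df[[nm]]))
    if (length(bad))
      stop(path, ": column '", nm, "' must hold non-negative integers (row ",
           bad[1], ")", call. = FALSE)
  }
  df
}

#' @rdname read_cross_csv
#' @export
write_cross_csv <- function(x, path) {
  stopifnot(all(CROSS_SCHEMA %in% names(x)))
  write_with_header(x[, CROSS_SCHEMA], path, "cross")
}

#' Read and write cage trajectory tables
#'
#' Cage CSV schema: `generation`, `census`, `n_egfp_only`, `n_dsred_only`,
#' `n_both`, `n_neither`. The four phenotype counts must sum to the census
#' in every row; the first offending row is named.
#'
#' @param path file path.
#' @param x a cage trajectory data frame.
#' @return `read_cage_csv` returns the validated data frame (classed
#'   `"cage_trajectory"`); `write_cage_csv` returns `path` invisibly.
#' @export
read_cage_csv <- function(path) {
  df <- read_with_header(path, "cage", CAGE_SCHEMA)
  cnt <- c("n_egfp_only", "n_dsred_only", "n_both", "n_neither")
  for (nm in c(cnt, "census")) {
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0 |
                   df[[nm]] != round(df[[nm]]))
    if (length(bad))
      stop(path, ": column '", nm, "' must hold non-negative integers (row ",
           bad[1], ")", call. = FALSE)
  }
  sums <- rowSums(df[, cnt])
  bad <- which(sums != df$census)
  if (length(bad))
    stop(path, ": phenotype counts do not sum to census in row ", bad[1],
         " (", sums[bad[1]], " vs ", df$census[bad[1]], ")", call. = FALSE)
  structure(df, class = c("cage_trajectory", "data.frame"))
}

#' @rdname read_cage_csv
#' @export
write_cage_csv <- function(x, path) {
  stopifnot(all(CAGE_SCHEMA %in% names(x)))
  write_with_header(as.data.frame(x)[, CAGE_SCHEMA], path, "cage")
}

#' Read and write drive-parameter configs
#'
#' YAML key-value config mirroring the [drive_params()] arguments, plus an
#' optional `fitness:` block (`f_hom`, `component`, `f_homing`). Unknown
#' keys and out-of-range probabilities are rejected with the field named.
#'
#' @param path file path.
#' @param params a [drive_params()] object.
#' @param fitness optional [fitness_model()] to store alongside.
#' @return `read_params_config` returns a list with elements `params` and
#'   (if present) `fitness`; `write_params_config` returns `path`
#'   invisibly.
#' @export
read_params_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fit_cfg <- cfg$fitness
  cfg$fitness <- NULL
  known <- names(formals(drive_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(path, ": unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- tryCatch(do.call(drive_params, cfg), error = function(e)
    stop(path, ": ", conditionMessage(e), call. = FALSE))
  out <- list(params = params)
  if (!is.null(fit_cfg)) {
    fknown <- names(formals(fitness_model))
    funknown <- setdiff(names(fit_cfg), fknown)
    if (length(funknown))
      stop(path, ": unknown fitness field(s): ",
           paste(funknown, collapse = ", "), call. = FALSE)
    out$fitness <- do.call(fitness_model, fit_cfg)
  }
  out
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path, fitness = NULL) {
  stopifnot(inherits(params, "drive_params"))
  cfg <- unclass(params)
  if (!is.null(fitness)) {
    stopifnot(inherits(fitness, "fitness_model"))
    cfg$fitness <- unclass(fitness)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read and write likelihood-fit reports
#'
#' JSON serialisation of a `"likelihood_fit"` (point estimates, CIs,
#' log-likelihood, per-transition table).
#'
#' @param fit a `"likelihood_fit"`.
#' @param path file path.
#' @return `read_fit_json` returns the fit as a `"likelihood_fit"` list;
#'   `write_fit_json` returns `path` invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "likelihood_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_transition <- as.data.frame(x$per_transition)
  structure(x, class = "likelihood_fit")
}
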