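#' Read and write long-format DI datasets
#'
#' The CSV schema is `plot,block,year,treatment,y,<one column per species>`.
#' Reading validates through [di_data()] (proportion sums, plot-year
#' uniqueness, contiguous years) and forces monoculture rows to treatment
#' `none`; parse failures report the offending rows.
#'
#' @param path file path.
#' @param pool a [species_pool()] naming the proportion columns.
#' @param tolerance,renormalize passed to [di_data()].
#' @return a [di_data()].
#' @export
read_di_csv <- function(path, pool, tolerance = 1e-6, renormalize = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("plot", "block", "year", "treatment", "y", pool$species)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("CSV lacks required columns: ",
                         paste(miss, collapse = ", "))
  df$y <- as.numeric(df$y)
  for (sp in pool$species)
    if (!is.numeric(df[[sp]]))
      stop("non-numeric proportion column '", sp, "' (first bad row: ",
           which(is.na(suppressWarnings(as.numeric(df[[sp]]))))[1], ")")
  di_data(df, pool, tolerance = tolerance, renormalize = renormalize)
}

#' @rdname read_di_csv
#' @param data a [di_data()] to write.
#' @export
write_di_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Write analysis reports to a directory
#'
#' Writes delimited-text reports for fitted models, selection traces and
#' simulation-study summaries, plus a JSON run manifest carrying the seed
#' and a configuration hash so runs can be reproduced bit for bit.
#'
#' @param object a `dimix` fit, `di_selection`, `di_power_study` or
#'   `di_power_setting`.
#' @param dir output directory (created if absent).
#' @param seed the seed used to produce `object` (recorded in the manifest).
#' @return invisibly, the paths written.
#' @export
write_reports <- function(object, dir, seed = NA_integer_) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if (inherits(object, "dimix")) {
    p <- file.path(dir, "fit_parameters.csv")
    s <- summary(object)
    tab <- data.frame(term = rownames(s$coefficients), s$coefficients,
                      check.names = FALSE)
    utils::write.csv(tab, p, row.names = FALSE)
    paths <- c(paths, p)
    p2 <- file.path(dir, "fit_report.txt")
    con <- file(p2, "w"); sink(con); print(s); sink(); close(con)
    paths <- c(paths, p2)
  } else if (inherits(object, "di_selection")) {
    p <- file.path(dir, "selection_trace.csv")
    utils::write.csv(x = transform(object$trace,
                                   LRT = statistic)[, c("step", "comparison",
                                                        "LRT", "df", "p",
                                                        "decision")],
                     file = p, row.names = FALSE)
    paths <- c(paths, p)
  } else if (inherits(object, "di_power_study")) {
    p <- file.path(dir, "power_study.csv")
    utils::write.csv(object$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  } else if (inherits(object, "di_power_setting")) {
    p <- file.path(dir, "power_setting.csv")
    utils::write.csv(summarize_study(list(object)), p, row.names = FALSE)
    paths <- c(paths, p)
  } else stop("unsupported object class: ", class(object)[1])
  mp <- file.path(dir, "manifest.json")
  cfg <- utils::capture.output(utils::str(object, max.level = 1))
  tf <- tempfile(); writeLines(cfg, tf)
  manifest <- list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   seed = seed, object_class = class(object)[1],
                   config_hash = unname(tools::md5sum(tf)),
                   files = basename(paths))
  unlink(tf)
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
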