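#' Read a tidy degradation time-series CSV
#'
#' Reads and validates the package's interchange layout: one row per
#' measurement with columns `analyte`, `temperature_C`, `time_min`,
#' `replicate`, `response` (RFC-4180 CSV, UTF-8, `.` decimal). Errors name
#' the offending rows; rows with non-positive responses are flagged with a
#' warning but kept (the kinetic fit excludes them itself).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @seealso [write_timeseries_csv()], [thermal_study()]
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("analyte", "temperature_C", "time_min", "replicate", "response")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty time-series file: ", path, call. = FALSE)
  for (col in c("temperature_C", "time_min", "response")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-numeric '", col, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$analyte, df$temperature_C, df$time_min, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (analyte, temperature, time, replicate) at data ",
         "row(s) ", paste(utils::head(which(duplicated(key)), 5),
                          collapse = ", "), call. = FALSE)
  if (any(df$time_min < 0))
    stop("negative time at data row(s) ",
         paste(utils::head(which(df$time_min < 0), 5), collapse = ", "),
         call. = FALSE)
  npos <- which(!is.na(df$response) & df$response <= 0)
  if (length(npos))
    warning(length(npos), " non-positive response value(s) flagged ",
            "(row(s) ", paste(utils::head(npos, 5), collapse = ", "),
            "); they are excluded from log-linear fits", call. = FALSE)
  for (grp in split(df, list(df$analyte, df$temperature_C), drop = TRUE)) {
    if (!any(grp$time_min == 0))
      warning("no time-0 measurement for ", grp$analyte[1L], " at ",
              grp$temperature_C[1L], " degC; the free intercept absorbs ",
              "the reference scale", call. = FALSE)
  }
  df
}

#' Write a tidy degradation time-series CSV
#'
#' @param data Data frame in the layout of [read_timeseries_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(data, path) {
  req <- c("analyte", "temperature_C", "time_min", "replicate", "response")
  stopifnot(all(req %in% names(data)))
  utils::write.csv(data[req], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dose-response CSV
#'
#' Validates the layout `enzyme`, `concentration_ug_mL`, `replicate`,
#' `inhibition_pct`.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_dose_response_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("enzyme", "concentration_ug_mL", "replicate", "inhibition_pct")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty dose-response file: ", path,
                           call. = FALSE)
  if (any(df$concentration_ug_mL <= 0))
    stop("non-positive concentration at data row(s) ",
         paste(utils::head(which(df$concentration_ug_mL <= 0), 5),
               collapse = ", "), call. = FALSE)
  df
}

#' Full thermal-degradation study analysis
#'
#' Runs the complete kinetic chain on a tidy multi-temperature time-series:
#' per-(analyte, temperature) first-order fits, then per-analyte Arrhenius
#' activation energy, z-value regression on the derived D-values, and the
#' per-temperature Eyring activation thermodynamics.
#'
#' @param data Tidy time-series data frame (see [read_timeseries_csv()]).
#' @param ... Fit options passed to [first_order_fit()] (`method`, `c0`,
#'   `aggregate`).
#' @return Object of class `"thermal_study"`: a list with `fits` (named
#'   list of [first_order_fit()] objects), `kinetics` (summary data frame),
#'   `arrhenius` and `z_value` (named lists per analyte) and `thermo`
#'   (named list of [thermo_table()]s). Supports `print()` and
#'   `summary()`.
#' @examples
#' des <- degradation_design(noise_cv = 0)
#' sim <- simulate_degradation(des, k = c(0.0069, 0.0138, 0.0253, 0.0737,
#'                                        0.1865))
#' st <- thermal_study(sim, replicate = "replicate")
#' st
#' @export
thermal_study <- function(data, ...) {
  req <- c("analyte", "temperature_C", "time_min", "replicate", "response")
  stopifnot(all(req %in% names(data)))
  groups <- split(data,
                  list(data$analyte, data$temperature_C), drop = TRUE)
  fits <- lapply(groups, function(g) {
    first_order_fit(response ~ time_min, g, replicate = "replicate",
                    temperature = g$temperature_C[1L],
                    analyte = g$analyte[1L], ...)
  })
  kin <- do.call(rbind, lapply(fits, summary))
  kin <- kin[order(kin$analyte, kin$temperature_C), , drop = FALSE]
  rownames(kin) <- NULL
  class(kin) <- "data.frame"

  analytes <- unique(kin$analyte)
  arr <- zval <- thermo <- stats::setNames(vector("list", length(analytes)),
                                           analytes)
  for (a in analytes) {
    sub <- kin[kin$analyte == a, ]
    if (nrow(sub) >= 2 && all(sub$k > 0)) {
      arr[[a]] <- arrhenius_fit(sub$temperature_C, sub$k)
      zval[[a]] <- z_value_fit(sub$temperature_C, sub$d_value_min)
      tf <- data.frame(analyte = a, temperature_C = sub$temperature_C,
                       k = sub$k, k_sd = sub$k_sd)
      thermo[[a]] <- thermo_table(arr[[a]], tf)
    }
  }
  structure(list(fits = fits, kinetics = kin, arrhenius = arr,
                 z_value = zval, thermo = thermo, call = match.call()),
            class = "thermal_study")
}

#' @export
print.thermal_study <- function(x, digits = 4, ...) {
  cat("Thermal degradation study:",
      length(unique(x$kinetics$analyte)), "analyte(s),",
      length(unique(x$kinetics$temperature_C)), "temperature(s)\n\n")
  tab <- x$kinetics
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  for (a in names(x$arrhenius)) {
    if (is.null(x$arrhenius[[a]])) next
    cat("\n", a, ": Ea = ", signif(x$arrhenius[[a]]$Ea, digits),
        " +/- ", signif(x$arrhenius[[a]]$Ea_se, digits),
        " kJ/mol (R^2 = ", signif(x$arrhenius[[a]]$r2, digits), ")",
        ", z = ", signif(x$z_value[[a]]$z, digits),
        " +/- ", signif(x$z_value[[a]]$z_se, digits),
        " degC (R^2 = ", signif(x$z_value[[a]]$r2, digits), ")\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.thermal_study <- function(object, ...) object$kinetics

#' Run the thermal analysis pipeline from a configuration
#'
#' File-level orchestration: reads a tidy time-series CSV, runs
#' [thermal_study()], and writes the kinetics table, the secondary-model
#' block (Ea, z) and the thermodynamics table as CSVs plus a plain-text
#' log. Outputs are deterministic given the same inputs and configuration;
#' the configuration (and a content hash of the input) is recorded in the
#' report for provenance.
#'
#' @param config A named list — or path to a YAML file — with elements
#'   `input` (time-series CSV path), `output_dir`, and optionally `method`,
#'   `c0`, `aggregate` (see [first_order_fit()]) and `seed` (recorded, and
#'   used by any simulation step).
#' @return Object of class `"study_report"`: the [thermal_study()] plus
#'   `files` (paths written) and `provenance`.
#' @examples
#' des <- degradation_design(noise_cv = 0)
#' sim <- simulate_degradation(des, k = c(0.0069, 0.0138, 0.0253, 0.0737,
#'                                        0.1865))
#' tsv <- file.path(tempdir(), "series.csv")
#' write_timeseries_csv(sim, tsv)
#' rep <- run_thermal_analysis(list(input = tsv,
#'                                  output_dir = tempdir()))
#' rep$files
#' @export
run_thermal_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$input))
    stop("config must name an 'input' time-series CSV", call. = FALSE)
  out_dir <- if (is.null(config$output_dir)) "." else config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  data <- read_timeseries_csv(config$input)
  opts <- config[intersect(names(config), c("method", "c0", "aggregate"))]
  study <- do.call(thermal_study, c(list(data = data), opts))

  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  files <- c(kinetics = file.path(out_dir, "kinetics.csv"),
             secondary = file.path(out_dir, "secondary_models.csv"),
             thermodynamics = file.path(out_dir, "thermodynamics.csv"),
             log = file.path(out_dir, "analysis_log.txt"))
  utils::write.csv(fmt(study$kinetics), files[["kinetics"]],
                   row.names = FALSE, quote = FALSE)

  sec <- do.call(rbind, lapply(names(study$arrhenius), function(a) {
    ar <- study$arrhenius[[a]]; zv <- study$z_value[[a]]
    if (is.null(ar)) return(NULL)
    data.frame(analyte = a, Ea_kJ_mol = ar$Ea, Ea_se = ar$Ea_se,
               lnA = ar$lnA, Ea_r2 = ar$r2, z_C = zv$z, z_se = zv$z_se,
               z_r2 = zv$r2, stringsAsFactors = FALSE)
  }))
  utils::write.csv(fmt(sec), files[["secondary"]], row.names = FALSE,
                   quote = FALSE)

  th <- do.call(rbind, lapply(study$thermo, as.data.frame))
  rownames(th) <- NULL
  utils::write.csv(fmt(th), files[["thermodynamics"]], row.names = FALSE,
                   quote = FALSE)

  prov <- list(
    input = config$input,
    input_md5 = unname(tools::md5sum(config$input)),
    seed = if (is.null(config$seed)) NA else config$seed,
    options = opts,
    package_version = as.character(utils::packageVersion("thermokin")))
  writeLines(c(
    "thermal degradation analysis log",
    paste0("input: ", prov$input, " (md5 ", prov$input_md5, ")"),
    paste0("seed: ", prov$seed),
    paste0("options: ", if (length(opts))
      paste(names(opts), unlist(opts), sep = "=", collapse = ", ")
      else "defaults"),
    paste0("analytes: ", paste(unique(study$kinetics$analyte),
                               collapse = ", ")),
    paste0("fits: ", nrow(study$kinetics))),
    files[["log"]])

  structure(c(study, list(files = files, provenance = prov)),
            class = c("study_report", "thermal_study"))
}

#' Reference thermal-degradation kinetic parameters
#'
#' Published per-temperature first-order parameters (k, R^2, half-life,
#' D-value; mean +/- SD over triplicate heating runs) for total
#' anthocyanin content and DPPH antioxidant activity of a red onion skin
#' extract heated at 75-155 degC. Shipped as the package's reference
#' input: the secondary models, thermodynamic tables and report layouts
#' are reproduced from these values.
#'
#' @param analyte Optionally restrict to `"TAC"` or
#'   `"antioxidant_activity"`.
#' @return Data frame with columns `analyte`, `temperature_C`, `k_per_min`,
#'   `k_sd`, `r2`, `t_half_min`, `t_half_sd`, `d_min`, `d_sd`.
#' @examples
#' reference_kinetics("TAC")
#' @export
reference_kinetics <- function(analyte = NULL) {
  path <- system.file("extdata", "ros_kinetics_reference.csv",
                      package = "thermokin", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(analyte)) {
    stopifnot(analyte %in% df$analyte)
    df <- df[df$analyte %in% analyte, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Reference enzyme-inhibition IC50 summary
#'
#' Published IC50 values (mean +/- SD, n = 3) of a red onion skin extract
#' and positive-control inhibitors against alpha-amylase,
#' alpha-glucosidase, pancreatic lipase and lipoxygenase, with the
#' published compact significance letters. Raw inhibition percentages were
#' not published, so this summary (not a dose-response table) is the
#' reference input for the group-comparison step.
#'
#' @param enzyme Optionally restrict to one enzyme label.
#' @return Data frame with columns `enzyme`, `sample`, `ic50_ug_mL`, `sd`,
#'   `n`, `letter`.
#' @examples
#' reference_ic50("alpha_amylase")
#' @export
reference_ic50 <- function(enzyme = NULL) {
  path <- system.file("extdata", "ros_ic50_reference.csv",
                      package = "thermokin", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(enzyme)) {
    stopifnot(enzyme %in% df$enzyme)
    df <- df[df$enzyme %in% enzyme, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
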