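#' Read an incidence table from CSV
#'
#' Expects a comma-separated UTF-8 file with a header and columns
#' `age`, `incidence` and optionally `cases`, `person_years`; ages must
#' be strictly increasing and rates non-negative (incidence is always
#' per person-year). When counts are present, `incidence` must equal
#' `cases / person_years` within 1e-9. Errors name the offending row and
#' column.
#'
#' @param path Path to the CSV file.
#' @return An [incidence_curve()].
#' @export
read_incidence_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("age", "incidence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  has_counts <- all(c("cases", "person_years") %in% names(df))
  for (col in intersect(c("age", "incidence", "cases", "person_years"),
                        names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))) &
                     !is.na(v))[1]
      stop("non-numeric value in column '", col, "', row ",
           if (is.na(bad)) "?" else bad)
    }
  }
  dup <- which(duplicated(df$age))[1]
  if (!is.na(dup)) stop("duplicate age at row ", dup, " (age = ",
                        df$age[dup], ")")
  bad <- which(diff(df$age) <= 0)[1]
  if (!is.na(bad)) stop("ages not strictly increasing at row ", bad + 1)
  neg <- which(df$incidence < 0)[1]
  if (!is.na(neg)) stop("negative incidence at row ", neg)
  if (has_counts) {
    ok <- df$person_years > 0
    off <- which(abs(df$incidence[ok] -
                       df$cases[ok] / df$person_years[ok]) > 1e-9)[1]
    if (!is.na(off))
      stop("incidence != cases / person_years at row ", which(ok)[off],
           " (column 'incidence')")
    incidence_curve(df$age, df$incidence, df$cases, df$person_years)
  } else {
    incidence_curve(df$age, df$incidence)
  }
}

#' Write an incidence table to CSV
#'
#' Full-precision writer for the dialect of [read_incidence_csv()].
#' Bins with missing incidence (no person-years) are omitted with a
#' message so the file always round-trips through the reader.
#'
#' @param curve An [incidence_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(curve, path) {
  stopifnot(inherits(curve, "incidence_curve"))
  drop <- !is.finite(curve$incidence)
  if (any(drop)) {
    message("omitting ", sum(drop), " bin(s) with missing incidence")
    curve <- curve[!drop, , drop = FALSE]
  }
  df <- as.data.frame(curve)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                scientific = TRUE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Default run configuration
#'
#' Bundles the regression constants, the calibrated SR parameters and the
#' package-wide numerical defaults (integration step, horizon, bin width,
#' seed) into one structured object that can be written to and read from
#' YAML.
#'
#' @return A list of class `"run_config"`.
#' @export
default_run_config <- function() {
  sr <- sr_default_parameters()
  structure(list(constants = unclass(regression_constants()),
                 sr = list(eta = sr$eta, beta = sr$beta, kappa = sr$kappa,
                           epsilon = sr$epsilon),
                 defaults = list(dt = 0.01, horizon = 110, bin_width = 1,
                                 seed = 1L),
                 output_dir = "."),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file written by [write_run_config()].
#' @return A `"run_config"` list; constants and SR parameters are
#'   validated on read.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  ct <- do.call(regression_constants, cfg$constants)
  sr <- do.call(sr_parameters, cfg$sr[c("eta", "beta", "kappa", "epsilon")])
  structure(list(constants = unclass(ct), sr = unclass(sr),
                 defaults = cfg$defaults,
                 output_dir = cfg$output_dir %||% "."),
            class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `"run_config"` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
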