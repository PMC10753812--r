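## Readers, writers and validation for the tabular energy-record schema
## shared by the extrapolation and counterpoise tools.

.record_cols <- c("system", "subsystem", "family", "X", "component",
                  "cp_flavor", "unit", "energy")
.enums <- list(subsystem = c("dimer", "monomer_A", "monomer_B"),
               family = c("cc", "aug-cc"),
               component = c("HF", "corr", "total"),
               cp_flavor = c("own_basis", "ghost_basis"),
               unit = c("hartree", "kcal/mol"))

#' Validate a data frame of energy records
#'
#' Checks the tabular schema used throughout the package: one row per
#' (system, subsystem, family, X, component, cp_flavor) key with an explicit
#' unit and a numeric energy.  Duplicate keys are an input error (they are
#' never averaged), `X` must lie in 2..5, and the enum columns must take
#' their documented values.
#'
#' @param df data frame with columns `system`, `subsystem`, `family`, `X`,
#'   `component`, `cp_flavor`, `unit`, `energy`.
#' @return the validated data frame (invisibly unchanged apart from type
#'   coercion of `X` and `energy`).
#' @export
energy_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(.record_cols, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(df)
  bad <- which(is.na(suppressWarnings(as.numeric(df$energy))))
  if (length(bad))
    stop("non-numeric energy in row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  df$energy <- as.numeric(df$energy)
  df$X <- as.integer(df$X)
  if (any(!df$X %in% 2:5))
    stop("X must satisfy X ∈ {2..5}; offending row(s): ",
         paste(which(!df$X %in% 2:5), collapse = ", "), call. = FALSE)
  for (col in names(.enums)) {
    bad <- which(!df[[col]] %in% .enums[[col]])
    if (length(bad))
      stop(sprintf("invalid %s in row(s) %s (allowed: %s)", col,
                   paste(bad, collapse = ", "),
                   paste(.enums[[col]], collapse = ", ")), call. = FALSE)
  }
  key <- do.call(paste, c(df[c("system", "subsystem", "family", "X",
                               "component", "cp_flavor")], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (system, subsystem, family, X, component, cp_flavor) records: ",
         "rows ", paste(which(duplicated(key)), collapse = ", "), call. = FALSE)
  df
}

#' Read an energy table from delimited text
#'
#' Comma and tab dialects are auto-detected from the header line; unknown
#' columns are preserved.  Records are validated with [energy_records()].
#'
#' @param path file path.
#' @param dialect `"auto"`, `"comma"`, or `"tab"`.
#' @return validated data frame of energy records.
#' @export
read_energy_table <- function(path, dialect = c("auto", "comma", "tab")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    header <- readLines(path, n = 1)
    dialect <- if (grepl("\t", header)) "tab" else "comma"
  }
  sep <- if (dialect == "tab") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  energy_records(df)
}

#' Write an energy table
#'
#' @param df validated record data frame.
#' @param path output path.
#' @param dialect `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(df, path, dialect = c("comma", "tab")) {
  dialect <- match.arg(dialect)
  utils::write.table(df, path, sep = if (dialect == "tab") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_to_list <- function(fit) {
  list(scheme = fit$scheme,
       points = list(X = fit$points$X, energy = fit$points$energy),
       E_CBS = fit$E_CBS,
       params = as.list(fit$params),
       residuals = fit$residuals,
       interpolation_mae = interpolation_error(fit),
       fit_mode = fit$fit_mode,
       unit = fit$unit)
}

#' Write results to JSON, CSV, or markdown
#'
#' Serializes extrapolation fits (`cbs_fit`), deviation statistics
#' (`deviation_stats`), or plain lists/data frames.  Field ordering is
#' deterministic; JSON and CSV keep full precision, markdown tables round to
#' three decimals in the usual kcal/mol reporting style.  Identical inputs
#' produce byte-identical files.
#'
#' @param results a `cbs_fit`, `deviation_stats`, data frame, or list of
#'   such objects.
#' @param path output path.
#' @param format `"json"`, `"csv"`, or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "markdown")) {
  format <- match.arg(format)
  if (length(results) == 0) stop("results must be nonempty", call. = FALSE)
  norm <- function(x) {
    if (inherits(x, "cbs_fit")) fit_to_list(x)
    else if (inherits(x, "deviation_stats")) unclass(x)
    else x
  }
  single <- inherits(results, c("cbs_fit", "deviation_stats")) ||
    is.data.frame(results)
  payload <- if (single) norm(results) else lapply(results, norm)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "csv") {
    df <- if (is.data.frame(payload)) payload else
      as.data.frame(lapply(payload, function(x) if (length(x) == 1) x else I(list(x))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- if (is.data.frame(payload)) payload else
      as.data.frame(lapply(payload, function(x) if (length(x) == 1) x else NA))
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.3f", x))
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Extrapolate every (system, subsystem) group of an energy table
#'
#' Splits validated records by system and subsystem, fits the requested
#' scheme to each group's `(X, energy)` series, and (optionally) differences
#' dimer and monomer limits into an interaction energy.  Extrapolating the
#' subsystems separately and differencing equals extrapolating the
#' differenced series for all linear-in-parameter schemes at exact-solve
#' point counts.
#'
#' @param records validated data frame (see [energy_records()]).
#' @param scheme scheme id or `cbs_scheme`.
#' @param component which component rows to use.
#' @param family which basis family rows to use.
#' @param cp_flavor which counterpoise flavour rows to use.
#' @return data frame with one row per (system, subsystem): `E_CBS` and
#'   `interpolation_mae`; when all three subsystems of a system are present
#'   an extra `dimer - A - B` row labelled `interaction` is appended.
#' @export
extrapolate_table <- function(records, scheme, component = "corr",
                              family = "aug-cc", cp_flavor = "ghost_basis") {
  records <- energy_records(records)
  sel <- records$component == component & records$family == family &
    records$cp_flavor == cp_flavor
  df <- records[sel, , drop = FALSE]
  if (nrow(df) == 0) stop("no records match the requested slice", call. = FALSE)
  out <- do.call(rbind, lapply(split(df, df[c("system", "subsystem")], drop = TRUE),
    function(g) {
      fit <- extrapolate(g[c("X", "energy")], scheme, component = component,
                         unit = g$unit[1])
      data.frame(system = g$system[1], subsystem = g$subsystem[1],
                 E_CBS = fit$E_CBS, interpolation_mae = interpolation_error(fit))
    }))
  rownames(out) <- NULL
  for (sys in unique(out$system)) {
    sub <- out[out$system == sys, ]
    if (all(c("dimer", "monomer_A", "monomer_B") %in% sub$subsystem)) {
      delta <- sub$E_CBS[sub$subsystem == "dimer"] -
        sub$E_CBS[sub$subsystem == "monomer_A"] -
        sub$E_CBS[sub$subsystem == "monomer_B"]
      out <- rbind(out, data.frame(system = sys, subsystem = "interaction",
                                   E_CBS = delta, interpolation_mae = NA))
    }
  }
  out
}
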