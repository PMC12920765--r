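# CSV readers/writers for long-format colony observation tables.
# The canonical columns are colony_id, habitat, region, time_days,
# concentration; a ColumnMapping adapts arbitrary source headers.

#' Map canonical observation fields to source CSV column names
#'
#' @param colony_id,habitat,region,time_days,concentration source column
#'   names holding each canonical field.
#' @return A named character vector of class `column_mapping`.
#' @examples
#' column_mapping(time_days = "day", concentration = "cd_mg_kg")
#' @export
column_mapping <- function(colony_id = "colony_id", habitat = "habitat",
                           region = "region", time_days = "time_days",
                           concentration = "concentration") {
  m <- c(colony_id = colony_id, habitat = habitat, region = region,
         time_days = time_days, concentration = concentration)
  if (anyNA(m) || any(!nzchar(m)))
    stop("column_mapping: every canonical field must map to a column name")
  structure(m, class = "column_mapping")
}

#' Read a long-format observation CSV
#'
#' Reads, renames via the mapping, validates and normalizes: habitat and
#' region are lower-cased, `time_days` and `concentration` must be numeric
#' and non-negative, and rows with missing or non-numeric concentration are
#' rejected with row-numbered messages.
#'
#' @param path CSV file with a header row (decimal point '.').
#' @param mapping a [column_mapping()]; defaults to canonical names.
#' @return A validated observation table (data frame with the canonical
#'   columns).
#' @export
read_observations <- function(path, mapping = column_mapping()) {
  stopifnot(inherits(mapping, "column_mapping"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_cols <- mapping[!mapping %in% names(raw)]
  if (length(missing_cols))
    stop("read_observations: column(s) not found in ", path, ": ",
         paste(sprintf("%s (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "))
  out <- data.frame(colony_id = as.character(raw[[mapping["colony_id"]]]),
                    habitat = tolower(as.character(raw[[mapping["habitat"]]])),
                    region = tolower(as.character(raw[[mapping["region"]]])),
                    time_days = raw[[mapping["time_days"]]],
                    concentration = raw[[mapping["concentration"]]],
                    stringsAsFactors = FALSE)
  validate_observations(out)
}

#' Validate an observation table
#'
#' @param data data frame with the canonical columns.
#' @return The table, invisibly unchanged, or an error listing offending
#'   rows (row numbers refer to the data rows, header excluded).
#' @export
validate_observations <- function(data) {
  need <- c("colony_id", "habitat", "region", "time_days", "concentration")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("validate_observations: missing column(s): ",
         paste(miss, collapse = ", "))
  as_num <- function(x) suppressWarnings(as.numeric(x))
  tn <- as_num(data$time_days)
  cn <- as_num(data$concentration)
  bad_t <- which(is.na(tn) & !is.na(data$time_days))
  bad_c <- which(is.na(cn) &
                   !(is.na(data$concentration) |
                       data$concentration %in% c("", "NA")))
  na_c <- which(is.na(cn) & !seq_along(cn) %in% bad_c)
  neg_t <- which(tn < 0)
  neg_c <- which(cn < 0)
  msgs <- c(
    if (length(bad_c)) paste0("non-numeric concentration in row(s) ",
                              paste(bad_c, collapse = ", ")),
    if (length(na_c)) paste0("missing concentration in row(s) ",
                             paste(na_c, collapse = ", ")),
    if (length(bad_t)) paste0("non-numeric time in row(s) ",
                              paste(bad_t, collapse = ", ")),
    if (length(neg_t)) paste0("negative time in row(s) ",
                              paste(neg_t, collapse = ", ")),
    if (length(neg_c)) paste0("negative concentration in row(s) ",
                              paste(neg_c, collapse = ", ")))
  if (length(msgs))
    stop("validate_observations: ", paste(msgs, collapse = "; "))
  if (anyDuplicated(data$colony_id))
    warning("validate_observations: duplicated colony_id(s) -- destructive ",
            "sampling implies one row per colony", call. = FALSE)
  data$time_days <- tn
  data$concentration <- cn
  data
}

#' Write an observation table to CSV
#'
#' @param data observation table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated dataset: observations CSV plus truth/seed sidecar JSON
#'
#' @param dataset a `simulated_dataset`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.truth.json` suffix.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_simulated <- function(dataset, path) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  write_observations(dataset$observations, path)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, ".truth.json")
  truth <- lapply(dataset$truth, function(tr)
    list(contamination = list(kA = tr$contamination$kA,
                              kE = tr$contamination$kE),
         decontamination = list(kA = tr$decontamination$kA,
                                kE = tr$decontamination$kE)))
  jsonlite::write_json(list(seed = dataset$seed, truth = truth,
                            schedule = unclass(dataset$config$schedule)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, truth = sidecar))
}
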