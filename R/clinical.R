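#' Read and validate a clinical covariate table
#'
#' Expects a UTF-8 CSV with a header row and columns `patient_id`,
#' `weight_kg`, `height_cm`, `ipi`, `pfs_months`, `pfs_event`, `os_months`,
#' `os_event`. Progression-free survival (PFS) and overall survival (OS) are
#' right-censored endpoints; event indicators must be 0/1 and PFS time can
#' never exceed OS time. Rows with missing weight or height are kept but
#' flagged `bsa_available = FALSE`: body surface area, and hence the
#' standardized distance sDspleen, cannot be computed for them and the
#' unstandardized Dspleen is used instead.
#'
#' @param path path to the CSV file.
#' @param time_unit unit of the time columns, recorded in the result's
#'   attributes; the package assumes months throughout its defaults.
#' @return A `data.frame` with one row per patient and an added logical
#'   column `bsa_available`.
#' @export
read_clinical_table <- function(path, time_unit = "months") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical_table(df, time_unit = time_unit)
}

#' Validate an in-memory clinical table
#' @param df data.frame with the columns listed in [read_clinical_table].
#' @inheritParams read_clinical_table
#' @return the validated data.frame with `bsa_available` added.
#' @export
validate_clinical_table <- function(df, time_unit = "months") {
  required <- c("patient_id", "weight_kg", "height_cm", "ipi",
                "pfs_months", "pfs_event", "os_months", "os_event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("clinical table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicated patient_id values in clinical table")

  num_cols <- c("weight_kg", "height_cm", "pfs_months", "pfs_event",
                "os_months", "os_event")
  for (cc in num_cols) df[[cc]] <- as.numeric(df[[cc]])

  for (cc in c("pfs_months", "os_months")) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad))
      stop("negative ", cc, " for patient(s): ",
           paste(df$patient_id[bad], collapse = ", "))
  }
  for (cc in c("pfs_event", "os_event")) {
    bad <- which(!is.na(df[[cc]]) & !(df[[cc]] %in% c(0, 1)))
    if (length(bad))
      stop(cc, " must be 0/1; offending patient(s): ",
           paste(df$patient_id[bad], collapse = ", "))
  }
  both <- !is.na(df$pfs_months) & !is.na(df$os_months)
  bad <- which(both & df$pfs_months > df$os_months + 1e-9)
  if (length(bad))
    stop("pfs_months exceeds os_months for patient(s): ",
         paste(df$patient_id[bad], collapse = ", "))

  bad_w <- which(!is.na(df$weight_kg) & df$weight_kg <= 0)
  bad_h <- which(!is.na(df$height_cm) & df$height_cm <= 0)
  if (length(bad_w) || length(bad_h))
    stop("non-positive weight/height for patient(s): ",
         paste(df$patient_id[unique(c(bad_w, bad_h))], collapse = ", "))

  df$bsa_available <- !is.na(df$weight_kg) & !is.na(df$height_cm)
  attr(df, "time_unit") <- time_unit
  df
}
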