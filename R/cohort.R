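# Cohort data model: one row per patient, reserved clinical/acquisition
# columns plus an arbitrary number of numeric radiomic-feature columns.

metadata_columns <- function() {
  c("scanner_model", "convolution_kernel",
    "pixel_spacing_mm", "slice_thickness_mm", "tube_voltage_kvp")
}

reserved_columns <- function() {
  c("patient_id", "label", "histotype", metadata_columns(), ".synthetic")
}

#' Names of the radiomic-feature columns of a cohort table
#'
#' Every column that is not one of the reserved clinical/acquisition columns
#' (`patient_id`, `label`, `histotype`, scanner and reconstruction metadata,
#' `.synthetic`) is treated as a radiomic feature.
#'
#' @param x A cohort tibble (see [as_cohort()]).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(x) {
  setdiff(names(x), reserved_columns())
}

#' Validate and class a patient-by-feature table as a cohort
#'
#' A cohort holds one row per patient: a unique `patient_id`, a binary
#' outcome `label` (1 = malignant, 0 = benign), an optional `histotype`,
#' the five CT acquisition/reconstruction metadata columns
#' (`scanner_model`, `convolution_kernel`, `pixel_spacing_mm`,
#' `slice_thickness_mm`, `tube_voltage_kvp`) and numeric feature columns.
#'
#' @param x A data frame with the columns above.
#' @return `x` as a tibble with class `radsig_cohort`, invisibly checked.
#' @export
as_cohort <- function(x) {
  x <- tibble::as_tibble(x)
  validate_cohort(x)
  class(x) <- unique(c("radsig_cohort", class(x)))
  x
}

#' Check cohort invariants
#'
#' Errors if patient ids are duplicated, labels are not exactly 0/1,
#' acquisition metadata is missing or non-positive, or any feature value is
#' missing or non-finite.
#'
#' @param x A cohort data frame.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  abort_if(!is.data.frame(x), "cohort must be a data frame")
  needed <- c("patient_id", "label", metadata_columns())
  missing_cols <- setdiff(needed, names(x))
  abort_if(length(missing_cols) > 0,
           paste0("cohort is missing required column(s): ",
                  paste(missing_cols, collapse = ", ")))
  abort_if(anyDuplicated(x$patient_id) > 0,
           paste0("duplicate patient_id: ",
                  paste(unique(x$patient_id[duplicated(x$patient_id)]), collapse = ", ")))
  abort_if(!all(x$label %in% c(0L, 1L)),
           "label must be 0 (benign) or 1 (malignant) for every patient")
  for (col in c("pixel_spacing_mm", "slice_thickness_mm", "tube_voltage_kvp")) {
    v <- x[[col]]
    abort_if(!is.numeric(v) || any(!is.finite(v)) || any(v <= 0),
             paste0(col, " must be finite and > 0 for every patient"))
  }
  for (col in c("scanner_model", "convolution_kernel")) {
    abort_if(any(is.na(x[[col]])), paste0(col, " must be present for every patient"))
  }
  feats <- feature_names(x)
  abort_if(anyDuplicated(feats) > 0, "duplicate feature names")
  for (f in feats) {
    v <- x[[f]]
    abort_if(!is.numeric(v), paste0("feature column '", f, "' is not numeric"))
    bad <- which(!is.finite(v))
    abort_if(length(bad) > 0,
             paste0("feature column '", f, "' has missing/non-finite value at row ",
                    bad[1]))
  }
  invisible(x)
}

#' Read a delimited feature table into a cohort
#'
#' Reads a comma-separated table with a header row, one row per patient.
#' Columns can be mapped to the standard roles through `schema`, a named
#' character vector `c(standard_name = file_column_name)`; unmapped columns
#' keep their names. All non-reserved columns are coerced to numeric
#' features; a cell that cannot be parsed is a hard error naming its row and
#' column (no imputation is performed).
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector renaming file columns to
#'   the standard roles, e.g. `c(patient_id = "id", label = "outcome")`.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, schema = NULL) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    abort_if(length(missing_src) > 0,
             paste0("schema maps column(s) absent from the file: ",
                    paste(missing_src, collapse = ", ")))
    for (std in names(schema)) {
      names(raw)[names(raw) == schema[[std]]] <- std
    }
  }
  needed <- c("patient_id", "label", metadata_columns())
  missing_cols <- setdiff(needed, names(raw))
  abort_if(length(missing_cols) > 0,
           paste0("input table is missing required column(s): ",
                  paste(missing_cols, collapse = ", ")))
  numeric_cols <- c("label", "pixel_spacing_mm", "slice_thickness_mm",
                    "tube_voltage_kvp", setdiff(names(raw), reserved_columns()))
  for (col in numeric_cols) {
    v <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(parsed) & !is.na(v))
    abort_if(length(bad) > 0,
             paste0("non-numeric value '", v[bad[1]], "' in column '", col,
                    "', row ", bad[1]))
    raw[[col]] <- parsed
  }
  raw$label <- as.integer(raw$label)
  if (".synthetic" %in% names(raw)) raw$.synthetic <- as.logical(raw$.synthetic)
  as_cohort(raw)
}

#' Write a cohort to a delimited file with a JSON sidecar
#'
#' Writes the table as CSV (full float precision, round-trip safe) and, by
#' default, a `<path>.json` sidecar echoing the cohort composition, feature
#' names, and the generator ground-truth roles when present.
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sidecar = TRUE) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path, progress = FALSE)
  if (sidecar) {
    info <- list(
      n_patients = nrow(cohort),
      n_malignant = sum(cohort$label == 1),
      n_benign = sum(cohort$label == 0),
      feature_names = feature_names(cohort)
    )
    roles <- attr(cohort, "roles")
    if (!is.null(roles)) info$roles <- roles
    jsonlite::write_json(info, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Stratified train/test split of a cohort
#'
#' Splits patients into train and test sets at `test_fraction`, balanced on
#' the outcome label. Per-class test counts are the rounded class shares,
#' reconciled by largest remainder so they sum to the rounded overall count;
#' the 51-malignant / 34-benign cohort at `test_fraction = 0.2` therefore
#' yields a 17-patient test set with 10 malignant and 7 benign members.
#'
#' @param cohort A cohort tibble; every row must carry a label.
#' @param test_fraction Fraction of patients assigned to the test set,
#'   strictly between 0 and 1. Default 0.2.
#' @param stratify Balance the split on the outcome label? Default `TRUE`.
#' @param seed Optional integer seed; identical seeds give identical splits.
#'   `NULL` draws from the current RNG stream.
#' @return A list with cohort tibbles `train` and `test`.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2, stratify = TRUE,
                             seed = NULL) {
  abort_if(!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1,
           "test_fraction must be strictly between 0 and 1")
  n <- nrow(cohort)
  with_seed(seed, {
    if (!stratify) {
      n_test <- round_half_up(n * test_fraction)
      abort_if(n_test < 1 || n_test >= n, "split leaves an empty train or test set")
      idx <- sample.int(n, n_test)
    } else {
      classes <- sort(unique(cohort$label))
      n_class <- vapply(classes, function(cl) sum(cohort$label == cl), integer(1))
      abort_if(any(n_class < 2), "each class needs at least 2 members to split")
      ideal <- n_class * test_fraction
      counts <- floor(ideal)
      target <- round_half_up(n * test_fraction)
      short <- target - sum(counts)
      if (short > 0) {
        # largest-remainder apportionment; ties go to the larger class
        ord <- order(ideal - counts, n_class, decreasing = TRUE)
        bump <- ord[seq_len(min(short, length(ord)))]
        counts[bump] <- counts[bump] + 1
      } else if (short < 0) {
        ord <- order(ideal - counts, -n_class)
        drop_from <- ord[seq_len(min(-short, length(ord)))]
        counts[drop_from] <- counts[drop_from] - 1
      }
      abort_if(any(counts < 1),
               "a class would receive no test members; use a larger test_fraction")
      abort_if(any(counts >= n_class),
               "a class would have no training members; use a smaller test_fraction")
      idx <- integer(0)
      for (i in seq_along(classes)) {
        members <- which(cohort$label == classes[i])
        idx <- c(idx, members[sample.int(length(members), counts[i])])
      }
    }
    list(train = cohort[setdiff(seq_len(n), idx), , drop = FALSE],
         test = cohort[sort(idx), , drop = FALSE])
  })
}
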