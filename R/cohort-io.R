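#' Column schema of the flat per-eye cohort CSV
#'
#' One row per eye; keratometry columns are suffixed by epoch
#' (`preop`/`postop`) and zone (`24` = 2.4 mm, `33` = 3.3 mm).  Manifest
#' refraction is stored as sphere/cylinder/axis at the spectacle plane; the
#' cylinder convention on disk may be plus or minus
#' (see the `cylinder_convention` argument of [read_cohort()]) and is
#' canonicalized to minus-cylinder in memory.  Optional columns may be
#' absent; rules that depend on them are then skipped.
#'
#' The same dictionary ships as a CSV at
#' `system.file("extdata", "cohort_schema.csv", package = "astigzone")`.
#'
#' @return A tibble with columns `column`, `type`, `unit`, `required`,
#'   `description`.
#' @export
cohort_schema <- function() {
  k_cols <- expand.grid(kind = c("flat_k", "steep_k", "steep_axis"),
                        zone = c("24", "33"), epoch = c("preop", "postop"),
                        stringsAsFactors = FALSE)
  k <- tibble::tibble(
    column = paste(k_cols$epoch, k_cols$kind, k_cols$zone, sep = "_"),
    type = "numeric",
    unit = ifelse(k_cols$kind == "steep_axis", "degree", "D"),
    required = TRUE,
    description = sprintf("%s %s at the %s-mm zone",
                          ifelse(k_cols$epoch == "preop", "Preoperative", "Postoperative"),
                          c(flat_k = "flattest keratometry",
                            steep_k = "steepest keratometry",
                            steep_axis = "steep-meridian axis")[k_cols$kind],
                          ifelse(k_cols$zone == "24", "2.4", "3.3")))
  dplyr::bind_rows(
    tibble::tribble(
      ~column, ~type, ~unit, ~required, ~description,
      "patient_id", "character", "", TRUE, "Opaque patient identifier",
      "eye_id", "character", "", TRUE, "Opaque eye identifier, unique per row",
      "laterality", "character", "", TRUE, "OD (right) or OS (left)",
      "age", "numeric", "year", TRUE, "Age at surgery, in (0, 120)",
      "sex", "character", "", TRUE, "M or F",
      "axial_length", "numeric", "mm", TRUE, "Axial length, in (15, 40)",
      "iol_power", "numeric", "D", TRUE, "Implanted IOL spherical power"),
    k,
    tibble::tribble(
      ~column, ~type, ~unit, ~required, ~description,
      "ref_sphere", "numeric", "D", TRUE, "Postoperative manifest sphere (spectacle plane)",
      "ref_cylinder", "numeric", "D", TRUE, "Postoperative manifest cylinder (spectacle plane)",
      "ref_axis", "numeric", "degree", TRUE, "Manifest cylinder axis",
      "corneal_irregularity", "numeric", "", FALSE, "Scheimpflug corneal irregularity index",
      "bcva_decimal", "numeric", "", FALSE, "Postoperative best corrected visual acuity, decimal",
      "prior_refractive_surgery", "logical", "", FALSE, "History of refractive/intraocular surgery",
      "complication", "logical", "", FALSE, "Intra- or postoperative complication",
      "corneal_opacity", "logical", "", FALSE, "Corneal opacity"))
}

k_columns <- function() {
  grep("_k_|_axis_", cohort_schema()$column, value = TRUE)
}

#' Transpose a sphero-cylinder to minus-cylinder convention
#'
#' Rows with positive cylinder are transposed
#' (`sphere + cyl, -cyl, axis + 90`); the axis is normalized to `[0, 180)`.
#' Minus-cylinder rows are returned unchanged apart from axis
#' normalization.
#'
#' @param sphere,cylinder Diopters.
#' @param axis Cylinder axis, degrees.
#' @return Tibble with columns `sphere`, `cylinder` (`<= 0`), `axis`.
#' @export
#' @examples
#' as_minus_cylinder(0, 1, 90)  # 1.00 / -1.00 x 180
as_minus_cylinder <- function(sphere, cylinder, axis) {
  plus <- !is.na(cylinder) & cylinder > 0
  tibble::tibble(
    sphere = ifelse(plus, sphere + cylinder, sphere),
    cylinder = ifelse(plus, -cylinder, cylinder),
    axis = normalize_axis(ifelse(plus, axis + 90, axis)))
}

validate_cohort_rows <- function(data) {
  n <- nrow(data)
  reasons <- rep("", n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    reasons[bad] <<- ifelse(reasons[bad] == "", msg, paste(reasons[bad], msg, sep = "; "))
  }
  num_req <- intersect(cohort_schema()$column[cohort_schema()$type == "numeric" &
                                                cohort_schema()$required],
                       names(data))
  for (col in num_req) add(is.na(data[[col]]), paste0("non-numeric or missing ", col))
  for (epoch in c("preop", "postop")) {
    for (zone in c("24", "33")) {
      fl <- data[[paste(epoch, "flat_k", zone, sep = "_")]]
      st <- data[[paste(epoch, "steep_k", zone, sep = "_")]]
      add(st < fl, paste0("steep K < flat K (", epoch, ", ", zone, ")"))
    }
  }
  axis_cols <- grep("axis", names(data), value = TRUE)
  for (col in axis_cols) add(data[[col]] < 0 | data[[col]] > 180,
                             paste0(col, " outside [0, 180]"))
  add(data$age <= 0 | data$age >= 120, "age outside (0, 120)")
  add(data$axial_length <= 15 | data$axial_length >= 40,
      "axial length outside (15, 40)")
  add(!data$laterality %in% c("OD", "OS"), "laterality not OD/OS")
  add(duplicated(data$eye_id), "duplicate eye_id")
  reasons
}

#' Read a per-eye cohort CSV
#'
#' Reads a cohort in the [cohort_schema()] layout, canonicalizes axes to
#' `[0, 180)` and the manifest refraction to minus-cylinder, and applies
#' row-level validity checks (steep K >= flat K per zone and epoch, axis and
#' biometric ranges, unique eye ids).  Malformed rows are not silently
#' dropped: they are collected in a rejects report retrievable with
#' [cohort_rejects()].
#'
#' @param path Path to a CSV file (RFC 4180, UTF-8, `.` decimal separator).
#' @param cylinder_convention `"minus"` (default) or `"plus"`: the sign
#'   convention of `ref_cylinder` on disk.  Plus-cylinder input is
#'   transposed on read.
#' @return A tibble of valid eyes with attributes `rejects` (tibble with
#'   `row`, `eye_id`, `reason`) and `provenance`.
#' @export
read_cohort <- function(path, cylinder_convention = c("minus", "plus")) {
  cylinder_convention <- match.arg(cylinder_convention)
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  schema <- cohort_schema()
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(schema$column[schema$required], names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- raw
  for (col in intersect(schema$column[schema$type == "numeric"], names(data))) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  for (col in intersect(schema$column[schema$type == "logical"], names(data))) {
    data[[col]] <- as.logical(data[[col]])
  }
  # canonicalize to minus-cylinder; transposition also fixes the occasional
  # plus-cylinder row in a nominally minus-convention file
  r <- as_minus_cylinder(data$ref_sphere, data$ref_cylinder, data$ref_axis)
  data$ref_sphere <- r$sphere; data$ref_cylinder <- r$cylinder; data$ref_axis <- r$axis
  for (col in intersect(grep("axis", names(data), value = TRUE), names(data))) {
    ok <- !is.na(data[[col]]) & data[[col]] == 180
    data[[col]][ok] <- 0
  }
  reasons <- validate_cohort_rows(data)
  rejects <- tibble::tibble(row = which(reasons != ""),
                            eye_id = data$eye_id[reasons != ""],
                            reason = reasons[reasons != ""])
  cohort <- tibble::as_tibble(data[reasons == "", , drop = FALSE])
  attr(cohort, "rejects") <- rejects
  attr(cohort, "provenance") <- paste0("read_cohort(", path, ")")
  cohort
}

#' Rejected rows from the last [read_cohort()] call on a cohort
#'
#' @param cohort A cohort tibble as returned by [read_cohort()].
#' @return Tibble with columns `row`, `eye_id`, `reason` (empty if none).
#' @export
cohort_rejects <- function(cohort) {
  r <- attr(cohort, "rejects")
  if (is.null(r)) tibble::tibble(row = integer(), eye_id = character(),
                                 reason = character()) else r
}

#' Write a cohort to CSV
#'
#' Numeric fields are written with six decimal places so that
#' `read_cohort(write_cohort(x))` reproduces `x` field-by-field at that
#' precision.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]])) out[[col]] <- round(out[[col]], 6)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Apply the study's row-level inclusion filters
#'
#' Excludes, in order: eyes below the best-corrected visual acuity floor
#' (decimal notation; the 20/30 criterion is decimal 0.67), eyes with prior
#' refractive or intraocular surgery, eyes with surgical complications, and
#' eyes with corneal opacity.  A rule whose column is absent from the
#' cohort is skipped and logged as not applied.  Eyes are counted against
#' the first rule (in this order) that excludes them, so the retained count
#' plus the logged exclusions always totals the input.
#'
#' @param cohort Cohort tibble.
#' @param bcva_min Decimal BCVA floor (default 0.67, i.e. Snellen 20/30
#'   rounded to 2 decimals).
#' @return A list with `cohort` (filtered tibble) and `log` (tibble with
#'   `rule`, `applied`, `n_excluded`).
#' @export
apply_inclusion_filters <- function(cohort, bcva_min = 0.67) {
  rules <- list(
    low_bcva = function(d) d$bcva_decimal < bcva_min,
    prior_refractive_surgery = function(d) d$prior_refractive_surgery,
    complication = function(d) d$complication,
    corneal_opacity = function(d) d$corneal_opacity)
  cols <- c(low_bcva = "bcva_decimal", prior_refractive_surgery = "prior_refractive_surgery",
            complication = "complication", corneal_opacity = "corneal_opacity")
  keep <- rep(TRUE, nrow(cohort))
  log <- tibble::tibble(rule = names(rules), applied = FALSE, n_excluded = 0L)
  for (i in seq_along(rules)) {
    rule <- names(rules)[i]
    if (!cols[[rule]] %in% names(cohort)) next
    log$applied[i] <- TRUE
    hit <- rules[[rule]](cohort)
    hit[is.na(hit)] <- FALSE
    newly <- keep & hit
    log$n_excluded[i] <- sum(newly)
    keep <- keep & !hit
  }
  out <- cohort[keep, , drop = FALSE]
  attr(out, "rejects") <- attr(cohort, "rejects")
  attr(out, "provenance") <- attr(cohort, "provenance")
  list(cohort = out, log = log)
}
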