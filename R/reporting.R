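#' Configuration for a full pipeline run
#'
#' @param input Path to a cohort CSV, or `NULL` to generate a synthetic
#'   cohort from `generator`.
#' @param generator A [generator_config()] (used when `input` is `NULL`).
#' @param zones Zones to analyze, subset of `c(2.4, 3.3)`, non-empty.
#' @param path Prediction path: `"postop_k"`, `"preop_sia"`, or `"both"`.
#' @param pca Analysis-side [pca_model()] standing in for a proprietary
#'   toric calculator's posterior-cornea adjustment; the report always
#'   states which model was used.
#' @param vertex_distance Metres.
#' @param ellipse_level Confidence level for ellipses.
#' @param thresholds Ascending diopter thresholds for cumulative tables.
#' @param apply_filters Apply [apply_inclusion_filters()] before analysis.
#' @param bcva_min Decimal BCVA floor for the inclusion filter.
#' @param output_dir Directory for CSV/markdown/SVG output, or `NULL` to
#'   keep everything in memory.
#' @param cylinder_convention Disk cylinder convention for `input`.
#' @return A classed list (`analysis_config`).
#' @export
analysis_config <- function(input = NULL,
                            generator = generator_config(),
                            zones = c(2.4, 3.3),
                            path = c("both", "postop_k", "preop_sia"),
                            pca = pca_fixed_atr(0.30),
                            vertex_distance = 0.012,
                            ellipse_level = 0.95,
                            thresholds = c(0.5, 1, 1.5, 2),
                            apply_filters = TRUE,
                            bcva_min = 0.67,
                            output_dir = NULL,
                            cylinder_convention = "minus") {
  path <- match.arg(path)
  stopifnot(length(zones) >= 1, all(zones %in% c(2.4, 3.3)),
            !is.unsorted(thresholds), inherits(pca, "pca_model"))
  structure(as.list(environment()), class = "analysis_config")
}

table1_characteristics <- function(cohort, zone) {
  pre <- zone_ca(cohort, zone, "preop")
  subtype <- classify_astigmatism(pre$axis)
  fmt <- function(x) sprintf("%.1f ± %.1f (%.2f–%.2f)",
                             mean(x), stats::sd(x), min(x), max(x))
  counts <- table(subtype)
  tibble::tibble(
    parameter = c("Eyes", "Patients", "Age (y)", "Sex (M:F)",
                  "Laterality (OD:OS)", "Axial length (mm)", "IOL power (D)",
                  "Preoperative CA (D)", "Astigmatism type (WTR:ATR:oblique)"),
    value = c(nrow(cohort),
              length(unique(cohort$patient_id)),
              fmt(cohort$age),
              sprintf("%d:%d", sum(cohort$sex == "M"), sum(cohort$sex == "F")),
              sprintf("%d:%d", sum(cohort$laterality == "OD"),
                      sum(cohort$laterality == "OS")),
              fmt(cohort$axial_length),
              fmt(cohort$iol_power),
              sprintf("%.1f ± %.1f (%.2f–%.2f)", mean(pre$magnitude),
                      stats::sd(pre$magnitude), min(pre$magnitude),
                      max(pre$magnitude)),
              sprintf("%d (%.1f%%):%d (%.1f%%):%d (%.1f%%)",
                      counts[1], 100 * counts[1] / nrow(cohort),
                      counts[2], 100 * counts[2] / nrow(cohort),
                      counts[3], 100 * counts[3] / nrow(cohort))))
}

table2_keratometry <- function(cohort, zones, thresholds) {
  rows <- list()
  for (epoch in c("preop", "postop")) {
    for (zone in zones) {
      suffix <- zone_suffix(zone)
      flat <- cohort[[paste0(epoch, "_flat_k_", suffix)]]
      steep <- cohort[[paste0(epoch, "_steep_k_", suffix)]]
      ca <- steep - flat
      cum <- cumulative_magnitude_table(ca, thresholds)
      rows[[length(rows) + 1]] <- tibble::tibble(
        epoch = epoch, zone = zone,
        average_k_mean = mean((flat + steep) / 2),
        average_k_sd = stats::sd((flat + steep) / 2),
        flat_k_mean = mean(flat), flat_k_sd = stats::sd(flat),
        steep_k_mean = mean(steep), steep_k_sd = stats::sd(steep),
        mean_abs_ca = mean(ca), sd_abs_ca = stats::sd(ca),
        !!!stats::setNames(as.list(cum$n_le),
                           sprintf("n_le_%.2f", cum$threshold)))
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the full zone-comparison analysis pipeline
#'
#' Reads (or generates) a cohort, applies inclusion filters, mirrors left
#' eyes, computes per-eye predicted residual astigmatism and prediction
#' errors per zone and path, and assembles the report: cohort
#' characteristics, per-zone keratometry and CA summaries with cumulative
#' counts, per-subtype centroid summaries with paired between-zone tests,
#' cumulative error distributions, and double-angle plots.  Every table
#' value is produced by the statistics layer; the renderer only formats.
#'
#' @param config An [analysis_config()].
#' @return A `report_bundle` list: `cohort`, `filter_log`, `records` (per
#'   eye, zone and path), `table1`, `table2`, `table3` (per path),
#'   `fig1_data` (cumulative proportions of absolute error), `sia` (the
#'   cohort-mean SIA per zone, if the preoperative path ran), `figures`
#'   (ggplot objects), `pca_model_name`, `logs`, `config`.  With
#'   `config$output_dir` set, tables are also written as CSV and markdown
#'   and figures as SVG.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  logs <- character()
  truth <- NULL
  if (!is.null(config$input)) {
    cohort <- read_cohort(config$input, config$cylinder_convention)
    nrej <- nrow(cohort_rejects(cohort))
    if (nrej > 0) logs <- c(logs, sprintf("%d malformed row(s) rejected on read", nrej))
  } else {
    gen <- generate_cohort(config$generator)
    cohort <- gen$cohort
    truth <- gen$truth
    logs <- c(logs, attr(cohort, "provenance"))
  }
  if (config$apply_filters) {
    flt <- apply_inclusion_filters(cohort, config$bcva_min)
    cohort <- flt$cohort
    filter_log <- flt$log
    logs <- c(logs, sprintf("inclusion filters: %d eye(s) excluded",
                            sum(filter_log$n_excluded)))
  } else {
    filter_log <- NULL
  }
  if (nrow(cohort) == 0) stop("no eyes remain after inclusion filters", call. = FALSE)
  zones <- sort(config$zones)
  for (zone in zones) {
    suffix <- zone_suffix(zone)
    needed <- paste0(c("preop_flat_k_", "postop_flat_k_"), suffix)
    if (!all(needed %in% names(cohort))) {
      stop("cohort lacks keratometry for the requested ", zone, "-mm zone",
           call. = FALSE)
    }
  }
  paths <- if (config$path == "both") c("preop_sia", "postop_k") else config$path
  sia_tbl <- NULL
  if ("preop_sia" %in% paths) {
    sia_tbl <- dplyr::bind_rows(lapply(zones, function(z) {
      dplyr::bind_cols(tibble::tibble(zone = z), mean_sia(cohort, z))
    }))
  }
  records <- dplyr::bind_rows(lapply(paths, function(p) {
    dplyr::bind_rows(lapply(zones, function(z) {
      sia <- if (p == "preop_sia") {
        s <- sia_tbl[sia_tbl$zone == z, ]
        c(s$x, s$y)
      } else NULL
      prediction_records(cohort, z, p, pca = config$pca, sia = sia,
                         vertex_distance = config$vertex_distance)
    }))
  }))
  table1 <- table1_characteristics(cohort, zones[1])
  table2 <- table2_keratometry(cohort, zones, config$thresholds)
  table3 <- list()
  for (p in paths) {
    rp <- records[records$path == p, ]
    if (length(zones) == 2) {
      table3[[p]] <- subgroup_analysis(rp)
    } else {
      logs <- c(logs, "single zone requested: no paired zone comparison")
      table3[[p]] <- list(
        summaries = dplyr::bind_cols(
          tibble::tibble(group = "Total", zone = zones[1]),
          centroid_summary(rp$error_x, rp$error_y)),
        comparisons = NULL, discordant_n = 0L, dropped = character())
    }
  }
  fig1_data <- dplyr::bind_rows(lapply(split(records, list(records$zone, records$path)),
                                       function(r) {
    if (nrow(r) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(zone = r$zone[1], path = r$path[1]),
                     cumulative_magnitude_table(r$abs_error, config$thresholds))
  }))
  figures <- list()
  for (p in paths) {
    for (z in zones) {
      r <- records[records$path == p & records$zone == z, ]
      groups <- c("all", levels(r$subtype))
      for (g in groups) {
        rr <- if (g == "all") r else r[as.character(r$subtype) == g, ]
        if (nrow(rr) == 0) next
        key <- sprintf("%s_%s_%s", p, zone_suffix(z), tolower(g))
        figures[[key]] <- render_double_angle_plot(
          tibble::tibble(x = rr$error_x, y = rr$error_y),
          level = config$ellipse_level,
          title = sprintf("%.1f mm, %s, %s", z, p, g))
      }
    }
  }
  bundle <- structure(list(
    cohort = cohort, truth = truth, filter_log = filter_log,
    records = records, table1 = table1, table2 = table2, table3 = table3,
    fig1_data = fig1_data, sia = sia_tbl, figures = figures,
    pca_model_name = config$pca$name, logs = logs, config = config),
    class = "report_bundle")
  if (!is.null(config$output_dir)) write_report_bundle(bundle, config$output_dir)
  bundle
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) formatC(x, digits = 4, format = "fg", flag = "#") else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write a report bundle to disk
#'
#' Tables as CSV plus markdown, per-eye records as CSV, figures as SVG.
#' The markdown report states which PCA model stood in for the toric
#' calculator's posterior-cornea adjustment.
#'
#' @param bundle A `report_bundle` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$table1, file.path(dir, "table1_characteristics.csv"))
  readr::write_csv(bundle$table2, file.path(dir, "table2_keratometry.csv"))
  readr::write_csv(bundle$records, file.path(dir, "per_eye_records.csv"))
  readr::write_csv(bundle$fig1_data, file.path(dir, "fig1_cumulative_error.csv"))
  if (!is.null(bundle$sia)) readr::write_csv(bundle$sia, file.path(dir, "mean_sia.csv"))
  md <- c("# Zone-comparison astigmatism report", "",
          sprintf("PCA model used in place of a proprietary toric calculator: `%s`.",
                  bundle$pca_model_name), "",
          "No multiple-testing correction is applied to the reported p-values.", "",
          "## Cohort characteristics", "", md_table(bundle$table1), "",
          "## Keratometry by zone", "", md_table(bundle$table2), "")
  for (p in names(bundle$table3)) {
    t3 <- bundle$table3[[p]]
    readr::write_csv(t3$summaries,
                     file.path(dir, sprintf("table3_summaries_%s.csv", p)))
    if (!is.null(t3$comparisons)) {
      readr::write_csv(t3$comparisons,
                       file.path(dir, sprintf("table3_comparisons_%s.csv", p)))
    }
    md <- c(md, sprintf("## Prediction error by subtype (%s path)", p), "",
            md_table(t3$summaries), "")
    if (!is.null(t3$comparisons)) md <- c(md, md_table(t3$comparisons), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  for (key in names(bundle$figures)) {
    save_svg(bundle$figures[[key]], file.path(dir, paste0("fig2_", key, ".svg")))
  }
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  eyes:", nrow(x$cohort), " zones:", paste(unique(x$records$zone), collapse = ", "),
      " paths:", paste(unique(x$records$path), collapse = ", "), "\n")
  cat("  PCA model:", x$pca_model_name, "\n")
  for (p in names(x$table3)) {
    tot <- x$table3[[p]]$summaries
    tot <- tot[tot$group == "Total", ]
    for (i in seq_len(nrow(tot))) {
      cat(sprintf("  [%s] %.1f mm centroid %.2f D @ %.0f° (±%.2f), MAE %.2f D\n",
                  p, tot$zone[i], tot$centroid_magnitude[i], tot$centroid_axis[i],
                  tot$combined_sd[i], tot$mean_abs[i]))
    }
  }
  invisible(x)
}
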