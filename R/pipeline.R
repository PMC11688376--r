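#' Run the biometry pipeline over a cohort
#'
#' Applies the measurement chain to every case of a study table and
#' assembles a per-case report; when clinician gestational-age estimates
#' are present, a Bland-Altman agreement analysis of automated versus
#' clinician estimates is appended. Cases are supplied either as
#' precomputed masks (the usual desk-scale route) or as images to be
#' segmented by a trained model.
#'
#' Per-case failures (unreadable files, empty masks) do not abort the run:
#' they are collected in `failures` and excluded from the report.
#'
#' @param records A data frame with columns `case_id`, either `mask`
#'   (list-column of matrices) or `mask_path`, spacing columns
#'   `row_spacing_cm`/`col_spacing_cm` (or a `spacing` list-column), and
#'   optionally `clinician_gw` plus, with `model`, `image`/`image_path`.
#' @param model Optional trained [build_model()] network used to segment
#'   `image` into a mask when no mask is given.
#' @param threshold Binarization threshold for model predictions.
#' @return A list of class `"sac_report"`: `report` (tibble `case_id`,
#'   `DM_cm`, `Dm_cm`, `GW_weeks`), `agreement` (a [agreement()] object or
#'   NULL), `failures` (tibble `case_id`, `error`), `n_requested`.
#' @export
run_pipeline <- function(records, model = NULL, threshold = 0.5) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) abort("empty record list")
  if (!"case_id" %in% names(records))
    records$case_id <- sprintf("case_%04d", seq_len(nrow(records)))

  rows <- list(); fails <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      mask <- pipeline_mask(rec, model, threshold)
      spacing <- pipeline_spacing(rec)
      bio <- run_biometry(mask, spacing)
      tibble::tibble(case_id = rec$case_id, DM_cm = bio$DM_cm,
                     Dm_cm = bio$Dm_cm, GW_weeks = bio$GW_weeks)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(case_id = rec$case_id, error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  report <- dplyr::bind_rows(rows)
  agr <- NULL
  if ("clinician_gw" %in% names(records) && nrow(report) >= 2L) {
    merged <- dplyr::inner_join(report,
                                records[, c("case_id", "clinician_gw")],
                                by = "case_id")
    agr <- agreement(merged, reference = "clinician_gw", test = "GW_weeks")
  }
  structure(list(report = report, agreement = agr,
                 failures = dplyr::bind_rows(fails),
                 n_requested = nrow(records)),
            class = "sac_report")
}

pipeline_mask <- function(rec, model, threshold) {
  if ("mask" %in% names(rec) && !is.null(rec$mask[[1L]]))
    return(as_binary_mask(rec$mask[[1L]]))
  if ("mask_path" %in% names(rec) && !is.na(rec$mask_path))
    return(read_mask(rec$mask_path))
  if (is.null(model))
    abort("record supplies no mask and no model was given")
  img <- if ("image" %in% names(rec) && !is.null(rec$image[[1L]]))
    rec$image[[1L]] else read_image(rec$image_path)
  predict_mask(model, img, threshold)
}

pipeline_spacing <- function(rec) {
  if ("spacing" %in% names(rec) && !is.null(rec$spacing[[1L]]))
    return(as_spacing(rec$spacing[[1L]]))
  if (all(c("row_spacing_cm", "col_spacing_cm") %in% names(rec)))
    return(pixel_spacing(rec$row_spacing_cm, rec$col_spacing_cm))
  abort("record has no pixel spacing")
}

#' @export
print.sac_report <- function(x, ...) {
  cat(sprintf("<sac_report> %d/%d cases measured\n",
              nrow(x$report), x$n_requested))
  print(x$report)
  if (!is.null(x$agreement)) print(x$agreement)
  if (nrow(x$failures) > 0L) {
    cat("failures:\n")
    print(x$failures)
  }
  invisible(x)
}

#' @export
tidy.sac_report <- function(x, ...) x$report

#' @export
glance.sac_report <- function(x, ...) {
  out <- tibble::tibble(n_requested = x$n_requested, n_measured = nrow(x$report),
                        n_failed = nrow(x$failures))
  if (!is.null(x$agreement)) out <- dplyr::bind_cols(out, glance(x$agreement))
  out
}

#' Write a biometry report to CSV
#'
#' Gestational weeks are written with two decimals (full precision is kept
#' in the in-memory tibble and in JSON exports).
#'
#' @param x A [run_pipeline()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(x, path) {
  stopifnot(inherits(x, "sac_report"))
  out <- x$report
  out$GW_weeks <- sprintf("%.2f", out$GW_weeks)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
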