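# End-to-end study pipeline: per-specimen metrics, group comparisons and
# the four bivariate PGLS analyses (TTL ~ r; ETL ~ ITL raw, log-log and
# as fractions of a circle; sqrt(CSA) ~ ETL; SMA^(1/4) ~ ETL).
# The pipeline adds no arithmetic of its own beyond table joins; every
# number traces to a module operation with its own tests.

#' Per-specimen incisor metrics
#'
#' Combines arc geometry from the landmark table with cross-sectional
#' geometry from optional per-specimen masks. Specimens with invalid
#' landmarks (missing/duplicate labels, coincident or collinear points)
#' are dropped and reported in the `rejected` attribute rather than
#' failing the run; specimens without a mask get `NA` section columns.
#'
#' @param landmarks Landmark table ([read_landmarks()] layout).
#' @param masks Optional named list of [section_mask()] objects, names
#'   matching `specimen_id`.
#' @param loading_axis Passed to [section_geometry()].
#' @return A tibble, one row per valid specimen, with the arc-metric
#'   columns plus `CSA_mm2`, `Ixx`, `Iyy`, `Ixy`, `Imin`, `Imax`,
#'   `SMA_loading`, `sqrt_CSA`, `fourth_root_SMA`. Attribute `rejected`
#'   is a tibble (`specimen_id`, `reason`) of dropped specimens.
#' @export
compute_specimen_metrics <- function(landmarks, masks = NULL,
                                     loading_axis = "mesio-distal") {
  landmarks <- validate_landmarks(landmarks)
  if (nrow(landmarks) == 0) stop("empty landmark table", call. = FALSE)
  ids <- unique(landmarks$specimen_id)
  per <- purrr::map(ids, function(id) {
    res <- tryCatch(
      arc_metrics(landmarks[landmarks$specimen_id == id, , drop = FALSE]),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) list(id = id, error = res) else list(metrics = res)
  })
  rejected <- purrr::keep(per, ~ !is.null(.x$error)) |>
    purrr::map(~ tibble::tibble(specimen_id = .x$id, reason = .x$error)) |>
    purrr::list_rbind()
  if (is.null(rejected) || nrow(rejected) == 0) {
    rejected <- tibble::tibble(specimen_id = character(),
                               reason = character())
  }
  metrics <- purrr::keep(per, ~ !is.null(.x$metrics)) |>
    purrr::map(~ .x$metrics) |>
    purrr::list_rbind()
  if (nrow(metrics) == 0) {
    stop("no specimen had a valid landmark triplet", call. = FALSE)
  }
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " specimen(s) rejected: ",
            paste(rejected$specimen_id, collapse = ", "), call. = FALSE)
  }
  if (!is.null(masks)) {
    sect <- purrr::imap(masks, function(m, id) {
      dplyr::bind_cols(tibble::tibble(specimen_id = id),
                       section_geometry(m, loading_axis = loading_axis))
    }) |>
      purrr::list_rbind() |>
      dplyr::select(-"centroid_x", -"centroid_y", -"principal_angle")
    metrics <- dplyr::left_join(metrics, sect, by = "specimen_id")
  }
  attr(metrics, "rejected") <- rejected
  metrics
}

#' Run the full comparative study
#'
#' Computes per-specimen metrics, rodent/non-rodent style group
#' summaries of the fraction of circle, the comparison against the
#' published upper-incisor reference, and the suite of bivariate PGLS
#' fits (with OLS-on-star-tree behaviour recoverable by supplying a star
#' phylogeny). Requires one specimen per species; duplicated species are
#' averaged with a warning.
#'
#' @inheritParams compute_specimen_metrics
#' @param tree A `phylo` tree whose tips name the specimens/species.
#' @param species_table Optional tibble (`species`, `pct_circle`,
#'   `is_rodent`) used for the group-summary stage; defaults to treating
#'   every specimen as one species with no grouping.
#' @param transforms Named list overriding the transform used per
#'   analysis; see Details.
#' @return An object of class `study_report`: a list with `metrics`,
#'   `rejected`, `summaries`, `comparison`, `fits` (named list of
#'   [pgls_fit()] objects), `fit_table` (their [glance.pgls_fit()] rows)
#'   and a `provenance` block.
#'
#' @details The default analyses are `TTL_vs_r` (untransformed),
#' `ETL_vs_ITL` (untransformed), `ETL_vs_ITL_log` (log-log),
#' `ETL_vs_ITL_fraction` (both arc lengths divided by the specimen's
#' circumference 2 pi r), `sqrtCSA_vs_ETL` and `fourthrootSMA_vs_ETL`
#' (the linearized cross-section analyses; these require masks).
#' @export
run_study <- function(landmarks, masks = NULL, tree,
                      species_table = NULL,
                      loading_axis = "mesio-distal",
                      transforms = list()) {
  metrics <- compute_specimen_metrics(landmarks, masks,
                                      loading_axis = loading_axis)
  if (anyDuplicated(metrics$specimen_id)) {
    warning("duplicated species averaged to one row each", call. = FALSE)
    metrics <- metrics |>
      dplyr::group_by(.data$specimen_id) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                     ~ mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  summaries <- if (!is.null(species_table)) {
    group_summary(species_table, .data$pct_circle, by = .data$is_rodent)
  } else {
    group_summary(metrics, .data$pct_circle)
  }
  comparison <- if (!is.null(species_table)) {
    incisor_comparison(species_table$pct_circle[species_table$is_rodent])
  } else {
    incisor_comparison(metrics$pct_circle)
  }

  analyses <- list(
    TTL_vs_r = list(y = "r", x = "TTL", ty = "none", tx = "none"),
    ETL_vs_ITL = list(y = "ETL", x = "ITL", ty = "none", tx = "none"),
    ETL_vs_ITL_log = list(y = "ETL", x = "ITL", ty = "log10",
                          tx = "log10"),
    ETL_vs_ITL_fraction = list(y = "ETL", x = "ITL",
                               ty = "fraction_of_circle",
                               tx = "fraction_of_circle"),
    sqrtCSA_vs_ETL = list(y = "CSA_mm2", x = "ETL", ty = "sqrt",
                          tx = "none"),
    fourthrootSMA_vs_ETL = list(y = "SMA_loading", x = "ETL",
                                ty = "fourth_root", tx = "none")
  )
  for (nm in names(transforms)) {
    if (nm %in% names(analyses)) {
      analyses[[nm]]$ty <- analyses[[nm]]$tx <- transforms[[nm]]
    }
  }
  fits <- list()
  skipped <- character()
  for (nm in names(analyses)) {
    an <- analyses[[nm]]
    if (!an$y %in% names(metrics) || all(is.na(metrics[[an$y]]))) {
      skipped <- c(skipped, nm)
      next
    }
    d <- metrics[stats::complete.cases(metrics[, c(an$x, an$y)]), ]
    fit <- tryCatch(
      pgls_fit(d, !!rlang::sym(an$y), !!rlang::sym(an$x), tree = tree,
               species = .data$specimen_id,
               transform_y = an$ty, transform_x = an$tx),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) skipped <- c(skipped, nm) else fits[[nm]] <- fit
  }
  if (length(skipped) > 0) {
    message("analyses skipped: ", paste(skipped, collapse = ", "))
  }
  fit_table <- purrr::imap(fits, ~ dplyr::bind_cols(
    tibble::tibble(analysis = .y), glance(.x))) |>
    purrr::list_rbind()
  structure(list(
    metrics = metrics,
    rejected = attr(metrics, "rejected"),
    summaries = summaries,
    comparison = comparison,
    fits = fits,
    fit_table = fit_table,
    skipped = skipped,
    provenance = list(
      package_version = as.character(utils::packageVersion("incisorarc")),
      n_specimens = nrow(metrics),
      loading_axis = loading_axis
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", nrow(x$metrics), " specimens, ",
      length(x$fits), " PGLS fits\n", sep = "")
  print(x$fit_table)
  invisible(x)
}

#' Write a study report to disk
#'
#' Metrics as TSV, fits/summaries/tests as JSON. Deterministic for a
#' given report (no timestamps).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics_path <- file.path(dir, "specimen_metrics.tsv")
  readr::write_tsv(report$metrics, metrics_path)
  json_path <- file.path(dir, "study_report.json")
  jsonlite::write_json(list(
    summaries = report$summaries,
    comparison = report$comparison,
    fits = report$fit_table,
    rejected = report$rejected,
    provenance = report$provenance
  ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(metrics = metrics_path, report = json_path))
}
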