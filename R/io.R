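#' Write a cell-index panel to CSV with a JSON sidecar
#'
#' The CSV has columns `time_h, ci, replicate, condition_id`; the sidecar
#' JSON records, per condition id, the dosing (E:T ratio, virus dose,
#' administration times, trigger burden) and the attachment-window end, so
#' that a re-read panel is identical to the in-memory one.
#'
#' @param panel A `ci_panel`.
#' @param path CSV path; the sidecar defaults to `<path>.json`.
#' @param sidecar Sidecar JSON path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(panel, path,
                             sidecar = paste0(path, ".json")) {
  write.csv(as.data.frame(panel)[, c("time_h", "ci", "replicate",
                                     "condition_id")],
            path, row.names = FALSE)
  meta <- lapply(attr(panel, "conditions"), function(m) {
    c(unclass(m$condition),
      list(attach_end = m$attach_end, t_treat = m$t_treat))
  })
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cell-index panel from CSV
#'
#' Validates the schema (required columns, non-negative cell index,
#' strictly increasing times per replicate and condition). A uniform
#' 15-minute spacing is expected; other uniform spacings are accepted with
#' a warning and the observed spacing is stored in the `spacing_h`
#' attribute rather than assumed.
#'
#' @param path CSV path (columns `time_h, ci, replicate, condition_id`).
#' @param sidecar Sidecar JSON path written by [write_series_csv()].
#' @return A `ci_panel`.
#' @export
read_series_csv <- function(path, sidecar = paste0(path, ".json")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "ci", "replicate", "condition_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$ci < 0)) {
    stop("negative cell index at row ", which(df$ci < 0)[1])
  }
  meta_raw <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    stop("sidecar JSON not found: ", sidecar)
  }
  spacings <- c()
  for (id in unique(df$condition_id)) {
    for (r in unique(df$replicate[df$condition_id == id])) {
      tt <- df$time_h[df$condition_id == id & df$replicate == r]
      if (is.unsorted(tt, strictly = TRUE)) {
        bad <- which(diff(tt) <= 0)[1] + 1L
        stop("non-monotone time in condition ", id, " replicate ", r,
             " at row ", bad)
      }
      spacings <- c(spacings, diff(tt))
    }
  }
  spacing <- round(median(spacings), 6)
  if (abs(spacing - 0.25) > 1e-9) {
    warning(sprintf("sampling spacing is %g h, not the usual 0.25 h",
                    spacing))
  }
  meta <- lapply(meta_raw, function(m) {
    list(condition = dose_condition(et_ratio = m$et_ratio, v0 = m$v0,
                                    t_admin_cart = m$t_admin_cart,
                                    t_admin_ov = m$t_admin_ov,
                                    t0_tumor = m$t0_tumor),
         attach_end = m$attach_end, t_treat = m$t_treat)
  })
  attach_end <- vapply(meta, function(m) m$attach_end, numeric(1))
  df$attachment <- df$time_h < attach_end[df$condition_id]
  structure(df, conditions = meta, spacing_h = spacing,
            class = c("ci_panel", "data.frame"))
}

#' Write an infected-fraction assay table to CSV
#'
#' Columns: `dose_moi, time_h, replicate, infected_fraction`.
#'
#' @param assay An `infected_fraction_assay`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(assay, path) {
  write.csv(as.data.frame(assay), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_moi", "time_h", "replicate", "infected_fraction")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(df$infected_fraction < 0 | df$infected_fraction > 1)) {
    stop("infected_fraction outside [0, 1] at row ",
         which(df$infected_fraction < 0 | df$infected_fraction > 1)[1])
  }
  structure(df, class = c("infected_fraction_assay", "data.frame"))
}

#' Serialize a fit result to JSON
#'
#' Writes the per-replicate estimates and the aggregate mean/sd blocks.
#'
#' @param fit A `fit_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result_json <- function(fit, path) {
  jsonlite::write_json(
    list(free_names = fit$free_names,
         per_replicate = fit$per_replicate,
         aggregate = fit$aggregate),
    path, auto_unbox = FALSE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_fit_result_json
#' @export
read_fit_result_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(per_replicate = x$per_replicate,
                 aggregate = x$aggregate,
                 free_names = x$free_names),
            class = "fit_result")
}
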