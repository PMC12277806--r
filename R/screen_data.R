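# Column order of the fixed (non-analyte) part of the plate table.
SCREEN_REQUIRED_COLS <- c("plate_id", "position", "role", "compound_id",
                          "dose_um", "platform", "diameter_um")

#' Well roles recognised by the screen
#'
#' `compound` wells carry a library compound; `vehicle` wells are DMSO-only
#' baselines; `positive` wells are LPS-stimulated; `negative` wells carry the
#' threshold-anchoring inhibitor (tocilizumab); `untreated` wells received
#' nothing and serve as an optional viability reference.
#'
#' @export
well_roles <- function() c("compound", "vehicle", "positive", "negative", "untreated")

#' Culture platforms recognised by the screen
#' @export
screen_platforms <- function() {
  c("spinal_microtissue", "microglia_spheroid", "coculture", "triculture")
}

#' The 14-plex inflammatory cytokine panel
#'
#' Default analyte panel for multiplex profiling of microtissue supernatants.
#' Concentrations are in pg/mL throughout the package.
#'
#' @return Character vector of 14 analyte names.
#' @export
cytokine_panel_14 <- function() {
  c("IL-6", "IL-8", "IL-2", "IL-4", "IL-5", "IL-10", "IL-12", "IL-12p70",
    "IL-13", "IL-17A", "IL-1b", "TNF-a", "IFN-g", "GM-CSF")
}

#' Construct a screen dataset
#'
#' A `screen_dataset` bundles one row per well with the analyte panel and
#' free-form metadata. Analyte concentrations are pg/mL, diameters are
#' micrometres, compound doses are micromolar (controls may override the unit
#' via the `dose_unit` column, e.g. LPS in ug/mL).
#'
#' @param wells data.frame with columns `plate_id`, `position`, `role`,
#'   `compound_id`, `dose_um`, `platform`, `diameter_um` and one numeric
#'   column per analyte. An optional `dose_unit` column is preserved.
#' @param analyte_panel Ordered character vector of analyte column names.
#' @param metadata Named list of free-form metadata (genotype, day, ...).
#' @return Object of class `screen_dataset`.
#' @export
screen_dataset <- function(wells, analyte_panel, metadata = list()) {
  stopifnot(is.data.frame(wells), is.character(analyte_panel))
  missing_cols <- setdiff(SCREEN_REQUIRED_COLS, names(wells))
  if (length(missing_cols) > 0) {
    stop("screen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  missing_an <- setdiff(analyte_panel, names(wells))
  if (length(missing_an) > 0) {
    stop("screen table is missing analyte column(s): ",
         paste(missing_an, collapse = ", "), call. = FALSE)
  }
  bad_role <- setdiff(unique(wells$role), well_roles())
  if (length(bad_role) > 0) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  for (a in analyte_panel) {
    v <- wells[[a]]
    if (!is.numeric(v)) stop("analyte column '", a, "' is not numeric", call. = FALSE)
    neg <- which(!is.na(v) & v < 0)
    if (length(neg) > 0) {
      stop("negative concentration for analyte '", a, "' at row ", neg[1], call. = FALSE)
    }
  }
  bad_diam <- which(!is.na(wells$diameter_um) & wells$diameter_um <= 0)
  if (length(bad_diam) > 0) {
    stop("non-positive diameter at row ", bad_diam[1], call. = FALSE)
  }
  wells$compound_id <- as.character(wells$compound_id)
  wells$compound_id[is.na(wells$compound_id)] <- ""
  structure(list(wells = wells, analyte_panel = analyte_panel, metadata = metadata),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("<screen_dataset> ", nrow(x$wells), " wells, ",
      length(x$analyte_panel), " analytes (",
      paste(utils::head(x$analyte_panel, 4), collapse = ", "),
      if (length(x$analyte_panel) > 4) ", ..." else "", ")\n", sep = "")
  tab <- table(x$wells$platform, x$wells$role)
  print(tab)
  invisible(x)
}

#' Read a plate-format screen table from CSV
#'
#' Expects a UTF-8, comma-delimited file with a header row containing the
#' required columns `plate_id`, `position`, `role`, `compound_id`, `dose_um`,
#' `platform`, `diameter_um`, followed by one numeric column per analyte.
#' A `dose_unit` column, if present, is carried along.
#'
#' @param path Path to the CSV file.
#' @param analyte_panel Optional explicit panel; by default every column that
#'   is not a required/bookkeeping column is treated as an analyte.
#' @return A [screen_dataset()].
#' @export
load_screen_table <- function(path, analyte_panel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
                 error = function(e) stop("empty or unreadable screen table: ",
                                          path, call. = FALSE))
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty screen table: ", path, call. = FALSE)
  missing_cols <- setdiff(SCREEN_REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("screen table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(analyte_panel)) {
    analyte_panel <- setdiff(names(df), c(SCREEN_REQUIRED_COLS, "dose_unit"))
  }
  screen_dataset(df, analyte_panel)
}

#' Write a screen dataset to CSV
#'
#' Inverse of [load_screen_table()]: numeric fields round-trip at full
#' double precision (15 significant digits).
#'
#' @param ds A [screen_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(ds, path) {
  stopifnot(inherits(ds, "screen_dataset"))
  keep <- intersect(c(SCREEN_REQUIRED_COLS, "dose_unit", ds$analyte_panel),
                    names(ds$wells))
  df <- ds$wells[, keep, drop = FALSE]
  old <- options(scipen = 100, digits = 15)
  on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate the control layout of a screen dataset
#'
#' Structural rules mirror the screen design: on every platform present,
#' each control role (vehicle, positive, negative) must have at least three
#' replicate wells; compound wells must carry a compound identifier, control
#' wells must not; untreated wells are optional. All findings go into the
#' report; nothing throws.
#'
#' @param ds A [screen_dataset()].
#' @param min_control_replicates Minimum wells per control role per platform.
#' @return A `validation_report` with `errors`, `warnings` and a
#'   role-by-platform `counts` table. Zero errors means the layout passes.
#' @export
validate_layout <- function(ds, min_control_replicates = 3) {
  stopifnot(inherits(ds, "screen_dataset"))
  w <- ds$wells
  errors <- character(0)
  warnings <- character(0)
  counts <- table(platform = w$platform, role = factor(w$role, levels = well_roles()))
  for (pf in rownames(counts)) {
    for (role in c("vehicle", "positive", "negative")) {
      n <- counts[pf, role]
      if (n < min_control_replicates) {
        errors <- c(errors, sprintf("%s replicate count < %d on platform %s (found %d)",
                                    role, min_control_replicates, pf, n))
      }
    }
    if (counts[pf, "untreated"] == 0) {
      warnings <- c(warnings, sprintf("no untreated wells on platform %s (optional)", pf))
    }
  }
  no_id <- which(w$role == "compound" & (is.na(w$compound_id) | w$compound_id == ""))
  if (length(no_id) > 0) {
    errors <- c(errors, sprintf("compound well without compound_id at row(s) %s",
                                paste(no_id, collapse = ", ")))
  }
  stray_id <- which(w$role != "compound" & !is.na(w$compound_id) & w$compound_id != "")
  if (length(stray_id) > 0) {
    errors <- c(errors, sprintf("non-compound well carries compound_id at row(s) %s",
                                paste(stray_id, collapse = ", ")))
  }
  n_missing_diam <- sum(is.na(w$diameter_um))
  if (n_missing_diam > 0) {
    warnings <- c(warnings, sprintf("%d wells have missing diameters (viability filtering will skip them)",
                                    n_missing_diam))
  }
  structure(list(errors = errors, warnings = warnings, counts = counts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", length(x$errors), " error(s), ",
      length(x$warnings), " warning(s)\n", sep = "")
  if (length(x$errors)) cat(paste0("  ERROR: ", x$errors, collapse = "\n"), "\n")
  if (length(x$warnings)) cat(paste0("  warn: ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

# Wells of a given role on a platform; internal helper used across modules.
wells_of <- function(ds, role, platform) {
  w <- ds$wells
  w[w$role == role & w$platform == platform, , drop = FALSE]
}
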