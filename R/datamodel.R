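# Record schemas and CSV I/O for the queen-morphometry pipeline.
#
# Units are fixed: lengths mm, dry masses mg, durations s, areas mm^2.
# The morphometry table mirrors the deposited queen dataset: one row per
# queen, snake_case columns, comma-separated, "." decimal, empty cell =
# missing value.

MORPH_COLUMNS <- c(
  "queen_id", "species", "caste", "colony_id",
  "head_width", "abdomen_length", "abdomen_height",
  "abdomen_mass", "thorax_mass", "wing_mass", "body_mass",
  "forewing_length", "total_wing_area"
)

MORPH_NUMERIC <- setdiff(MORPH_COLUMNS, c("queen_id", "species", "caste", "colony_id"))

SPECIES_LEVELS <- c("geminata", "invicta")
CASTE_LEVELS <- c("claustral", "parasitic")

# Mass additivity tolerance: microbalance resolution is 0.001 mg per
# component, so allow 0.005 mg slack on the component sum.
MASS_TOL <- 5e-3

#' Validate one queen-morphometry record
#'
#' Checks the row-level invariants: all measurements strictly positive where
#' present, component masses (abdomen + thorax + wings) not exceeding total
#' body mass, and abdomen length at least abdomen height (the prolate
#' spheroid's major axis).
#'
#' @param row a one-row data.frame or named list with the morphometry fields.
#' @return `character(0)` if valid, otherwise the diagnostic messages.
#' @export
validate_morph_record <- function(row) {
  msgs <- character(0)
  for (col in MORPH_NUMERIC) {
    v <- row[[col]]
    if (!is.null(v) && length(v) == 1 && !is.na(v) && v <= 0) {
      msgs <- c(msgs, sprintf("%s must be strictly positive (got %g)", col, v))
    }
  }
  sp <- row[["species"]]
  if (!is.null(sp) && !is.na(sp) && !sp %in% SPECIES_LEVELS) {
    msgs <- c(msgs, sprintf("unknown species '%s'", sp))
  }
  ca <- row[["caste"]]
  if (!is.null(ca) && !is.na(ca) && !ca %in% CASTE_LEVELS) {
    msgs <- c(msgs, sprintf("unknown caste '%s'", ca))
  }
  comp <- c(row[["abdomen_mass"]], row[["thorax_mass"]], row[["wing_mass"]])
  if (length(comp) == 3 && !anyNA(comp) && !is.na(row[["body_mass"]])) {
    if (sum(comp) > row[["body_mass"]] + MASS_TOL) {
      msgs <- c(msgs, sprintf(
        "component masses (%.4f mg) exceed body mass (%.4f mg)",
        sum(comp), row[["body_mass"]]))
    }
  }
  L <- row[["abdomen_length"]]; H <- row[["abdomen_height"]]
  if (!is.null(L) && !is.null(H) && !is.na(L) && !is.na(H) && H > L) {
    msgs <- c(msgs, sprintf(
      "abdomen_height (%.3f mm) exceeds abdomen_length (%.3f mm)", H, L))
  }
  msgs
}

#' Read a queen-morphometry table
#'
#' Reads a CSV with one row per queen (columns as in the package schema:
#' identity, species/caste labels, linear measurements in mm, dry component
#' masses in mg, wing dimensions). Lines starting with `#` are provenance
#' comments and are skipped. Every row is either accepted or produces exactly
#' one diagnostic.
#'
#' @param path CSV file path.
#' @param strict if `TRUE` (default) any invalid row aborts the read; if
#'   `FALSE` invalid rows are dropped with a warning.
#' @return data.frame of validated records, with attributes `n_accepted`,
#'   `n_rejected` and `rejected` (a data.frame of queen_id/diagnostic pairs).
#' @export
read_morphometry_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_fof("morphometry file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(MORPH_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_fof("morphometry table %s is missing mandatory column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  df <- df[, MORPH_COLUMNS]
  for (col in MORPH_NUMERIC) {
    raw <- df[[col]]
    raw[raw == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad)) {
      stop_fof("non-numeric value '%s' in column %s at data row %d of %s",
               raw[bad[1]], col, bad[1], path)
    }
    df[[col]] <- num
  }
  diagnostics <- vapply(seq_len(nrow(df)), function(i) {
    msgs <- validate_morph_record(df[i, ])
    if (length(msgs)) paste(msgs, collapse = "; ") else NA_character_
  }, character(1))
  bad <- which(!is.na(diagnostics))
  if (length(bad)) {
    detail <- sprintf("row %d (queen %s): %s", bad, df$queen_id[bad], diagnostics[bad])
    if (strict) {
      stop_fof("invalid morphometry record(s):\n%s", paste(detail, collapse = "\n"))
    }
    warning(sprintf("dropped %d invalid morphometry record(s):\n%s",
                    length(bad), paste(detail, collapse = "\n")), call. = FALSE)
  }
  rejected <- data.frame(queen_id = df$queen_id[bad],
                         diagnostic = diagnostics[bad],
                         stringsAsFactors = FALSE)
  out <- if (length(bad)) df[-bad, , drop = FALSE] else df
  rownames(out) <- NULL
  attr(out, "n_accepted") <- nrow(out)
  attr(out, "n_rejected") <- length(bad)
  attr(out, "rejected") <- rejected
  out
}

#' Read a tethered-flight bout table
#'
#' The flight table is long format: one row per bout with columns `queen_id`,
#' `colony_id`, `bout`, `duration_s` and optional `temperature_C`,
#' `humidity_pct`. Bouts are grouped per queen in file order; each queen must
#' resolve to a morphometry record and may have at most `max_bouts` bouts,
#' every bout strictly positive.
#'
#' @param path CSV file path.
#' @param morph morphometry data.frame from [read_morphometry_table()] (or
#'   the synthetic generator) used to resolve queen ids.
#' @param max_bouts maximum bouts per queen (default 6 consecutive trials).
#' @return data.frame with one row per queen: `queen_id`, `colony_id`,
#'   `n_bouts`, a `bouts` list-column of durations, and averaged
#'   environmental covariates where present.
#' @export
read_flight_table <- function(path, morph, max_bouts = 6L) {
  if (!file.exists(path)) stop_fof("flight file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("queen_id", "colony_id", "duration_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_fof("flight table %s is missing mandatory column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  orphan <- setdiff(df$queen_id, morph$queen_id)
  if (length(orphan)) {
    stop_fof("flight table references queen_id(s) absent from morphometry: %s",
             paste(orphan, collapse = ", "))
  }
  if (any(!is.finite(df$duration_s) | df$duration_s <= 0)) {
    i <- which(!is.finite(df$duration_s) | df$duration_s <= 0)[1]
    stop_fof("bout duration must be > 0 s (queen %s, data row %d)",
             df$queen_id[i], i)
  }
  ids <- unique(df$queen_id)  # file order
  rec <- lapply(ids, function(id) {
    rows <- df[df$queen_id == id, , drop = FALSE]
    if (nrow(rows) > max_bouts) {
      stop_fof("queen %s has %d bouts; at most %d allowed", id, nrow(rows), max_bouts)
    }
    list(queen_id = id,
         colony_id = rows$colony_id[1],
         n_bouts = nrow(rows),
         bouts = rows$duration_s,
         temperature_C = if ("temperature_C" %in% names(rows))
           mean(rows$temperature_C, na.rm = TRUE) else NA_real_,
         humidity_pct = if ("humidity_pct" %in% names(rows))
           mean(rows$humidity_pct, na.rm = TRUE) else NA_real_)
  })
  out <- data.frame(
    queen_id = vapply(rec, `[[`, character(1), "queen_id"),
    colony_id = vapply(rec, function(r) as.character(r$colony_id), character(1)),
    n_bouts = vapply(rec, `[[`, integer(1), "n_bouts"),
    temperature_C = vapply(rec, `[[`, numeric(1), "temperature_C"),
    humidity_pct = vapply(rec, `[[`, numeric(1), "humidity_pct"),
    stringsAsFactors = FALSE
  )
  out$bouts <- lapply(rec, `[[`, "bouts")
  out
}

#' Write a result table as CSV
#'
#' Deterministic serialization: fixed column order (as given), UTF-8, floats
#' at `digits` significant digits via C `%g` formatting, optional `#`-prefixed
#' provenance header (stage, config digest, seed). Writing, re-reading and
#' re-writing a table is byte-idempotent.
#'
#' @param table data.frame to serialize.
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @param provenance optional named list (e.g. stage, digest, seed) emitted as
#'   `# key: value` comment lines.
#' @param timestamp add a wall-clock line to the provenance header; off by
#'   default so identical runs produce identical bytes.
#' @return invisibly, `path`.
#' @export
write_results_table <- function(table, path, digits = 6, provenance = NULL,
                                timestamp = FALSE) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) stop_fof("column names must be unique")
  ser <- table
  for (col in names(ser)) {
    if (is.numeric(ser[[col]])) {
      ser[[col]] <- ifelse(is.na(ser[[col]]), "",
                           sprintf(paste0("%.", digits, "g"), ser[[col]]))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- character(0)
  if (timestamp) {
    provenance <- c(provenance, list(written = format(Sys.time(), tz = "UTC")))
  }
  if (length(provenance)) {
    hdr <- sprintf("# %s: %s", names(provenance),
                   vapply(provenance, function(v) paste(as.character(v), collapse = " "),
                          character(1)))
  }
  lines <- c(hdr, paste(names(ser), collapse = ","))
  if (nrow(ser)) {
    body <- do.call(paste, c(lapply(ser, as.character), sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
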