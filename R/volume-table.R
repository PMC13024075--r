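# Subject-level volume tables: construction, validation, CSV/TSV I/O.
#
# A volume table is a data.frame with columns subject_id, age, sex,
# diagnosis, then one numeric column per region in canonical order, plus a
# "volume_table" class and a "regions" attribute. Region columns hold
# volumes in mm^3.

.DIAGNOSIS_LEVELS <- c("AD", "CN", "REFERENCE", "UNKNOWN")

#' Construct a validated volume table
#'
#' Assembles subject demographics and regional volumes into the canonical
#' container consumed by every downstream stage. Columns may arrive in any
#' order and with cosmetic region-name variants; they are stored in the
#' canonical region order of `regions`.
#'
#' @param subjects A data.frame with columns `subject_id`, `age` (years),
#'   `sex` (0 = female, 1 = male; `"F"/"M"` and `"female"/"male"` accepted),
#'   `diagnosis` (one of `"AD"`, `"CN"`, `"REFERENCE"`, `"UNKNOWN"`), and
#'   one numeric column per region (volumes in mm^3).
#' @param regions Character vector of required region names (default the
#'   canonical 95-region set).
#' @return A `volume_table`: a data.frame with the demographics columns
#'   followed by the region columns in canonical order, with attribute
#'   `"regions"`.
#' @export
volume_table <- function(subjects, regions = brain_regions()) {
  stopifnot(is.data.frame(subjects))
  required <- c("subject_id", "age", "sex", "diagnosis")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  other <- setdiff(names(subjects), required)
  canon <- match_regions(other, regions)
  missing_regions <- setdiff(region_key(regions), region_key(other))
  if (length(missing_regions) > 0L) {
    miss <- regions[region_key(regions) %in% missing_regions]
    stop("missing region column(s): ", paste(miss, collapse = ", "))
  }

  out <- data.frame(
    subject_id = as.character(subjects$subject_id),
    age = .parse_numeric(subjects$age, "age"),
    sex = .parse_sex(subjects$sex),
    diagnosis = .parse_diagnosis(subjects$diagnosis),
    stringsAsFactors = FALSE
  )
  for (r in regions) {
    src <- other[which(!is.na(canon) & canon == r)[1L]]
    out[[r]] <- .parse_numeric(subjects[[src]], r)
  }

  .validate_volume_table(out, regions)
  structure(out, regions = regions,
            class = c("volume_table", "data.frame"))
}

.parse_numeric <- function(x, what) {
  if (is.numeric(x)) return(as.numeric(x))
  v <- suppressWarnings(as.numeric(as.character(x)))
  bad <- which(is.na(v) & !is.na(x) & trimws(as.character(x)) != "")
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value for '%s' in row %d: '%s'",
                 what, bad[1L], as.character(x)[bad[1L]]))
  }
  v
}

.parse_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(key))
  out[key %in% c("0", "f", "female")] <- 0
  out[key %in% c("1", "m", "male")] <- 1
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop(sprintf("unknown sex code in row %d: '%s' (expected 0/1, F/M, female/male)",
                 bad[1L], as.character(x)[bad[1L]]))
  }
  out
}

.parse_diagnosis <- function(x) {
  v <- toupper(trimws(as.character(x)))
  bad <- which(!v %in% .DIAGNOSIS_LEVELS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown diagnosis in row %d: '%s' (expected %s)",
                 bad[1L], as.character(x)[bad[1L]],
                 paste(.DIAGNOSIS_LEVELS, collapse = "/")))
  }
  v
}

.validate_volume_table <- function(df, regions) {
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ",
         df$subject_id[anyDuplicated(df$subject_id)])
  }
  if (any(!is.finite(df$age)) || any(df$age <= 0)) {
    stop("age must be finite and > 0")
  }
  vols <- as.matrix(df[regions])
  if (nrow(df) > 0L && (any(!is.finite(vols)) || any(vols < 0))) {
    bad <- which(!is.finite(vols) | vols < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("volume for region '%s', subject '%s' is missing, non-finite or negative",
                 regions[bad[2L]], df$subject_id[bad[1L]]))
  }
  invisible(df)
}

#' @export
print.volume_table <- function(x, ...) {
  regs <- attr(x, "regions")
  cat(sprintf("Volume table: %d subject(s), %d region(s)\n", nrow(x), length(regs)))
  if (nrow(x) > 0L) {
    tab <- table(factor(x$diagnosis, levels = .DIAGNOSIS_LEVELS))
    tab <- tab[tab > 0]
    cat("  diagnosis:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  age: %.1f-%.1f years, %.0f%% female\n",
                min(x$age), max(x$age), 100 * mean(x$sex == 0)))
  }
  invisible(x)
}

# Extract the n x R volume matrix (canonical region order).
volume_matrix <- function(table) {
  regs <- attr(table, "regions")
  m <- as.matrix(as.data.frame(table)[regs])
  rownames(m) <- table$subject_id
  m
}

#' Read a volume table from delimited text
#'
#' Expects a UTF-8 header row `subject_id,age,sex,diagnosis,<region...>`
#' (any column order; region headers matched case-/whitespace-insensitively
#' against the canonical set). Values use `.` as decimal separator; no
#' missing values are allowed.
#'
#' @param path File path.
#' @param dialect `"csv"` (comma) or `"tsv"` (tab).
#' @param regions Required region set (default canonical 95).
#' @return A [volume_table()].
#' @export
read_volume_table <- function(path, dialect = c("csv", "tsv"),
                              regions = brain_regions()) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  volume_table(raw, regions = regions)
}

#' Write a volume table to delimited text
#'
#' Values are written at full double precision (17 significant digits) so
#' that a write/read round trip reproduces the table exactly.
#'
#' @param table A [volume_table()].
#' @param path Output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_volume_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!inherits(table, "volume_table")) {
    stop("'table' must be a volume_table")
  }
  regs <- attr(table, "regions")
  .validate_volume_table(as.data.frame(table), regs)
  sep <- if (dialect == "csv") "," else "\t"
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a table against a required region set
#'
#' Report-only check: lists required regions absent from the table, extra
#' non-schema columns, and subjects with non-finite volumes. The check
#' passes iff no required region is missing and no value is missing.
#'
#' @param table A data.frame (a [volume_table()] or a raw import).
#' @param required Character vector of required region names.
#' @return A list with elements `ok` (logical), `missing_regions`,
#'   `extra_columns`, and `subjects_with_missing` (subject ids).
#' @export
validate_regions <- function(table, required = brain_regions()) {
  meta <- c("subject_id", "age", "sex", "diagnosis")
  cols <- setdiff(names(table), meta)
  canon <- match_regions(cols, required)
  missing <- required[!region_key(required) %in% region_key(cols)]
  extra <- cols[is.na(canon)]
  present <- cols[!is.na(canon)]
  bad_subj <- character(0)
  if (nrow(table) > 0L && length(present) > 0L) {
    vals <- suppressWarnings(
      vapply(table[present], function(x) as.numeric(as.character(x)),
             numeric(nrow(table)))
    )
    vals <- matrix(vals, nrow = nrow(table))
    has_bad <- apply(vals, 1L, function(v) any(!is.finite(v)))
    bad_subj <- as.character(table$subject_id[has_bad])
  }
  list(
    ok = length(missing) == 0L && length(bad_subj) == 0L,
    missing_regions = missing,
    extra_columns = extra,
    subjects_with_missing = bad_subj
  )
}
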