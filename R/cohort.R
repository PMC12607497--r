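## Cohort I/O: tidy one-row-per-subject tables with per-analyte status flags.
##
## CSV dialect: comma-separated, UTF-8, header required. Canonical columns:
##   subject_id, group, sex, age_years, bsc_type, creatinine, unit_state,
##   adma, sdma, tmao, is, pcs
## Toxin cells: a number, "" (missing) or "<LOQ" (below the limit of
## quantification). bsc_type and creatinine may be empty.

#' Canonical cohort column names
#' @keywords internal
cohort_columns <- function() {
  c("subject_id", "group", "sex", "age_years", "bsc_type", "creatinine",
    "unit_state", ANALYTES)
}

#' Build a validated cohort table
#'
#' Constructs a `migd_cohort` from a data frame holding one row per subject.
#' Rows that fail validation are dropped and recorded in the `diagnostics`
#' attribute (`row`, `field`, `message`), so that retained + rejected always
#' account for every input row. Structural problems (missing required
#' columns, duplicate subject identifiers) are fatal.
#'
#' @param data data frame with the canonical columns (see [read_cohort()]);
#'   `unit_state` may be omitted if supplied via the argument.
#' @param unit_state unit state used when the table has no `unit_state`
#'   column: `"normalized_umol_per_mmol"` (default) or `"raw_umol_per_L"`.
#' @param provenance free-text source tag stored on the object.
#' @return A `migd_cohort`: a data frame with typed columns, per-analyte flag
#'   columns (`adma_flag`, ..., `pcs_flag` in `"ok"`, `"below_loq"`,
#'   `"missing"`), a derived `bsc_category` column, and attributes
#'   `unit_state`, `provenance` and `diagnostics`.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
as_migd_cohort <- function(data, unit_state = "normalized_umol_per_mmol",
                           provenance = "in-memory") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- setdiff(cohort_columns(), "unit_state")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop_migd(paste0("missing required column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "migd_missing_column")
  }

  if ("unit_state" %in% names(data) && nrow(data) > 0L) {
    us <- unique(as.character(data$unit_state))
    us <- us[!is.na(us) & nzchar(us)]
    if (length(us) > 1L) {
      stop_migd("unit_state is not consistent across rows", "migd_unit_state")
    }
    if (length(us) == 1L) unit_state <- us
  }
  unit_state <- match.arg(unit_state, UNIT_STATES)

  n <- nrow(data)
  diag <- list()
  bad <- rep(FALSE, n)
  note <- function(i, field, msg) {
    diag[[length(diag) + 1L]] <<- data.frame(
      row = i, field = field, message = msg, stringsAsFactors = FALSE)
    bad[i] <<- TRUE
  }

  out <- data.frame(subject_id = trimws(as.character(data$subject_id)),
                    stringsAsFactors = FALSE)

  grp <- tolower(trimws(as.character(data$group)))
  ok_grp <- grp %in% c("control", "asd")
  for (i in which(!ok_grp)) note(i, "group", paste0("unknown group '", grp[i], "'"))
  out$group <- grp

  sex <- tolower(trimws(as.character(data$sex)))
  sex[is.na(sex) | !nzchar(sex)] <- "unknown"
  ok_sex <- sex %in% c("boy", "girl", "unknown")
  for (i in which(!ok_sex)) note(i, "sex", paste0("unknown sex '", sex[i], "'"))
  out$sex <- sex

  age <- suppressWarnings(as.numeric(data$age_years))
  for (i in which(is.na(age) | age < 0)) note(i, "age_years", "age must be a non-negative number")
  out$age_years <- age

  bsc_raw <- trimws(as.character(data$bsc_type))
  bsc <- suppressWarnings(as.numeric(bsc_raw))
  bsc[!nzchar(bsc_raw) | is.na(bsc_raw)] <- NA_real_
  bad_bsc <- !is.na(bsc) & (bsc != round(bsc) | bsc < 1 | bsc > 7)
  bad_bsc <- bad_bsc | (nzchar(bsc_raw) & !is.na(bsc_raw) & is.na(bsc))
  for (i in which(bad_bsc)) {
    note(i, "bsc_type", paste0("BSC type must be an integer in 1-7, got '", bsc_raw[i], "'"))
  }
  out$bsc_type <- as.integer(bsc)

  cre_raw <- trimws(as.character(data$creatinine))
  cre <- suppressWarnings(as.numeric(cre_raw))
  cre[!nzchar(cre_raw) | is.na(cre_raw)] <- NA_real_
  bad_cre <- nzchar(cre_raw) & !is.na(cre_raw) & (is.na(cre) | cre <= 0)
  for (i in which(bad_cre)) note(i, "creatinine", "creatinine must be a positive number")
  out$creatinine <- cre

  for (a in ANALYTES) {
    raw <- trimws(as.character(data[[a]]))
    raw[is.na(raw)] <- ""
    flag <- rep("ok", n)
    val <- rep(NA_real_, n)
    is_loq <- toupper(raw) == "<LOQ"
    is_missing <- !nzchar(raw)
    flag[is_loq] <- "below_loq"
    flag[is_missing] <- "missing"
    parse_idx <- !is_loq & !is_missing
    val[parse_idx] <- suppressWarnings(as.numeric(raw[parse_idx]))
    bad_val <- parse_idx & (is.na(val) | val < 0)
    for (i in which(bad_val)) {
      note(i, a, paste0(toupper(a), " must be a non-negative number or '<LOQ', got '", raw[i], "'"))
    }
    out[[a]] <- val
    out[[paste0(a, "_flag")]] <- flag
  }

  keep <- !bad
  diagnostics <- if (length(diag) > 0L) do.call(rbind, diag) else
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  dup <- unique(out$subject_id[duplicated(out$subject_id)])
  if (length(dup) > 0L) {
    stop_migd(paste0("duplicate subject_id: ", paste(dup, collapse = ", ")),
              "migd_duplicate_id")
  }

  out$bsc_category <- assign_bsc_category(out$bsc_type)

  structure(out,
            class = c("migd_cohort", "data.frame"),
            unit_state = unit_state,
            provenance = provenance,
            diagnostics = diagnostics)
}

#' Read a cohort table from CSV
#'
#' Reads a comma-separated, one-row-per-subject cohort file and validates it
#' into a [as_migd_cohort()] object. Empty toxin cells are flagged
#' `missing`; the sentinel `"<LOQ"` is flagged `below_loq`. Rows failing
#' validation (e.g. a BSC type outside 1-7) are rejected individually and
#' listed in `attr(x, "diagnostics")`; structural errors are fatal.
#'
#' @param path CSV file path.
#' @param schema optional column-name mapping for files whose headers differ
#'   from the canonical names: a named list/vector `canonical = file_column`,
#'   or the path to a YAML/JSON file holding such a mapping.
#' @param unit_state fallback unit state when the file carries no
#'   `unit_state` column.
#' @return A `migd_cohort`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(simulate_cohort(seed = 1), path)
#' cohort <- read_cohort(path)
#' nrow(cohort)
#' @export
read_cohort <- function(path, schema = NULL,
                        unit_state = "normalized_umol_per_mmol") {
  if (!file.exists(path)) stop_migd(paste0("file not found: ", path), "migd_io")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  schema <- load_schema(schema)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(raw)) {
        stop_migd(paste0("schema maps '", canon, "' to '", src,
                         "' but that column is absent"), "migd_missing_column")
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  as_migd_cohort(raw, unit_state = unit_state, provenance = path)
}

load_schema <- function(schema) {
  if (is.null(schema)) return(NULL)
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::read_json(schema, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  as.list(schema)
}

#' Write a cohort table to CSV
#'
#' Inverse of [read_cohort()]: writes the canonical CSV dialect, encoding
#' `missing` as an empty cell and `below_loq` as `"<LOQ"`, so that
#' `read_cohort(write_cohort(x))` reproduces `x` field for field at full
#' numeric precision.
#'
#' @param cohort a `migd_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "migd_cohort"))
  fmt_num <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                     scientific = FALSE))
  out <- data.frame(subject_id = cohort$subject_id,
                    group = cohort$group,
                    sex = cohort$sex,
                    age_years = fmt_num(cohort$age_years),
                    bsc_type = ifelse(is.na(cohort$bsc_type), "",
                                      as.character(cohort$bsc_type)),
                    creatinine = fmt_num(cohort$creatinine),
                    unit_state = rep(attr(cohort, "unit_state"), nrow(cohort)),
                    stringsAsFactors = FALSE)
  for (a in ANALYTES) {
    flag <- cohort[[paste0(a, "_flag")]]
    cell <- fmt_num(cohort[[a]])
    cell[flag == "below_loq"] <- "<LOQ"
    cell[flag == "missing"] <- ""
    out[[a]] <- cell
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_migd(paste0("cannot write: ", path), "migd_io")
  invisible(path)
}

#' @export
print.migd_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects (%s)\n", nrow(x), attr(x, "unit_state")))
  tab <- table(group = x$group, category = addNA(x$bsc_category))
  print(tab)
  d <- attr(x, "diagnostics")
  if (nrow(d) > 0L) cat(sprintf("%d input row(s) rejected; see attr(x, \"diagnostics\")\n",
                                length(unique(d$row))))
  invisible(x)
}
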