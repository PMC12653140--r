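#' Canonical cohort schema
#'
#' The participant table used throughout the package has one row per subject
#' with the canonical columns below. [load_cohort()] maps arbitrary source
#' column names onto this schema.
#'
#' @return character vector of canonical column names.
#' @export
cohort_fields <- function() {
  c("id", "sex", "age", "weight", "waist", "bmi", "sbp", "dbp",
    "glucose", "triglycerides", "hdl", paste0("phq", 1:10),
    "icd_codes", "on_psychotropic")
}

phq_cols <- function() paste0("phq", 1:10)
panel_cols <- function() c("sex", "waist", "triglycerides", "hdl",
                           "sbp", "dbp", "glucose")

#' Load a participant table into the canonical schema
#'
#' Reads a delimited text file (comma or tab, autodetected from the header
#' line) and maps source columns onto [cohort_fields()]. Unparseable numeric
#' entries become `NA` (explicit missingness); rows with a PHQ item outside
#' \{0,1,2,3\} are rejected, with the reasons returned in the `rejections`
#' attribute and summarised in a message. Row order is preserved.
#'
#' ICD-10 codes may be given as a single delimited string per row
#' (separators `;`, `|` or space); they are normalised by trimming and
#' upper-casing. `sex` accepts `male`/`female` (any case) or `m`/`f`;
#' `on_psychotropic` accepts logicals, 0/1 or yes/no.
#'
#' @param table_path path to a CSV/TSV file with a header row.
#' @param column_map named character vector, canonical field -> source column
#'   name. Fields not named in the map default to their canonical name;
#'   a field mapped to `NA` is treated as absent and filled with `NA`.
#' @return `data.frame` in the canonical schema, `icd_codes` as a
#'   semicolon-joined normalised string; attribute `rejections` is a
#'   `data.frame` (`row`, `reason`) of dropped rows.
#' @export
load_cohort <- function(table_path, column_map = character()) {
  if (!file.exists(table_path)) stop("file not found: ", table_path)
  header <- readLines(table_path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  raw <- utils::read.table(table_path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  fields <- cohort_fields()
  src <- stats::setNames(fields, fields)
  if (length(column_map)) {
    unknown <- setdiff(names(column_map), fields)
    if (length(unknown)) stop("column_map names not canonical fields: ",
                              toString(unknown))
    src[names(column_map)] <- column_map
  }
  get_col <- function(f) {
    s <- src[[f]]
    if (is.na(s) || !s %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[s]]
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- data.frame(id = get_col("id"), stringsAsFactors = FALSE)
  if (all(is.na(out$id))) out$id <- as.character(seq_len(nrow(raw)))
  if (anyDuplicated(out$id)) stop("duplicated participant ids")
  sex_raw <- tolower(trimws(get_col("sex")))
  out$sex <- ifelse(sex_raw %in% c("male", "m"), "male",
                    ifelse(sex_raw %in% c("female", "f"), "female",
                           NA_character_))
  for (f in c("age", "weight", "waist", "bmi", "sbp", "dbp",
              "glucose", "triglycerides", "hdl", phq_cols())) {
    out[[f]] <- num(get_col(f))
  }
  out$icd_codes <- vapply(get_col("icd_codes"), normalize_icd, character(1),
                          USE.NAMES = FALSE)
  psy <- tolower(trimws(get_col("on_psychotropic")))
  out$on_psychotropic <- psy %in% c("true", "t", "1", "yes", "y")
  out$on_psychotropic[is.na(psy) | psy == ""] <- NA

  # validity: PHQ items must be integers in 0..3 when present
  bad_phq <- rep(FALSE, nrow(out))
  reason <- rep(NA_character_, nrow(out))
  for (f in phq_cols()) {
    v <- out[[f]]
    bad <- !is.na(v) & (v < 0 | v > 3 | v != round(v))
    reason[bad & !bad_phq] <- paste0(f, " outside {0,1,2,3}")
    bad_phq <- bad_phq | bad
  }
  rejections <- data.frame(row = which(bad_phq),
                           id = out$id[bad_phq],
                           reason = reason[bad_phq],
                           stringsAsFactors = FALSE)
  if (nrow(rejections)) {
    message("rejected ", nrow(rejections), " row(s): ",
            paste(rejections$id, rejections$reason, collapse = "; "))
    out <- out[!bad_phq, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejections") <- rejections
  out
}

normalize_icd <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return("")
  parts <- toupper(trimws(strsplit(s, "[;|[:space:]]+")[[1]]))
  paste(parts[nzchar(parts)], collapse = ";")
}

# codes are normalised (trim, uppercase) on both sides of the match, so
# apply_inclusion also accepts tables assembled in code rather than loaded
icd_list <- function(records) {
  lapply(strsplit(records$icd_codes, "[;|[:space:]]+"),
         function(cc) toupper(trimws(cc)))
}

#' Apply the cohort inclusion filters
#'
#' Retains participants who are on psychotropic medication AND carry at least
#' one of the required ICD-10 depression codes (exact match on normalised
#' codes, no prefix matching) AND have all ten PHQ items AND a complete
#' metabolic panel (sex, waist, triglycerides, HDL, systolic/diastolic
#' pressure, fasting glucose). Participants with incomplete data are
#' excluded, not imputed.
#'
#' @param records cohort `data.frame` from [load_cohort()].
#' @param required_codes ICD-10 codes defining the diagnosis; default the
#'   unspecified single-episode and recurrent MDD codes F32.9 and F33.9.
#' @return the filtered `data.frame` (possibly empty).
#' @export
apply_inclusion <- function(records, required_codes = c("F32.9", "F33.9")) {
  required_codes <- toupper(trimws(required_codes))
  has_code <- vapply(icd_list(records),
                     function(cc) any(cc %in% required_codes), logical(1))
  on_med <- !is.na(records$on_psychotropic) & records$on_psychotropic
  phq_ok <- !Reduce(`|`, lapply(phq_cols(), function(f) is.na(records[[f]])))
  panel_ok <- !Reduce(`|`, lapply(panel_cols(), function(f)
    is.na(records[[f]])))
  out <- records[has_code & on_med & phq_ok & panel_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Metabolic-syndrome criterion thresholds
#'
#' Defaults follow the AHA/IDF-style rule used in the analysis: waist >= 102
#' cm (men) / >= 88 cm (women); triglycerides >= 150 mg/dL; HDL < 40 (men) /
#' < 50 (women) mg/dL — note the strict inequality; blood pressure systolic
#' >= 130 OR diastolic >= 80 mmHg; fasting glucose >= 100 mg/dL. The
#' diastolic cut-off of 80 is the one used here (some guideline variants use
#' 85); it is exposed so either convention can be run.
#'
#' @param waist_male,waist_female,triglycerides,hdl_male,hdl_female,sbp,dbp,glucose
#'   numeric thresholds in the units above.
#' @return named list of thresholds.
#' @export
mets_thresholds <- function(waist_male = 102, waist_female = 88,
                            triglycerides = 150, hdl_male = 40,
                            hdl_female = 50, sbp = 130, dbp = 80,
                            glucose = 100) {
  list(waist_male = waist_male, waist_female = waist_female,
       triglycerides = triglycerides, hdl_male = hdl_male,
       hdl_female = hdl_female, sbp = sbp, dbp = dbp, glucose = glucose)
}

#' Classify metabolic syndrome by the 3-of-5 rule
#'
#' Evaluates the five criteria of [mets_thresholds()] for each record and
#' sets `mets_status` when at least three are met. All inequalities are
#' inclusive (>=) except HDL, which is strictly below the threshold. Errors
#' if any required field (the five criterion inputs or sex) is missing,
#' naming the field — run [apply_inclusion()] first on raw extracts.
#'
#' @param records cohort `data.frame` (one or more rows).
#' @param thresholds a [mets_thresholds()] list.
#' @return `data.frame` with logical columns `flag_waist`,
#'   `flag_triglycerides`, `flag_hdl`, `flag_bp`, `flag_glucose`, integer
#'   `mets_count` and logical `mets_status`, one row per record.
#' @examples
#' r <- data.frame(sex = "female", waist = 88, triglycerides = 149.9,
#'                 hdl = 50, sbp = 129, dbp = 80, glucose = 100)
#' classify_mets(r)  # waist, BP, glucose flagged; HDL 50 is NOT (strict <)
#' @export
classify_mets <- function(records, thresholds = mets_thresholds()) {
  for (f in panel_cols()) {
    if (is.null(records[[f]])) stop("missing column: ", f)
    if (anyNA(records[[f]])) stop("missing value in field: ", f)
  }
  if (!all(records$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  male <- records$sex == "male"
  flag_waist <- ifelse(male, records$waist >= thresholds$waist_male,
                       records$waist >= thresholds$waist_female)
  flag_tg <- records$triglycerides >= thresholds$triglycerides
  flag_hdl <- ifelse(male, records$hdl < thresholds$hdl_male,
                     records$hdl < thresholds$hdl_female)
  flag_bp <- records$sbp >= thresholds$sbp | records$dbp >= thresholds$dbp
  flag_glu <- records$glucose >= thresholds$glucose
  count <- flag_waist + flag_tg + flag_hdl + flag_bp + flag_glu
  data.frame(flag_waist = flag_waist, flag_triglycerides = flag_tg,
             flag_hdl = flag_hdl, flag_bp = flag_bp, flag_glucose = flag_glu,
             mets_count = as.integer(count), mets_status = count >= 3)
}

#' Partition a cohort by metabolic-syndrome status
#'
#' @inheritParams classify_mets
#' @return list with elements `mets` and `non_mets`, each a `data.frame`;
#'   the two sizes always sum to the input size.
#' @export
split_groups <- function(records, thresholds = mets_thresholds()) {
  cls <- classify_mets(records, thresholds)
  list(mets = records[cls$mets_status, , drop = FALSE],
       non_mets = records[!cls$mets_status, , drop = FALSE])
}

#' Write the normalized cohort with classification columns appended
#'
#' @inheritParams classify_mets
#' @param path output TSV path.
#' @return the augmented `data.frame`, invisibly.
#' @export
write_cohort <- function(records, path, thresholds = mets_thresholds()) {
  out <- cbind(records, classify_mets(records, thresholds))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
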