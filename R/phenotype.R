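## MHO / MAO phenotype classification and clinical summaries.
##
## Three published definitions of metabolically healthy obesity are
## implemented. All subjects must be obese (BMI >= 30 kg/m^2); an obese
## subject is MHO when every criterion of the chosen definition holds,
## MAO otherwise. All threshold comparisons are inclusive (<=, >=).

.MHO_REQUIRED_FIELDS <- list(
  `1` = c("bmi", "sbp", "dbp", "bp_medication", "glucose", "hdl", "sex"),
  `2` = c("bmi", "sbp", "dbp", "bp_medication", "glucose", "homa_ir",
          "tg", "hdl", "sex"),
  `3` = c("bmi", "sbp", "dbp", "bp_medication", "glucose", "homa_ir",
          "tg", "hdl", "hscrp", "sex")
)

#' Triglyceride to HDL-cholesterol ratio
#'
#' Surrogate index of insulin resistance; enters the MHO definition with
#' sex-specific cut-offs (<= 1.65 male, <= 1.32 female).
#'
#' @param tg triglycerides (mg/dl), non-negative.
#' @param hdl HDL cholesterol (mg/dl), strictly positive.
#' @return `tg / hdl` (unitless). Vectorised.
#' @examples
#' tgHdlRatio(150, 50) # 3
#' @export
tgHdlRatio <- function(tg, hdl) {
  if (any(!is.finite(hdl)) || any(hdl <= 0))
    stop("'hdl' must be finite and > 0")
  if (any(!is.finite(tg)) || any(tg < 0))
    stop("'tg' must be finite and >= 0")
  tg / hdl
}

.as_record <- function(record) {
  if (is.data.frame(record)) record <- as.list(record)
  if (!is.list(record)) stop("'record' must be a list or one-row data.frame")
  if (!is.null(record$tg) && !is.null(record$hdl) && is.null(record$tg_hdl))
    record$tg_hdl <- tgHdlRatio(record$tg, record$hdl)
  record
}

.need <- function(record, fields) {
  for (f in fields) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || (!is.character(v) && is.na(v)))
      stop(sprintf("required clinical field '%s' is missing", f))
  }
}

#' Classify a subject as MHO, MAO or not obese
#'
#' Applies one of three published definitions of metabolically healthy
#' obesity. Definition 1 (basic): no hypertension (SBP <= 130 and DBP <= 85,
#' no blood-pressure medication), no diabetes (glucose <= 126 mg/dl),
#' HDL-C >= 40 (male) / >= 50 (female) mg/dl. Definition 2 (modified
#' Wildman): no hypertension, glucose <= 100 mg/dl, HOMA-IR <= 5.1,
#' TG/HDL <= 1.65 (male) / <= 1.32 (female). Definition 3 adds
#' hsCRP <= 0.3 mg/dl to Definition 2 and is the study default. All
#' criteria must be met; obese subjects failing any criterion are MAO;
#' subjects with BMI < 30 are labelled `NOT_OBESE`.
#'
#' @param record named list or one-row data.frame with fields `sex`
#'   (`"M"`/`"F"`), `bmi`, `sbp`, `dbp`, `bp_medication` (logical),
#'   `glucose`, `homa_ir`, `tg`, `hdl` (or `tg_hdl`), `hscrp`. Only the
#'   fields the chosen definition needs are required; a missing required
#'   field is an error, never a silent pass.
#' @param definition 1, 2 or 3 (default 3).
#' @return list with `label` (`"MHO"`, `"MAO"` or `"NOT_OBESE"`),
#'   `definition`, and `criteria`, a named logical vector of per-criterion
#'   pass flags.
#' @examples
#' classifyMHO(list(sex = "M", bmi = 34, sbp = 120, dbp = 80,
#'   bp_medication = FALSE, glucose = 87, homa_ir = 1.99,
#'   tg = 49, hdl = 50, hscrp = 0.13))
#' @export
classifyMHO <- function(record, definition = 3) {
  stopifnot(definition %in% 1:3)
  record <- .as_record(record)
  .need(record, .MHO_REQUIRED_FIELDS[[as.character(definition)]])
  sex <- toupper(substr(as.character(record$sex), 1, 1))
  if (!sex %in% c("M", "F")) stop("'sex' must be \"M\" or \"F\"")

  if (record$bmi < 30) {
    return(list(label = "NOT_OBESE", definition = definition,
                criteria = c(obese = FALSE)))
  }
  crit <- c(
    obese = TRUE,
    no_hypertension = record$sbp <= 130 && record$dbp <= 85 &&
      !isTRUE(as.logical(record$bp_medication))
  )
  if (definition == 1) {
    crit <- c(crit,
      no_diabetes = record$glucose <= 126,
      hdl = if (sex == "M") record$hdl >= 40 else record$hdl >= 50)
  } else {
    tgh <- if (!is.null(record$tg_hdl)) record$tg_hdl
           else tgHdlRatio(record$tg, record$hdl)
    crit <- c(crit,
      no_prediabetes = record$glucose <= 100,
      homa = record$homa_ir <= 5.1,
      tg_hdl = if (sex == "M") tgh <= 1.65 else tgh <= 1.32)
    if (definition == 3) crit <- c(crit, hscrp = record$hscrp <= 0.3)
  }
  list(label = if (all(crit)) "MHO" else "MAO",
       definition = definition, criteria = crit)
}

#' Classify every row of a clinical table
#'
#' @param clinical data.frame of [classifyMHO()] fields, one row per subject.
#' @param definition MHO definition (default 3).
#' @return data.frame with columns `label`, `definition`, and one logical
#'   column per criterion (for audit).
#' @export
classifyCohort <- function(clinical, definition = 3) {
  res <- lapply(seq_len(nrow(clinical)), function(i)
    classifyMHO(clinical[i, , drop = FALSE], definition))
  crit_names <- unique(unlist(lapply(res, function(r) names(r$criteria))))
  crit <- t(vapply(res, function(r) {
    out <- stats::setNames(rep(NA, length(crit_names)), crit_names)
    out[names(r$criteria)] <- r$criteria
    out
  }, numeric(length(crit_names))))
  out <- data.frame(label = vapply(res, `[[`, "", "label"),
                    definition = definition,
                    crit == 1)
  rownames(out) <- rownames(clinical)
  out
}

#' Per-group clinical summary statistics
#'
#' Arithmetic mean and SD (n-1 denominator), range, and geometric mean
#' (`exp(mean(log(x)))`, positive values only) of each numeric clinical
#' variable, by group.
#'
#' @param records data.frame of clinical variables, one row per subject.
#' @param labels group label per subject (factor or character).
#' @param variables which columns to summarise; default all numeric columns.
#' @return data.frame with columns `group`, `variable`, `n`, `mean`, `sd`,
#'   `min`, `max`, `geometric_mean`. Non-positive values make the geometric
#'   mean `NA` for that group/variable with a warning.
#' @examples
#' groupSummary(data.frame(x = c(2, 8, 5, 5)),
#'              labels = c("a", "a", "b", "b"))
#' @export
groupSummary <- function(records, labels, variables = NULL) {
  stopifnot(nrow(records) == length(labels))
  labels <- as.character(labels)
  if (is.null(variables))
    variables <- names(records)[vapply(records, is.numeric, TRUE)]
  rows <- list()
  for (g in unique(labels)) {
    idx <- labels == g
    if (!any(idx)) next
    for (v in variables) {
      x <- records[[v]][idx]
      x <- x[!is.na(x)]
      if (!length(x)) next
      gm <- if (all(x > 0)) exp(mean(log(x))) else {
        warning(sprintf(
          "non-positive values in '%s' (group %s): geometric mean omitted",
          v, g))
        NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, variable = v, n = length(x),
        mean = mean(x), sd = stats::sd(x),
        min = min(x), max = max(x), geometric_mean = gm)
    }
  }
  do.call(rbind, rows)
}
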