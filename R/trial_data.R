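#' @useDynLib tgios
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom rpois rlnorm
#'   sd var median quantile optim nlminb optimHess setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Times for tumor dynamics are stored in weeks (rate constants are week^-1);
# survival times in days. Single conversion constant used everywhere.
DAYS_PER_WEEK <- 7

#' Convert between the week scale of tumor dynamics and the day scale of survival
#'
#' Tumor growth/shrinkage rate constants are per week; overall survival is
#' analyzed in days. These helpers keep the conversion in one place.
#'
#' @param weeks,days numeric vector of times.
#' @return numeric vector of converted times.
#' @export
weeks_to_days <- function(weeks) weeks * DAYS_PER_WEEK

#' @rdname weeks_to_days
#' @export
days_to_weeks <- function(days) days / DAYS_PER_WEEK

#' Cap the number of metastatic sites at five
#'
#' The OS model uses the number of baseline metastatic sites truncated at 5:
#' any count of five or more enters the linear predictor as 5. Counts are
#' stored raw and capped at the point of use.
#'
#' @param n integer vector of metastatic site counts, each >= 1.
#' @return `pmin(n, 5)`.
#' @export
cap_met_sites <- function(n) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("number of metastatic sites must be finite and >= 1")
  }
  pmin(n, 5)
}

ARM_LEVELS <- c("treatment", "control")

#' Assemble a trial dataset
#'
#' Bundles the three tables of a TGI-OS analysis: longitudinal tumor size
#' records, baseline covariates, and overall-survival outcomes. Validates the
#' structural invariants (non-negative SLD, unique subject/time pairs, one arm
#' per subject, covariate/OS subjects present in the tumor table).
#'
#' @param tumor data.frame with columns `subject_id`, `arm`
#'   ("treatment"/"control"), `time_weeks` (may be negative for screening),
#'   `sld_mm` (>= 0).
#' @param covariates data.frame with one row per subject: `subject_id`,
#'   `albumin` (g/L), `ecog` (0 or 1, where 1 means ECOG >= 1), `race`
#'   ("Asian"/"non-Asian"), `n_met_sites` (integer >= 1, stored raw),
#'   `nlr` (> 0), `liver_met` ("yes"/"no"), `baseline_sld` (mm),
#'   `line_of_therapy` ("1"/"2+"), `sex` ("female"/"male"). May be `NULL`.
#' @param os data.frame with `subject_id`, `os_days` (> 0), `event`
#'   (1 = death, 0 = censored). May be `NULL`.
#' @return object of class `trial_dataset`.
#' @export
trial_dataset <- function(tumor, covariates = NULL, os = NULL) {
  need <- c("subject_id", "arm", "time_weeks", "sld_mm")
  miss <- setdiff(need, names(tumor))
  if (length(miss)) stop("tumor table missing column(s): ", paste(miss, collapse = ", "))
  tumor$subject_id <- as.character(tumor$subject_id)
  bad_arm <- setdiff(unique(tumor$arm), ARM_LEVELS)
  if (length(bad_arm)) {
    stop("unknown arm level(s): ", paste(bad_arm, collapse = ", "),
         " (expected treatment/control; use a dialect to map study labels)")
  }
  if (any(tumor$sld_mm < 0)) stop("sld_mm must be >= 0")
  key <- paste(tumor$subject_id, tumor$time_weeks)
  if (anyDuplicated(key)) {
    stop("duplicate (subject_id, time_weeks) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  arms <- tapply(tumor$arm, tumor$subject_id, function(a) length(unique(a)))
  if (any(arms > 1)) {
    stop("subject(s) with more than one arm: ",
         paste(names(arms)[arms > 1], collapse = ", "))
  }
  subj <- unique(tumor$subject_id)
  check_subset <- function(tab, what) {
    if (is.null(tab)) return(invisible())
    extra <- setdiff(as.character(tab$subject_id), subj)
    if (length(extra)) {
      stop(what, " table has subject(s) absent from tumor records: ",
           paste(extra, collapse = ", "))
    }
  }
  check_subset(covariates, "covariate")
  check_subset(os, "os")
  if (!is.null(os)) {
    if (any(os$os_days <= 0)) stop("os_days must be > 0")
    if (!all(os$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
    os$subject_id <- as.character(os$subject_id)
  }
  if (!is.null(covariates)) {
    covariates$subject_id <- as.character(covariates$subject_id)
    validate_covariates(covariates)
  }
  structure(
    list(tumor = tumor, covariates = covariates, os = os),
    class = "trial_dataset"
  )
}

COVARIATE_LEVELS <- list(
  race = c("Asian", "non-Asian"),
  liver_met = c("yes", "no"),
  line_of_therapy = c("1", "2+"),
  sex = c("female", "male")
)

validate_covariates <- function(cv) {
  need <- c("subject_id", "albumin", "ecog", "race", "n_met_sites", "nlr",
            "liver_met", "baseline_sld", "line_of_therapy", "sex")
  miss <- setdiff(need, names(cv))
  if (length(miss)) stop("covariate table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cv$subject_id)) stop("covariate table must have one row per subject")
  for (col in names(COVARIATE_LEVELS)) {
    bad <- setdiff(unique(stats::na.omit(cv[[col]])), COVARIATE_LEVELS[[col]])
    if (length(bad)) {
      stop("unknown level(s) in '", col, "': ", paste(bad, collapse = ", "),
           " (expected ", paste(COVARIATE_LEVELS[[col]], collapse = "/"), ")")
    }
  }
  if (!all(stats::na.omit(cv$ecog) %in% c(0, 1))) {
    stop("ecog must be 0 or 1 (1 codes ECOG >= 1)")
  }
  ok_pos <- function(x) all(!is.finite(x) | x > 0)
  if (any(stats::na.omit(cv$albumin) <= 0)) stop("albumin must be > 0 g/L")
  if (any(stats::na.omit(cv$nlr) <= 0)) stop("nlr must be > 0")
  if (any(stats::na.omit(cv$baseline_sld) <= 0)) stop("baseline_sld must be > 0 mm")
  if (any(stats::na.omit(cv$n_met_sites) < 1)) stop("n_met_sites must be >= 1")
  invisible(cv)
}

#' @export
print.trial_dataset <- function(x, ...) {
  ns <- length(unique(x$tumor$subject_id))
  cat("<trial_dataset>\n")
  cat(sprintf("  %d subjects, %d tumor-size records\n", ns, nrow(x$tumor)))
  arm_n <- table(x$tumor$arm[!duplicated(x$tumor$subject_id)])
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s=%d", names(arm_n), arm_n), collapse = ", ")))
  if (!is.null(x$covariates)) cat(sprintf("  covariates: %d subjects\n", nrow(x$covariates)))
  if (!is.null(x$os)) {
    cat(sprintf("  OS: %d subjects, %d events\n", nrow(x$os), sum(x$os$event)))
  }
  invisible(x)
}

#' Column-name and level dialect for trial CSV files
#'
#' Describes how an external CSV triplet maps onto the canonical schema
#' (`tumor.csv`: subject_id, arm, time_weeks, sld_mm; `covariates.csv`: one
#' row per subject; `os.csv`: subject_id, os_days, event). `arm_map` converts
#' study-specific arm labels (e.g. drug names) to "treatment"/"control".
#'
#' @param tumor_cols,covariate_cols,os_cols named character vectors mapping
#'   canonical name -> file column name; defaults are the identity.
#' @param arm_map named character vector, file label -> canonical arm.
#' @return object of class `trial_dialect`.
#' @export
trial_dialect <- function(tumor_cols = NULL, covariate_cols = NULL,
                          os_cols = NULL, arm_map = NULL) {
  structure(list(tumor_cols = tumor_cols, covariate_cols = covariate_cols,
                 os_cols = os_cols, arm_map = arm_map),
            class = "trial_dialect")
}

rename_cols <- function(df, map, file) {
  if (is.null(map)) return(df)
  for (canon in names(map)) {
    src <- map[[canon]]
    if (!src %in% names(df)) {
      stop("file '", file, "': dialect maps '", canon, "' to missing column '", src, "'")
    }
    names(df)[names(df) == src] <- canon
  }
  df
}

read_one <- function(path, need, map, file) {
  if (!file.exists(path)) stop("missing input file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- rename_cols(df, map, file)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("file '", file, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read a trial dataset from a directory of CSV files
#'
#' Expects `tumor.csv` (always) plus optional `covariates.csv` and `os.csv`
#' in `dir`, in the canonical schema or translated through a
#' [trial_dialect()]. Unknown arm labels or categorical levels are reported
#' with the offending rows.
#'
#' @param dir directory containing the CSV files.
#' @param dialect a [trial_dialect()].
#' @return a [trial_dataset()].
#' @export
read_trial <- function(dir, dialect = trial_dialect()) {
  tum <- read_one(file.path(dir, "tumor.csv"),
                  c("subject_id", "arm", "time_weeks", "sld_mm"),
                  dialect$tumor_cols, "tumor.csv")
  if (!is.null(dialect$arm_map)) {
    known <- tum$arm %in% names(dialect$arm_map)
    canon <- tum$arm %in% ARM_LEVELS
    if (any(!known & !canon)) {
      rows <- which(!known & !canon)
      stop("tumor.csv: unknown arm label(s) ",
           paste(unique(tum$arm[rows]), collapse = ", "),
           " at data row(s) ", paste(head(rows, 10), collapse = ", "))
    }
    tum$arm[known] <- unname(dialect$arm_map[tum$arm[known]])
  }
  cov_path <- file.path(dir, "covariates.csv")
  cov <- NULL
  if (file.exists(cov_path)) {
    cov <- read_one(cov_path,
                    c("subject_id", "albumin", "ecog", "race", "n_met_sites",
                      "nlr", "liver_met", "baseline_sld", "line_of_therapy", "sex"),
                    dialect$covariate_cols, "covariates.csv")
    cov$line_of_therapy <- as.character(cov$line_of_therapy)
  }
  os_path <- file.path(dir, "os.csv")
  os <- NULL
  if (file.exists(os_path)) {
    os <- read_one(os_path, c("subject_id", "os_days", "event"),
                   dialect$os_cols, "os.csv")
  }
  trial_dataset(tum, cov, os)
}

#' Write a trial dataset as canonical CSV files
#'
#' Inverse of [read_trial()] with the canonical dialect: writes `tumor.csv`
#' and, when present, `covariates.csv` and `os.csv` under `dir`.
#'
#' @param ds a [trial_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(ds, dir) {
  stopifnot(inherits(ds, "trial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(ds$tumor, file.path(dir, "tumor.csv"), row.names = FALSE)
  if (!is.null(ds$covariates)) {
    write.csv(ds$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  }
  if (!is.null(ds$os)) {
    write.csv(ds$os, file.path(dir, "os.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Restrict a trial to TGI-evaluable subjects
#'
#' A subject is evaluable when they have at least one baseline assessment
#' (time <= 0 weeks) and at least one post-baseline assessment (time > 0).
#' Subjects with only baseline scans carry no information on the tumor
#' dynamic parameters and are excluded before fitting.
#'
#' @param ds a [trial_dataset()].
#' @return list with `data` (the filtered [trial_dataset()], covariate and OS
#'   tables subset accordingly) and `excluded`, a data.frame of dropped
#'   subjects with a `reason` column.
#' @export
filter_evaluable <- function(ds) {
  stopifnot(inherits(ds, "trial_dataset"))
  tum <- ds$tumor
  has_base <- tapply(tum$time_weeks <= 0, tum$subject_id, any)
  has_post <- tapply(tum$time_weeks > 0, tum$subject_id, any)
  subj <- names(has_base)
  keep <- has_base & has_post
  reason <- ifelse(!has_base & !has_post, "no assessments",
            ifelse(!has_post, "baseline only", "no baseline assessment"))
  excluded <- data.frame(subject_id = subj[!keep], reason = reason[!keep],
                         row.names = NULL, stringsAsFactors = FALSE)
  keep_ids <- subj[keep]
  sub_tab <- function(tab) {
    if (is.null(tab)) return(NULL)
    out <- tab[tab$subject_id %in% keep_ids, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  out <- trial_dataset(sub_tab(tum), sub_tab(ds$covariates), sub_tab(ds$os))
  list(data = out, excluded = excluded)
}

# Baseline SLD convention: among records at time <= 0, the one closest to 0.
baseline_sld_of <- function(tumor) {
  base <- tumor[tumor$time_weeks <= 0, , drop = FALSE]
  idx <- tapply(seq_len(nrow(base)), base$subject_id, function(i) {
    i[which.max(base$time_weeks[i])]
  })
  setNames(base$sld_mm[unlist(idx)], names(idx))
}

# One arm label per subject, named by subject id.
arm_of <- function(tumor) {
  first <- !duplicated(tumor$subject_id)
  setNames(tumor$arm[first], tumor$subject_id[first])
}
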