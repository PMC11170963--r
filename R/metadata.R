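#' Construct cohort metadata
#'
#' Per-sample metadata for a paired intervention cohort: subject, study arm
#' (drug), sampling day, demographic covariates and glycemic measures. The
#' paired design is always recovered from `subject_id` + `timepoint_day`
#' (day 0 = pre-treatment); sample identifiers are treated as opaque strings.
#'
#' @param df Data frame with required columns `sample_id`, `subject_id`,
#'   `arm`, `timepoint_day`, and optional covariate columns (`age`, `sex`,
#'   `bmi`) and clinical measure columns (e.g. `hba1c`, `fpg`, `ppg`,
#'   `homa_ir`). Clinical values may be `NA` (flagged, not dropped here).
#' @return A `cohort_metadata` object (a validated data frame).
#' @export
cohort_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "arm", "timepoint_day")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$arm <- as.character(df$arm)
  df$timepoint_day <- as.integer(df$timepoint_day)
  if (any(is.na(df$timepoint_day)) || any(df$timepoint_day < 0)) {
    stop("timepoint_day must be integer >= 0", call. = FALSE)
  }
  dup_s <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup_s)) {
    stop("duplicate sample_id: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$subject_id, df$timepoint_day, sep = "\r")
  dup_k <- df[duplicated(key), c("subject_id", "timepoint_day"), drop = FALSE]
  if (nrow(dup_k)) {
    stop("duplicated (subject_id, timepoint_day): ",
         paste(sprintf("(%s, %d)", dup_k$subject_id, dup_k$timepoint_day),
               collapse = ", "), call. = FALSE)
  }
  # arms partition subjects: a subject may not switch arm across timepoints
  arm_per_subject <- tapply(df$arm, df$subject_id,
                            function(a) length(unique(a)))
  if (any(arm_per_subject > 1)) {
    stop("subject(s) appear in more than one arm: ",
         paste(names(arm_per_subject)[arm_per_subject > 1], collapse = ", "),
         call. = FALSE)
  }
  no_baseline <- setdiff(df$subject_id, df$subject_id[df$timepoint_day == 0L])
  if (length(no_baseline)) {
    stop("subject(s) lacking a day-0 (baseline) sample: ",
         paste(unique(no_baseline), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Read cohort metadata from TSV
#'
#' Missing clinical or covariate values are encoded `NA` in the file; they
#' load as `NA` and the per-column missing counts are attached as the
#' `"n_missing"` attribute so downstream stages can report how many subjects
#' they drop.
#'
#' @param path Path to a tab-separated metadata file.
#' @return A `cohort_metadata` object.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = "NA")
  meta <- cohort_metadata(df)
  opt <- setdiff(colnames(meta),
                 c("sample_id", "subject_id", "arm", "timepoint_day"))
  attr(meta, "n_missing") <- vapply(opt, function(cn) sum(is.na(meta[[cn]])),
                                    integer(1))
  meta
}

#' Write cohort metadata to TSV
#'
#' @param meta A `cohort_metadata`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "cohort_metadata"))
  out <- as.data.frame(meta)
  for (cn in colnames(out)) {
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]])) {
      out[[cn]] <- format_repr(out[[cn]])
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Build the paired pre/post design for one post-treatment day
#'
#' Materializes the (subject, pre sample, post sample, arm) tuples used by
#' every paired analysis. Subjects lacking either the baseline or the chosen
#' post-day sample are excluded and reported via the `"excluded"` attribute.
#'
#' @param meta A `cohort_metadata`.
#' @param post_day Positive integer day of the post-treatment sample.
#' @return A `paired_design`: data frame with columns `subject_id`,
#'   `pre_sample_id`, `post_sample_id`, `arm`; attributes `post_day` and
#'   `excluded` (data frame of excluded subjects and reasons).
#' @export
build_paired_design <- function(meta, post_day) {
  stopifnot(inherits(meta, "cohort_metadata"))
  post_day <- as.integer(post_day)
  if (is.na(post_day) || post_day <= 0L) {
    stop("post_day must be a positive integer", call. = FALSE)
  }
  days <- sort(unique(meta$timepoint_day))
  if (!post_day %in% days) {
    stop(sprintf("post_day %d not present in cohort; available days: %s",
                 post_day, paste(days, collapse = ", ")), call. = FALSE)
  }
  subjects <- unique(meta$subject_id)
  pre <- meta[meta$timepoint_day == 0L, ]
  post <- meta[meta$timepoint_day == post_day, ]
  have_post <- subjects %in% post$subject_id
  keep <- subjects[have_post]
  design <- data.frame(
    subject_id = keep,
    pre_sample_id = pre$sample_id[match(keep, pre$subject_id)],
    post_sample_id = post$sample_id[match(keep, post$subject_id)],
    arm = pre$arm[match(keep, pre$subject_id)],
    stringsAsFactors = FALSE
  )
  excluded <- data.frame(
    subject_id = subjects[!have_post],
    reason = if (any(!have_post)) sprintf("no day-%d sample", post_day)
             else character(0),
    stringsAsFactors = FALSE
  )
  structure(design, class = c("paired_design", "data.frame"),
            post_day = post_day, excluded = excluded)
}

#' @exportS3Method base::print
print.paired_design <- function(x, ...) {
  cat(sprintf("<paired_design> %d pairs (day 0 vs day %d), %d excluded\n",
              nrow(x), attr(x, "post_day"), nrow(attr(x, "excluded"))))
  NextMethod()
}
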