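# Cohort ingestion, exclusion accounting, and leak-free patient-level splits.

.annotation_categories <- c("Negative", "Positive", "NoTMA", "NoTissue",
                            "NoTumor", "DeficientStaining", "OutOfFocus")

#' Load an annotation table into patient records
#'
#' Accepts a CSV (or data frame) with columns `patient_id`,
#' `label_or_exclusion`, and optionally `cohort` and `image_id`.  Tables may
#' be one row per patient or one row per image; image-level rows are
#' aggregated to one record per patient.  Every label must be one of the
#' seven annotation categories (`Negative`, `Positive`, `NoTMA`, `NoTissue`,
#' `NoTumor`, `DeficientStaining`, `OutOfFocus`); malformed or conflicting
#' rows are rejected with their line numbers.
#'
#' @param table path to a CSV file, or a data frame.
#' @return data frame of patient records: `patient_id`, `cohort`,
#'   `category`, `n_images`, and a list column `image_ids`.
#' @export
load_annotations <- function(table) {
  df <- if (is.character(table)) read.csv(table, stringsAsFactors = FALSE) else as.data.frame(table)
  need <- c("patient_id", "label_or_exclusion")
  if (!all(need %in% names(df)))
    stopf("annotation table must have columns: %s", paste(need, collapse = ", "))
  rowno <- seq_len(nrow(df))
  bad_id <- which(is.na(df$patient_id) | df$patient_id == "")
  if (length(bad_id))
    stopf("malformed rows (missing patient_id) at lines: %s",
          paste(utils::head(bad_id, 10), collapse = ", "))
  unknown <- which(!(df$label_or_exclusion %in% .annotation_categories))
  if (length(unknown))
    stopf("unknown annotation category %s at lines: %s",
          paste(sQuote(unique(df$label_or_exclusion[unknown])), collapse = ", "),
          paste(utils::head(unknown, 10), collapse = ", "))
  if (!"cohort" %in% names(df)) df$cohort <- "unspecified"
  per_image <- "image_id" %in% names(df)

  if (per_image) {
    sp <- split(rowno, df$patient_id)
    recs <- lapply(sp, function(ix) {
      cat <- unique(df$label_or_exclusion[ix])
      if (length(cat) > 1)
        stopf("conflicting categories for patient '%s' at lines: %s",
              df$patient_id[ix[1]], paste(ix, collapse = ", "))
      coh <- unique(df$cohort[ix])
      if (length(coh) > 1)
        stopf("discordant cohort tags for patient '%s' at lines: %s",
              df$patient_id[ix[1]], paste(ix, collapse = ", "))
      ids <- df$image_id[ix]
      ids <- ids[!is.na(ids) & ids != ""]
      list(patient_id = df$patient_id[ix[1]], cohort = coh, category = cat,
           n_images = length(ids), image_ids = ids)
    })
    out <- data.frame(patient_id = vapply(recs, `[[`, "", "patient_id"),
                      cohort = vapply(recs, `[[`, "", "cohort"),
                      category = vapply(recs, `[[`, "", "category"),
                      n_images = vapply(recs, `[[`, 0L, "n_images"))
    out$image_ids <- I(lapply(recs, `[[`, "image_ids"))
  } else {
    dup <- duplicated(df$patient_id)
    if (any(dup))
      stopf("duplicate patient rows at lines: %s",
            paste(utils::head(rowno[dup], 10), collapse = ", "))
    out <- data.frame(patient_id = as.character(df$patient_id),
                      cohort = df$cohort, category = df$label_or_exclusion,
                      n_images = if ("n_images" %in% names(df)) df$n_images else NA_integer_)
    out$image_ids <- I(vector("list", nrow(out)))
  }
  bad <- which(out$category != "NoTMA" & !is.na(out$n_images) & out$n_images == 0 &
                 vapply(out$image_ids, length, 0L) == 0 & per_image)
  if (length(bad))
    stopf("patients with no images but category != NoTMA: %s",
          paste(utils::head(out$patient_id[bad], 10), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Apply the exclusion accounting
#'
#' Retains only patients annotated `Negative` or `Positive` and tabulates the
#' exclusion arithmetic: total = included + sum over exclusion categories,
#' included = positives + negatives.
#'
#' @param records patient records from [load_annotations()].
#' @return list with `included` (the retained records) and `report`, an
#'   `accounting_report` with counts and percentages.
#' @export
apply_exclusions <- function(records) {
  stopifnot(is.data.frame(records), "category" %in% names(records))
  inc <- records$category %in% c("Negative", "Positive")
  excl_cats <- setdiff(.annotation_categories, c("Negative", "Positive"))
  excl_counts <- vapply(excl_cats, function(cc) sum(records$category == cc), 0L)
  total <- nrow(records)
  report <- structure(list(
    total = total,
    included = sum(inc),
    excluded = sum(!inc),
    excluded_by_category = excl_counts,
    positives = sum(records$category == "Positive"),
    negatives = sum(records$category == "Negative"),
    pct_included = round(100 * sum(inc) / total, 1),
    pct_excluded = round(100 * sum(!inc) / total, 1),
    pct_excluded_by_category = round(100 * excl_counts / max(1L, sum(!inc)), 1)),
    class = "accounting_report")
  if (report$included == 0) warning("no patients left after exclusions")
  list(included = records[inc, , drop = FALSE], report = report)
}

#' @export
print.accounting_report <- function(x, ...) {
  cat(sprintf("Cohort accounting: %d total; included %d (%.1f%%), excluded %d (%.1f%%)\n",
              x$total, x$included, x$pct_included, x$excluded, x$pct_excluded))
  for (nm in names(x$excluded_by_category))
    if (x$excluded_by_category[[nm]] > 0)
      cat(sprintf("  %-18s %6d (%.1f%% of excluded)\n", nm,
                  x$excluded_by_category[[nm]], x$pct_excluded_by_category[[nm]]))
  cat(sprintf("  included: %d negative, %d positive\n", x$negatives, x$positives))
  invisible(x)
}

#' Patient-level train/test split
#'
#' The test set receives `floor(test_fraction * n)` patients (floor, then
#' remainder to train: with n = 3376 and fraction 0.255 this reproduces the
#' 860/2516 split), drawn uniformly (or stratified by label) at the patient
#' level, deterministically under the seed.
#'
#' @param patients character vector of patient ids, or a records data frame
#'   with a `patient_id` column (and `category` when `stratify = TRUE`).
#' @param test_fraction fraction of patients assigned to the test set,
#'   in (0, 1).
#' @param seed integer RNG seed.
#' @param stratify if `TRUE`, split positives and negatives separately so the
#'   test prevalence matches the cohort prevalence.
#' @return a `split_assignment` data frame: `patient_id`, `partition`
#'   (`"train"`/`"test"`).
#' @export
split_train_test <- function(patients, test_fraction, seed = 1, stratify = FALSE) {
  rec <- if (is.data.frame(patients)) patients else data.frame(patient_id = patients)
  ids <- as.character(rec$patient_id)
  n <- length(ids)
  if (n < 2) stopf("need at least 2 patients to split")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stopf("test_fraction must lie strictly between 0 and 1")
  with_seed(seed, {
    if (stratify && "category" %in% names(rec)) {
      test <- unlist(lapply(split(ids, rec$category), function(g) {
        sample(g, floor(test_fraction * length(g)))
      }), use.names = FALSE)
    } else {
      test <- sample(ids, floor(test_fraction * n))
    }
    out <- data.frame(patient_id = ids,
                      partition = ifelse(ids %in% test, "test", "train"))
    class(out) <- c("split_assignment", "data.frame")
    out
  })
}

#' Patient-level cross-validation folds
#'
#' Partitions patients into k folds whose sizes differ by at most one, at the
#' patient level (so no image of a patient can appear in two folds).
#'
#' @param patients character vector of patient ids, or a `split_assignment`
#'   (its `"train"` patients are used), or a records data frame.
#' @param k number of folds, >= 2.
#' @param seed integer RNG seed.
#' @return a `split_assignment` data frame: `patient_id`, `partition`
#'   (`"fold_1"` ... `"fold_k"`).
#' @export
make_cv_folds <- function(patients, k = 5, seed = 1) {
  ids <- if (is.data.frame(patients)) {
    if ("partition" %in% names(patients))
      as.character(patients$patient_id[patients$partition == "train"])
    else as.character(patients$patient_id)
  } else as.character(patients)
  n <- length(ids)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (n < k) stopf("cannot make %d folds from %d patients", k, n)
  with_seed(seed, {
    perm <- sample(ids)
    # deal round-robin over the shuffled order: sizes differ by <= 1
    out <- data.frame(patient_id = perm,
                      partition = paste0("fold_", rep_len(seq_len(k), n)))
    out <- out[order(match(out$patient_id, ids)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("split_assignment", "data.frame")
    out
  })
}

#' Audit a set of partitions for patient-level leakage
#'
#' Checks that every patient appears in exactly one partition and, when an
#' image-level table is supplied, that all images of a patient share that
#' partition.
#'
#' @param assignment a `split_assignment` (or any data frame with
#'   `patient_id`, `partition`).
#' @param image_table optional data frame with `patient_id`, `image_id`.
#' @return `TRUE` invisibly; errors describe any leakage found.
#' @export
audit_no_leakage <- function(assignment, image_table = NULL) {
  dup <- assignment$patient_id[duplicated(assignment$patient_id)]
  if (length(dup))
    stopf("patients assigned to more than one partition: %s",
          paste(utils::head(unique(dup), 5), collapse = ", "))
  if (!is.null(image_table)) {
    m <- merge(image_table[!is.na(image_table$image_id), c("patient_id", "image_id")],
               assignment, by = "patient_id")
    npart <- tapply(m$partition, m$patient_id, function(p) length(unique(p)))
    if (any(npart > 1))
      stopf("images of a patient span multiple partitions: %s",
            paste(utils::head(names(npart)[npart > 1], 5), collapse = ", "))
  }
  invisible(TRUE)
}
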