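# Cohort manifests: one row per subject with site, demographics, cognition
# score and optional disability / head-motion covariates.

MANIFEST_COLS <- c("subject_id", "site", "age", "gender", "sdmt_z",
                   "edss", "mean_fd")

#' Construct a cohort manifest
#'
#' @param df data.frame with columns `subject_id`, `site`, `age`, `gender`
#'   (0 = female, 1 = male), `sdmt_z`, and optionally `edss`, `mean_fd`.
#' @return A `cohort_manifest` (data.frame subclass) with attribute
#'   `site_set` listing the distinct sites in first-appearance order.
#' @export
cohort_manifest <- function(df) {
  need <- c("subject_id", "site", "age", "gender", "sdmt_z")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!all(df$gender %in% c(0, 1))) {
    stop("gender must be coded 0 (female) / 1 (male)", call. = FALSE)
  }
  for (opt in c("edss", "mean_fd")) if (!opt %in% names(df)) df[[opt]] <- NA_real_
  df <- df[, MANIFEST_COLS]
  attr(df, "site_set") <- unique(as.character(df$site))
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Read a cohort manifest from TSV
#'
#' Tab-separated, header row, `#`-comment lines ignored.
#'
#' @param path Path to the TSV file.
#' @return A [cohort_manifest].
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  cohort_manifest(df)
}

#' Write a cohort manifest to TSV
#' @param manifest A [cohort_manifest].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter subjects by a predicate on manifest fields
#'
#' Row order is preserved. The canonical use is motion-based exclusion,
#' e.g. `filter_subjects(m, function(s) is.na(s$mean_fd) | s$mean_fd <= 0.2)`.
#'
#' @param manifest A [cohort_manifest].
#' @param predicate Function taking the manifest data.frame and returning a
#'   logical vector (vectorized over rows); rows evaluating TRUE are kept.
#' @return The filtered [cohort_manifest].
#' @export
filter_subjects <- function(manifest, predicate) {
  keep <- predicate(manifest)
  if (!is.logical(keep) || length(keep) != nrow(manifest)) {
    stop("predicate must return one logical per manifest row", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  cohort_manifest(as.data.frame(manifest)[keep, , drop = FALSE])
}
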