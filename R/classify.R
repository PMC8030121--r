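#' WHO 2013 GDM diagnostic subgroups
#'
#' A pregnancy's oral glucose tolerance test triplet (fasting, 1-hour and
#' 2-hour plasma glucose after a 75 g load, all mmol/L) is assigned to one
#' of six labels. Case thresholds are the WHO 2013 cut-offs, inclusive:
#' fasting >= 5.1, 1-hour >= 10.0, 2-hour >= 8.5. Controls must be strictly
#' below all case thresholds and additionally below the control 2-hour
#' bound, which defaults to 7.8 mmol/L (a stricter normal-tolerance bound)
#' but can be set to 8.5. Records meeting no case definition but failing the
#' control bound are `unclassified`, as are records with fasting < 5.1 but
#' both post-load values elevated (the "only" subgroups exclude them and the
#' combined group requires fasting elevation); `merge_combined = TRUE`
#' folds the latter into a broadened combined group.
#'
#' @name classify
NULL

.gdm_levels <- c("control", "fasting_only", "one_hour_only", "two_hour_only",
                 "combined", "unclassified")

#' Assign diagnostic subgroups from glucose triplets
#'
#' Vectorised over records. Exactly one label per complete triplet; a
#' missing glucose value is an error naming the field.
#'
#' @param fpg,glu_1h,glu_2h Fasting, 1-hour and 2-hour glucose (mmol/L).
#' @param control_2h_bound Upper (exclusive) 2-hour bound for controls,
#'   7.8 by default.
#' @param merge_combined If `TRUE`, records with fasting < 5.1 but both
#'   1-hour >= 10 and 2-hour >= 8.5 join `combined` instead of
#'   `unclassified`.
#' @return Factor with levels control, fasting_only, one_hour_only,
#'   two_hour_only, combined, unclassified.
#' @examples
#' assign_category(4.5, 7.1, 5.8)    # control
#' assign_category(5.2, 8.4, 6.6)    # fasting_only
#' @export
assign_category <- function(fpg, glu_1h, glu_2h, control_2h_bound = 7.8,
                            merge_combined = FALSE) {
  n <- max(length(fpg), length(glu_1h), length(glu_2h))
  fpg <- rep_len(fpg, n); glu_1h <- rep_len(glu_1h, n)
  glu_2h <- rep_len(glu_2h, n)
  for (nm in c("fpg", "glu_1h", "glu_2h")) {
    v <- get(nm)
    if (anyNA(v))
      stop("missing glucose value in field '", nm, "' at record(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           call. = FALSE)
    if (any(v <= 0 | !is.finite(v)))
      stop("glucose values must be positive and finite (field '", nm, "')",
           call. = FALSE)
  }
  f <- fpg >= 5.1; h1 <- glu_1h >= 10.0; h2 <- glu_2h >= 8.5
  lab <- rep("unclassified", n)
  lab[f & !h1 & !h2] <- "fasting_only"
  lab[!f & h1 & !h2] <- "one_hour_only"
  lab[!f & !h1 & h2] <- "two_hour_only"
  lab[f & (h1 | h2)] <- "combined"
  if (merge_combined) lab[!f & h1 & h2] <- "combined"
  lab[!f & !h1 & glu_2h < control_2h_bound] <- "control"
  factor(lab, levels = .gdm_levels)
}

#' Classify a phenotype table
#'
#' @param phenotypes Data frame with columns `sample_id`, `fpg`, `glu_1h`,
#'   `glu_2h` (optional `bmi`, `age`, `sbp`).
#' @inheritParams assign_category
#' @return The input with a `category` factor column appended.
#' @export
classify_cohort <- function(phenotypes, control_2h_bound = 7.8,
                            merge_combined = FALSE) {
  req <- c("sample_id", "fpg", "glu_1h", "glu_2h")
  missing_cols <- setdiff(req, names(phenotypes))
  if (length(missing_cols) > 0L)
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  phenotypes$category <- assign_category(phenotypes$fpg, phenotypes$glu_1h,
                                         phenotypes$glu_2h,
                                         control_2h_bound, merge_combined)
  phenotypes
}

.median_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L)
    return(c(n = 0, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(n = length(x), median = q[2], q1 = q[1], q3 = q[3])
}

#' Per-subgroup summary table
#'
#' Clinical-characteristics table in the conventional per-group layout:
#' median (IQR) and n for each continuous clinical variable, mean (SD) and n
#' for each genetic score, one row per (category, variable).
#'
#' @param phenotypes Classified phenotype table (see [classify_cohort()]),
#'   i.e. including a `category` column.
#' @param scores Optional data frame `sample_id, fpg_gs, t2d_gs` (see
#'   [merge_scores()]); joined on `sample_id`.
#' @param clinical_vars Clinical columns to summarise when present.
#' @return Data frame: category, variable, n, median, q1, q3, mean, sd.
#'   Empty groups are emitted with n = 0 and NA statistics.
#' @export
tabulate_groups <- function(phenotypes, scores = NULL,
                            clinical_vars = c("fpg", "glu_1h", "glu_2h",
                                              "age", "bmi", "sbp")) {
  if (!"category" %in% names(phenotypes))
    stop("phenotypes must carry a 'category' column; run classify_cohort()",
         call. = FALSE)
  dat <- phenotypes
  score_vars <- character(0)
  if (!is.null(scores)) {
    dat <- merge(dat, scores, by = "sample_id", all.x = TRUE, sort = FALSE)
    score_vars <- intersect(c("fpg_gs", "t2d_gs"), names(dat))
  }
  clinical_vars <- intersect(clinical_vars, names(dat))
  rows <- list()
  for (cat_lab in .gdm_levels) {
    sub <- dat[dat$category == cat_lab, , drop = FALSE]
    for (v in clinical_vars) {
      s <- .median_iqr(sub[[v]])
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_lab, variable = v, n = s["n"], median = s["median"],
        q1 = s["q1"], q3 = s["q3"], mean = NA_real_, sd = NA_real_)
    }
    for (v in score_vars) {
      x <- sub[[v]][!is.na(sub[[v]])]
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat_lab, variable = v, n = length(x),
        median = NA_real_, q1 = NA_real_, q3 = NA_real_,
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
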