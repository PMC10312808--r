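#' Parcel-level cortical surface-area table
#'
#' A long-format table of cortical surface area per subject, hemisphere and
#' atlas parcel, either raw (mm^2) or normalized (per-hemisphere percent,
#' in which case each subject-hemisphere sums to 100).
#'
#' @param df Data frame with columns `subject_id`, `hemi` (`"LH"`/`"RH"`),
#'   `parcel`, `value`.
#' @param kind `"raw"` (mm^2) or `"normalized"` (percent).
#' @return An object of class `parcel_table` (a data frame with a `kind`
#'   attribute).
#' @export
parcel_table <- function(df, kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  need <- c("subject_id", "hemi", "parcel", "value")
  if (!all(need %in% names(df))) {
    stop("parcel table needs columns: ", paste(need, collapse = ", "))
  }
  df$hemi <- toupper(df$hemi)
  if (!all(df$hemi %in% c("LH", "RH"))) stop("hemi must be LH or RH")
  if (anyDuplicated(df[, c("subject_id", "hemi", "parcel")])) {
    stop("duplicate (subject, hemisphere, parcel) rows")
  }
  if (kind == "raw" && any(df$value <= 0)) {
    stop("raw surface areas must be positive")
  }
  df <- df[order(df$subject_id, df$hemi, df$parcel), need]
  rownames(df) <- NULL
  structure(df, class = c("parcel_table", "data.frame"), kind = kind)
}

#' @export
print.parcel_table <- function(x, ...) {
  cat(sprintf("<parcel_table> %s, %d subjects, %d (hemi, parcel) labels\n",
              attr(x, "kind"), length(unique(x$subject_id)),
              nrow(unique(x[, c("hemi", "parcel")]))))
  NextMethod()
}

#' Read a parcel surface-area table
#'
#' Two dialects are supported. `"tsv"` is the tidy layout with columns
#' `subject_id`, `hemi`, `parcel`, `surfarea_mm2`. `"freesurfer_stats"` is
#' a tolerant reader for anatomical-stats-style whitespace tables (one file
#' per subject and hemisphere): comment lines start with `#`, column names
#' are taken from a `# ColHeaders ...` line when present (otherwise the
#' first data line is assumed to follow the standard layout with the
#' structure name first and surface area third), and the structure-name and
#' `SurfArea` columns are extracted. Hemisphere and subject are inferred
#' from the file name (`lh`/`rh` tokens) unless given explicitly.
#'
#' @param path File path (for `"freesurfer_stats"`, may be a vector of
#'   per-hemisphere files).
#' @param dialect `"tsv"` or `"freesurfer_stats"`.
#' @param subject_id,hemi Optional overrides for the stats dialect,
#'   recycled along `path`.
#' @return A raw [parcel_table()].
#' @export
read_parcel_table <- function(path, dialect = c("tsv", "freesurfer_stats"),
                              subject_id = NULL, hemi = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    stopifnot(length(path) == 1, file.exists(path))
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    need <- c("subject_id", "hemi", "parcel", "surfarea_mm2")
    missing_cols <- setdiff(need, names(df))
    if (length(missing_cols)) {
      stop("missing SurfArea/required columns: ",
           paste(missing_cols, collapse = ", "))
    }
    return(parcel_table(data.frame(
      subject_id = as.character(df$subject_id), hemi = df$hemi,
      parcel = df$parcel, value = as.numeric(df$surfarea_mm2)), "raw"))
  }
  stopifnot(all(file.exists(path)))
  subject_id <- if (is.null(subject_id)) rep(NA_character_, length(path))
                else rep_len(subject_id, length(path))
  hemi <- if (is.null(hemi)) rep(NA_character_, length(path))
          else rep_len(hemi, length(path))
  parts <- lapply(seq_along(path), function(i) {
    read_fs_stats_one(path[i], subject_id[i], hemi[i])
  })
  parcel_table(do.call(rbind, parts), "raw")
}

read_fs_stats_one <- function(path, subject_id = NA, hemi = NA) {
  lines <- readLines(path, warn = FALSE)
  fname <- basename(path)
  if (is.na(hemi)) {
    hemi <- if (grepl("(^|[._])rh([._])", fname)) "RH"
            else if (grepl("(^|[._])lh([._])", fname)) "LH"
            else stop("cannot infer hemisphere from file name: ", fname)
  }
  if (is.na(subject_id)) {
    subject_id <- sub("[._](lh|rh)[._].*$", "", sub("^(lh|rh)[._]", "", fname))
    subject_id <- sub("\\.stats$", "", subject_id)
  }
  ch <- grep("^#\\s*ColHeaders", lines, value = TRUE)
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(data_lines), "\\s+")
  if (length(ch)) {
    headers <- strsplit(trimws(sub("^#\\s*ColHeaders\\s*", "", ch[1])), "\\s+")[[1]]
    i_name <- match("StructName", headers)
    i_area <- match("SurfArea", headers)
    if (is.na(i_area)) stop("missing SurfArea column in ", path)
    if (is.na(i_name)) i_name <- 1L
  } else {
    ## standard anatomical-stats layout: StructName NumVert SurfArea ...
    i_name <- 1L; i_area <- 3L
  }
  data.frame(
    subject_id = subject_id, hemi = hemi,
    parcel = vapply(fields, `[`, "", i_name),
    value = as.numeric(vapply(fields, `[`, "", i_area)))
}

#' Normalize surface areas to per-hemisphere percent
#'
#' Each parcel value is divided by its subject's total over that hemisphere
#' and multiplied by 100, e.g.
#' `RH_V1_normalized = (RH_V1 / sum(all_RH_parcels)) * 100`, so every
#' subject-hemisphere sums to exactly 100.
#'
#' @param table A raw [parcel_table()].
#' @return A normalized `parcel_table`.
#' @export
normalize_sa <- function(table) {
  stopifnot(inherits(table, "parcel_table"))
  if (attr(table, "kind") != "raw") stop("table is already normalized")
  key <- interaction(table$subject_id, table$hemi, drop = TRUE)
  totals <- tapply(table$value, key, sum)
  if (any(totals <= 0)) stop("zero hemisphere total surface area")
  out <- as.data.frame(table)
  out$value <- 100 * out$value / as.numeric(totals[key])
  parcel_table(out, "normalized")
}

#' Region definition
#'
#' A named set of (hemisphere, parcel) pairs summed together in analyses.
#'
#' @param name Region name.
#' @param hemi,parcel Equal-length vectors of members.
#' @return An object of class `region_def`.
#' @export
region_def <- function(name, hemi, parcel) {
  stopifnot(length(hemi) == length(parcel), length(parcel) >= 1)
  structure(list(name = name,
                 members = data.frame(hemi = toupper(hemi), parcel = parcel)),
            class = "region_def")
}

#' Default parietal and frontal regions
#'
#' The regions where duration thresholds were found to be negatively
#' correlated with normalized surface area: five right-parietal parcels
#' (7AL, VIP, LIPd, IP1, IP2) and one left-frontal parcel (11l), in
#' 180-parcel multimodal-atlas nomenclature.
#'
#' @return A named list of two [region_def()]s, `parietal` and `frontal`.
#' @export
default_regions <- function() {
  list(
    parietal = region_def("parietal", rep("RH", 5),
                          c("7AL", "VIP", "LIPd", "IP1", "IP2")),
    frontal = region_def("frontal", "LH", "11l"))
}

#' Per-subject sum over a region's member parcels
#'
#' @param table A [parcel_table()] (raw or normalized).
#' @param region A [region_def()].
#' @return A named numeric vector (one value per subject), in table units.
#' @export
region_sum <- function(table, region) {
  stopifnot(inherits(table, "parcel_table"), inherits(region, "region_def"))
  key <- paste(table$hemi, table$parcel)
  want <- paste(region$members$hemi, region$members$parcel)
  missing_members <- setdiff(want, key)
  if (length(missing_members)) {
    stop("region members missing from table: ",
         paste(missing_members, collapse = ", "))
  }
  sub <- table[key %in% want, ]
  out <- tapply(sub$value, sub$subject_id, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Rank-based group split
#'
#' Splits subjects into `small` and `large` groups by a per-subject value:
#' the bottom `floor(n * fraction)` and the top
#' `min(ceiling(n * fraction), n - floor(n * fraction))` subjects (group
#' sizes differ by at most 1). With `fraction = 1/3` the middle third is
#' labeled `middle`. Ties are broken by stable subject-id order.
#'
#' @param values Named per-subject numeric vector.
#' @param fraction `1/3` (default) or `1/2`.
#' @return A named factor with levels `small`, `middle`, `large`.
#' @export
group_split <- function(values, fraction = 1/3) {
  n <- length(values)
  stopifnot(n >= 4, fraction > 0, fraction <= 0.5)
  ord <- order(values, names(values))      # stable: ties by subject id
  k_lo <- floor(n * fraction)
  k_hi <- min(ceiling(n * fraction), n - k_lo)
  lab <- rep("middle", n)
  lab[ord[seq_len(k_lo)]] <- "small"
  lab[ord[seq.int(n - k_hi + 1, n)]] <- "large"
  stats::setNames(factor(lab, levels = c("small", "middle", "large")),
                  names(values))
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' Product-moment correlation over pairwise-complete observations, with the
#' two-sided p-value from the t transform on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3
#'   pairwise-complete pairs; perfect correlations give p = 0).
#' @return A list with `r`, `p`, `n`, and `status` (`"ok"` or
#'   `"undefined"` when either input has zero variance).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairwise-complete observations")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, status = "undefined"))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n, status = "ok")
}

#' Parcel-wise brain-behavior correlation screen
#'
#' Correlates each parcel's (typically normalized) surface area with a
#' per-subject behavioral measure and selects parcels passing a sign filter
#' and an uncorrected alpha threshold. P-values are two-sided by default,
#' matching the reporting convention, with a separate sign filter; a
#' one-sided option and an optional Benjamini-Hochberg correction are
#' available.
#'
#' @param table A [parcel_table()].
#' @param behavior Named per-subject numeric vector (names = subject ids).
#' @param alpha Uncorrected significance threshold (default 0.01; 0.05 is
#'   the relaxed variant).
#' @param sign `"negative"` (default), `"positive"`, or `"any"`.
#' @param sided `"two"` (default) or `"one"` (one-sided in the filter
#'   direction).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame (class `screen_result`) with one row per
#'   (hemi, parcel): `r`, `p`, `n`, `selected`.
#' @export
parcel_screen <- function(table, behavior, alpha = 0.01,
                          sign = c("negative", "positive", "any"),
                          sided = c("two", "one"), adjust = c("none", "BH")) {
  sign <- match.arg(sign); sided <- match.arg(sided)
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "parcel_table"))
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 10) stop("need at least 10 subjects to screen")
  if (is.null(names(behavior)) || !all(subjects %in% names(behavior))) {
    stop("behavior must be a named vector covering every subject in the table")
  }
  b <- behavior[subjects]
  wide <- stats::xtabs(value ~ subject_id + interaction(hemi, parcel, sep = "|"),
                       data = table)
  wide <- wide[subjects, , drop = FALSE]
  keep <- is.finite(b)
  X <- as.matrix(wide)[keep, , drop = FALSE]
  b <- b[keep]
  n <- length(b)
  zx <- scale(X); zy <- as.vector(scale(b))
  r <- as.vector(crossprod(zx, zy)) / (n - 1)
  r <- pmax(-1, pmin(1, r))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (sided == "two") 2 * stats::pt(-abs(tt), df = n - 2)
       else if (sign == "negative") stats::pt(tt, df = n - 2)
       else stats::pt(-tt, df = n - 2)
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  lab <- do.call(rbind, strsplit(colnames(wide), "|", fixed = TRUE))
  sign_ok <- switch(sign, negative = r < 0, positive = r > 0,
                    any = rep(TRUE, length(r)))
  out <- data.frame(hemi = lab[, 1], parcel = lab[, 2], r = r, p = p, n = n,
                    selected = sign_ok & p < alpha)
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Average thresholds over small and large gap sizes
#'
#' For the center-surround configuration, averages duration thresholds over
#' the two smallest gaps (0.5 and 1.0 deg; the stimulus approximates one
#' large high-contrast patch) and the three largest gaps (1.5, 2.5 and
#' 4.5 deg; the target is perceptually isolated).
#'
#' @param thresholds Named numeric vector or data frame with columns
#'   `gap_deg` and `threshold_ms`; names/gaps must cover
#'   0.5, 1.0, 1.5, 2.5, 4.5.
#' @return A list with `small_gap_mean` and `large_gap_mean`.
#' @export
gap_average <- function(thresholds) {
  if (is.data.frame(thresholds)) {
    v <- stats::setNames(thresholds$threshold_ms,
                         format(thresholds$gap_deg, trim = TRUE))
  } else {
    v <- thresholds
  }
  want <- c("0.5", "1", "1.5", "2.5", "4.5")
  have <- as.character(as.numeric(names(v)))
  missing_gaps <- setdiff(want, have)
  if (length(missing_gaps)) {
    stop("missing gap condition(s): ", paste(missing_gaps, collapse = ", "),
         " deg")
  }
  v <- v[match(want, have)]
  list(small_gap_mean = mean(v[1:2]), large_gap_mean = mean(v[3:5]))
}
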