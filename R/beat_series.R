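#' Beat-aligned cardiovascular series
#'
#' Container for a single subject's beat-to-beat interval (BBI, ms),
#' end-systolic (SBP, mmHg) and end-diastolic (DBP, mmHg) pressure series,
#' one value per heart beat, with per-beat artifact flags.
#'
#' @param bbi numeric vector of beat-to-beat intervals in ms, all > 0.
#' @param sbp numeric vector of per-beat systolic pressures in mmHg.
#' @param dbp numeric vector of per-beat diastolic pressures in mmHg;
#'   must be strictly below `sbp` at every beat.
#' @param subject_id character scalar identifying the subject.
#' @param group group label, one of `"CON"`, `"IDC_LR"`, `"IDC_HR"`,
#'   `"UNKNOWN"`.
#' @param artifact_flags logical vector marking beats flagged as artifacts;
#'   defaults to all `FALSE`.
#'
#' @return An object of class `beat_series`: a list with fields
#'   `subject_id`, `group`, `bbi`, `sbp`, `dbp`, `artifact_flags`.
#' @export
#' @examples
#' bs <- beat_series(bbi = c(800, 810, 805), sbp = c(120, 122, 121),
#'                   dbp = c(60, 61, 60))
#' length(bs$bbi)
beat_series <- function(bbi, sbp, dbp, subject_id = "S1", group = "UNKNOWN",
                        artifact_flags = NULL) {
  bbi <- as.numeric(bbi); sbp <- as.numeric(sbp); dbp <- as.numeric(dbp)
  n <- length(bbi)
  if (n < 1L)
    stop("beat series must contain at least one beat", call. = FALSE)
  if (length(sbp) != n || length(dbp) != n)
    stop("bbi, sbp and dbp must have equal length", call. = FALSE)
  if (anyNA(bbi) || anyNA(sbp) || anyNA(dbp))
    stop("beat series values must not contain NA", call. = FALSE)
  if (any(bbi <= 0))
    stop("all bbi values must be positive", call. = FALSE)
  if (any(sbp <= dbp))
    stop("sbp must exceed dbp at every beat", call. = FALSE)
  group <- match.arg(group, c("CON", "IDC_LR", "IDC_HR", "UNKNOWN"))
  if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, n)
  if (length(artifact_flags) != n || !is.logical(artifact_flags))
    stop("artifact_flags must be a logical vector matching series length",
         call. = FALSE)
  structure(list(subject_id = as.character(subject_id), group = group,
                 bbi = bbi, sbp = sbp, dbp = dbp,
                 artifact_flags = artifact_flags),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> subject %s (%s): %d beats, %.1f min, %d flagged\n",
              x$subject_id, x$group, length(x$bbi),
              sum(x$bbi) / 60000, sum(x$artifact_flags)))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$bbi)

#' Read beat series from delimited text
#'
#' Reads one or more subjects from a delimited file with header columns
#' `subject_id`, `group` (optional), `beat_index` (optional), `bbi_ms`,
#' `sbp_mmhg`, `dbp_mmhg`. Row order within a subject is preserved.
#'
#' @param path path to an existing delimited text file.
#' @param sep field delimiter, default `","`.
#' @param subject optional subject id to extract when the file holds a
#'   cohort; default takes the single subject present (error if several).
#' @return A [beat_series] object with artifact flags initialised `FALSE`.
#' @seealso [read_cohort()] for multi-subject files, [write_beat_series()].
#' @export
read_beat_series <- function(path, sep = ",", subject = NULL) {
  subjects <- read_cohort(path, sep = sep)
  if (!is.null(subject)) {
    hit <- vapply(subjects, function(s) s$subject_id == subject, logical(1))
    if (!any(hit))
      stop(sprintf("subject '%s' not found in %s", subject, path),
           call. = FALSE)
    return(subjects[[which(hit)[1]]])
  }
  if (length(subjects) > 1L)
    stop("file contains multiple subjects; use read_cohort() or `subject=`",
         call. = FALSE)
  subjects[[1L]]
}

#' Read a cohort of beat series from delimited text
#'
#' @inheritParams read_beat_series
#' @return A list of [beat_series] objects, in order of first appearance.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("bbi_ms", "sbp_mmhg", "dbp_mmhg")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0L)
    stop("file contains a header but no beats", call. = FALSE)
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d",
                   col, bad), call. = FALSE)
    }
  }
  bad <- which(df$sbp_mmhg <= df$dbp_mmhg)
  if (length(bad) > 0L)
    stop(sprintf("sbp <= dbp at data row %d", bad[1]), call. = FALSE)
  if (is.null(df$subject_id)) df$subject_id <- "S1"
  if (is.null(df$group)) df$group <- "UNKNOWN"
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    beat_series(bbi = sub$bbi_ms, sbp = sub$sbp_mmhg, dbp = sub$dbp_mmhg,
                subject_id = id, group = sub$group[1])
  })
}

#' Write beat series to delimited text
#'
#' Writes one subject or a list of subjects (a cohort) in the column layout
#' accepted by [read_beat_series()] / [read_cohort()]:
#' `subject_id,group,beat_index,bbi_ms,sbp_mmhg,dbp_mmhg`.
#'
#' @param x a [beat_series] or a list of them.
#' @param path output file path.
#' @param sep field delimiter, default `","`.
#' @return `path`, invisibly.
#' @export
write_beat_series <- function(x, path, sep = ",") {
  if (inherits(x, "beat_series")) x <- list(x)
  rows <- lapply(x, function(s) {
    # %.17g round-trips doubles exactly through text
    data.frame(subject_id = s$subject_id, group = s$group,
               beat_index = seq_along(s$bbi),
               bbi_ms = sprintf("%.17g", s$bbi),
               sbp_mmhg = sprintf("%.17g", s$sbp),
               dbp_mmhg = sprintf("%.17g", s$dbp),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
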