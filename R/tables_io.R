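#' Construct and validate an analysis-ready feature table
#'
#' One row per participant: `subject_id`, `group` (HC/uHC), `sex`
#' (Male/Female), `age`, `education`, `mmse`, `icv`, plus one positive
#' volume column (mm^3) per region. The set of volume columns is recorded in
#' the `"volume_cols"` attribute.
#'
#' @param df Data frame with the columns above.
#' @param volume_cols Character vector naming the volume columns; defaults
#'   to every column not among the demographic fields.
#' @return `df` with class `c("feature_table", "data.frame")`.
#' @export
feature_table <- function(df, volume_cols = NULL) {
  demo <- c("subject_id", "group", "sex", "age", "education", "mmse", "icv")
  missing <- setdiff(demo, names(df))
  if (length(missing)) {
    stop("missing demographic columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(volume_cols)) volume_cols <- setdiff(names(df), demo)
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id: ", paste(dup, collapse = ", "))
  }
  if (!all(levels(factor(df$group)) %in% c("HC", "uHC"))) {
    stop("group labels must be HC or uHC")
  }
  df$group <- factor(df$group, levels = c("HC", "uHC"))
  df$sex <- factor(df$sex, levels = c("Male", "Female"))
  if (any(df$icv <= 0)) stop("icv must be positive")
  vol <- as.matrix(df[, volume_cols, drop = FALSE])
  if (!is.numeric(vol)) stop("volume columns must be numeric")
  if (any(!is.finite(vol))) stop("volume columns must be finite")
  if (any(vol <= 0)) stop("volumes must be positive")
  attr(df, "volume_cols") <- volume_cols
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Volume column names of a feature table
#' @param table A `feature_table`.
#' @return Character vector of region names.
#' @export
volume_cols <- function(table) {
  vc <- attr(table, "volume_cols")
  if (is.null(vc)) {
    vc <- setdiff(names(table),
                  c("subject_id", "group", "sex", "age", "education",
                    "mmse", "icv"))
  }
  vc
}

#' Read a FreeSurfer-style stats table
#'
#' Parses the TSV output of `asegstats2table` / `aparcstats2table`: first
#' column subject identifier, remaining columns numeric measures.
#'
#' @param path Path to the TSV file.
#' @param kind `"aseg"` or `"aparc"` (recorded as an attribute; parsing is
#'   identical).
#' @return Data frame with the subject id in column 1; column names as in
#'   the file header.
#' @export
read_stats_table <- function(path, kind = c("aseg", "aparc")) {
  kind <- match.arg(kind)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("stats table must have a header and >= 2 columns")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate subject id in ", basename(path), ": ",
         paste(dup, collapse = ", "))
  }
  meas <- raw[, -1, drop = FALSE]
  for (j in seq_along(meas)) {
    v <- meas[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (any(is.na(conv) & !is.na(v))) {
        stop("non-numeric cells in column '", names(meas)[j], "'")
      }
      meas[[j]] <- conv
    }
    if (anyNA(meas[[j]])) stop("missing values in column '", names(meas)[j], "'")
  }
  out <- cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE), meas)
  names(out) <- c("subject_id", names(meas))
  attr(out, "kind") <- kind
  out
}

#' Merge left/right hemisphere columns
#'
#' Sums paired `Left-*`/`Right-*` (aseg) or `lh_*`/`rh_*` (aparc) columns
#' into one total volume per region; unpaired bilateral/midline measures
#' (e.g. BrainSegVolNotVent) pass through unchanged. aparc names are
#' lower-cased with the hemisphere prefix dropped; aseg names keep their
#' hyphenated spelling.
#'
#' @param raw Data frame from [read_stats_table()] (subject id in col 1).
#' @return Data frame with merged columns.
#' @export
merge_hemispheres <- function(raw) {
  ids <- raw[[1]]
  meas <- raw[, -1, drop = FALSE]
  nm <- names(meas)
  strip <- function(x, pre) sub(paste0("^", pre), "", x)
  side <- ifelse(grepl("^Left-", nm), "L",
          ifelse(grepl("^Right-", nm), "R",
          ifelse(grepl("^lh_", nm), "L",
          ifelse(grepl("^rh_", nm), "R", "none"))))
  base <- nm
  base[grepl("^Left-", nm)] <- strip(nm[grepl("^Left-", nm)], "Left-")
  base[grepl("^Right-", nm)] <- strip(nm[grepl("^Right-", nm)], "Right-")
  base[grepl("^lh_", nm)] <- tolower(strip(nm[grepl("^lh_", nm)], "lh_"))
  base[grepl("^rh_", nm)] <- tolower(strip(nm[grepl("^rh_", nm)], "rh_"))
  # drop a trailing _volume suffix some aparc exports carry
  base <- sub("_volume$", "", base)

  out <- list()
  for (b in unique(base)) {
    idx <- which(base == b)
    sides <- side[idx]
    if (all(sides == "none")) {
      for (i in idx) out[[nm[i]]] <- meas[[i]]
    } else {
      if (!("L" %in% sides) || !("R" %in% sides)) {
        stop("unpaired hemisphere column for region '", b, "': ",
             paste(nm[idx], collapse = ", "))
      }
      out[[b]] <- meas[[idx[sides == "L"][1]]] + meas[[idx[sides == "R"][1]]]
    }
  }
  cbind(data.frame(subject_id = ids, stringsAsFactors = FALSE),
        as.data.frame(out, check.names = FALSE, optional = TRUE))
}

#' Assemble the analysis-ready feature table
#'
#' Inner join of merged volumes and demographics on `subject_id`; subjects
#' present in only one input are dropped with a message.
#'
#' @param volumes Data frame of merged volumes (subject_id + regions).
#' @param demographics Data frame with `subject_id`, `group`, `sex`, `age`,
#'   `education`, `mmse`, `icv`.
#' @return A [feature_table()].
#' @export
assemble_feature_table <- function(volumes, demographics) {
  common <- intersect(volumes$subject_id, demographics$subject_id)
  if (!length(common)) stop("empty join: no shared subject_id")
  dropped <- setdiff(union(volumes$subject_id, demographics$subject_id),
                     common)
  if (length(dropped)) {
    message("dropping ", length(dropped), " unmatched subject(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  }
  merged <- merge(demographics, volumes, by = "subject_id")
  feature_table(merged, volume_cols = setdiff(names(volumes), "subject_id"))
}

#' Write / read a feature table as TSV
#'
#' Lossless round trip at 12 significant digits; the volume-column set is
#' recovered from the header on read.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 12))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param harmonization Tag of the stored table: `"uncorrected"` (default)
#'   enforces volume positivity; `"residual"`/`"zscore"` skip it, since
#'   harmonized values are centred around zero.
#' @export
read_feature_table <- function(path,
                               harmonization = c("uncorrected", "residual",
                                                 "zscore")) {
  harmonization <- match.arg(harmonization)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (harmonization == "uncorrected") return(feature_table(df))
  demo <- c("subject_id", "group", "sex", "age", "education", "mmse", "icv")
  missing <- setdiff(demo, names(df))
  if (length(missing)) {
    stop("missing demographic columns: ", paste(missing, collapse = ", "))
  }
  df$group <- factor(df$group, levels = c("HC", "uHC"))
  df$sex <- factor(df$sex, levels = c("Male", "Female"))
  attr(df, "volume_cols") <- setdiff(names(df), demo)
  attr(df, "harmonization") <- harmonization
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write / read a long-format results table as CSV
#'
#' Fixed schema: replication, dataset, harmonization, subset, classifier,
#' mode, estimate_type, metric, value.
#'
#' @param results Results data frame (see [monte_carlo_run()]).
#' @param path File path.
#' @export
write_results <- function(results, path) {
  stopifnot(all(results_schema() %in% names(results)))
  df <- results[, results_schema()]
  df$value <- signif(df$value, 12)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(results_schema(), names(df))
  if (length(missing)) {
    stop("results file lacks columns: ", paste(missing, collapse = ", "))
  }
  df
}

results_schema <- function() {
  c("replication", "dataset", "harmonization", "subset", "classifier",
    "mode", "estimate_type", "metric", "value")
}
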