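# Sentinel strings treated as missing when reading delimited matrices.
.default_na_strings <- c("", "NA", "NaN", "null")

#' Construct a per-platform omics matrix
#'
#' An `omics_matrix` holds one platform's feature-by-sample measurements
#' together with an explicit missing-value mask and, optionally, the
#' platform's lower limit of quantitation (LLQ). Masked cells carry no
#' information: any placeholder value behind a `TRUE` mask entry is ignored
#' by every downstream operation.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Rownames are feature ids and colnames sample ids; both must be unique.
#' @param platform character scalar naming the platform (e.g. "mrna").
#' @param missing_mask logical matrix of the same shape as `values`;
#'   defaults to `is.na(values)`.
#' @param llq optional nonnegative scalar: the platform's lower limit of
#'   quantitation. When set, all observed values must be nonnegative.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, platform = "platform",
                         missing_mask = NULL, llq = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask shape must equal values shape")
  storage.mode(missing_mask) <- "logical"
  dimnames(missing_mask) <- dimnames(values)
  if (!is.null(llq)) {
    llq <- as.numeric(llq)
    if (length(llq) != 1L || is.na(llq) || llq < 0)
      stop("llq must be a single nonnegative number")
    obs <- values[!missing_mask]
    if (any(obs < 0, na.rm = TRUE))
      stop("llq is set but observed values are negative")
  }
  structure(list(platform = as.character(platform)[1L],
                 values = values, missing_mask = missing_mask, llq = llq),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix '%s': %d features x %d samples, %.1f%% missing%s\n",
              x$platform, nrow(x$values), ncol(x$values),
              100 * mean(x$missing_mask),
              if (is.null(x$llq)) "" else sprintf(", LLQ=%g", x$llq)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

feature_ids <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

#' Construct a clinical table
#'
#' One row per sample, with vital status (1 = deceased, 0 = alive), total
#' survival time in days, and a censoring indicator. Unless overridden,
#' alive patients are treated as right-censored. Extra covariate columns
#' (e.g. enrolment age in days) and an optional batch label are kept
#' alongside.
#'
#' @param sample_ids character vector of unique sample ids.
#' @param vital_status 0/1 per sample (1 = deceased).
#' @param survival_time_days nonnegative finite days per sample.
#' @param censored logical per sample; default `vital_status == 0`.
#' @param covariates optional data.frame of extra per-sample columns.
#' @param batch optional batch label per sample.
#' @return an object of class `clinical_table` (a data.frame).
#' @export
clinical_table <- function(sample_ids, vital_status, survival_time_days,
                           censored = NULL, covariates = NULL, batch = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vital_status <- as.integer(vital_status)
  if (!all(vital_status %in% c(0L, 1L)))
    stop("vital_status must be 0 (alive) or 1 (deceased)")
  survival_time_days <- as.numeric(survival_time_days)
  if (any(!is.finite(survival_time_days)) || any(survival_time_days < 0))
    stop("survival_time_days must be finite and nonnegative")
  if (is.null(censored)) censored <- vital_status == 0L
  df <- data.frame(sample_id = sample_ids,
                   vital_status = vital_status,
                   survival_time_days = survival_time_days,
                   censored = as.logical(censored),
                   stringsAsFactors = FALSE)
  if (!is.null(batch)) df$batch <- as.character(batch)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(sample_ids))
    df <- cbind(df, covariates)
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from a delimited file
#'
#' Requires columns `sample_id`, `vital_status`, `survival_time_days`;
#' any other columns become covariates (a `batch` column, if present, is
#' used as the batch label).
#'
#' @param path file path (.csv is comma-delimited, anything else tab).
#' @param sep optional delimiter override.
#' @return a `clinical_table`.
#' @export
read_clinical_table <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "vital_status", "survival_time_days")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(need, "censored", "batch"))
  clinical_table(df$sample_id, df$vital_status, df$survival_time_days,
                 censored = if ("censored" %in% names(df)) df$censored,
                 covariates = if (length(extra)) df[extra],
                 batch = if ("batch" %in% names(df)) df$batch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an omics matrix from a delimited text file
#'
#' The file must have one header row and one leading id column. Orientation
#' is an explicit flag, never guessed from the matrix shape. Cells equal to
#' one of `na_strings` become missing (mask = TRUE).
#'
#' @param path file path; `.csv` implies comma delimiter, otherwise tab
#'   (override with `sep`).
#' @param orientation `"features_in_rows"` or `"samples_in_rows"`.
#' @param platform platform label stored on the result.
#' @param sep optional delimiter override.
#' @param na_strings cell values treated as missing.
#' @param llq optional LLQ recorded on the result.
#' @return an `omics_matrix` oriented features x samples.
#' @export
read_omics_matrix <- function(path,
                              orientation = c("features_in_rows",
                                              "samples_in_rows"),
                              platform = "platform", sep = NULL,
                              na_strings = .default_na_strings, llq = NULL) {
  orientation <- match.arg(orientation)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2L) stop("expected an id column plus at least one data column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cn <- colnames(raw)[-1L]
  if (anyDuplicated(cn))
    stop("duplicate column ids: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  mask <- matrix(cells %in% na_strings | is.na(cells), nrow = nrow(cells))
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !mask, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], cn[bad[1L, 2L]]))
  dimnames(vals) <- list(ids, cn)
  dimnames(mask) <- list(ids, cn)
  if (orientation == "samples_in_rows") {
    vals <- t(vals); mask <- t(mask)
  }
  vals[mask] <- NA_real_
  omics_matrix(vals, platform = platform, missing_mask = mask, llq = llq)
}

#' Write an omics matrix to a delimited text file
#'
#' Masked cells are written as "NA", so write-then-read round-trips the
#' mask exactly and the values to text precision.
#'
#' @param m an `omics_matrix`.
#' @param path output path (`.csv` implies comma delimiter, otherwise tab).
#' @param sep optional delimiter override.
#' @export
write_omics_matrix <- function(m, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  v <- m$values
  v[m$missing_mask] <- NA_real_
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align views and clinical table on their common samples
#'
#' The retained sample set is the intersection of all views' and the
#' clinical table's sample ids, ordered lexicographically (byte order,
#' locale-independent) so downstream seeded computations are stable. Every
#' view is column-subset and reordered identically.
#'
#' @param views list of `omics_matrix` objects (at least one).
#' @param clinical a `clinical_table`.
#' @return a `multi_omics_dataset`: list with `views`, `clinical`, and a
#'   `dropped` table of per-view dropped-sample counts.
#' @export
align_samples <- function(views, clinical) {
  if (inherits(views, "omics_matrix")) views <- list(views)
  stopifnot(length(views) >= 1L, nrow(clinical) >= 1L)
  common <- clinical$sample_id
  for (v in views) common <- intersect(common, sample_ids(v))
  if (length(common) == 0L) stop("no samples shared by all views and clinical")
  common <- sort(common, method = "radix")
  dropped <- data.frame(
    view = c(vapply(views, function(v) v$platform, character(1L)), "clinical"),
    n_input = c(vapply(views, function(v) ncol(v$values), integer(1L)),
                nrow(clinical)),
    n_dropped = c(vapply(views, function(v) ncol(v$values) - length(common),
                         integer(1L)),
                  nrow(clinical) - length(common)),
    stringsAsFactors = FALSE)
  views <- lapply(views, function(v)
    omics_matrix(v$values[, common, drop = FALSE], platform = v$platform,
                 missing_mask = v$missing_mask[, common, drop = FALSE],
                 llq = v$llq))
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  class(clin) <- c("clinical_table", "data.frame")
  structure(list(views = views, clinical = clin, dropped = dropped),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("multi_omics_dataset: %d views, %d aligned samples\n",
              length(x$views), nrow(x$clinical)))
  for (v in x$views)
    cat(sprintf("  %s: %d features\n", v$platform, nrow(v$values)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' Duplicate members within a line are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return a `gene_set_collection`: named list of lists with `description`
#'   and `members`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                   i, length(f)))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("gene set '%s' lists duplicate members; deduplicated", f[1L]))
      members <- unique(members)
    }
    if (length(members) == 0L)
      stop(sprintf("GMT line %d defines an empty set", i))
    sets[[f[1L]]] <- list(description = f[2L], members = members)
  }
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets\n", length(x)))
  invisible(x)
}
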