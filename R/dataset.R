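#' Construct a concentration-response dataset
#'
#' A `bias_dataset` is a flat table of observations: one row per measured
#' response of one ligand in one pathway at one molar concentration and
#' replicate.  The pathway column plays the role of the indicator variable
#' that selects the pathway-specific branch of the joined two-pathway model;
#' for the opposing Gi/Gs variants it holds the receptor-expression level
#' (`"low"`/`"high"`).
#'
#' @param data A data.frame with columns `ligand`, `pathway`, `conc` (molar,
#'   >= 0), `replicate` and `response`.  Responses may be negative (additive
#'   noise can push observations below zero).
#' @return The validated data.frame with class `"bias_dataset"`.  Any
#'   (ligand, pathway) pair observed at fewer than 4 distinct concentrations
#'   is flagged as under-determined with a warning.
#' @export
bias_dataset <- function(data) {
  required <- c("ligand", "pathway", "conc", "replicate", "response")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("dataset is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[, required]
  data$ligand <- as.character(data$ligand)
  data$pathway <- as.character(data$pathway)
  data$conc <- as.numeric(data$conc)
  data$response <- as.numeric(data$response)
  if (anyNA(data$conc) || any(!is.finite(data$conc)) || any(data$conc < 0)) {
    stop("'conc' must be finite and >= 0 for every observation", call. = FALSE)
  }
  bad <- which(!is.finite(data$response))
  if (length(bad)) {
    stop("non-finite response in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  nconc <- tapply(data$conc, interaction(data$ligand, data$pathway, drop = TRUE),
                  function(x) length(unique(x)))
  under <- names(nconc)[nconc < 4L]
  if (length(under)) {
    warning("under-determined (ligand, pathway) pair(s) with < 4 distinct ",
            "concentrations: ", paste(under, collapse = ", "), call. = FALSE)
  }
  structure(data, class = c("bias_dataset", "data.frame"),
            underdetermined = under)
}

#' Read a concentration-response dataset from delimited text
#'
#' Expects a comma-delimited file with a header and columns `ligand`,
#' `pathway`, `replicate`, `response`, plus exactly one of `conc` (molar) or
#' `log10_conc`.  Lines starting with `#` are metadata comments and are
#' ignored.  Rows with a missing response are rejected with their row
#' numbers; duplicated (ligand, pathway, conc, replicate) rows raise a
#' warning but are all kept.
#'
#' @param path Path to the file.
#' @return A [bias_dataset()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  has_conc <- "conc" %in% names(raw)
  has_log <- "log10_conc" %in% names(raw)
  if (has_conc == has_log) {
    stop("need exactly one of 'conc' or 'log10_conc' columns", call. = FALSE)
  }
  for (col in c("ligand", "pathway", "replicate", "response")) {
    if (!col %in% names(raw)) stop("missing column '", col, "'", call. = FALSE)
  }
  if (has_log) {
    lc <- suppressWarnings(as.numeric(raw$log10_conc))
    if (anyNA(lc)) {
      stop("non-numeric 'log10_conc' in row(s): ",
           paste(which(is.na(lc)), collapse = ", "), call. = FALSE)
    }
    raw$conc <- 10^lc
  } else {
    raw$conc <- suppressWarnings(as.numeric(raw$conc))
    if (anyNA(raw$conc)) {
      stop("non-numeric 'conc' in row(s): ",
           paste(which(is.na(raw$conc)), collapse = ", "), call. = FALSE)
    }
  }
  resp <- suppressWarnings(as.numeric(raw$response))
  if (anyNA(resp)) {
    stop("missing or non-numeric 'response' in row(s): ",
         paste(which(is.na(resp)), collapse = ", "), call. = FALSE)
  }
  raw$response <- resp
  key <- paste(raw$ligand, raw$pathway, signif(raw$conc, 12), raw$replicate)
  if (anyDuplicated(key)) {
    warning("duplicated (ligand, pathway, conc, replicate) rows kept as-is",
            call. = FALSE)
  }
  bias_dataset(raw)
}

#' Write a dataset (with metadata header) to delimited text
#'
#' Writes comma-delimited text readable by [read_dataset()].  Metadata
#' (free-form named values, e.g. the generating seed) is embedded as `#`
#' comment lines so every output file records how to regenerate it.
#'
#' @param dataset A [bias_dataset()].
#' @param path Output path.
#' @param meta Named character/numeric vector written as `# name: value`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# operbias dataset (%d observations)", nrow(dataset)), con)
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  utils::write.table(as.data.frame(dataset), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.bias_dataset <- function(x, ...) {
  cat(sprintf("<bias_dataset> %d observations, %d ligand(s) x %d pathway(s)\n",
              nrow(x), length(unique(x$ligand)), length(unique(x$pathway))))
  NextMethod()
}
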