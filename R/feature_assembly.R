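#' Assemble the subject x feature table
#'
#' Binds the static block, the network-flexibility grid block and the HMM
#' block into one table with deterministic column order
#' (f1ALFF, f2ALFF, ReHo, BDC, WDC by parcel; NF by grid cell and parcel;
#' FO1..FOK; SR). At the canonical scale (90 parcels, 3 x 3 grid, 6 states)
#' this is 450 + 810 + 6 + 1 = 1,267 columns. Any subject missing from a
#' block is an error; no imputation.
#'
#' @param static named list (by subject) of static feature vectors, or `NULL`
#'   for a dynamic-only table.
#' @param nf named list (by subject) of flexibility-grid vectors, or `NULL`.
#' @param hmm subjects x features matrix from [hmm_features()], or `NULL`.
#' @param manifest data.frame with columns `subject`, `group`.
#' @return `feature_table`: list with `x` (subjects x features numeric
#'   matrix), `group` (factor, levels control < patient), `manifest`.
#' @export
assemble_features <- function(static = NULL, nf = NULL, hmm = NULL,
                              manifest) {
  subjects <- manifest$subject
  blocks <- list()
  grab <- function(lst, what) {
    miss <- setdiff(subjects, names(lst))
    if (length(miss))
      stop("missing ", what, " features for: ", paste(miss, collapse = ", "))
    m <- do.call(rbind, lst[subjects])
    rownames(m) <- subjects
    m
  }
  if (!is.null(static)) blocks$static <- grab(static, "static")
  if (!is.null(nf)) blocks$nf <- grab(nf, "network-flexibility")
  if (!is.null(hmm)) {
    miss <- setdiff(subjects, rownames(hmm))
    if (length(miss))
      stop("missing HMM features for: ", paste(miss, collapse = ", "))
    blocks$hmm <- hmm[subjects, , drop = FALSE]
  }
  if (!length(blocks)) stop("no feature blocks supplied")
  x <- do.call(cbind, blocks)
  colnames(x) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  if (anyNA(x)) stop("missing values in assembled features")
  structure(list(x = x,
                 group = factor(manifest$group,
                                levels = c("control", "patient")),
                 manifest = manifest),
            class = "feature_table")
}

#' Write a feature table as TSV with a JSON provenance sidecar
#'
#' @param ft a `feature_table`.
#' @param path TSV output path; the sidecar is `<path>.json`.
#' @param meta optional named list recorded in the sidecar (seeds, config).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, meta = list()) {
  df <- data.frame(subject = rownames(ft$x), group = as.character(ft$group),
                   ft$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(n_subjects = nrow(ft$x), n_features = ncol(ft$x),
                 feature_hash = sum_hash(colnames(ft$x))), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject
  structure(list(x = x,
                 group = factor(df$group, levels = c("control", "patient")),
                 manifest = df[, 1:2]),
            class = "feature_table")
}

# cheap deterministic content hash (sum of char codes), enough to detect
# accidental column-layout drift in the sidecar
sum_hash <- function(strings) {
  sum(vapply(strings, function(s) sum(utf8ToInt(s)), numeric(1)))
}
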