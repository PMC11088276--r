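# Plain-file interchange: tidy plate CSV, DE TSV, gene-by-drug rank TSV,
# signature JSON and truth JSON. Every stage of the pipeline hands files in
# these formats to the next.

#' Read and write the tidy plate CSV
#'
#' Columns: `plate_id, layout, replicate, well, row, col, role,
#' compound_id, dose_uM, nuclei_count` (plus `norm_count` when
#' normalized).
#'
#' @param plates Plate data.frame.
#' @param path CSV path.
#' @rdname plate_io
#' @export
write_plate_csv <- function(plates, path) {
  .check_plates(plates)
  utils::write.csv(plates, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname plate_io
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) .fail_param("plate file not found: %s", path)
  plates <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(compound_id = "character"))
  plates$compound_id[is.na(plates$compound_id)] <- ""
  .check_plates(plates)
  plates
}

#' Read and write differential-expression tables (TSV: gene, lfc, pvalue)
#'
#' @param de DE data.frame.
#' @param path TSV path.
#' @rdname de_io
#' @export
write_de_tsv <- function(de, path) {
  stopifnot(all(c("gene", "lfc", "pvalue") %in% names(de)))
  utils::write.table(de, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname de_io
#' @export
read_de_tsv <- function(path) {
  if (!file.exists(path)) .fail_param("DE file not found: %s", path)
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "lfc", "pvalue") %in% names(de)))
  de
}

#' Read and write reference rank matrices (TSV: genes x drugs)
#'
#' First column `gene`, remaining columns one per drug holding integer
#' ranks; drug classes travel in a companion two-column TSV
#' (`drug_id, class`).
#'
#' @param refmat A `reference_matrix`.
#' @param path Rank-matrix TSV path.
#' @param class_path Optional class-label TSV path.
#' @rdname refmat_io
#' @export
write_reference_matrix <- function(refmat, path, class_path = NULL) {
  stopifnot(inherits(refmat, "reference_matrix"))
  df <- data.frame(gene = rownames(refmat$ranks), refmat$ranks,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(class_path))
    utils::write.table(
      data.frame(drug_id = names(refmat$classes), class = refmat$classes,
                 stringsAsFactors = FALSE),
      class_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname refmat_io
#' @export
read_reference_matrix <- function(path, class_path = NULL) {
  if (!file.exists(path)) .fail_param("reference matrix not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df$gene
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  classes <- rep(NA_character_, ncol(m))
  names(classes) <- colnames(m)
  if (!is.null(class_path) && file.exists(class_path)) {
    cl <- utils::read.delim(class_path, stringsAsFactors = FALSE)
    classes[cl$drug_id] <- cl$class
  }
  structure(list(ranks = m, classes = classes), class = "reference_matrix")
}

#' Read and write signatures as JSON `{up: [...], down: [...]}`
#'
#' @param sig A `gene_signature`.
#' @param path JSON path.
#' @rdname signature_io
#' @export
write_signature_json <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  jsonlite::write_json(list(up = sig$up, down = sig$down,
                            n = sig$n, alpha = sig$alpha),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname signature_io
#' @export
read_signature_json <- function(path) {
  if (!file.exists(path)) .fail_param("signature file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(up = as.character(x$up), down = as.character(x$down),
                 n = as.integer(x$n %||% length(x$up)),
                 alpha = as.numeric(x$alpha %||% NA_real_)),
            class = "gene_signature")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
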