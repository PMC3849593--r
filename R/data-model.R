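#' Read a samples-by-markers platform matrix from delimited text
#'
#' Reads one molecular platform (mRNA expression, methylation or copy number)
#' from a delimited text file with a header row of marker/gene identifiers and
#' a first column of sample identifiers. The delimiter is auto-detected (tab
#' or comma) unless given. Missing values are encoded by `missing` and come
#' back as `NA`, never as zero.
#'
#' @param path file path.
#' @param missing token encoding a missing value (default `"NA"`).
#' @param delim delimiter; `NULL` (default) auto-detects tab vs comma from the
#'   header line.
#' @return Numeric matrix with sample ids as row names and marker ids as
#'   column names.
#' @export
read_platform_matrix <- function(path, missing = "NA", delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  df <- readr::read_delim(
    path, delim = delim, na = missing, col_types = readr::cols(
      readr::col_character(), .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(df) < 2) stop("platform file must have an id column plus >= 1 data column")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cn <- colnames(df)[-1]
  if (anyDuplicated(cn)) {
    stop("duplicated column id(s): ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at sample '%s', column '%s': '%s'",
                 ids[bad[1, 1]], cn[bad[1, 2]], body[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(ids, cn)
  num
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a platform matrix to delimited text
#'
#' Inverse of [read_platform_matrix()]; values are written at full double
#' precision so a write-then-read round trip is exact.
#'
#' @param x numeric matrix with row and column names.
#' @param path output file path.
#' @param delim delimiter (default tab).
#' @param missing token used for `NA` entries.
#' @param id_column name for the sample-id column header.
#' @return `path`, invisibly.
#' @export
write_platform_matrix <- function(x, path, delim = "\t", missing = "NA",
                                  id_column = "sample_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  body <- matrix(vapply(x, format_full, character(1)), nrow = nrow(x))
  body[is.na(x)] <- missing
  lines <- c(
    paste(c(id_column, colnames(x)), collapse = delim),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], body[i, ]), collapse = delim)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

format_full <- function(v) {
  if (is.na(v)) return("NA")
  sprintf("%.17g", v)
}

#' Read a marker-to-gene map
#'
#' Two-column delimited file `(marker_id, gene_id)`; header optional but the
#' first row is treated as a header when its first field is one of
#' `marker_id`, `marker`, `probe`. Column order within a gene is preserved.
#'
#' @param path file path.
#' @param delim delimiter; auto-detected when `NULL`.
#' @return A [tibble::tibble] with columns `marker_id`, `gene_id`.
#' @export
read_marker_map <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_names = FALSE,
                           col_types = "cc", progress = FALSE,
                           show_col_types = FALSE)
  if (tolower(raw[[1]][1]) %in% c("marker_id", "marker", "probe")) {
    raw <- raw[-1, , drop = FALSE]
  }
  marker_map(raw[[1]], raw[[2]])
}

#' Construct a marker-to-gene map
#'
#' @param marker_id character vector of marker identifiers (unique).
#' @param gene_id character vector of gene identifiers, parallel to
#'   `marker_id`.
#' @return A tibble with columns `marker_id`, `gene_id`.
#' @export
marker_map <- function(marker_id, gene_id) {
  stopifnot(length(marker_id) == length(gene_id))
  if (anyDuplicated(marker_id)) {
    stop("duplicated marker id(s) in map: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  }
  tibble::tibble(marker_id = as.character(marker_id),
                 gene_id = as.character(gene_id))
}

#' Assemble an aligned multi-platform dataset
#'
#' Aligns mRNA, methylation and copy-number matrices plus survival times by
#' sample id (intersection join), reorders all platforms to a common sample
#' order, drops samples missing from any platform (logged in the returned
#' object), and validates marker-to-gene maps. Genes named in a map but
#' absent from the mRNA matrix are recorded as orphans with a warning; a gene
#' with zero methylation markers is legal (its methylation component is later
#' set to zero).
#'
#' @param mrna samples x genes numeric matrix (row/col names required).
#' @param meth samples x methylation-markers matrix.
#' @param meth_map tibble from [marker_map()] mapping methylation markers to
#'   genes.
#' @param cn samples x copy-number-markers matrix.
#' @param cn_map tibble mapping copy-number markers to genes.
#' @param survival_days strictly positive numeric vector named by sample id,
#'   or a two-column data frame `(sample_id, days)`.
#' @return An object of class `platform_dataset`: a list with elements
#'   `sample_ids`, `mrna`, `meth`, `cn`, `meth_map`, `cn_map`,
#'   `survival_days`, `dropped_samples`, `orphan_genes`.
#' @export
assemble_dataset <- function(mrna, meth, meth_map, cn, cn_map, survival_days) {
  if (is.data.frame(survival_days)) {
    sv <- as.numeric(survival_days[[2]])
    names(sv) <- as.character(survival_days[[1]])
    survival_days <- sv
  }
  if (is.null(names(survival_days)))
    stop("survival_days must be named by sample id")
  for (m in list(mrna, meth, cn)) {
    stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  }
  common <- Reduce(intersect, list(rownames(mrna), rownames(meth),
                                   rownames(cn), names(survival_days)))
  if (length(common) == 0) stop("no sample ids shared by all platforms")
  # keep the mRNA matrix's ordering of the common samples for determinism
  common <- rownames(mrna)[rownames(mrna) %in% common]
  all_ids <- unique(c(rownames(mrna), rownames(meth), rownames(cn),
                      names(survival_days)))
  dropped <- setdiff(all_ids, common)
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " sample(s) absent from at least one platform: ",
            paste(head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }

  check_map <- function(map, mat, what) {
    missing_markers <- setdiff(colnames(mat), map$marker_id)
    if (length(missing_markers) > 0) {
      stop(what, " markers absent from map: ",
           paste(head(missing_markers, 5), collapse = ", "))
    }
    map <- map[map$marker_id %in% colnames(mat), , drop = FALSE]
    orphans <- setdiff(unique(map$gene_id), colnames(mrna))
    if (length(orphans) > 0) {
      warning(what, " map names gene(s) absent from mRNA matrix: ",
              paste(orphans, collapse = ", "), call. = FALSE)
    }
    list(map = map, orphans = orphans)
  }
  mm <- check_map(meth_map, meth, "methylation")
  cm <- check_map(cn_map, cn, "copy-number")

  sv <- survival_days[common]
  if (any(!is.finite(sv)) || any(sv <= 0)) {
    stop("survival_days must be finite and strictly positive ",
         "(log survival must be defined)")
  }

  structure(list(
    sample_ids = common,
    mrna = mrna[common, , drop = FALSE],
    meth = meth[common, , drop = FALSE],
    cn = cn[common, , drop = FALSE],
    meth_map = mm$map,
    cn_map = cm$map,
    survival_days = sv,
    dropped_samples = dropped,
    orphan_genes = unique(c(mm$orphans, cm$orphans))
  ), class = "platform_dataset")
}

#' @export
print.platform_dataset <- function(x, ...) {
  cat("<platform_dataset>\n")
  cat("  samples:            ", length(x$sample_ids), "\n")
  cat("  genes (mRNA):       ", ncol(x$mrna), "\n")
  cat("  methylation markers:", ncol(x$meth), "\n")
  cat("  copy-number markers:", ncol(x$cn), "\n")
  no_meth <- setdiff(colnames(x$mrna), unique(x$meth_map$gene_id))
  if (length(no_meth) > 0)
    cat("  genes without methylation markers:", length(no_meth), "\n")
  if (length(x$dropped_samples) > 0)
    cat("  dropped samples:    ", length(x$dropped_samples), "\n")
  if (length(x$orphan_genes) > 0)
    cat("  orphan mapped genes:", length(x$orphan_genes), "\n")
  invisible(x)
}
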