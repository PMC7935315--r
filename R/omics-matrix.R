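#' Omics matrices
#'
#' An `omics_matrix` is a tibble holding a features-by-samples matrix of one
#' of three kinds of molecular measurements: `"expression"` (non-negative
#' normalized expression units, e.g. RSEM or cRPKM), `"methylation"`
#' (promoter methylation beta values in \[0, 1\]) or `"psi"` (exon percent
#' spliced in, on the 0--100 scale, missing values allowed). The first
#' column, `feature_id`, carries unique feature identifiers; every other
#' column is one sample. Range invariants are enforced at construction:
#' out-of-range or unexpectedly missing values are an error, never silently
#' clamped.
#'
#' @param values A numeric matrix with rownames (feature ids), or a data
#'   frame whose first column is `feature_id`.
#' @param kind One of `"expression"`, `"methylation"`, `"psi"`.
#' @return A tibble of class `omics_matrix` with attribute `kind`.
#' @examples
#' m <- matrix(c(100, 0, NA, 50), 2, 2,
#'             dimnames = list(c("ex1", "ex2"), c("s1", "s2")))
#' omics_matrix(m, kind = "psi")
#' @export
omics_matrix <- function(values, kind = c("expression", "methylation", "psi")) {
  kind <- match.arg(kind)
  if (is.matrix(values)) {
    if (is.null(rownames(values))) {
      abort("matrix input must have rownames giving feature ids")
    }
    if (anyDuplicated(colnames(values))) {
      abort(paste0("duplicate sample ids: ",
                   paste(unique(colnames(values)[duplicated(colnames(values))]),
                         collapse = ", ")))
    }
    df <- tibble::as_tibble(values, .name_repair = "minimal")
    df <- tibble::add_column(df, feature_id = rownames(values), .before = 1)
  } else {
    df <- tibble::as_tibble(values)
    if (names(df)[1] != "feature_id") names(df)[1] <- "feature_id"
    df$feature_id <- as.character(df$feature_id)
  }
  validate_omics_values(df, kind)
  structure(df, class = c("omics_matrix", class(tibble::tibble())),
            kind = kind)
}

validate_omics_values <- function(df, kind) {
  if (ncol(df) < 2) abort("omics matrix needs at least one sample column")
  ids <- df$feature_id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate feature ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  sids <- names(df)[-1]
  if (anyDuplicated(sids)) {
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sids[duplicated(sids)]), collapse = ", ")))
  }
  vals <- as.matrix(df[-1])
  if (!is.numeric(vals)) abort("non-numeric cell in omics matrix")
  if (kind != "psi" && anyNA(vals)) {
    abort(sprintf("missing values are not allowed for kind '%s'", kind))
  }
  finite <- vals[!is.na(vals)]
  if (any(!is.finite(finite))) abort("non-finite value in omics matrix")
  switch(kind,
    expression = if (any(finite < 0)) abort("expression value out of range (< 0)"),
    methylation = if (any(finite < 0 | finite > 1)) abort("beta out of range [0, 1]"),
    psi = if (any(finite < 0 | finite > 100)) abort("PSI out of range [0, 100]")
  )
  invisible(df)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("# omics_matrix <%s>: %d features x %d samples\n",
              omics_kind(x), nrow(x), ncol(x) - 1L))
  NextMethod()
}

#' Kind of an omics matrix
#' @param x An [omics_matrix()].
#' @return `"expression"`, `"methylation"` or `"psi"`.
#' @export
omics_kind <- function(x) attr(x, "kind", exact = TRUE)

#' Feature and sample identifiers of an omics matrix
#' @param x An [omics_matrix()].
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) x$feature_id

#' @rdname feature_ids
#' @export
sample_ids <- function(x) names(x)[-1]

#' Extract the numeric values of an omics matrix
#'
#' @param x An [omics_matrix()] (or a tibble in the same layout).
#' @return A numeric matrix, features in rows (rownames = feature ids).
#' @export
omics_values <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

#' Read a tab-separated omics matrix
#'
#' Expects a TSV with a header row of sample ids, the first column holding
#' feature ids. The missing token is `"NA"` (the empty string is also
#' accepted on read); missing cells are only legal for `kind = "psi"`.
#' Lines starting with `#` are treated as comments.
#'
#' @inheritParams omics_matrix
#' @param path Path to the TSV file.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, kind = c("expression", "methylation", "psi")) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", na = character(),
                         progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort("omics matrix file needs >= 2 columns")
  ids <- as.character(raw[[1]])
  num <- lapply(raw[-1], parse_numeric_column)
  df <- tibble::tibble(feature_id = ids, !!!num)
  omics_matrix(df, kind)
}

parse_numeric_column <- function(chr) {
  missing <- chr %in% c("NA", "")
  out <- suppressWarnings(as.numeric(chr))
  bad <- !missing & is.na(out)
  if (any(bad)) {
    abort(sprintf("non-numeric cell value '%s'", chr[which(bad)[1]]))
  }
  out[missing] <- NA_real_
  out
}

#' Write an omics matrix as TSV
#'
#' Values round-trip bit-identically through [read_omics_matrix()]; missing
#' values are written as `"NA"`. Optional comment lines (prefixed `#`) can
#' record provenance such as a config hash or seed.
#'
#' @param x An [omics_matrix()].
#' @param path Output path.
#' @param comments Optional character vector of comment lines (written with
#'   a leading `# `).
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, comments = NULL) {
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), path)
    readr::write_tsv(x, path, na = "NA", append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(x, path, na = "NA", progress = FALSE)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' The TSV must contain columns `sample_id`, `tissue` and `condition`.
#' Condition labels are case-normalized and must be `"tumor"` or
#' `"normal"`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `tissue`, `condition` plus any
#'   extra covariate columns present in the file.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  validate_sample_table(df)
}

validate_sample_table <- function(df) {
  req <- c("sample_id", "tissue", "condition")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("sample table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  df$tissue <- as.character(df$tissue)
  df$condition <- tolower(as.character(df$condition))
  if (anyDuplicated(df$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")))
  }
  bad <- setdiff(unique(df$condition), c("tumor", "normal"))
  if (length(bad)) {
    abort(sprintf("unknown condition label '%s'; allowed labels: tumor, normal",
                  bad[1]))
  }
  tibble::as_tibble(df)
}

#' Read an exon annotation table
#'
#' The TSV must contain columns `exon_id`, `gene_id` and `length_nt`
#' (positive integer length in nucleotides); an optional `coord` column is
#' carried through opaquely.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `exon_id`, `gene_id`, `length_nt`
#'   (and `coord` when present).
#' @export
read_exon_annotation <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  req <- c("exon_id", "gene_id", "length_nt")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("exon annotation missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$exon_id)) abort("duplicate exon_id in annotation")
  if (any(is.na(df$length_nt)) || any(df$length_nt < 1) ||
      any(df$length_nt != trunc(df$length_nt))) {
    abort("length_nt must be a positive integer")
  }
  df$length_nt <- as.integer(df$length_nt)
  tibble::as_tibble(df)
}

#' Read a splicing-factor-to-exon target map
#'
#' Two-column TSV `sf_id`, `exon_id`. When an annotation is supplied, every
#' exon in the map must be annotated.
#'
#' @param path Path to the TSV file.
#' @param annotation Optional exon annotation tibble
#'   (see [read_exon_annotation()]).
#' @return A tibble with columns `sf_id` and `exon_id`.
#' @export
read_target_map <- function(path, annotation = NULL) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("sf_id", "exon_id") %in% names(df))) {
    abort("target map must have columns sf_id and exon_id")
  }
  if (!is.null(annotation)) {
    unknown <- setdiff(df$exon_id, annotation$exon_id)
    if (length(unknown)) {
      abort(paste0("target exons absent from annotation: ",
                   paste(head(unknown, 5), collapse = ", ")))
    }
  }
  tibble::as_tibble(df[c("sf_id", "exon_id")])
}

#' Default ordering of vast-tools coverage quality grades
#'
#' Worst to best. The leading field of a vast-tools quality string is an
#' ordinal read-coverage grade; this is the default ordering used by
#' [read_vast_inclusion_table()].
#' @export
vast_quality_levels <- c("N", "VLOW", "LOW", "OK", "SOK")

#' Read a vast-tools style inclusion table
#'
#' Parses tables in the vast-tools dialect: per-event metadata columns
#' (`EVENT`, `GENE`, `LENGTH`, plus any others), followed by repeated pairs
#' of columns -- one PSI column per sample and its quality column named
#' `<sample>-Q`. The leading comma-separated field of each quality string is
#' an ordinal coverage grade; PSI cells whose grade falls below
#' `min_quality` are set to missing. The published pipeline removes
#' "very low quality" quantifications without naming the grade cutoff, so
#' the cutoff is an explicit argument here (default `"VLOW"`, i.e. only
#' grade `"N"` cells are dropped).
#'
#' @param path Path to the inclusion table (TSV).
#' @param min_quality Minimum acceptable grade (an element of
#'   `quality_levels`). Cells strictly below it become `NA`.
#' @param quality_levels Ordered character vector of grades, worst first.
#' @return A list with elements `psi` (an [omics_matrix()] of kind
#'   `"psi"`) and `annotation` (a tibble `exon_id`, `gene_id`,
#'   `length_nt`).
#' @export
read_vast_inclusion_table <- function(path,
                                      min_quality = "VLOW",
                                      quality_levels = vast_quality_levels) {
  if (!min_quality %in% quality_levels) {
    abort("min_quality must be one of quality_levels")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  q_idx <- grep("-Q$", names(raw))
  if (!length(q_idx)) abort("no quality columns (suffix -Q) found")
  psi_idx <- q_idx - 1L
  expected <- paste0(names(raw)[psi_idx], "-Q")
  if (!identical(names(raw)[q_idx], expected) ||
      any(psi_idx %in% q_idx)) {
    abort("sample columns must come in (PSI, PSI-Q) pairs")
  }
  meta_idx <- setdiff(seq_along(raw), c(psi_idx, q_idx))
  meta <- raw[meta_idx]
  req <- c("EVENT", "GENE", "LENGTH")
  if (!all(req %in% names(meta))) {
    abort("inclusion table must have metadata columns EVENT, GENE, LENGTH")
  }
  min_rank <- match(min_quality, quality_levels)
  psi_cols <- lapply(seq_along(psi_idx), function(i) {
    v <- parse_numeric_column(raw[[psi_idx[i]]])
    qstr <- raw[[q_idx[i]]]
    grade <- vapply(strsplit(qstr, ",", fixed = TRUE), function(f) {
      if (!length(f) || !nzchar(f[1])) {
        abort(sprintf("unparsable quality string '%s'", paste(f, collapse = ",")))
      }
      f[1]
    }, character(1))
    grank <- match(grade, quality_levels)
    if (anyNA(grank)) {
      abort(sprintf("unknown quality grade '%s'", grade[which(is.na(grank))[1]]))
    }
    v[grank < min_rank] <- NA_real_
    v
  })
  names(psi_cols) <- names(raw)[psi_idx]
  psi <- omics_matrix(tibble::tibble(feature_id = meta$EVENT, !!!psi_cols),
                      kind = "psi")
  ann <- tibble::tibble(
    exon_id = meta$EVENT,
    gene_id = meta$GENE,
    length_nt = as.integer(parse_numeric_column(meta$LENGTH))
  )
  list(psi = psi, annotation = ann)
}
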