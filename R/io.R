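#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample IDs, a first column of feature IDs, and
#' a numeric body; `NA` or empty cells are missing values. Features keep
#' file order. Malformed input (ragged rows, non-numeric cells, duplicate
#' feature IDs) raises an error naming the offending line or ID.
#'
#' @param path Path to the TSV file.
#' @return Wide tibble: `feature_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("expression file needs a feature-id column plus sample columns",
      call. = FALSE
    )
  }
  tbl <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", ""), progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0L) {
    stop(
      "parse error in ", path, " at line ", probs$row[1L],
      " column ", probs$col[1L], ": expected ", probs$expected[1L],
      ", got '", probs$actual[1L], "'",
      call. = FALSE
    )
  }
  names(tbl)[1L] <- "feature_id"
  for (v in names(tbl)[-1L]) {
    # base-R strtod: correctly rounded, so written values round-trip exactly
    val <- suppressWarnings(as.numeric(tbl[[v]]))
    bad <- which(is.na(val) & !is.na(tbl[[v]]))
    if (length(bad) > 0L) {
      stop(
        "parse error in ", path, " at line ", bad[1L] + 1L, " column ", v,
        ": expected a number, got '", tbl[[v]][bad[1L]], "'",
        call. = FALSE
      )
    }
    tbl[[v]] <- val
  }
  dup <- unique(tbl$feature_id[duplicated(tbl$feature_id)])
  if (length(dup) > 0L) {
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "),
      call. = FALSE
    )
  }
  tbl
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: missing values become `NA` cells, and a
#' write-then-read round trip reproduces values and missingness exactly.
#'
#' @param data Wide expression tibble (`feature_id` + sample columns).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_expression <- function(data, path) {
  out <- data
  for (v in names(out)[-1L]) {
    # 17 significant digits: lossless double -> text -> double round trip
    txt <- sprintf("%.17g", out[[v]])
    txt[is.na(out[[v]])] <- NA_character_
    out[[v]] <- txt
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(data)
}

#' Read a typed sample metadata table
#'
#' Reads a TSV whose first column holds sample IDs, with every other
#' column's type declared `"numeric"` or `"categorical"` — the declaration
#' decides how the CCC partitions the variable, so it is required rather
#' than guessed.
#'
#' @param path Path to the TSV file.
#' @param types Named character vector mapping every non-ID column to
#'   `"numeric"` or `"categorical"`.
#' @return Tibble: `sample_id` plus typed variable columns (numeric or
#'   character).
#' @export
read_metadata <- function(path, types) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("NA", ""), progress = FALSE, show_col_types = FALSE
  )
  names(tbl)[1L] <- "sample_id"
  vars <- names(tbl)[-1L]
  undeclared <- setdiff(vars, names(types))
  if (length(undeclared) > 0L) {
    stop(
      "no type declared for metadata column(s): ",
      paste(undeclared, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- types[!types %in% c("numeric", "categorical")]
  if (length(bad) > 0L) {
    stop("metadata types must be 'numeric' or 'categorical'", call. = FALSE)
  }
  for (v in vars) {
    if (types[[v]] == "numeric") {
      val <- suppressWarnings(as.numeric(tbl[[v]]))
      introduced <- which(is.na(val) & !is.na(tbl[[v]]))
      if (length(introduced) > 0L) {
        stop(
          "non-numeric value in numeric metadata column '", v,
          "' at data line ", introduced[1L],
          call. = FALSE
        )
      }
      tbl[[v]] <- val
    }
  }
  tbl
}

#' Write a per-pair result table as TSV
#'
#' Long-format writer for pairwise results ([ccc_pairwise()],
#' [compare_methods()]`$pairs`, intersection tables): plain TSV with
#' missing coefficients encoded as `NA`.
#'
#' @param data Tibble of per-pair results.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_pairs <- function(data, path) {
  readr::write_tsv(data, path, na = "NA", progress = FALSE)
  invisible(data)
}
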