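# Normalise an expression input (wide tibble with a feature-id first column,
# or a numeric matrix with feature rownames) into ids + a features-by-samples
# numeric matrix. Used by every data-frame-first entry point.
parse_features <- function(data, min_features = 2L) {
  if (is.matrix(data)) {
    mat <- data
    storage.mode(mat) <- "double"
    ids <- rownames(mat) %||% paste0("f", seq_len(nrow(mat)))
    sample_ids <- colnames(mat) %||% paste0("s", seq_len(ncol(mat)))
  } else if (is.data.frame(data)) {
    if (ncol(data) < 2L) {
      stop("expression data needs a feature-id column plus sample columns",
        call. = FALSE
      )
    }
    first <- data[[1L]]
    if (!is.character(first) && !is.factor(first)) {
      stop("first column must hold feature identifiers", call. = FALSE)
    }
    ids <- as.character(first)
    body <- data[, -1L, drop = FALSE]
    bad <- names(body)[!vapply(body, is.numeric, logical(1))]
    if (length(bad) > 0L) {
      stop("non-numeric sample columns: ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    mat <- matrix(unlist(body, use.names = FALSE),
      nrow = nrow(data),
      dimnames = NULL
    )
    sample_ids <- names(body)
  } else {
    stop("expression data must be a data frame or a numeric matrix",
      call. = FALSE
    )
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate feature IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (length(ids) < min_features) {
    stop("need at least ", min_features, " features", call. = FALSE)
  }
  list(
    ids = ids, mat = mat, sample_ids = sample_ids,
    n_features = length(ids), n_samples = ncol(mat)
  )
}

# Coerce one feature vector and tag its type for ccc_pair().
feature_type <- function(x) {
  if (is.numeric(x)) "numeric" else "categorical"
}
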