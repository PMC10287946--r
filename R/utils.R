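# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class = "treesem_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

validation_error <- function(msg) abort(msg, class = "treesem_validation_error")

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# canonical label for an undirected edge, used for deterministic tie-breaks
edge_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

check_expression_matrix <- function(X, min_subjects = 1L) {
  if (!is.matrix(X) || !is.numeric(X))
    validation_error("expression data must be a numeric matrix (subjects x genes)")
  if (is.null(colnames(X)))
    validation_error("expression matrix must have gene identifiers as column names")
  if (anyNA(X) || any(!is.finite(X)))
    validation_error("expression matrix contains missing or non-finite values")
  if (nrow(X) < min_subjects)
    validation_error(sprintf("at least %d subjects required, got %d", min_subjects, nrow(X)))
  invisible(X)
}

check_groups <- function(groups, n, min_per_group = 1L) {
  if (length(groups) != n)
    validation_error(sprintf("group labels (%d) do not match number of subjects (%d)",
                             length(groups), n))
  g <- factor(groups)
  if (nlevels(g) != 2L)
    validation_error(sprintf("exactly two groups required, got %d level(s)", nlevels(g)))
  cnt <- table(g)
  if (any(cnt < min_per_group))
    validation_error(sprintf("each group needs >= %d subjects (sizes: %s)",
                             min_per_group, paste(cnt, collapse = ", ")))
  g
}

clip_correlation <- function(r, clip_r = 0.999999, warn = TRUE) {
  out <- abs(r) >= 1 - .Machine$double.eps
  if (any(out, na.rm = TRUE)) {
    if (warn)
      warning(sprintf("%d correlation(s) with |r| >= 1 clipped to %g", sum(out), clip_r),
              call. = FALSE)
    r[out] <- sign(r[out]) * clip_r
  }
  r
}

# default gene identifiers shared by the simulators
gene_ids <- function(p) paste0("g", seq_len(p))
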