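# Internal helpers shared across modules.

# Derive a reproducible 32-bit sub-seed from a master seed and a stream name,
# so each stochastic stage (subsampling, NMF init, label propagation,
# permutation tests, simulation) has its own independent stream and toggling
# one stage never perturbs another.
derive_seed <- function(master, ...) {
  if (is.null(master)) return(NULL)
  key <- paste(c(as.character(master), as.character(unlist(list(...)))),
               collapse = "/")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483563
  as.integer(h)
}

set_stream <- function(master, ...) {
  s <- derive_seed(master, ...)
  if (!is.null(s)) set.seed(s)
  invisible(s)
}

# Transpose helper: clustering operates on samples, the expression matrix is
# genes x samples.
samples_by_genes <- function(expr) t(expr)

assert_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must carry gene row names and sample column names")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (anyNA(expr))
    stop("expression matrix contains missing values")
  invisible(expr)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
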