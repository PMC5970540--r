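#' Transform a matrix to non-negative values for NMF
#'
#' Log-scale expression data contains negative values, which non-negative
#' matrix factorization cannot consume directly. `"shift"` subtracts the
#' global minimum so the smallest entry becomes zero, preserving the gene
#' count; `"posneg"` splits every row into its positive and negative parts
#' (doubling the rows), the standard alternative when the sign pattern itself
#' is informative.
#'
#' @param v Numeric matrix (features x samples).
#' @param mode `"shift"` (default) or `"posneg"`.
#' @return A non-negative matrix.
#' @export
nonneg_transform <- function(v, mode = c("shift", "posneg")) {
  mode <- match.arg(mode)
  if (mode == "shift") {
    mn <- min(v)
    if (mn < 0) v <- v - mn
    v
  } else {
    pos <- pmax(v, 0)
    neg <- pmax(-v, 0)
    rownames(pos) <- paste0(rownames(v), "_pos")
    rownames(neg) <- paste0(rownames(v), "_neg")
    rbind(pos, neg)
  }
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (features x samples) as `V ~ W %*% H`
#' with `W` (features x k) and `H` (k x samples), minimizing the Frobenius
#' reconstruction error with Lee-Seung multiplicative updates. The objective
#' is non-increasing across iterations; iteration stops at `max_iter` or when
#' the relative decrease of the error falls below `tol`.
#'
#' @param v Non-negative numeric matrix, features x samples.
#' @param k Number of factors (>= 2).
#' @param seed Optional integer seed for the random initialization.
#' @param max_iter Iteration cap.
#' @param tol Relative-change convergence tolerance on the Frobenius error.
#' @return List with components `w`, `h`, `loss` (Frobenius error trace,
#'   one entry per iteration including the initial error) and `iterations`.
#' @export
nmf_factorize <- function(v, k, seed = NULL, max_iter = 500, tol = 1e-5) {
  stopifnot(is.matrix(v), is.numeric(v))
  if (any(v < 0)) stop("NMF input must be non-negative")
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(v)) stop("k (", k, ") exceeds number of samples (", ncol(v), ")")
  zero_cols <- which(colSums(v) == 0)
  if (length(zero_cols) > 0)
    stop("all-zero input column(s) for NMF: ",
         paste(utils::head(colnames(v)[zero_cols], 5), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  scale <- sqrt(mean(v) / k)
  w <- matrix(stats::runif(nrow(v) * k, 0, 1) * scale + 1e-4, nrow(v), k)
  h <- matrix(stats::runif(k * ncol(v), 0, 1) * scale + 1e-4, k, ncol(v))
  eps <- .Machine$double.eps
  frob <- function(wh) sqrt(sum((v - wh)^2))
  loss <- frob(w %*% h)
  for (it in seq_len(max_iter)) {
    h <- h * crossprod(w, v) / (crossprod(w) %*% h + eps)
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    e <- frob(w %*% h)
    loss <- c(loss, e)
    prev <- loss[length(loss) - 1]
    if (prev > 0 && abs(prev - e) / prev < tol) break
  }
  dimnames(h) <- list(NULL, colnames(v))
  list(w = w, h = h, loss = loss, iterations = length(loss) - 1L)
}
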