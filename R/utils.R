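#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "prsf_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Cosine similarity between two vectors
#'
#' Zero-norm vectors are assigned similarity 0 by convention (they carry no
#' directional information), so downstream credit and importance computations
#' stay finite.
#'
#' @param a,b numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Row-wise cosine similarity of each row of M against vector v.
# Zero-norm rows (or zero-norm v) get similarity 0.
cosine_similarity_rows <- function(M, v) {
  nv <- sqrt(sum(v * v))
  if (nv == 0) return(rep(0, nrow(M)))
  nr <- sqrt(rowSums(M * M))
  out <- as.numeric(M %*% v) / (nr * nv)
  out[nr == 0] <- 0
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
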