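#' Non-negative least-squares mixture baseline
#'
#' Expresses a target copying-fraction vector as a non-negative combination
#' of surrogate profiles by solving `min || t(F) w - target ||^2` subject to
#' `w >= 0` (Lawson-Hanson active set), then rescaling the weights to sum
#' to 1. The residual norm is reported before rescaling. This is the
#' mixture-regression baseline the Bayesian sampler is compared against.
#'
#' @param target Donor-level probability vector (length D, sums to 1), or a
#'   single-row chunklengths tibble which is normalized first.
#' @param profiles Surrogate profile tibble or S x D matrix.
#' @return A tibble with columns `surrogate`, `weight` plus attributes
#'   `residual_norm` and `degenerate` (TRUE when the unconstrained fit was
#'   all-zero and weights were set uniform).
#' @export
nnls_mixture <- function(target, profiles) {
  f <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (is.data.frame(target)) {
    target <- as.numeric(copy_matrix(target)[1L, ])
    target <- target / sum(target)
  }
  stopifnot(length(target) == ncol(f))
  sol <- pracma::lsqnonneg(t(f), target)
  w <- sol$x
  resid <- sqrt(max(sol$resid.norm, 0))
  degenerate <- all(w <= 0)
  if (degenerate) {
    warn("NNLS fit is degenerate (all-zero weights); reporting uniform weights")
    w <- rep(1 / length(w), length(w))
  } else {
    w <- w / sum(w)
  }
  out <- tibble::tibble(surrogate = rownames(f) %||% paste0("s", seq_len(nrow(f))),
                        weight = w)
  attr(out, "residual_norm") <- resid
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-recipient NNLS ancestry estimates
#'
#' Applies [nnls_mixture()] to every recipient of a chunklengths table,
#' mirroring the output shape of [sourcefind()].
#'
#' @param x Chunklengths tibble.
#' @param profiles Surrogate profile tibble.
#' @return Tibble: `recipient` plus one weight column per surrogate.
#' @export
nnls_ancestry <- function(x, profiles) {
  f <- profile_matrix(profiles)
  m <- copy_matrix(x)
  if (!identical(colnames(m), colnames(f))) {
    abort("donor columns of chunklengths and profiles must match (same order)")
  }
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tgt <- m[i, ] / sum(m[i, ])
    setNames(nnls_mixture(tgt, f)$weight, rownames(f))
  })
  dplyr::bind_cols(tibble::tibble(recipient = x$recipient),
                   tibble::as_tibble(do.call(rbind, rows)))
}
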