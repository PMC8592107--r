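#' Conjugate-normal posterior update for the mean incremental net benefit
#'
#' With known sampling SD, the posterior mean after observing per-pair
#' incremental net monetary benefits x_1, ..., x_n is the
#' precision-weighted average
#' \deqn{\mu_n = (\mu_0 n_0 + \sum_j x_j) / (n_0 + n)}
#' and the effective pair count grows from m to m + n. Block means enter
#' with multiplicity `weights` (a block mean counted n_pairs times),
#' which is exactly equivalent to the per-pair update for the posterior
#' mean under known sigma_x.
#'
#' @param beliefs A [beliefs()] state.
#' @param x Observations (GBP per pair): per-pair values or block means.
#' @param weights Multiplicity of each observation (default 1); need not
#'   be integer, so partial blocks are supported.
#' @return The updated [beliefs()] state. An empty observation set
#'   returns the input unchanged.
#' @examples
#' b <- beliefs(mu = 0, m = 2, sigma_x = 100)
#' update_posterior(b, c(3, 3))                 # mu 1.5, m 4
#' update_posterior(b, -1000, weights = 10)     # block mean, multiplicity 10
#' @export
update_posterior <- function(beliefs, x, weights = NULL) {
  validate_beliefs(beliefs)
  if (length(x) == 0L) return(beliefs)
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x))
    abort("`weights` must match `x` in length", class = "valseq_invalid_input")
  if (any(!is.finite(x)) || any(!is.finite(weights)) || any(weights <= 0))
    abort("observations and weights must be finite, weights positive",
          class = "valseq_invalid_input")
  n_new <- sum(weights)
  total <- sum(x * weights)
  beliefs(
    mu = (beliefs$mu * beliefs$m + total) / (beliefs$m + n_new),
    m = beliefs$m + n_new,
    sigma_x = beliefs$sigma_x
  )
}

#' Prior effective sample size from prior and sampling SDs
#'
#' The weight of a normal prior expressed in pairwise allocations:
#' n0 = sigma_x^2 / sigma_0^2. A vague prior (large `sigma_0`) has
#' n0 near 0; sigma_0 = sigma_x corresponds to one pair's worth of
#' information.
#'
#' @param sigma_x Known per-pair sampling SD (GBP, > 0).
#' @param sigma_0 Prior SD of the unknown mean (GBP, > 0).
#' @return Effective pair count.
#' @examples
#' effective_sample_size(10, 5) # 4
#' @export
effective_sample_size <- function(sigma_x, sigma_0) {
  stopifnot(is.numeric(sigma_x), is.numeric(sigma_0), sigma_x > 0)
  if (any(sigma_0 <= 0))
    abort("`sigma_0` must be positive (an infinitely informative prior is unsupported)",
          class = "valseq_invalid_input")
  sigma_x^2 / sigma_0^2
}
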