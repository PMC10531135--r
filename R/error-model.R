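# Per-read error-rate model: exponentiated Weibull distribution plus the
# insertion/deletion/substitution split.

#' Exponentiated Weibull parameters
#'
#' The per-read error rate (percent of read length) is modelled by the
#' exponentiated Weibull distribution with CDF
#' \deqn{F(x) = [1 - \exp(-((x - loc)/scale)^c)]^a, \quad x \ge loc,}
#' where `a` (alpha) and `c` (kappa) are the two shape parameters, `loc` the
#' location and `scale` the scale, all on the percent scale for `loc`/`scale`.
#'
#' @param a,c Shape parameters (> 0).
#' @param loc Location in percent (>= 0).
#' @param scale Scale in percent (> 0).
#' @return An object of class `exp_weibull_params` (a named list).
#' @export
exp_weibull_params <- function(a, c, loc = 0, scale = 1) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(c) || c <= 0)
    rlang::abort("Shape parameters `a` and `c` must be > 0.")
  if (!is.numeric(scale) || scale <= 0) rlang::abort("`scale` must be > 0.")
  if (!is.numeric(loc) || loc < 0) rlang::abort("`loc` must be >= 0.")
  structure(list(a = as.double(a), c = as.double(c),
                 loc = as.double(loc), scale = as.double(scale)),
            class = "exp_weibull_params")
}

#' @export
print.exp_weibull_params <- function(x, ...) {
  cat(sprintf(
    "Exponentiated Weibull: a = %.4g, c = %.4g, loc = %.4g, scale = %.4g (mean %.3f%%)\n",
    x$a, x$c, x$loc, x$scale, exp_weibull_mean(x)))
  invisible(x)
}

as_exp_weibull_params <- function(params) {
  if (inherits(params, "exp_weibull_params")) return(params)
  if (is.list(params) && all(c("a", "c", "loc", "scale") %in% names(params)))
    return(exp_weibull_params(params$a, params$c, params$loc, params$scale))
  rlang::abort("`params` must be an exp_weibull_params object.")
}

#' Exponentiated Weibull distribution functions
#'
#' Density, distribution function, quantile function and random generation
#' for the exponentiated Weibull distribution used as the per-read
#' error-rate law. `rexpweibull()` draws by inverse-CDF transform of
#' uniform variates.
#'
#' @param x,q,p Numeric vectors of values (percent), quantiles, probabilities.
#' @param n Number of draws.
#' @param params An [exp_weibull_params()] object.
#' @return Numeric vector.
#' @examples
#' p <- exp_weibull_params(a = 1, c = 1, loc = 0, scale = 1)
#' pexpweibull(1, p)  # 1 - exp(-1), the exponential special case
#' @export
pexpweibull <- function(q, params) {
  params <- as_exp_weibull_params(params)
  z <- (q - params$loc) / params$scale
  out <- numeric(length(q))
  pos <- !is.na(z) & z > 0
  out[pos] <- (1 - exp(-z[pos]^params$c))^params$a
  out[is.na(z)] <- NA_real_
  out
}

#' @rdname pexpweibull
#' @param log Return log-density?
#' @export
dexpweibull <- function(x, params, log = FALSE) {
  params <- as_exp_weibull_params(params)
  z <- (x - params$loc) / params$scale
  out <- rep(-Inf, length(x))
  pos <- !is.na(z) & z > 0
  zp <- z[pos]
  lg <- log(params$a) + log(params$c) - log(params$scale) +
    (params$c - 1) * log(zp) - zp^params$c +
    (params$a - 1) * log1p(-exp(-zp^params$c))
  out[pos] <- lg
  out[is.na(z)] <- NA_real_
  if (log) out else exp(out)
}

#' @rdname pexpweibull
#' @export
qexpweibull <- function(p, params) {
  params <- as_exp_weibull_params(params)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    rlang::abort("Probabilities must be in [0, 1].")
  params$loc + params$scale * (-log1p(-p^(1 / params$a)))^(1 / params$c)
}

#' @rdname pexpweibull
#' @export
rexpweibull <- function(n, params) {
  qexpweibull(runif(n), params)
}

# Mean of the distribution, by numerical integration of the survival function.
exp_weibull_mean <- function(params) {
  params <- as_exp_weibull_params(params)
  upper <- params$loc + params$scale * (-log1p(-0.999999^(1 / params$a)))^(1 / params$c)
  s <- integrate(function(x) 1 - pexpweibull(x, params),
                 lower = params$loc, upper = max(upper, params$loc + 1),
                 rel.tol = 1e-9)$value
  params$loc + s
}

#' Error-type split
#'
#' Fractions of insertions, deletions and substitutions among introduced
#' errors. The defaults (28% insertions, 42% deletions, 30% substitutions)
#' are representative of R9.4.1 nanopore 16S metabarcoding runs.
#'
#' @param p_ins,p_del,p_sub Fractions in `[0, 1]` summing to 1.
#' @return A named list of class `error_type_split`.
#' @export
error_type_split <- function(p_ins = 0.28, p_del = 0.42, p_sub = 0.30) {
  p <- c(p_ins, p_del, p_sub)
  if (any(!is.numeric(p)) || any(p < 0 | p > 1))
    rlang::abort("Split fractions must be in [0, 1].")
  if (abs(sum(p) - 1) > 1e-9)
    rlang::abort("Split fractions must sum to 1 (within 1e-9).")
  structure(list(p_ins = p_ins, p_del = p_del, p_sub = p_sub),
            class = "error_type_split")
}

#' Draw per-read error rates
#'
#' `n` i.i.d. error-rate percentages are drawn by inverse-CDF sampling from
#' the exponentiated Weibull law and clipped to `[0, 100]` (a fitted
#' distribution can produce unphysical rates; clipping keeps the draw count
#' exact).
#'
#' @param n Number of reads.
#' @param params [exp_weibull_params()].
#' @param seed Integer seed (NULL = use current RNG stream).
#' @return Numeric vector of `n` percentages in `[0, 100]`.
#' @export
sample_error_rates <- function(n, params, seed = NULL) {
  assert_count(n, "n")
  params <- as_exp_weibull_params(params)
  with_seed(seed, pmin(pmax(rexpweibull(n, params), 0), 100))
}

#' Generate a per-read error profile
#'
#' For each read an error rate `r` is drawn from the exponentiated Weibull
#' law and deterministically apportioned to the three error types:
#' `(r * p_ins, r * p_del, r * p_sub)`. Rounding to integer edit counts
#' happens later in the injector, so each entry's percentages sum exactly to
#' its drawn rate.
#'
#' @param n Number of reads (profile lines).
#' @param params [exp_weibull_params()].
#' @param split [error_type_split()] (defaults 0.28/0.42/0.30).
#' @param seed Integer seed.
#' @return A profile tibble (`ins_pct`, `del_pct`, `sub_pct`) with `n` rows.
#' @export
make_profile <- function(n, params, split = error_type_split(), seed = NULL) {
  if (!inherits(split, "error_type_split"))
    rlang::abort("`split` must be an error_type_split object.")
  r <- sample_error_rates(n, params, seed = seed)
  tibble(ins_pct = r * split$p_ins,
         del_pct = r * split$p_del,
         sub_pct = r * split$p_sub)
}

#' Constant-rate profile
#'
#' Convenience for simulations at a fixed per-read error rate (e.g. a flat
#' 10% rate split 28/42/30).
#'
#' @param n Number of reads.
#' @param rate Error rate percent applied to every read.
#' @param split [error_type_split()].
#' @return A profile tibble with `n` identical rows.
#' @export
constant_profile <- function(n, rate, split = error_type_split()) {
  assert_count(n, "n", min = 1L)
  if (!is.numeric(rate) || rate < 0 || rate > 100)
    rlang::abort("`rate` must be a percentage in [0, 100].")
  tibble(ins_pct = rep(rate * split$p_ins, n),
         del_pct = rep(rate * split$p_del, n),
         sub_pct = rep(rate * split$p_sub, n))
}
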