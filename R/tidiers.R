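#' Tidy a power-law fit
#'
#' @param x an `agg_powerfit`.
#' @param ... unused.
#' @return tibble with one row per parameter (`a`, `b`).
#' @method tidy agg_powerfit
#' @export
tidy.agg_powerfit <- function(x, ...) {
  tibble(term = c("a", "b"),
         estimate = c(x$a, x$b),
         std.error = c(NA_real_, x$se_b))
}

#' One-row summary of a power-law fit
#'
#' @param x an `agg_powerfit`.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance agg_powerfit
#' @export
glance.agg_powerfit <- function(x, ...) {
  tibble(r.squared = x$r_squared, residual_ss = x$residual_ss,
         n = x$n, method = x$method)
}

#' Tidy a pairwise comparison
#'
#' @param x an `agg_comparison`.
#' @param ... unused.
#' @return the comparison as a plain tibble.
#' @method tidy agg_comparison
#' @export
tidy.agg_comparison <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a multi-group comparison
#'
#' @param x an `agg_multicomp`.
#' @param ... unused.
#' @return per-group tibble with letters; omnibus results as attributes-free
#'   columns `kw_statistic`, `kw_p` repeated per row.
#' @method tidy agg_multicomp
#' @export
tidy.agg_multicomp <- function(x, ...) {
  x$groups %>%
    mutate(kw_statistic = x$omnibus$statistic, kw_p = x$omnibus$p)
}
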