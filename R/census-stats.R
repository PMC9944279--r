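INFECTED_STAGES <- c("early", "mature", "post")
ALL_STAGES <- c("non", "early", "mature", "post", "decaying")

# Accepts per-cell rows (stage column) or per-stage counts (stage + count);
# returns named counts over the five stages.
stage_counts <- function(census) {
  if (!is.data.frame(census) || !"stage" %in% names(census)) {
    abort_config("`census` must be a data frame with a `stage` column")
  }
  stage <- as.character(census$stage)
  bad <- setdiff(unique(stage), ALL_STAGES)
  if (length(bad) > 0) {
    abort_config("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  counts <- if ("count" %in% names(census)) {
    tapply(census$count, factor(stage, levels = ALL_STAGES), sum,
           default = 0)
  } else {
    table(factor(stage, levels = ALL_STAGES))
  }
  out <- as.numeric(counts)
  names(out) <- ALL_STAGES
  out
}

#' Infection prevalence of a census
#'
#' Percentage of host cells that are early-, maturely-, or post-infected.
#' Decaying cells count in the denominator (they are part of the scored
#' population) but not in the numerator, since their state is most likely
#' not the result of a fungal infection.
#'
#' @param census data frame with a `stage` column, either one row per cell
#'   or per-stage rows with a `count` column. Stages:
#'   non, early, mature, post, decaying.
#' @return prevalence in percent.
#' @examples
#' prevalence(tibble::tibble(
#'   stage = c("non", "early", "mature", "post", "decaying"),
#'   count = c(53, 10, 20, 17, 0))) # 47
#' @export
prevalence <- function(census) {
  counts <- stage_counts(census)
  total <- sum(counts)
  if (total == 0) {
    abort_config("cannot compute prevalence of an empty census")
  }
  100 * sum(counts[INFECTED_STAGES]) / total
}

#' Fold-enrichment of infected cells within aggregates
#'
#' Ratio of the infection prevalence inside the aggregate compartment to
#' the prevalence in the ambient water. Values are kept unrounded; round
#' only at reporting (71% over 42% prints as 1.7).
#'
#' @param prev_aggregate prevalence within aggregates, percent.
#' @param prev_ambient prevalence in the ambient water, percent, > 0.
#' @return dimensionless fold-enrichment.
#' @examples
#' enrichment(71, 42) # 1.69
#' @export
enrichment <- function(prev_aggregate, prev_ambient) {
  if (any(!is.finite(prev_aggregate)) || any(prev_aggregate < 0)) {
    abort_config("`prev_aggregate` must be finite and >= 0")
  }
  if (any(!is.finite(prev_ambient)) || any(prev_ambient <= 0)) {
    abort_config("enrichment is undefined for zero ambient prevalence")
  }
  prev_aggregate / prev_ambient
}

#' Bacterial load of a whole aggregate
#'
#' Scales the per-cell census to a whole aggregate: assumed cells per
#' aggregate times the stage-fraction-weighted mean bacteria per cell,
#' sum over stages of fraction_stage * mean_bacteria_stage.
#'
#' @param census either a per-cell data frame with `stage` and `bacteria`
#'   columns, or a per-stage summary with `stage`, `fraction` and
#'   `mean_bacteria` columns.
#' @param cells_per_aggregate assumed host cells per aggregate,
#'   default 20000.
#' @return expected bacteria per aggregate.
#' @examples
#' bacteria_per_aggregate(tibble::tibble(
#'   stage = c("non", "post"), fraction = c(0.5, 0.5),
#'   mean_bacteria = c(2, 10))) # 120000
#' @export
bacteria_per_aggregate <- function(census, cells_per_aggregate = 20000) {
  check_number(cells_per_aggregate, "cells_per_aggregate",
               function(v) v >= 0, ">= 0")
  if (all(c("fraction", "mean_bacteria") %in% names(census))) {
    if (any(!is.finite(census$mean_bacteria))) {
      abort_config("missing per-stage bacterial means")
    }
    return(cells_per_aggregate * sum(census$fraction * census$mean_bacteria))
  }
  if (!all(c("stage", "bacteria") %in% names(census))) {
    abort_config("`census` must have `stage` + `bacteria` (per cell) or ",
                 "`stage` + `fraction` + `mean_bacteria` (per stage) columns")
  }
  if (any(is.na(census$bacteria))) {
    abort_config("missing bacterial counts in census")
  }
  cells_per_aggregate * mean(census$bacteria)
}

#' Pairwise comparison with the Shapiro/F-test decision tree
#'
#' Normality of each sample is assessed with the Shapiro test; if either
#' sample rejects, the groups are compared with the two-sided Mann-Whitney
#' test. Otherwise variances are compared with the F-test: unequal
#' variances route to the Welch test, equal variances to the Student
#' t-test. Two identical zero-variance samples are degenerate: no p-value
#' is emitted.
#'
#' @param x,y numeric samples, each n >= 3.
#' @param alpha significance level driving the routing decisions,
#'   default 0.05 (tests are two-sided).
#' @return one-row tibble of class `agg_comparison`: `test`
#'   (t/welch/mann_whitney/degenerate), `statistic`, `p`, `shapiro_p_x`,
#'   `shapiro_p_y`, `var_p`, `n_x`, `n_y`.
#' @export
pairwise_compare <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3) {
    abort_config("each sample must have n >= 3")
  }
  check_number(alpha, "alpha", function(v) v > 0 && v < 1, "in (0,1)")
  if (sd(x) == 0 && sd(y) == 0 && x[1] == y[1]) {
    rlang::warn(
      "pairwise_compare: degenerate (identical zero-variance samples); no p-value")
    return(structure(
      tibble(test = "degenerate", statistic = NA_real_, p = NA_real_,
             shapiro_p_x = NA_real_, shapiro_p_y = NA_real_,
             var_p = NA_real_, n_x = length(x), n_y = length(y)),
      class = c("agg_comparison", class(tibble()))))
  }
  shapiro_p <- function(v) {
    if (sd(v) == 0) return(0) # constant sample: clearly non-normal
    shapiro.test(v)$p.value
  }
  sx <- shapiro_p(x); sy <- shapiro_p(y)
  ht <- tryCatch({
    if (sx < alpha || sy < alpha) {
      test <- "mann_whitney"; vp <- NA_real_
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    } else {
      vp <- var.test(x, y)$p.value
      if (vp < alpha) {
        test <- "welch"
        t.test(x, y, var.equal = FALSE)
      } else {
        test <- "t"
        t.test(x, y, var.equal = TRUE)
      }
    }
  }, error = function(e) NULL)
  if (is.null(ht)) {
    rlang::warn(paste0("pairwise_compare: degenerate samples (",
                       "no test statistic available); no p-value"))
    return(structure(
      tibble(test = "degenerate", statistic = NA_real_, p = NA_real_,
             shapiro_p_x = sx, shapiro_p_y = sy, var_p = NA_real_,
             n_x = length(x), n_y = length(y)),
      class = c("agg_comparison", class(tibble()))))
  }
  structure(
    tibble(test = test, statistic = unname(ht$statistic), p = ht$p.value,
           shapiro_p_x = sx, shapiro_p_y = sy, var_p = vp,
           n_x = length(x), n_y = length(y)),
    class = c("agg_comparison", class(tibble())))
}

# Compact letter display, insert-and-absorb: start from one letter spanning
# all groups; for each significantly different pair split every letter
# containing both; absorb letters that became subsets. Letters are assigned
# in group-mean order.
compact_letters <- function(group_names, group_means, sig_pairs) {
  ord <- order(group_means)
  groups <- group_names[ord]
  sets <- list(groups)
  for (r in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$group1[r]; g2 <- sig_pairs$group2[r]
    new_sets <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets and empties
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      if (length(new_sets[[i]]) == 0) { keep[i] <- FALSE; next }
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            length(new_sets[[i]]) < length(new_sets[[j]])) {
          keep[i] <- FALSE; break
        }
      }
    }
    sets <- unique(new_sets[keep])
  }
  # order letters by the lowest-mean group they contain
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  lett <- setNames(rep("", length(group_names)), group_names)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) lett[g] <- paste0(lett[g], letters[i])
  }
  lett[group_names]
}

#' Multi-group comparison: Kruskal-Wallis with Bonferroni post hoc
#'
#' Omnibus Kruskal-Wallis test across three or more groups, followed by
#' pairwise Mann-Whitney tests with Bonferroni correction
#' (p_adj = min(1, m p)) and a compact-letter display: groups sharing a
#' letter are not significantly different.
#'
#' @param data data frame with the value and group columns.
#' @param value,group column names (unquoted); defaults `value`, `group`.
#' @param alpha significance level, default 0.05.
#' @return list of class `agg_multicomp`: `omnibus` (tibble: statistic, df,
#'   p), `pairwise` (tibble of adjusted p-values), `groups` (tibble: group,
#'   n, mean, letter).
#' @export
multi_group_compare <- function(data, value = value, group = group,
                                alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  check_number(alpha, "alpha", function(v_) v_ > 0 && v_ < 1, "in (0,1)")
  tab <- table(g)
  if (length(tab) < 3) {
    abort_config("multi_group_compare requires at least 3 groups")
  }
  if (any(tab < 3)) {
    abort_config("every group must have n >= 3 (violated by: ",
                 paste(names(tab)[tab < 3], collapse = ", "), ")")
  }
  kw <- kruskal.test(v, factor(g))
  gnames <- names(tab)
  pairs <- utils::combn(gnames, 2)
  m <- ncol(pairs)
  raw_p <- numeric(m)
  for (i in seq_len(m)) {
    raw_p[i] <- suppressWarnings(
      wilcox.test(v[g == pairs[1, i]], v[g == pairs[2, i]])$p.value)
  }
  adj_p <- pmin(1, m * raw_p) # Bonferroni
  pairwise <- tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                     p_raw = raw_p, p_adj = adj_p,
                     significant = adj_p < alpha)
  means <- tapply(v, g, mean)[gnames]
  lett <- compact_letters(gnames, means,
                          pairwise[pairwise$significant, , drop = FALSE])
  structure(list(
    omnibus = tibble(statistic = unname(kw$statistic),
                     df = unname(kw$parameter), p = kw$p.value),
    pairwise = pairwise,
    groups = tibble(group = gnames, n = as.integer(tab[gnames]),
                    mean = as.numeric(means), letter = unname(lett))
  ), class = "agg_multicomp")
}

#' @export
print.agg_multicomp <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p))
  print(x$groups)
  invisible(x)
}

#' First-order Gaussian error propagation
#'
#' Propagates standard deviations through elementary expressions: absolute
#' sds add in quadrature for sums and differences; relative sds add in
#' quadrature for products and quotients; a power multiplies the relative
#' sd by |k|.
#'
#' @param values numeric vector of the combined quantities (a single value
#'   for `"power"`).
#' @param sds standard deviations of `values`, all >= 0.
#' @param expression one of `"sum"`, `"difference"`, `"product"`,
#'   `"quotient"`, `"power"`.
#' @param k exponent for `"power"`.
#' @return one-row tibble with `value` and `sd` of the result.
#' @examples
#' propagate_uncertainty(c(10, 20), c(3, 4), "sum")        # sd 5
#' propagate_uncertainty(c(10, 20), c(0.3, 0.8), "product") # rel sd 5%
#' @export
propagate_uncertainty <- function(values, sds,
                                  expression = c("sum", "difference",
                                                 "product", "quotient",
                                                 "power"),
                                  k = NULL) {
  expression <- match.arg(expression)
  if (length(values) != length(sds)) {
    abort_config("`values` and `sds` must have the same length")
  }
  if (any(!is.finite(sds)) || any(sds < 0)) {
    abort_config("`sds` must be finite and >= 0")
  }
  if (expression %in% c("sum", "difference")) {
    val <- if (expression == "sum") sum(values) else
      values[1] - sum(values[-1])
    return(tibble(value = val, sd = sqrt(sum(sds^2))))
  }
  if (expression == "power") {
    if (length(values) != 1) {
      abort_config("`power` takes a single value")
    }
    check_number(k, "k")
    if (values[1] == 0) abort_config("relative sd undefined at value 0")
    val <- values[1]^k
    rel <- abs(k) * sds[1] / abs(values[1])
    return(tibble(value = val, sd = abs(val) * rel))
  }
  if (any(values == 0)) {
    abort_config("relative sds undefined: zero value in product/quotient ",
                 "(division by zero)")
  }
  val <- if (expression == "product") prod(values) else
    values[1] / prod(values[-1])
  rel <- sqrt(sum((sds / values)^2))
  tibble(value = val, sd = abs(val) * rel)
}
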