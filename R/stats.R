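#' Statistical configuration for group comparisons
#'
#' Regional cell counts are modeled as negative-binomial with a log link and
#' a log-volume offset; groups are compared on the group coefficient (log
#' fold change of density). The assumed effect size for power calculations
#' (default 0.85) is interpreted on that same log scale — a detectable log
#' fold change of 0.85, i.e. a rate ratio of about 2.3 — which is the
#' interpretation under which five subjects per group give most regions at
#' least 80% power.
#'
#' @param alpha significance level, default 0.05.
#' @param effect_size assumed effect size for power analysis (log fold
#'   change), default 0.85.
#' @param fdr_threshold BH false-discovery threshold, default 0.05.
#' @param test `"quasi"` (Wald t with quasi-likelihood dispersion; default,
#'   chosen for small-sample type-I control), `"wald"` (NB Wald z) or
#'   `"lrt"` (NB likelihood ratio).
#' @param seed integer seed for Monte-Carlo power simulations.
#' @return object of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, effect_size = 0.85,
                         fdr_threshold = 0.05,
                         test = c("quasi", "wald", "lrt"), seed = 1L) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (effect_size <= 0) stop("effect_size must be > 0", call. = FALSE)
  structure(list(alpha = alpha, effect_size = effect_size,
                 fdr_threshold = fdr_threshold, test = test,
                 seed = as.integer(seed)),
            class = "stats_config")
}

# moment estimate of the NB size parameter from two groups (pooled), floored
# at 1e-8 distance from the Poisson limit (returned as Inf when var <= mean)
theta_moment <- function(a, b) {
  mu <- c(mean(a), mean(b))
  vv <- c(stats::var(a), stats::var(b))
  num <- sum(c(length(a), length(b)) * mu^2)
  excess <- sum(c(length(a), length(b)) * pmax(vv - mu, 0))
  if (excess <= 0) return(Inf)
  max(num / excess, 1e-8)
}

#' Compare regional counts between two groups under an NB count model
#'
#' Fits `count ~ group + offset(log volume)` and tests the group
#' coefficient. The default `"quasi"` test estimates the overdispersion by
#' quasi-likelihood (Pearson) and refers the Wald statistic to a t
#' distribution with `n - 2` degrees of freedom; `"wald"` and `"lrt"` use a
#' maximum-likelihood NB fit. Regions with all-zero counts in both groups
#' are degenerate: flagged, `p = 1` by convention.
#'
#' @param counts_a,counts_b nonnegative integer counts, one per subject
#'   (>= 2 per group).
#' @param offsets_a,offsets_b region volumes (mm^3) per subject entering as
#'   `log` offsets; default 1 (pure count comparison).
#' @param config a [stats_config()].
#' @return one-row tibble (class `nb_test`): group mean densities, log fold
#'   change estimate, dispersion estimate (NB size), statistic, p-value,
#'   degenerate flag.
#' @export
nb_group_test <- function(counts_a, counts_b, offsets_a = NULL,
                          offsets_b = NULL, config = stats_config()) {
  if (length(counts_a) < 2 || length(counts_b) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (any(c(counts_a, counts_b) < 0) ||
      any(c(counts_a, counts_b) %% 1 != 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (is.null(offsets_a)) offsets_a <- rep(1, length(counts_a))
  if (is.null(offsets_b)) offsets_b <- rep(1, length(counts_b))
  y <- c(counts_a, counts_b)
  g <- rep(c(0, 1), c(length(counts_a), length(counts_b)))
  lo <- log(c(offsets_a, offsets_b))
  mean_a <- mean(counts_a / offsets_a)
  mean_b <- mean(counts_b / offsets_b)
  theta <- theta_moment(counts_a, counts_b)
  res <- tibble::tibble(
    mean_a = mean_a, mean_b = mean_b,
    log_fc = NA_real_, dispersion = theta,
    statistic = NA_real_, se = NA_real_, phi = NA_real_, df = NA_real_,
    p_value = NA_real_, test = config$test, degenerate = FALSE)
  if (all(y == 0)) {
    res$degenerate <- TRUE
    res$p_value <- 1
    res$log_fc <- 0
    class(res) <- c("nb_test", class(res))
    return(res)
  }
  if (config$test == "quasi") {
    fit <- suppressWarnings(
      stats::glm(y ~ g + offset(lo), family = stats::quasipoisson()))
    smm <- summary(fit)
    sm <- smm$coefficients
    res$log_fc <- sm[2, 1]
    res$statistic <- sm[2, 3]
    res$se <- sm[2, 2]
    res$phi <- smm$dispersion
    res$df <- length(y) - 2
    res$p_value <- 2 * stats::pt(-abs(sm[2, 3]), df = length(y) - 2)
  } else {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ g + offset(lo))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # Poisson-limit fallback when the NB fit cannot converge
      fit <- suppressWarnings(
        stats::glm(y ~ g + offset(lo), family = stats::poisson()))
      th <- Inf
    } else th <- fit$theta
    res$dispersion <- th
    sm <- summary(fit)$coefficients
    res$log_fc <- sm[2, 1]
    if (config$test == "wald") {
      res$statistic <- sm[2, 3]
      res$p_value <- 2 * stats::pnorm(-abs(sm[2, 3]))
    } else {
      fam <- if (is.infinite(th)) stats::poisson()
             else MASS::negative.binomial(th)
      f1 <- suppressWarnings(stats::glm(y ~ g + offset(lo), family = fam))
      f0 <- suppressWarnings(stats::glm(y ~ 1 + offset(lo), family = fam))
      lr <- max(0, 2 * as.numeric(stats::logLik(f1) - stats::logLik(f0)))
      res$statistic <- lr
      res$p_value <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    }
  }
  res$p_value <- min(max(res$p_value, 0), 1)
  class(res) <- c("nb_test", class(res))
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values across a family of regional tests. NaN p-values are
#' rejected rather than silently dropped.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)))
    stop("NaN/NA p-values are not allowed", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Compare groups across many regions with FDR control
#'
#' Runs [nb_group_test()] per region from a tidy per-subject table and
#' adjusts p-values with [bh_adjust()]. Degenerate all-zero regions are
#' excluded from the FDR family (their untestable hypotheses would dilute
#' the correction) and reported with `q_value = NA`.
#'
#' With the default `"quasi"` test and `moderate = TRUE`, per-region
#' quasi-likelihood dispersions are shrunk toward a common value by empirical
#' Bayes (limma's `squeezeVar`) before the Wald t statistics are formed, and
#' the degrees of freedom gain the prior df — the standard remedy for the
#' power loss of per-region dispersion estimation with few subjects per
#' group.
#'
#' @param stats tidy tibble with columns `region_id`, `group`, `n3d` (or
#'   `count`), `volume_mm3` (optional offset), one row per subject x region.
#' @param config a [stats_config()].
#' @param count_col column used as the count (rounded to integer), default
#'   `"n3d"`.
#' @param moderate share dispersion information across regions (default
#'   TRUE; only applies to the `"quasi"` test with >= 5 testable regions).
#' @return tibble of class `region_comparison`: one row per region with
#'   group means, log fold change, dispersion, p, q and `significant`.
#' @export
compare_groups <- function(stats, config = stats_config(),
                           count_col = "n3d", moderate = TRUE) {
  groups <- sort(unique(stats$group))
  if (length(groups) != 2)
    stop("`stats$group` must have exactly 2 levels", call. = FALSE)
  use_offset <- "volume_mm3" %in% names(stats)
  res <- lapply(split(stats, stats$region_id), function(df) {
    a <- df[df$group == groups[1], , drop = FALSE]
    b <- df[df$group == groups[2], , drop = FALSE]
    r <- nb_group_test(
      round(a[[count_col]]), round(b[[count_col]]),
      offsets_a = if (use_offset) a$volume_mm3,
      offsets_b = if (use_offset) b$volume_mm3,
      config = config)
    r$region_id <- df$region_id[1]
    r
  })
  out <- dplyr::bind_rows(res)
  out <- out[, c("region_id", setdiff(names(out), "region_id"))]
  ok <- !out$degenerate & is.finite(out$phi) & is.finite(out$se) &
    out$phi > 0 & out$se > 0
  if (moderate && config$test == "quasi" && sum(ok) >= 5) {
    sq <- limma::squeezeVar(out$phi[ok], df = out$df[ok])
    scale <- sqrt(sq$var.post / out$phi[ok])
    t_mod <- out$log_fc[ok] / (out$se[ok] * scale)
    df_tot <- out$df[ok] + sq$df.prior
    out$statistic[ok] <- t_mod
    out$p_value[ok] <- 2 * stats::pt(-abs(t_mod), df = df_tot)
    out$phi[ok] <- sq$var.post
    out$df[ok] <- df_tot
  }
  out$q_value <- NA_real_
  testable <- !out$degenerate
  out$q_value[testable] <- bh_adjust(out$p_value[testable])
  out$significant <- !is.na(out$q_value) &
    out$q_value < config$fdr_threshold
  class(out) <- c("region_comparison", class(out))
  out
}

#' Fraction of regions with adequate power
#'
#' Monte-Carlo power per region at the configured significance level and
#' assumed effect size (log fold change): group A at the region's mean,
#' group B at `mean x exp(effect_size)`, both NB with the region's
#' dispersion.
#'
#' @param means expected counts per region (group A).
#' @param dispersions NB size per region (recycled).
#' @param n_per_group subjects per group (>= 2).
#' @param config a [stats_config()].
#' @param n_sim simulation replicates per region, default 200.
#' @param power_threshold target power, default 0.8.
#' @return list: `power` (per-region), `fraction_sufficient` (share of
#'   regions with power >= `power_threshold`).
#' @export
power_regions <- function(means, dispersions, n_per_group = 5,
                          config = stats_config(), n_sim = 200,
                          power_threshold = 0.8) {
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  dispersions <- rep_len(dispersions, length(means))
  rnb <- function(n, mu, th) {
    if (is.infinite(th)) stats::rpois(n, mu) else stats::rnbinom(n, size = th, mu = mu)
  }
  power <- local_seed(config$seed, vapply(seq_along(means), function(i) {
    mu <- means[i]; th <- dispersions[i]
    mu_b <- mu * exp(config$effect_size)
    rej <- vapply(seq_len(n_sim), function(s) {
      a <- rnb(n_per_group, mu, th)
      b <- rnb(n_per_group, mu_b, th)
      nb_group_test(a, b, config = config)$p_value < config$alpha
    }, logical(1))
    mean(rej)
  }, numeric(1)))
  list(power = power,
       fraction_sufficient = mean(power >= power_threshold))
}

#' Colocalization percentage
#'
#' Double-positive cells over total marker-positive cells, as a percentage
#' rounded to `decimals` (e.g. 321 double-positive of 383 total gives 83.8
#' at one decimal).
#'
#' @param n_double number of double-positive cells (0 <= n_double <= n_total).
#' @param n_total total marker-positive cells (> 0).
#' @param decimals decimal places, default 1.
#' @return percentage.
#' @export
colocalization_percent <- function(n_double, n_total, decimals = 1) {
  if (any(n_total <= 0))
    stop("percentage undefined for n_total = 0", call. = FALSE)
  if (any(n_double < 0) || any(n_double > n_total))
    stop("need 0 <= n_double <= n_total", call. = FALSE)
  round(100 * n_double / n_total, decimals)
}

#' Puncta-count positivity rule
#'
#' A cell is called reporter-positive from its in-situ puncta count. The
#' comparator is configurable because both conventions ("more than" and "at
#' least" the threshold) occur in practice; the default is `>=` 4.
#'
#' @param puncta nonnegative integer puncta counts.
#' @param threshold default 4.
#' @param comparator `">="` (default) or `">"`.
#' @return logical vector.
#' @export
puncta_positive <- function(puncta, threshold = 4, comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  if (any(puncta < 0)) stop("puncta counts must be >= 0", call. = FALSE)
  if (comparator == ">=") puncta >= threshold else puncta > threshold
}

#' Dendritic spine density comparison
#'
#' Per-segment spine density is `10 x spines / length_um` (spines per 10 um
#' of dendrite); groups are compared with a two-tailed two-sample pooled
#' -variance (equal variance) Student's t-test.
#'
#' @param spines_a,spines_b spine counts per dendritic segment.
#' @param lengths_a,lengths_b segment lengths in um (> 0).
#' @return list: per-group densities, group means, `t`, `df`, `p_value`.
#' @export
spine_density_test <- function(spines_a, lengths_a, spines_b, lengths_b) {
  if (length(spines_a) < 2 || length(spines_b) < 2)
    stop("need at least 2 segments per group", call. = FALSE)
  if (any(c(lengths_a, lengths_b) <= 0))
    stop("segment lengths must be > 0", call. = FALSE)
  da <- 10 * spines_a / lengths_a
  db <- 10 * spines_b / lengths_b
  tt <- stats::t.test(da, db, var.equal = TRUE)
  list(density_a = da, density_b = db,
       mean_a = mean(da), mean_b = mean(db),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
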