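#' Shapiro-Wilk normality check
#'
#' Thin, validated front end to the Shapiro-Wilk test used to screen each
#' parameter before parametric inference (samples are treated as normal when
#' p > 0.05).
#'
#' @param values numeric sample with 3 <= n <= 5000.
#' @return The Shapiro-Wilk p-value.
#' @export
check_normality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(values) == 0) stop("zero-variance sample: normality undefined")
  stats::shapiro.test(values)$p.value
}

pivot_rm <- function(dataset, parameter, compartment) {
  d <- dataset[dataset$parameter == parameter &
                 dataset$compartment == compartment, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no records for ", parameter, " / ", compartment)
  if (any(!is.finite(d$value))) stop("non-finite values in dataset")
  animals <- sort(unique(d$animal))
  weeks <- sort(unique(d$week))
  limbs <- c("MIA", "control")
  if (!all(d$limb %in% limbs)) stop("limb labels must be 'MIA' or 'control'")
  arr <- array(NA_real_, dim = c(length(animals), 2L, length(weeks)),
               dimnames = list(animals, limbs, weeks))
  idx <- cbind(match(d$animal, animals), match(d$limb, limbs),
               match(d$week, weeks))
  if (anyDuplicated(idx)) stop("duplicate animal x limb x week records")
  arr[idx] <- d$value
  if (anyNA(arr))
    stop("incomplete design: every animal needs both limbs at every timepoint")
  arr
}

#' Two-way repeated-measures ANOVA (time x limb, both within-subject)
#'
#' Balanced within-subject decomposition computed directly from cell and
#' marginal means. Each effect is tested against its own subject-interaction
#' error term: time against time x subject, limb (group) against limb x
#' subject, and the time-by-group interaction against its three-way
#' residual. Sphericity is not corrected by default; `gg = TRUE` applies the
#' Greenhouse-Geisser epsilon to the time and interaction tests.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param parameter,compartment which parameter cell to analyse.
#' @param gg apply Greenhouse-Geisser correction (default `FALSE`).
#' @return An object of class `rm_anova`: a data.frame with one row per
#'   effect (`time`, `group`, `time_x_group`) and columns `SS`, `df1`, `df2`,
#'   `F`, `p`.
#' @export
rm_anova <- function(dataset, parameter, compartment, gg = FALSE) {
  y <- pivot_rm(dataset, parameter, compartment)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  if (n < 2L) stop("repeated-measures ANOVA needs at least 2 animals")
  if (b < 2L) stop("repeated-measures ANOVA needs at least 2 timepoints")

  M <- mean(y)
  m_i <- apply(y, 1, mean)              # subject
  m_j <- apply(y, 2, mean)              # limb (group)
  m_k <- apply(y, 3, mean)              # time
  m_ij <- apply(y, c(1, 2), mean)
  m_ik <- apply(y, c(1, 3), mean)
  m_jk <- apply(y, c(2, 3), mean)

  ss_subj <- a * b * sum((m_i - M)^2)
  ss_a <- n * b * sum((m_j - M)^2)
  ss_b <- n * a * sum((m_k - M)^2)
  ss_ab <- n * sum((m_jk - outer(m_j, rep(1, b)) -
                      outer(rep(1, a), m_k) + M)^2)
  ss_as <- b * sum((m_ij - outer(m_i, rep(1, a)) -
                      outer(rep(1, n), m_j) + M)^2)
  ss_bs <- a * sum((m_ik - outer(m_i, rep(1, b)) -
                      outer(rep(1, n), m_k) + M)^2)
  ss_tot <- sum((y - M)^2)
  ss_abs <- ss_tot - ss_subj - ss_a - ss_b - ss_ab - ss_as - ss_bs

  eff <- function(ss, df1, ss_err, df2, eps = 1) {
    f <- (ss / df1) / (ss_err / df2)
    data.frame(SS = ss, df1 = df1, df2 = df2, F = f,
               p = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE))
  }
  eps_b <- 1; eps_ab <- 1
  if (gg && b > 2L) {
    eps_b <- gg_epsilon(m_ik)                        # time, averaged over limb
    diffs <- y[, 1, ] - y[, 2, ]                     # limb difference profile
    eps_ab <- gg_epsilon(diffs)
  }
  out <- rbind(
    time = eff(ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b),
    group = eff(ss_a, a - 1, ss_as, (a - 1) * (n - 1)),
    time_x_group = eff(ss_ab, (a - 1) * (b - 1), ss_abs,
                       (a - 1) * (b - 1) * (n - 1), eps_ab))
  out <- cbind(effect = rownames(out), out)
  rownames(out) <- NULL
  attr(out, "parameter") <- parameter
  attr(out, "compartment") <- compartment
  attr(out, "n_animals") <- n
  attr(out, "gg") <- gg
  class(out) <- c("rm_anova", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from an n x b matrix of within-factor scores
gg_epsilon <- function(x) {
  S <- stats::cov(x)
  b <- ncol(S)
  # double-centred covariance
  Sc <- S - outer(rowMeans(S), rep(1, b)) - outer(rep(1, b), colMeans(S)) +
    mean(S)
  eps <- sum(diag(Sc))^2 / ((b - 1) * sum(Sc^2))
  min(1, max(1 / (b - 1), eps))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA: %s, %s compartment (n = %d%s)\n",
              attr(x, "parameter"), attr(x, "compartment"),
              attr(x, "n_animals"),
              if (isTRUE(attr(x, "gg"))) ", Greenhouse-Geisser" else ""))
  df <- as.data.frame(x)
  df$SS <- signif(df$SS, 5); df$F <- signif(df$F, 5)
  df$p <- format.pval(df$p, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Holm stepdown adjustment of p-values
#'
#' Sequentially rejective Bonferroni: sort ascending, multiply the i-th
#' smallest by `m - i + 1`, enforce monotonicity by running maxima, cap at 1,
#' and return in the original order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  o <- order(pvals)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * pvals[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Percent difference between group means
#'
#' `100 * (oa - ctl) / ctl`, the "%d OA-CTL" column of the summary tables.
#'
#' @param oa_mean,ctl_mean group means; `ctl_mean` must be non-zero.
#' @return Percent difference.
#' @export
percent_difference <- function(oa_mean, ctl_mean) {
  if (any(ctl_mean == 0)) stop("control mean of zero: percent difference undefined")
  100 * (oa_mean - ctl_mean) / ctl_mean
}

#' Paired limb comparisons per timepoint
#'
#' Paired Student's t-tests of MIA versus control limb at each timepoint,
#' Holm-adjusted as one family per parameter x compartment. Following the
#' published recipe, the t-tests are gated on the repeated-measures ANOVA:
#' with `gate = "any"` (default) they run when any ANOVA effect is
#' significant at `alpha`; `gate = "interaction"` requires the time-by-group
#' interaction; `gate = "none"` disables gating (useful in simulation
#' studies). Gated-out comparisons carry `NA` p-values.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param parameter,compartment which parameter cell to analyse.
#' @param alpha significance level (default 0.05).
#' @param gate `"any"`, `"interaction"` or `"none"`.
#' @return A data.frame of class `paired_comparisons`: one row per timepoint
#'   with group means and SDs, percent difference, raw and Holm-adjusted
#'   p-values and a significance flag.
#' @export
paired_tests <- function(dataset, parameter, compartment, alpha = 0.05,
                         gate = c("any", "interaction", "none")) {
  gate <- match.arg(gate)
  y <- pivot_rm(dataset, parameter, compartment)
  n <- dim(y)[1]
  if (n < 2L) stop("paired tests need at least 2 animals")
  weeks <- as.numeric(dimnames(y)[[3]])

  gated_out <- FALSE
  anova_res <- NULL
  if (gate != "none") {
    anova_res <- rm_anova(dataset, parameter, compartment)
    sig <- if (gate == "any") any(anova_res$p < alpha)
    else anova_res$p[anova_res$effect == "time_x_group"] < alpha
    gated_out <- !isTRUE(sig)
  }

  rows <- lapply(seq_along(weeks), function(k) {
    mia <- y[, "MIA", k]; ctl <- y[, "control", k]
    p <- if (gated_out) NA_real_ else {
      diffs <- mia - ctl
      if (stats::sd(diffs) == 0) {
        if (all(diffs == 0)) 1 else 0   # degenerate: identical differences
      } else stats::t.test(mia, ctl, paired = TRUE)$p.value
    }
    data.frame(parameter = parameter, compartment = compartment,
               week = weeks[k],
               mia_mean = mean(mia), mia_sd = stats::sd(mia),
               ctl_mean = mean(ctl), ctl_sd = stats::sd(ctl),
               pct_diff = percent_difference(mean(mia), mean(ctl)),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- if (gated_out) NA_real_ else holm_adjust(out$p_raw)
  out$significant <- !is.na(out$p_holm) & out$p_holm < alpha
  attr(out, "anova") <- anova_res
  attr(out, "gated_out") <- gated_out
  class(out) <- c("paired_comparisons", "data.frame")
  out
}

#' Paired within-limb comparisons between timepoints
#'
#' The secondary analysis: for one limb, paired t-tests between every pair of
#' timepoints, Holm-adjusted as one family.
#'
#' @param dataset a `longitudinal_dataset`.
#' @param parameter,compartment which parameter cell to analyse.
#' @param limb `"MIA"` or `"control"`.
#' @param alpha significance level.
#' @return A data.frame with one row per timepoint pair.
#' @export
timepoint_tests <- function(dataset, parameter, compartment,
                            limb = c("MIA", "control"), alpha = 0.05) {
  limb <- match.arg(limb)
  y <- pivot_rm(dataset, parameter, compartment)
  weeks <- as.numeric(dimnames(y)[[3]])
  if (length(weeks) < 2L) stop("need at least 2 timepoints")
  pairs <- utils::combn(seq_along(weeks), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    k1 <- pairs[1, i]; k2 <- pairs[2, i]
    v1 <- y[, limb, k1]; v2 <- y[, limb, k2]
    p <- if (stats::sd(v1 - v2) == 0) {
      if (all(v1 == v2)) 1 else 0
    } else stats::t.test(v2, v1, paired = TRUE)$p.value
    data.frame(parameter = parameter, compartment = compartment, limb = limb,
               week_from = weeks[k1], week_to = weeks[k2],
               mean_from = mean(v1), mean_to = mean(v2), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_raw)
  out$significant <- out$p_holm < alpha
  out
}

#' Build publication-style summary tables for a cohort
#'
#' For every parameter x compartment x timepoint: group means and SDs,
#' percent difference, raw and Holm-adjusted paired-t p-values (gated on the
#' repeated-measures ANOVA), plus an ANOVA summary per parameter x
#' compartment. A rounded view follows the usual table precision (integers
#' for micrometre/cubic-millimetre parameters, one decimal for percentages,
#' Tb.N and percent differences).
#'
#' @param dataset a non-empty `longitudinal_dataset` with >= 2 animals.
#' @param alpha significance level (default 0.05).
#' @param gate ANOVA gate passed to [paired_tests()].
#' @return An object of class `study_tables`: list with `comparisons`,
#'   `anova` and `comparisons_rounded` data.frames.
#' @export
build_tables <- function(dataset, alpha = 0.05,
                         gate = c("any", "interaction", "none")) {
  gate <- match.arg(gate)
  if (!is.data.frame(dataset) || nrow(dataset) == 0L)
    stop("empty dataset")
  if (length(unique(dataset$animal)) < 2L)
    stop("inference refused: need at least 2 animals")
  keys <- unique(as.data.frame(dataset)[, c("parameter", "compartment")])
  keys <- keys[order(keys$parameter, keys$compartment), ]
  comp <- list(); anova <- list()
  for (r in seq_len(nrow(keys))) {
    par <- keys$parameter[r]; cmp <- keys$compartment[r]
    pt <- paired_tests(dataset, par, cmp, alpha = alpha, gate = gate)
    comp[[r]] <- as.data.frame(pt)
    an <- attr(pt, "anova")
    if (is.null(an)) an <- rm_anova(dataset, par, cmp)
    an <- as.data.frame(an)
    an$parameter <- par; an$compartment <- cmp
    anova[[r]] <- an
  }
  comparisons <- do.call(rbind, comp)
  rounded <- comparisons
  len_par <- comparisons$parameter %in% c("BV", "Tb.Th", "Tb.Sp", "Pl.Th")
  for (col in c("mia_mean", "mia_sd", "ctl_mean", "ctl_sd")) {
    rounded[[col]] <- ifelse(len_par, round(comparisons[[col]]),
                             round(comparisons[[col]], 1))
  }
  rounded$pct_diff <- round(comparisons$pct_diff, 1)
  rounded$p_raw <- round(comparisons$p_raw, 3)
  rounded$p_holm <- round(comparisons$p_holm, 3)
  structure(list(comparisons = comparisons,
                 comparisons_rounded = rounded,
                 anova = do.call(rbind, anova),
                 alpha = alpha, gate = gate),
            class = "study_tables")
}

#' @export
print.study_tables <- function(x, ...) {
  cat(sprintf("<study_tables> %d comparisons, alpha = %g, gate = %s\n",
              nrow(x$comparisons), x$alpha, x$gate))
  print(utils::head(x$comparisons_rounded, 12), row.names = FALSE)
  if (nrow(x$comparisons) > 12) cat("...\n")
  invisible(x)
}
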