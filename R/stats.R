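#' Repeated-measures ANOVA for fully within-subject 2^k designs
#'
#' Every factor has two levels and varies within subjects, so each of the
#' `2^k - 1` effects has 1 numerator degree of freedom and reduces to a
#' one-sample t-test on a per-subject contrast score: cells are coded +1/-1
#' (the product of +1 for the first level and -1 for the second, over the
#' factors in the effect), the score is the mean of coded cell values, and
#' `F = n * mean(score)^2 / var(score)` with df `(1, n - 1)`.
#' Zero-variance contrasts are reported with a `degenerate` flag (p = 0 if
#' the mean score is nonzero, else F = 0 and p = 1) rather than erroring.
#'
#' @param tbl Long data frame: one row per subject x cell with a numeric
#'   response and one column per factor. Each subject must have a complete
#'   crossing (cell order is irrelevant; cells are matched by labels).
#' @param dv Name of the response column.
#' @param subject Name of the subject-identifier column.
#' @param factors Character vector of factor column names (each 2 levels).
#' @return An object of class `rm_anova`; its `table` element (also
#'   returned by [tidy()]) has one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p_value`, `mean_contrast` (positive = first factor
#'   level(s) larger), `degenerate`.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(subject = 1:6, a = c("x", "y"), b = c("u", "v"))
#' tbl$value <- rnorm(nrow(tbl)) + (tbl$a == "x")
#' rm_anova_2k(tbl, "value", "subject", c("a", "b"))
rm_anova_2k <- function(tbl, dv = "value", subject = "subject", factors) {
  stopifnot(all(c(dv, subject, factors) %in% names(tbl)))
  subs <- unique(tbl[[subject]])
  n <- length(subs)
  if (n < 2) stop("At least 2 subjects are required.", call. = FALSE)
  lev <- lapply(factors, function(f) {
    l <- sort(unique(as.character(tbl[[f]])))
    if (length(l) != 2) {
      stop("Factor `", f, "` must have exactly 2 levels.", call. = FALSE)
    }
    l
  })
  names(lev) <- factors
  cells <- tidyr::expand_grid(!!!lev)
  n_cells <- nrow(cells)
  # subject x cell response matrix, matched by labels
  key <- function(df) do.call(paste, c(lapply(factors,
                                              function(f) as.character(df[[f]])),
                                       sep = "\r"))
  cell_key <- key(cells)
  y <- matrix(NA_real_, n, n_cells)
  for (i in seq_len(n)) {
    rows <- tbl[tbl[[subject]] == subs[i], ]
    m <- match(cell_key, key(rows))
    if (anyNA(m)) {
      stop("Subject ", subs[i], " is missing cell(s): ",
           paste(gsub("\r", "/", cell_key[is.na(m)]), collapse = ", "),
           call. = FALSE)
    }
    # average duplicate rows per cell (e.g. multiple measurements)
    for (j in seq_len(n_cells)) {
      y[i, j] <- mean(rows[[dv]][key(rows) == cell_key[j]])
    }
  }
  codes <- lapply(factors, function(f) {
    ifelse(as.character(cells[[f]]) == lev[[f]][1], 1, -1)
  })
  names(codes) <- factors
  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map_dfr(effects, function(ef) {
    cc <- Reduce(`*`, codes[ef])
    score <- as.vector(y %*% cc) / n_cells
    mbar <- mean(score)
    v <- stats::var(score)
    if (v < 1e-24) {
      degenerate <- TRUE
      if (abs(mbar) < 1e-12) {
        f_stat <- 0
        p <- 1
      } else {
        f_stat <- Inf
        p <- 0
      }
    } else {
      degenerate <- FALSE
      f_stat <- n * mbar^2 / v
      p <- stats::pf(f_stat, 1, n - 1, lower.tail = FALSE)
    }
    tibble::tibble(effect = paste(ef, collapse = ":"),
                   df1 = 1L, df2 = n - 1L, statistic = f_stat,
                   p_value = p, mean_contrast = 2 * mbar,
                   degenerate = degenerate)
  })
  structure(list(table = rows, n = n, factors = factors, levels = lev,
                 dv = dv),
            class = "rm_anova")
}

#' 2 x 2 repeated-measures ANOVA on MMN peak latency
#'
#' Peak latency is measured once per cell (on the FCz difference wave), so
#' only the two stimulus factors enter: phonotactic probability and
#' syllable stress.
#'
#' @param tbl Long data frame with columns `subject`, `phonprob`, `sylstr`
#'   and the latency response.
#' @param dv Name of the latency column.
#' @return An `rm_anova` object (see [rm_anova_2k()]).
#' @export
rm_anova_latency <- function(tbl, dv = "latency_ms") {
  rm_anova_2k(tbl, dv = dv, subject = "subject",
              factors = c("phonprob", "sylstr"))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA (", paste(x$factors, collapse = " x "),
      "), n = ", x$n, " subjects\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, n_factors = length(x$factors),
                 n_effects = nrow(x$table))
}

#' Holm step-down adjustment of p-values
#'
#' Step-down familywise-error control: p-values are ranked ascending, the
#' i-th smallest is multiplied by `m - i + 1`, capped at 1, and monotonicity
#' is enforced; the family size `m` may exceed the number of supplied
#' p-values when further family members are tested elsewhere.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.04))
holm_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm", n = max(m, length(p)))
}

#' Post-hoc two-sided paired t-tests with Bonferroni correction
#'
#' Compares two paired conditions of a response within each stratum (e.g.
#' the FD - SD amplitude difference between high and low phonotactic
#' probability, within the frontocentral and centroparietal ROIs), and
#' multiplies p-values by the number of strata (capped at 1).
#'
#' @param tbl Long data frame with subject, group and response columns and
#'   an optional stratum column.
#' @param dv,subject,group Column names; `group` must have 2 levels.
#' @param by Optional stratum column name (tests run per stratum).
#' @return A tibble: stratum (if any), `estimate` (mean difference, first
#'   group level minus second), `statistic` (t), `df`, `p_value`,
#'   `p_adjusted`.
#' @export
posthoc_paired_t <- function(tbl, dv = "value", subject = "subject",
                             group, by = NULL) {
  strata <- if (is.null(by)) list(tbl) else split(tbl, tbl[[by]])
  rows <- purrr::imap_dfr(strata, function(d, nm) {
    g <- sort(unique(as.character(d[[group]])))
    if (length(g) != 2) {
      stop("`group` must have exactly 2 levels.", call. = FALSE)
    }
    wide <- tidyr::pivot_wider(d[, c(subject, group, dv)],
                               names_from = dplyr::all_of(group),
                               values_from = dplyr::all_of(dv))
    if (nrow(wide) < 2) stop("Need at least 2 subjects.", call. = FALSE)
    diffs <- wide[[g[1]]] - wide[[g[2]]]
    if (stats::sd(diffs) < 1e-15) {
      tt <- list(statistic = c(t = 0), parameter = c(df = nrow(wide) - 1),
                 p.value = 1)
    } else {
      tt <- stats::t.test(wide[[g[1]]], wide[[g[2]]], paired = TRUE)
    }
    tibble::tibble(stratum = if (is.null(by)) NA_character_ else nm,
                   estimate = mean(diffs),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value)
  })
  dplyr::mutate(rows, p_adjusted = pmin(1, .data$p_value * nrow(rows)))
}

#' A priori hypothesis report with Holm correction
#'
#' Assembles, for one deviant type, the a priori effect family -- amplitude:
#' the condition main effect, the feature x condition interaction
#' (phonotactic probability for formal deviants, syllable stress for
#' temporal ones), and the three-way feature x other-feature x condition
#' interaction; latency: the feature main effect and the phonprob x sylstr
#' interaction -- applies Holm correction within that family, and reports a
#' verdict per hypothesis.
#'
#' @param amplitude An `rm_anova` from the 2x2x2x2 amplitude analysis
#'   (factors `phonprob`, `sylstr`, `cond`, `roi`).
#' @param latency An `rm_anova` from the 2x2 latency analysis.
#' @param deviant_type `"FD"` (formal) or `"TD"` (temporal).
#' @param alpha Familywise significance level.
#' @return A tibble: `hypothesis`, `measure`, `effect`, `statistic`, `df1`,
#'   `df2`, `p_raw`, `p_holm`, `family_size`, `supported`, `direction`.
#' @export
hypothesis_report <- function(amplitude, latency, deviant_type = c("FD", "TD"),
                              alpha = 0.05) {
  deviant_type <- match.arg(deviant_type)
  feature <- if (deviant_type == "FD") "phonprob" else "sylstr"
  amp <- amplitude$table
  lat <- latency$table
  if (nrow(amp) == 0 && nrow(lat) == 0) {
    return(tibble::tibble(hypothesis = character(), measure = character(),
                          effect = character(), statistic = numeric(),
                          df1 = integer(), df2 = integer(),
                          p_raw = numeric(), p_holm = numeric(),
                          family_size = integer(), supported = logical(),
                          direction = character()))
  }
  pick <- function(tab, factors_in_effect) {
    hit <- vapply(tab$effect, function(e) {
      setequal(strsplit(e, ":")[[1]], factors_in_effect)
    }, logical(1))
    tab[hit, ]
  }
  fam <- dplyr::bind_rows(
    dplyr::mutate(pick(amp, "cond"), hypothesis = "H1: MMN elicited",
                  measure = "amplitude"),
    dplyr::mutate(pick(amp, c(feature, "cond")),
                  hypothesis = "H2: feature modulates MMN amplitude",
                  measure = "amplitude"),
    dplyr::mutate(pick(amp, c("phonprob", "sylstr", "cond")),
                  hypothesis = "H3: cross-feature modulation (amplitude)",
                  measure = "amplitude"),
    dplyr::mutate(pick(lat, feature),
                  hypothesis = "H2: feature modulates MMN latency",
                  measure = "latency"),
    dplyr::mutate(pick(lat, c("phonprob", "sylstr")),
                  hypothesis = "H3: cross-feature modulation (latency)",
                  measure = "latency")
  )
  fam$p_holm <- holm_adjust(fam$p_value, m = nrow(fam))
  direction <- character(nrow(fam))
  for (i in seq_len(nrow(fam))) {
    mc <- fam$mean_contrast[i]
    direction[i] <- if (fam$measure[i] == "latency" &&
                        fam$effect[i] == feature) {
      lv <- if (feature == "phonprob") c("HPP", "LPP")
            else c("SylStr1", "SylStr2")
      if (mc < 0) paste0(lv[1], " earlier") else paste0(lv[2], " earlier")
    } else if (fam$effect[i] == "cond") {
      # cond coded +1 for "Deviant" (alphabetically first)
      if (mc < 0) "deviant more negative" else "standard more negative"
    } else {
      sprintf("contrast %+0.3g", mc)
    }
  }
  tibble::tibble(
    hypothesis = fam$hypothesis, measure = fam$measure,
    effect = fam$effect, statistic = fam$statistic,
    df1 = fam$df1, df2 = fam$df2, p_raw = fam$p_value,
    p_holm = fam$p_holm, family_size = nrow(fam),
    supported = fam$p_holm < alpha, direction = direction)
}

#' Type-I error calibration of the repeated-measures ANOVA
#'
#' Simulates null cell-mean tables (independent standard-normal cell values
#' per subject) and reports, per effect, the fraction of replicates whose
#' raw p-value falls below `alpha`. With a calibrated test this rate
#' matches `alpha` up to Monte-Carlo error.
#'
#' @param factors Named list of 2-level factor levels, e.g.
#'   `list(a = c("1","2"), b = c("1","2"))`; only the number of factors
#'   matters under the null.
#' @param n_subjects Subjects per replicate.
#' @param n_reps Number of replicates.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return A tibble: `effect`, `rejections`, `n_reps`, `rate`.
#' @export
type1_calibration <- function(factors = list(phonprob = c("HPP", "LPP"),
                                             sylstr = c("SylStr1", "SylStr2"),
                                             cond = c("Deviant", "Standard"),
                                             roi = c("FC", "CP")),
                              n_subjects = 24, n_reps = 1000,
                              alpha = 0.05, seed = 1L) {
  k <- length(factors)
  n_cells <- 2^k
  cells <- tidyr::expand_grid(!!!lapply(factors, identity))
  codes <- lapply(names(factors), function(f) {
    ifelse(as.character(cells[[f]]) == sort(factors[[f]])[1], 1, -1)
  })
  effects <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(names(factors), m, simplify = FALSE)
  }), recursive = FALSE)
  cmat <- vapply(effects, function(ef) {
    Reduce(`*`, codes[match(ef, names(factors))])
  }, numeric(n_cells))
  crit <- stats::qf(1 - alpha, 1, n_subjects - 1)
  rej <- numeric(length(effects))
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      y <- matrix(stats::rnorm(n_subjects * n_cells), n_subjects, n_cells)
      s <- y %*% cmat / n_cells
      f_stat <- n_subjects * colMeans(s)^2 / apply(s, 2, stats::var)
      rej <- rej + (f_stat > crit)
    }
  })
  tibble::tibble(
    effect = vapply(effects, paste, "", collapse = ":"),
    rejections = as.integer(rej), n_reps = n_reps, rate = rej / n_reps)
}
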