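# Statistical surface: within-subject error bars, balanced split-plot
# repeated-measures ANOVA, and the post-hoc t tests.
#
# The designs here are fully balanced by construction (one value per
# subject x time x task cell), so the classical sums-of-squares
# decomposition is exact; unbalanced input is an error, never approximated.
# No sphericity correction is applied by default -- the reported F tests use
# uncorrected degrees of freedom -- and post-hoc t tests carry no
# multiple-testing correction; both choices match how such designs are
# conventionally reported and should be kept in mind when interpreting
# borderline p values.

#' Within-subject (Cousineau-Morey) means and standard errors
#'
#' Removes each subject's mean from their scores, adds back the grand mean,
#' takes the per-condition SEM of the normalized scores, and applies the
#' Morey bias correction `sqrt(M / (M - 1))` for `M` conditions. The result
#' reflects only within-subject variability, which is what matters when
#' comparing repeated-measures condition means.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns
#'   (complete; >= 2 subjects and >= 2 conditions).
#' @return Data frame: `condition`, `mean`, `within_subject_sem`.
#' @examples
#' m <- rbind(c(10, 12), c(20, 22))
#' cousineau_morey(m)  # SEMs are 0: subject offsets are purely additive
#' @export
cousineau_morey <- function(m) {
  m <- as.matrix(m)
  if (any(is.na(m))) stop_invalid("matrix must be complete (no missing cells)")
  n <- nrow(m); M <- ncol(m)
  if (n < 2L) stop_invalid("need at least 2 subjects")
  if (M < 2L) stop_invalid("need at least 2 conditions (Morey correction undefined for M = 1)")
  norm <- m - rowMeans(m) + mean(m)
  sems <- apply(norm, 2, sd) / sqrt(n) * sqrt(M / (M - 1))
  data.frame(
    condition = colnames(m) %||% paste0("C", seq_len(M)),
    mean = colMeans(m),
    within_subject_sem = as.numeric(sems),
    row.names = NULL
  )
}

check_balanced <- function(data, subject, factors) {
  cells <- interaction(data[factors], drop = FALSE)
  tab <- table(data[[subject]], cells)
  if (any(tab != 1L)) {
    stop_invalid("design must be balanced and complete: exactly one value ",
                 "per subject per within-cell")
  }
  invisible(TRUE)
}

# ANOVA table for data with zero variance: every sum of squares is exactly
# zero, reported as F = 0, p = 1 with the design's degrees of freedom.
constant_anova_table <- function(data, subject, within, between) {
  lv <- vapply(within, function(f) nlevels(factor(data[[f]])), integer(1))
  names(lv) <- within
  g <- if (!is.null(between)) nlevels(factor(data[[between]])) else 1L
  n_subjects <- length(unique(data[[subject]]))
  df_sw <- n_subjects - g
  rows <- list()
  add <- function(effect, df_num, df_den) {
    rows[[length(rows) + 1L]] <<- data.frame(effect = effect, df_num = df_num,
                                             df_den = df_den, F = 0, p = 1)
  }
  if (!is.null(between)) add(between, g - 1L, df_sw)
  subsets <- list()
  for (k in seq_along(within)) {
    subsets <- c(subsets, utils::combn(within, k, simplify = FALSE))
  }
  # order subsets the way aov orders Error strata (singletons first)
  subsets <- subsets[order(lengths(subsets))]
  for (s in subsets) {
    df_eff <- prod(lv[s] - 1L)
    df_err <- df_sw * df_eff
    add(paste(s, collapse = " x "), df_eff, df_err)
    if (!is.null(between)) {
      add(paste(c(between, s), collapse = " x "), (g - 1L) * df_eff, df_err)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Balanced split-plot repeated-measures ANOVA
#'
#' Classical sums-of-squares decomposition for designs with one
#' between-subject factor (e.g. Group) and one or two within-subject factors
#' (e.g. Time, Task), subjects nested in the between factor. The between
#' effect is tested against subjects-within-group; each within effect and
#' its interactions with the between factor are tested against the matching
#' effect-by-subject-within-group error stratum. Fitted via [stats::aov()]
#' with `Error()` strata, which is exact for balanced data; unbalanced or
#' incomplete data are rejected.
#'
#' @param data Long data frame with one value per subject x within-cell.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector of within-subject factor names (1 or more).
#' @param between Name of the between-subject factor, or `NULL` for a fully
#'   within design.
#' @return Data frame of class `rm_anova`: `effect`, `df_num`, `df_den`,
#'   `F`, `p`. Effects with zero numerator and error mean squares (all
#'   values identical) are reported as `F = 0`, `p = 1`.
#' @examples
#' d <- expand.grid(subject = factor(1:6), task = factor(2:4))
#' d$group <- factor(ifelse(as.integer(d$subject) <= 3, "trained", "control"))
#' set.seed(1); d$value <- rnorm(nrow(d))
#' mixed_rm_anova(d, dv = "value", within = "task", between = "group")
#' @export
mixed_rm_anova <- function(data, dv = "value", subject = "subject",
                           within, between = NULL) {
  need <- c(dv, subject, within, between)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_invalid("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(is.na(data[[dv]]))) stop_invalid("missing values are not allowed")
  data <- as.data.frame(data)
  data[[subject]] <- factor(data[[subject]])
  for (f in c(within, between)) data[[f]] <- factor(data[[f]])
  check_balanced(data, subject, within)
  if (!is.null(between)) {
    # each subject must sit in exactly one between-group
    gmap <- table(data[[subject]], data[[between]])
    if (any(rowSums(gmap > 0) != 1L)) {
      stop_invalid("each subject must belong to exactly one `between` group")
    }
    if (length(unique(colSums(gmap > 0))) != 1L) {
      stop_invalid("groups must have equal numbers of subjects")
    }
    if (any(colSums(gmap > 0) < 2)) stop_invalid("need >= 2 subjects per group")
  }

  if (stats::var(data[[dv]]) == 0) {
    # all values identical: every SS is exactly zero by definition
    return(constant_anova_table(data, subject, within, between))
  }

  rhs <- paste(c(between, within), collapse = " * ")
  err <- sprintf("Error(%s/(%s))", subject, paste(within, collapse = " * "))
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = data)

  rows <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid_i <- which(terms == "Residuals")
    if (!length(resid_i)) next
    df_err <- tab$Df[resid_i]
    ms_err <- tab$`Mean Sq`[resid_i]
    for (i in setdiff(seq_along(terms), resid_i)) {
      ms_eff <- tab$`Mean Sq`[i]
      if (!is.finite(ms_err) || ms_err == 0) {
        if (is.finite(ms_eff) && ms_eff > 0) { Fv <- Inf; p <- 0 }
        else { Fv <- 0; p <- 1 }
      } else {
        Fv <- ms_eff / ms_err
        p <- stats::pf(Fv, tab$Df[i], df_err, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", terms[i]),
        df_num = as.integer(tab$Df[i]), df_den = as.integer(df_err),
        F = Fv, p = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat("Repeated-measures ANOVA (balanced split-plot)\n")
  df <- as.data.frame(x)
  df$F <- signif(df$F, digits)
  df$p <- format.pval(df$p, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Paired t test (two-sided)
#'
#' Classical paired t on the per-subject differences, computed in closed
#' form so degenerate inputs (zero-variance differences, as arise when a
#' simulated effect is injected without noise) are handled explicitly
#' rather than rejected.
#'
#' @param x,y Paired per-subject values of equal length (>= 2).
#' @return List: `t`, `df` (= n - 1), `p`. A zero-variance difference with
#'   nonzero mean yields infinite `t` and `p = 0`, with a warning.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop_invalid("`x` and `y` must be paired vectors of equal length >= 2")
  }
  d <- x - y
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, df = n - 1L, p = 1))
    warning("zero variance of paired differences; reporting infinite t, p = 0")
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0))
  }
  t_val <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_val, df = n - 1L, p = 2 * stats::pt(-abs(t_val), n - 1L))
}

#' Pooled-variance two-sample t test (two-sided)
#'
#' @param a,b Group value vectors (each >= 2 values).
#' @return List: `t`, `df` (= n_a + n_b - 2), `p`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop_invalid("each group needs at least 2 values")
  }
  na <- length(a); nb <- length(b)
  df <- na + nb - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    warning("zero variance in both groups; reporting infinite t, p = 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  t_val <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_val, df = df, p = 2 * stats::pt(-abs(t_val), df))
}

#' Per-subject Task 4 - Task 2 difference scores
#'
#' The Task 4 and Task 2 conditions share identical response demands (both
#' require a central and a peripheral response), differing only in
#' target-like distractors, so their pupil difference isolates the
#' selective-attention load. Because Task 2 is the normalization reference
#' (exactly 0), the difference equals the Task 4 percent change -- asserted
#' here, not assumed.
#'
#' @param summary_rows Long data frame with `subject`, `time` (or any phase
#'   column named by `phase_col`), `task_level`, `pct_change_from_task2`.
#' @param phase_col Name of the phase column (default `"time"`).
#' @return Data frame: one row per subject x phase with `difference_pct`.
#' @export
difference_score <- function(summary_rows, phase_col = "time") {
  need <- c("subject", phase_col, "task_level", "pct_change_from_task2")
  missing_cols <- setdiff(need, names(summary_rows))
  if (length(missing_cols)) {
    stop_invalid("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  keys <- unique(summary_rows[c("subject", phase_col)])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- summary_rows$subject == keys$subject[i] &
      summary_rows[[phase_col]] == keys[[phase_col]][i]
    rows <- summary_rows[sel, ]
    v4 <- rows$pct_change_from_task2[rows$task_level == 4L]
    v2 <- rows$pct_change_from_task2[rows$task_level == 2L]
    if (length(v4) != 1L || length(v2) != 1L) {
      stop_invalid("both Task 2 and Task 4 must be present for subject ",
                   keys$subject[i])
    }
    stopifnot(isTRUE(all.equal(v2, 0)))   # normalization identity
    cbind(keys[i, , drop = FALSE], difference_pct = v4 - v2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
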