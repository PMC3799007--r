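# Brute-force split-plot ANOVA oracle: every sum of squares computed from
# cell means by definition, independent of aov()/Error() machinery.
# Supports one optional between factor and one or two within factors,
# balanced designs with one observation per subject x within-cell.

oracle_split_plot <- function(data, dv, subject, within, between = NULL) {
  y <- data[[dv]]
  S <- factor(data[[subject]])
  W <- lapply(within, function(f) factor(data[[f]]))
  names(W) <- within
  A <- if (!is.null(between)) factor(data[[between]]) else factor(rep("g", nrow(data)))
  grp_of_subj <- tapply(as.character(A), S, function(v) v[1])

  m <- mean(y)
  cellmean <- function(...) {
    idx <- list(...)
    tapply(y, idx, mean)
  }
  n_subj <- nlevels(S)
  a <- nlevels(A)
  n <- n_subj / a
  sizes <- vapply(W, nlevels, integer(1))
  n_within_cells <- prod(sizes)

  m_S <- tapply(y, S, mean)
  m_A <- tapply(y, A, mean)
  m_AS <- m_A[grp_of_subj[levels(S)]]

  ss <- list(); df <- list()
  ss$A <- n * n_within_cells * sum((m_A - m)^2); df$A <- a - 1
  ss$SwA <- n_within_cells * sum((m_S - m_AS)^2); df$SwA <- a * (n - 1)

  one_within <- function(B) {
    b <- nlevels(B)
    m_B <- tapply(y, B, mean)
    m_AB <- cellmean(A, B)
    m_SB <- cellmean(S, B)
    reps <- length(y) / (n_subj * b)          # cells of the other factor
    ssB <- n_subj * reps * sum((m_B - m)^2)
    ssAB <- n * reps * sum((sweep(sweep(m_AB, 1, m_A), 2, m_B) + m)^2)
    resid_sb <- m_SB - outer(as.numeric(m_S), as.numeric(m_B), "+") + m
    # remove the group x B component from the subject x B deviations
    for (si in seq_len(n_subj)) {
      g <- grp_of_subj[levels(S)[si]]
      resid_sb[si, ] <- resid_sb[si, ] - (m_AB[g, ] - m_A[g] - m_B + m)
    }
    ssBS <- reps * sum(resid_sb^2)
    list(ssB = ssB, ssAB = ssAB, ssBS = ssBS,
         dfB = b - 1, dfAB = (a - 1) * (b - 1), dfBS = a * (n - 1) * (b - 1))
  }

  effects <- list()
  push <- function(name, ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    if (ms_err == 0) {
      Fv <- if (ms_eff > 0) Inf else 0
      p <- if (ms_eff > 0) 0 else 1
    } else {
      Fv <- ms_eff / ms_err
      p <- pf(Fv, df_eff, df_err, lower.tail = FALSE)
    }
    effects[[name]] <<- list(df_num = df_eff, df_den = df_err, F = Fv, p = p)
  }

  if (!is.null(between)) push("A", ss$A, df$A, ss$SwA, df$SwA)

  r1 <- one_within(W[[1]])
  push("B", r1$ssB, r1$dfB, r1$ssBS, r1$dfBS)
  if (!is.null(between)) push("AB", r1$ssAB, r1$dfAB, r1$ssBS, r1$dfBS)
  total_ss <- sum((y - m)^2)
  accounted <- ss$A + ss$SwA + r1$ssB + r1$ssAB + r1$ssBS

  if (length(W) == 2L) {
    r2 <- one_within(W[[2]])
    push("C", r2$ssB, r2$dfB, r2$ssBS, r2$dfBS)
    if (!is.null(between)) push("AC", r2$ssAB, r2$dfAB, r2$ssBS, r2$dfBS)

    B <- W[[1]]; C <- W[[2]]
    b <- nlevels(B); cc <- nlevels(C)
    m_B <- tapply(y, B, mean); m_C <- tapply(y, C, mean)
    m_BC <- cellmean(B, C)
    m_ABC <- cellmean(A, B, C)
    m_AB <- cellmean(A, B); m_AC <- cellmean(A, C)
    ssBC <- n_subj * sum((sweep(sweep(m_BC, 1, m_B), 2, m_C) + m)^2)
    dev_abc <- array(0, dim = dim(m_ABC))
    for (ai in seq_len(a)) for (bi in seq_len(b)) for (ci in seq_len(cc)) {
      dev_abc[ai, bi, ci] <- m_ABC[ai, bi, ci] -
        m_AB[ai, bi] - m_AC[ai, ci] - m_BC[bi, ci] +
        m_A[ai] + m_B[bi] + m_C[ci] - m
    }
    ssABC <- n * sum(dev_abc^2)
    dfBC <- (b - 1) * (cc - 1)
    dfABC <- (a - 1) * dfBC
    accounted <- accounted + r2$ssB + r2$ssAB + r2$ssBS + ssBC + ssABC
    ssBCS <- total_ss - accounted
    dfBCS <- a * (n - 1) * dfBC
    push("BC", ssBC, dfBC, ssBCS, dfBCS)
    if (!is.null(between)) push("ABC", ssABC, dfABC, ssBCS, dfBCS)
    accounted <- accounted + ssBCS
  }

  map_name <- function(nm) {
    key <- c(A = between %||% "", B = within[1],
             C = if (length(within) > 1) within[2] else "",
             AB = paste(between %||% "", within[1], sep = " x "),
             AC = if (length(within) > 1) paste(between %||% "", within[2], sep = " x ") else "",
             BC = if (length(within) > 1) paste(within[1], within[2], sep = " x ") else "",
             ABC = if (length(within) > 1) paste(between %||% "", within[1], within[2], sep = " x ") else "")
    key[[nm]]
  }
  out <- do.call(rbind, lapply(names(effects), function(nm) {
    e <- effects[[nm]]
    data.frame(effect = map_name(nm), df_num = e$df_num, df_den = e$df_den,
               F = e$F, p = e$p, stringsAsFactors = FALSE)
  }))
  attr(out, "ss_total") <- total_ss
  attr(out, "ss_accounted") <- accounted
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random balanced split-plot dataset
random_split_plot <- function(n_per_group = 3, groups = 2, within_sizes = c(2, 3),
                              seed = 1) {
  set.seed(seed)
  n_subj <- n_per_group * groups
  within <- lapply(seq_along(within_sizes), function(i) {
    factor(seq_len(within_sizes[i]))
  })
  grid <- expand.grid(c(list(subject = factor(seq_len(n_subj))), within))
  names(grid) <- c("subject", paste0("w", seq_along(within_sizes)))
  grid$group <- factor(ifelse(as.integer(grid$subject) <= n_per_group, "g1", "g2"))
  grid$value <- rnorm(nrow(grid))
  grid
}
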