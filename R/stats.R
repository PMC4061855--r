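#' Mixed repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical univariate partition for a balanced fully-factorial
#' repeated-measures design with an optional between-subjects factor.  The
#' per-subject cell means are projected onto orthonormal within-subject
#' contrasts (Kronecker products of per-factor Helmert-type contrasts), so
#' every within effect, its interaction with the between factor, and its
#' subject-interaction error term fall out of one decomposition.  For each
#' within stratum the Greenhouse-Geisser epsilon is estimated from the
#' pooled within-group covariance of the contrast scores,
#'
#'   `eps = tr(S)^2 / (d * tr(S^2))`,
#'
#' clamped to `[1/d, 1]` where `d` is the effect's numerator df; corrected
#' p-values multiply both df by epsilon.  The correction is only applied to
#' effects with more than one numerator df (a two-level factor always has
#' `eps = 1`).
#'
#' @param data long-format data frame (e.g. a RoiTable slice).
#' @param dv name of the response column (default `"value"`).
#' @param within character vector of within-subject factor columns.
#' @param between optional single between-subjects factor column.
#' @param subject subject-identifier column (default `"subject"`).
#' @return an object of class `rm_anova`: a data frame of effects with
#'   columns `effect, df1, df2, ss, ss_error, F, epsilon, df1_gg, df2_gg,
#'   p, p_gg`.
#' @export
rm_anova <- function(data, dv = "value", within, between = NULL,
                     subject = "subject") {
  for (col in c(dv, within, between, subject))
    if (is.null(data[[col]]))
      stop_wavepls(paste("column missing from data:", col),
                   "wavepls_label_error")
  subj <- as.character(data[[subject]])
  subjects <- unique(subj)
  N <- length(subjects)
  lev <- lapply(within, function(w) sort(unique(as.character(data[[w]]))))
  names(lev) <- within
  k <- vapply(lev, length, 0L)
  p <- prod(k)
  # cell index with the first within factor varying fastest
  cell_of <- rep(1L, nrow(data))
  mult <- 1L
  for (j in seq_along(within)) {
    cell_of <- cell_of + (match(as.character(data[[within[j]]]), lev[[j]]) - 1L) * mult
    mult <- mult * k[j]
  }
  Y <- matrix(NA_real_, N, p)
  ij <- cbind(match(subj, subjects), cell_of)
  if (anyDuplicated(ij))
    stop_wavepls("more than one observation per subject and within-cell; aggregate first",
                 "wavepls_label_error")
  Y[ij] <- data[[dv]]
  if (anyNA(Y))
    stop_wavepls("unbalanced design: missing subject x cell combinations",
                 "wavepls_label_error")
  if (!is.null(between)) {
    g_by_subj <- tapply(as.character(data[[between]]), subj,
                        function(x) unique(x))
    if (any(lengths(g_by_subj) != 1L))
      stop_wavepls("a subject appears in more than one between-group level",
                   "wavepls_label_error")
    grp <- factor(unlist(g_by_subj)[subjects])
    if (any(table(grp) < 2L))
      stop_wavepls("need at least 2 subjects per group",
                   "wavepls_label_error")
  } else {
    grp <- factor(rep("all", N))
  }
  G <- nlevels(grp)
  n_g <- as.vector(table(grp))
  # orthonormal contrast columns per factor; unit vector for excluded factors
  Cmat <- lapply(k, function(kk) {
    qr.Q(qr(cbind(1, stats::contr.helmert(kk))))[, -1L, drop = FALSE]
  })
  umat <- lapply(k, function(kk) matrix(1 / sqrt(kk), kk, 1L))

  res <- list()
  add_row <- function(effect, df1, df2, ss, ss_err, Fv, eps, pv, pgg) {
    res[[length(res) + 1L]] <<- data.frame(
      effect = effect, df1 = df1, df2 = df2, ss = ss, ss_error = ss_err,
      F = Fv, epsilon = eps, df1_gg = df1 * eps, df2_gg = df2 * eps,
      p = pv, p_gg = pgg, stringsAsFactors = FALSE)
  }
  stratum <- function(M, eff_name) {
    Z <- Y %*% M
    d <- ncol(M)
    zbar <- colMeans(Z)
    gm <- rowsum(Z, grp) / n_g                      # group means, G x d
    resid <- Z - gm[as.integer(grp), , drop = FALSE]
    sse <- sum(resid^2)
    df_err <- (N - G) * d
    S <- crossprod(resid) / (N - G)
    eps <- if (d > 1L) {
      e <- sum(diag(S))^2 / (d * sum(S * S))
      min(1, max(1 / d, e))
    } else 1
    mse <- sse / df_err
    if (nzchar(eff_name)) {                         # within main effect
      ss <- N * sum(zbar^2)
      Fv <- (ss / d) / mse
      pv <- stats::pf(Fv, d, df_err, lower.tail = FALSE)
      # deflating both df can nominally lower p when F < 1; the correction
      # is a guard against liberal inference, so it is never allowed to
      # undercut the uncorrected p
      pgg <- if (d > 1L)
        max(pv, stats::pf(Fv, d * eps, df_err * eps, lower.tail = FALSE))
      else pv
      add_row(eff_name, d, df_err, ss, sse, Fv, eps, pv, pgg)
    }
    if (!is.null(between)) {
      ss_int <- sum(n_g * rowSums(sweep(gm, 2L, zbar)^2))
      df_int <- d * (G - 1L)
      Fv <- (ss_int / df_int) / mse
      pv <- stats::pf(Fv, df_int, df_err, lower.tail = FALSE)
      pgg <- if (d > 1L)
        max(pv, stats::pf(Fv, df_int * eps, df_err * eps,
                          lower.tail = FALSE))
      else pv
      nm <- if (nzchar(eff_name)) paste(between, eff_name, sep = ":")
            else between
      add_row(nm, df_int, df_err, ss_int, sse, Fv, eps, pv, pgg)
    }
  }
  # between-subject stratum (projection onto the grand unit vector)
  M0 <- Reduce(kronecker, rev(umat))
  stratum(M0, "")
  # all within strata
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(within)))
  for (r in seq_len(nrow(subsets))[-1L]) {
    inc <- unlist(subsets[r, ])
    comps <- lapply(seq_along(within), function(j)
      if (inc[j]) Cmat[[j]] else umat[[j]])
    M <- Reduce(kronecker, rev(comps))
    stratum(M, paste(within[inc], collapse = ":"))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("rm_anova", "data.frame"),
            within = within, between = between, n_subjects = N,
            groups = if (is.null(between)) NULL else table(grp))
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects%s)\n",
              attr(x, "n_subjects"),
              if (is.null(attr(x, "between"))) ""
              else paste0(", between factor: ", attr(x, "between"))))
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5); df$ss_error <- signif(df$ss_error, 5)
  df$F <- round(df$F, 3); df$epsilon <- round(df$epsilon, 4)
  df$df1_gg <- round(df$df1_gg, 2); df$df2_gg <- round(df$df2_gg, 2)
  df$p <- signif(df$p, 4); df$p_gg <- signif(df$p_gg, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Pairwise t tests between the levels of one factor, on per-subject means
#' (aggregated over any remaining columns).  Levels of a between-subjects
#' factor are compared with two-sample Welch tests, levels of a within
#' factor with paired tests.  Raw p-values are multiplied by the number of
#' pairs and capped at 1.
#'
#' @param data long-format data frame.
#' @param factor_col factor whose levels are compared.
#' @param dv response column (default `"value"`).
#' @param subject subject column (default `"subject"`).
#' @return data frame with one row per pair: `level1, level2, statistic,
#'   df, p_raw, p_adj`.
#' @export
bonferroni_pairwise <- function(data, factor_col, dv = "value",
                                subject = "subject") {
  lv <- sort(unique(as.character(data[[factor_col]])))
  if (length(lv) < 2L)
    stop_wavepls("factor has a single level", "wavepls_label_error")
  agg <- stats::aggregate(data[[dv]],
                          list(subject = as.character(data[[subject]]),
                               level = as.character(data[[factor_col]])),
                          mean)
  names(agg)[3L] <- "y"
  per_subj_levels <- tapply(agg$level, agg$subject, function(x) length(unique(x)))
  paired <- all(per_subj_levels == length(lv))
  pairs <- utils::combn(lv, 2L)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- agg[agg$level == pairs[1L, i], ]
    b <- agg[agg$level == pairs[2L, i], ]
    if (paired) {
      b <- b[match(a$subject, b$subject), ]
      tt <- stats::t.test(a$y, b$y, paired = TRUE)
    } else {
      tt <- stats::t.test(a$y, b$y)
    }
    data.frame(level1 = pairs[1L, i], level2 = pairs[2L, i],
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_adj = min(1, tt$p.value * n_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties.  The two-sided
#' p-value uses the t approximation for `n >= 10` and an exact permutation
#' enumeration below (where the number of permutations is still small).
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return an object of class `spearman_cor`: list with `rho`, `n`, `p`,
#'   `method`, and `degenerate = TRUE` when an input is constant (rho
#'   undefined).
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_wavepls("need at least 3 paired observations",
                           "wavepls_format_error")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(structure(list(rho = NA_real_, n = n, p = NA_real_,
                          method = "undefined", degenerate = TRUE),
                     class = "spearman_cor"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10L) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pv <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "t approximation"
  } else {
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow(perms), n)
    # cor(rx, ry[perm]) for every permutation, vectorized
    rho_perm <- (ry_perm %*% (rx - mean(rx))) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    pv <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  }
  structure(list(rho = rho, n = n, p = min(1, pv), method = method,
                 degenerate = FALSE),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("Spearman correlation undefined (constant input), n =", x$n, "\n")
  } else {
    cat(sprintf("Spearman rho = %.3f, n = %d, p = %.4g (%s, two-sided)\n",
                x$rho, x$n, x$p, x$method))
  }
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1L) * m + seq_len(m)
    out[rows, pos] <- n
    out[rows, setdiff(seq_len(n), pos)] <- sub
  }
  out
}

#' Type-I error / power validation suite for the pipeline statistics
#'
#' Repeatedly generates a synthetic study from each design variant, runs
#' the full analysis chain (re-referencing, artifact rejection, wavelet
#' transform, ROI extraction) and the mixed RM-ANOVA, and tabulates how
#' often each requested effect is significant at `alpha` under the
#' Greenhouse-Geisser-corrected p-value.
#'
#' @param designs named list of [study_design()] variants.
#' @param effects character vector of effect names as produced by
#'   [rm_anova()] (e.g. `"group:session"`).
#' @param n_sims simulations per design (>= 1; use >= 100 for rates).
#' @param seed master seed; simulation `i` of design `j` derives its own.
#' @param measure,band,scheme RoiTable slice analysed (defaults: power,
#'   gamma, midline).
#' @param within within-subject factors (default session, tone, condition,
#'   location).
#' @param between between factor (default `"group"`).
#' @param alpha significance level (default 0.05).
#' @param channels optional channel subset passed to the generator to keep
#'   scaled designs cheap.
#' @param fam optional [build_wavelet_family()] for the analysis.
#' @param ptp_threshold artifact rejection threshold (microvolt).
#' @return data frame: one row per design x effect with rejection counts,
#'   rate, and an exact binomial 95 percent confidence interval.
#' @export
type1_power_suite <- function(designs, effects = "group:session",
                              n_sims = 200, seed = 1L,
                              measure = "power", band = "gamma",
                              scheme = "midline",
                              within = c("session", "tone", "condition",
                                         "location"),
                              between = "group", alpha = 0.05,
                              channels = NULL, fam = NULL,
                              ptp_threshold = 150) {
  if (n_sims < 1L) stop_wavepls("n_sims must be >= 1", "wavepls_format_error")
  out <- list()
  for (j in seq_along(designs)) {
    des <- designs[[j]]
    rej <- matrix(0L, n_sims, length(effects))
    for (i in seq_len(n_sims)) {
      des_i <- des
      des_i$seed <- child_seed(seed, j, i)
      roi <- simulate_roi(des_i, channels = channels, fam = fam,
                          scheme = scheme, bands = band,
                          measures = measure,
                          ptp_threshold = ptp_threshold)
      sl <- roi[roi$measure == measure & roi$band == band &
                  roi$scheme == scheme, ]
      an <- rm_anova(sl, dv = "value", within = within, between = between)
      pv <- an$p_gg[match(effects, an$effect)]
      rej[i, ] <- !is.na(pv) & pv < alpha
    }
    for (e in seq_along(effects)) {
      r <- sum(rej[, e])
      ci <- stats::binom.test(r, n_sims)$conf.int
      out[[length(out) + 1L]] <- data.frame(
        design = names(designs)[j] %||% as.character(j),
        effect = effects[e], n_sims = n_sims, rejections = r,
        rate = r / n_sims, ci_lo = ci[1L], ci_hi = ci[2L],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# generate a study from a design and run it through preprocessing and ROI
# extraction; helper shared by the validation suite and the pipeline
simulate_roi <- function(design, channels = NULL, fam = NULL,
                         scheme = c("midline", "lateral"),
                         bands = c("alpha", "gamma"),
                         measures = c("power", "pls"),
                         ptp_threshold = 150, min_trials = 0) {
  study <- generate_study(design, channels = channels)
  bw <- default_band_windows()[bands]
  epochs <- lapply(study$epochs, function(es) {
    es <- rereference_to_average_mastoids(es, design$montage)
    reject_artifacts(es, ptp_threshold)
  })
  if (min_trials > 0) {
    keep <- vapply(epochs, screen_subject, TRUE, min_trials = min_trials)
    epochs <- epochs[keep]
  }
  build_roi_table(epochs, montage = design$montage, bands = bw, fam = fam,
                  schemes = scheme, measures = measures)
}

#' Follow-up ANOVAs after a significant interaction
#'
#' Convenience runner that slices the table by the levels of one column
#' (e.g. per group, or per location) and runs [rm_anova()] on every slice.
#' No alpha adjustment is applied across the follow-ups.
#'
#' @param data long-format data frame.
#' @param split_by column whose levels define the slices.
#' @param ... passed to [rm_anova()] (dv, within, between, subject).
#' @return named list of [rm_anova()] results, one per level.
#' @export
follow_up_anovas <- function(data, split_by, ...) {
  lv <- sort(unique(as.character(data[[split_by]])))
  out <- lapply(lv, function(l)
    rm_anova(data[as.character(data[[split_by]]) == l, , drop = FALSE], ...))
  stats::setNames(out, lv)
}
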