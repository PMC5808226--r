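#' Collapse technical qPCR replicates
#'
#' Averages the technical replicate Ct values within each
#' (condition, gene, biological replicate) cell and flags cells whose
#' technical standard deviation exceeds `sd_flag` cycles (a conventional
#' plate-QC threshold).
#'
#' @param ct_table Tidy Ct table: data frame with columns `condition`,
#'   `gene`, `bio_rep`, `tech_rep`, `ct` (an optional `sample_id` column is
#'   carried through).
#' @param sd_flag Technical-SD flag threshold in cycles (default 0.5).
#' @return A tibble with one row per cell: `condition`, `gene`, `bio_rep`,
#'   `ct` (mean), `ct_sd`, `n_tech`, `high_variance`.
#' @examples
#' tab <- gen_ct_table(conditions = c("a", "b"), true_folds = c(a = 1, b = 2))
#' collapse_technical(tab)
#' @export
collapse_technical <- function(ct_table, sd_flag = 0.5) {
  need <- c("condition", "gene", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss) > 0) {
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0)) {
    stop("all Ct values must be finite and positive", call. = FALSE)
  }
  ct_table |>
    dplyr::group_by(.data$condition, .data$gene, .data$bio_rep) |>
    dplyr::summarise(
      ct_sd = stats::sd(.data$ct),
      n_tech = dplyr::n(),
      ct = mean(.data$ct),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ct_sd = dplyr::if_else(.data$n_tech == 1L, 0, .data$ct_sd),
      high_variance = .data$ct_sd > sd_flag
    ) |>
    dplyr::select("condition", "gene", "bio_rep", "ct", "ct_sd", "n_tech",
                  "high_variance")
}

#' Relative expression by the 2^-ddCt (Livak) method
#'
#' Per biological replicate: dCt = Ct_target - Ct_reference; ddCt = dCt
#' minus the mean dCt of the calibrator condition; relative quantity
#' rq = 2^-ddCt. Equal amplification efficiencies of target and reference
#' are assumed (no efficiency correction). Centering on the calibrator's
#' mean dCt makes the calibrator's mean-dCt fold exactly 1 and is stable
#' under unbalanced replication. Results are invariant to adding any
#' constant to every Ct in the table.
#'
#' @param ct_table Tidy Ct table (see [collapse_technical()]); technical
#'   replicates, if present, are collapsed first.
#' @param target Target gene name.
#' @param reference Reference (normalizer) gene name; must differ from
#'   `target` and be present for every (condition, bio_rep) that has the
#'   target.
#' @param calibrator Condition whose mean dCt anchors fold = 1. Default
#'   `NULL` picks the condition with the highest mean dCt (i.e. the lowest
#'   expression).
#' @return A tibble with one row per (condition, bio_rep): `condition`,
#'   `bio_rep`, `delta_ct`, `delta_delta_ct`, `rq`, plus the chosen
#'   `calibrator` as an attribute.
#' @examples
#' tab <- gen_ct_table(conditions = c("fg", "hg"),
#'                     true_folds = c(fg = 1, hg = 19.23), ct_noise_sd = 0)
#' relative_quantity(tab, calibrator = "fg")
#' @export
relative_quantity <- function(ct_table, target = "target",
                              reference = "reference", calibrator = NULL) {
  if (identical(target, reference)) {
    stop("reference gene must differ from the target", call. = FALSE)
  }
  cells <- collapse_technical(ct_table)
  wide <- cells |>
    dplyr::filter(.data$gene %in% c(target, reference)) |>
    dplyr::select("condition", "gene", "bio_rep", "ct") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  for (g in c(target, reference)) {
    if (!g %in% names(wide) || anyNA(wide[[g]])) {
      gap <- if (!g %in% names(wide)) "all replicates" else {
        paste(sprintf("%s/rep %s", wide$condition[is.na(wide[[g]])],
                      wide$bio_rep[is.na(wide[[g]])]), collapse = "; ")
      }
      stop("gene '", g, "' missing for: ", gap, call. = FALSE)
    }
  }
  wide$delta_ct <- wide[[target]] - wide[[reference]]
  if (is.null(calibrator)) {
    by_cond <- tapply(wide$delta_ct, wide$condition, mean)
    calibrator <- names(which.max(by_cond))
  }
  if (!calibrator %in% wide$condition) {
    stop("calibrator condition '", calibrator, "' absent from the table",
         call. = FALSE)
  }
  anchor <- mean(wide$delta_ct[wide$condition == calibrator])
  out <- wide |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct - anchor,
                  rq = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("condition", "bio_rep", "delta_ct", "delta_delta_ct", "rq")
  attr(out, "calibrator") <- calibrator
  out
}

#' Group statistics for relative expression folds
#'
#' The screening-then-testing pipeline standard in expression studies:
#' folds are log-transformed, each group is screened for normality
#' (Shapiro-Wilk) and the groups for variance homogeneity (Levene's test);
#' with two conditions a two-sided Student's t-test is run; with more, a
#' one-way ANOVA with Tukey's HSD when variances are homogeneous, or
#' Dunnett's T3 (Welch-type pairwise tests with a studentized-maximum-
#' modulus correction) when they are not. Compact letter groupings at
#' `alpha` summarize the pairwise results.
#'
#' @param rq_table Output of [relative_quantity()] (or any data frame with
#'   `condition` and `rq` columns), >= 2 conditions with >= 2 replicates
#'   each.
#' @param alpha Significance level (default 0.05).
#' @param homogeneity_alpha Level of the Levene screen deciding between
#'   Tukey and Dunnett T3 (default 0.05).
#' @return An object of class `expression_stats`: a list with `omnibus`
#'   (one-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`),
#'   `pairwise` (tibble of adjusted pairwise comparisons), `screens`
#'   (Shapiro + Levene results), `letters` (tibble `condition`, `mean_rq`,
#'   `letters`), and `alpha`. Degenerate input (zero variance everywhere)
#'   yields p = 1 with `degenerate = TRUE` in the omnibus row.
#' @examples
#' tab <- gen_ct_table(conditions = c("a", "b", "c"),
#'                     true_folds = c(a = 1, b = 1, c = 4))
#' group_stats(relative_quantity(tab, calibrator = "a"))
#' @export
group_stats <- function(rq_table, alpha = 0.05, homogeneity_alpha = 0.05) {
  stopifnot(all(c("condition", "rq") %in% names(rq_table)))
  d <- tibble::tibble(condition = as.character(rq_table$condition),
                      log_rq = log(rq_table$rq))
  conds <- unique(d$condition)
  ns <- table(d$condition)
  if (length(conds) < 2 || any(ns < 2)) {
    stop(">= 2 conditions with >= 2 replicates each are required",
         call. = FALSE)
  }
  means <- tapply(d$log_rq, d$condition, mean)
  mean_rq <- tapply(rq_table$rq, as.character(rq_table$condition), mean)

  if (all(tapply(d$log_rq, d$condition, stats::sd) == 0)) {
    eq <- length(unique(round(means, 12))) == 1
    omnibus <- tibble::tibble(method = "degenerate", statistic = 0,
                              df1 = NA_real_, df2 = NA_real_,
                              p_value = if (eq) 1 else 0, degenerate = TRUE)
    return(.new_expression_stats(omnibus, pairwise = NULL, screens = NULL,
                                 mean_rq = mean_rq, alpha = alpha))
  }

  shapiro <- purrr::map_dfr(conds, function(cc) {
    x <- d$log_rq[d$condition == cc]
    p <- if (length(x) >= 3 && stats::sd(x) > 0)
      stats::shapiro.test(x)$p.value else NA_real_
    tibble::tibble(condition = cc, shapiro_p = p)
  })
  lev <- car::leveneTest(log_rq ~ factor(condition), data = d)
  levene_p <- lev[["Pr(>F)"]][1]
  homogeneous <- is.na(levene_p) || levene_p > homogeneity_alpha
  screens <- list(shapiro = shapiro,
                  levene = tibble::tibble(levene_p = levene_p,
                                          homogeneous = homogeneous))

  if (length(conds) == 2) {
    a <- d$log_rq[d$condition == conds[1]]
    b <- d$log_rq[d$condition == conds[2]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    omnibus <- tibble::tibble(method = "student_t",
                              statistic = unname(tt$statistic),
                              df1 = unname(tt$parameter), df2 = NA_real_,
                              p_value = tt$p.value, degenerate = FALSE)
    pairwise <- tibble::tibble(condition_a = conds[1], condition_b = conds[2],
                               estimate = means[[conds[1]]] - means[[conds[2]]],
                               p_adj = tt$p.value)
  } else if (homogeneous) {
    fit <- stats::aov(log_rq ~ factor(condition), data = d)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)[[1]]
    cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
    omnibus <- tibble::tibble(method = "anova_tukey",
                              statistic = an[["F value"]][1],
                              df1 = an[["Df"]][1], df2 = an[["Df"]][2],
                              p_value = an[["Pr(>F)"]][1], degenerate = FALSE)
    pairwise <- tibble::tibble(
      condition_a = vapply(cmp, `[`, "", 1),
      condition_b = vapply(cmp, `[`, "", 2),
      estimate = unname(tk[, "diff"]), p_adj = unname(tk[, "p adj"])
    )
  } else {
    omni <- stats::oneway.test(log_rq ~ factor(condition), data = d,
                               var.equal = FALSE)
    omnibus <- tibble::tibble(method = "welch_anova_dunnett_t3",
                              statistic = unname(omni$statistic),
                              df1 = unname(omni$parameter[1]),
                              df2 = unname(omni$parameter[2]),
                              p_value = omni$p.value, degenerate = FALSE)
    pairwise <- .dunnett_t3(d)
  }
  letters <- .letter_groups(conds, means, pairwise, alpha)
  .new_expression_stats(omnibus, pairwise, screens, mean_rq, alpha, letters)
}

# Dunnett T3: pairwise Welch t statistics referred to the studentized
# maximum modulus over all k(k-1)/2 comparisons, computed under the
# independence approximation p_adj = 1 - (2*pt(t, df) - 1)^k.
.dunnett_t3 <- function(d) {
  conds <- unique(d$condition)
  k <- choose(length(conds), 2)
  prs <- utils::combn(conds, 2)
  purrr::map_dfr(seq_len(ncol(prs)), function(j) {
    a <- d$log_rq[d$condition == prs[1, j]]
    b <- d$log_rq[d$condition == prs[2, j]]
    va <- stats::var(a) / length(a)
    vb <- stats::var(b) / length(b)
    t_stat <- abs(mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p_adj <- 1 - (2 * stats::pt(t_stat, df) - 1)^k
    tibble::tibble(condition_a = prs[1, j], condition_b = prs[2, j],
                   estimate = mean(a) - mean(b),
                   p_adj = min(1, max(0, p_adj)))
  })
}

# compact letter display: conditions sorted by mean; each letter covers a
# maximal run of conditions whose pairwise comparisons are all
# non-significant (insert-and-absorb along the ordering)
.letter_groups <- function(conds, means, pairwise, alpha) {
  ord <- names(sort(means, decreasing = TRUE))
  sig <- function(a, b) {
    row <- pairwise$p_adj[(pairwise$condition_a == a & pairwise$condition_b == b) |
                          (pairwise$condition_a == b & pairwise$condition_b == a)]
    length(row) > 0 && row[1] < alpha
  }
  runs <- lapply(seq_along(ord), function(i) {
    j <- i
    while (j < length(ord) &&
           !any(vapply(i:j, function(m) sig(ord[m], ord[j + 1]), logical(1)))) {
      j <- j + 1
    }
    i:j
  })
  # keep only maximal runs (not contained in another run)
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(seq_along(runs), function(s) {
      s != r && length(runs[[s]]) > length(runs[[r]]) &&
        all(runs[[r]] %in% runs[[s]])
    }, logical(1)))
  }, logical(1))
  runs <- unique(runs[keep])
  lab <- stats::setNames(rep("", length(ord)), ord)
  for (r in seq_along(runs)) {
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[r])
  }
  tibble::tibble(condition = ord, mean_log = unname(means[ord]),
                 letters = unname(lab))
}

.new_expression_stats <- function(omnibus, pairwise, screens, mean_rq,
                                  alpha, letters = NULL) {
  structure(list(omnibus = omnibus, pairwise = pairwise, screens = screens,
                 mean_rq = tibble::tibble(condition = names(mean_rq),
                                          mean_rq = as.numeric(mean_rq)),
                 letters = letters, alpha = alpha),
            class = "expression_stats")
}

#' @export
print.expression_stats <- function(x, ...) {
  o <- x$omnibus
  cat("Relative-expression group statistics (", o$method, ")\n", sep = "")
  cat(sprintf("  omnibus: statistic = %.4g, p = %.4g\n", o$statistic,
              o$p_value))
  if (!is.null(x$letters)) {
    print(dplyr::left_join(x$mean_rq, x$letters, by = "condition"))
  }
  invisible(x)
}

#' @export
tidy.expression_stats <- function(x, ...) {
  if (is.null(x$pairwise)) return(tibble::tibble())
  tibble::as_tibble(x$pairwise) |>
    dplyr::mutate(significant = .data$p_adj < x$alpha)
}

#' @export
glance.expression_stats <- function(x, ...) {
  x$omnibus
}
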