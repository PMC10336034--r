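#' Likelihood ratio test for episodic diversifying selection
#'
#' Compares an alternative fit against the null with the selection
#' category pinned at `omega_K = 1`.  Because the null lies on the
#' boundary of the parameter space, the test statistic is referred to a
#' 50:50 mixture of a point mass at zero and a chi-squared with two
#' degrees of freedom: `p = 0.5 * Pr(chisq_2 >= max(LRT, 0))`.  A
#' nonpositive statistic therefore reports p = 0.5, the capped value the
#' statistic attains when the alternative collapses onto the null.  A
#' statistic below -0.01 indicates the alternative optimizer stopped short
#' of the null's optimum and a refit is warranted; a warning is raised.
#'
#' @param lnL_alt,lnL_null Maximized log-likelihoods of the alternative
#'   and constrained fits (or `busted_fit` objects).
#' @return A list with `lrt` and `p`.
#' @examples
#' eds_pvalue(-1000, -1003)  # lrt = 6
#' @export
eds_pvalue <- function(lnL_alt, lnL_null) {
  if (inherits(lnL_alt, "busted_fit")) lnL_alt <- lnL_alt$lnL
  if (inherits(lnL_null, "busted_fit")) lnL_null <- lnL_null$lnL
  lrt <- 2 * (lnL_alt - lnL_null)
  if (lrt < -0.01) {
    warning("LRT statistic is ", format(lrt, digits = 4),
            "; the alternative fit is worse than the null - refit the ",
            "alternative seeded from the null's MLE", call. = FALSE)
  }
  list(lrt = lrt, p = 0.5 * pchisq(max(lrt, 0), df = 2,
                                   lower.tail = FALSE))
}

#' Tests for nonzero multiple-hit rates
#'
#' Nested comparisons along +S, +S+2H (delta free, psi = 0) and +S+MH:
#' delta > 0 is tested by +S vs +S+2H and psi > 0 by +S+2H vs +S+MH, each
#' against a conservative chi-squared with one degree of freedom; the
#' joint null delta = psi = 0 (+S vs +S+MH) uses a conservative
#' chi-squared with two degrees of freedom.
#'
#' @param fit_S,fit_S2H,fit_SMH `busted_fit` objects (or log-likelihoods)
#'   of the three nested models on the same data.
#' @return A list with `p_delta`, `p_psi`, `p_joint` and the three LRT
#'   statistics.
#' @export
mh_rate_tests <- function(fit_S, fit_S2H, fit_SMH) {
  ln <- function(x) if (inherits(x, "busted_fit")) x$lnL else x
  l_s <- ln(fit_S); l_2h <- ln(fit_S2H); l_mh <- ln(fit_SMH)
  tol <- 0.05
  if (l_2h < l_s - tol || l_mh < l_2h - tol) {
    stop("log-likelihood ordering violated (lnL ", format(l_s), " / ",
         format(l_2h), " / ", format(l_mh),
         "): refit the richer models seeded from the nested fits")
  }
  chisq_p <- function(lrt, df) pchisq(max(lrt, 0), df = df,
                                      lower.tail = FALSE)
  lrt_d <- 2 * (l_2h - l_s)
  lrt_p <- 2 * (l_mh - l_2h)
  lrt_j <- 2 * (l_mh - l_s)
  list(lrt_delta = lrt_d, lrt_psi = lrt_p, lrt_joint = lrt_j,
       p_delta = chisq_p(lrt_d, 1), p_psi = chisq_p(lrt_p, 1),
       p_joint = chisq_p(lrt_j, 2))
}

#' Akaike weights and the model-averaged p-value
#'
#' Akaike weights turn AICc differences into per-model probabilities,
#' `w_m` proportional to `exp((AICc_best - AICc_m) / 2)` and normalized to
#' sum to one; the model-averaged p-value is the weight-weighted mean of
#' the per-model selection p-values, a convex combination that always lies
#' within the range of its components.
#'
#' @param fits List of `busted_fit` objects (alternative fits), or a
#'   numeric vector of AICc values.
#' @param pvalues Numeric vector of matching per-model p-values.
#' @return A list with `weights` (named if the fits are) and `p_MA`.
#' @export
model_averaged_p <- function(fits, pvalues) {
  aicc <- if (is.numeric(fits)) fits else {
    vapply(fits, function(f) f$aicc, numeric(1))
  }
  if (length(aicc) != length(pvalues)) {
    stop("fits and pvalues must have matching lengths")
  }
  if (length(aicc) < 2) stop("model averaging requires at least 2 models")
  w <- exp((min(aicc) - aicc) / 2)
  w <- w / sum(w)
  list(weights = w, p_MA = sum(w * pvalues))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Standard step-up q-values with significance flags at a target FDR.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param q_threshold FDR level (the screening analyses use 0.2).
#' @return A tibble with `p`, `q` and `significant`.
#' @export
bh_fdr <- function(pvalues, q_threshold = 0.2) {
  if (!length(pvalues)) {
    return(tibble::tibble(p = numeric(0), q = numeric(0),
                          significant = logical(0)))
  }
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  tibble::tibble(p = pvalues, q = q, significant = q <= q_threshold)
}

#' Fit the model hierarchy and test for selection
#'
#' Runs the model-testing procedure on one alignment: fits BUSTED, +S,
#' +MH and +S+MH (optionally also the intermediate +S+2H), each with its
#' omega3 = 1 null, computes the per-model selection LRT p-values, Akaike
#' weights, the model-averaged p-value, the AICc-best model, and the
#' detection pattern at a given significance level.
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] with branch lengths.
#' @param models Models to fit (subset of BUSTED, +S, +MH, +S+2H, +S+MH).
#' @param K,L Omega and alpha bin counts.
#' @param level Significance level for the detection pattern.
#' @param starts,seed,branch_mode Passed to [fit_model()].
#' @return An object of class `busted_modeltest`: `table` (per-model
#'   tibble with lnL, k, AICc, weight, LRT, p), `p_averaged`,
#'   `best_model`, `detection_pattern` (named bits ordered +S+MH, BUSTED,
#'   +S, +MH, Averaged, Best), `mh_tests` (when +S, +S+2H and +S+MH are
#'   all fitted) and the fit objects.
#' @export
model_test <- function(aln, tree, models = c("BUSTED", "+S", "+MH",
                                             "+S+MH"),
                       K = 3, L = 3, level = 0.05, starts = 1, seed = 1,
                       branch_mode = c("full", "scale")) {
  branch_mode <- match.arg(branch_mode)
  validate_tree_alignment(tree, aln)
  res <- .grid_cell_fit(aln, tree, models, K = K, L = L, starts = starts,
                        seed = seed, branch_mode = branch_mode)
  tab <- res$table
  tab$k <- vapply(tab$model, function(m) res$fits[[m]]$k, numeric(1))
  tab$lrt <- 2 * (tab$lnL - tab$lnL_null)
  tab <- tab[order(tab$aicc), ]
  best <- tab$model[1]
  pattern <- c(
    "+S+MH" = unname(tab$p[tab$model == "+S+MH"] <= level),
    "BUSTED" = unname(tab$p[tab$model == "BUSTED"] <= level),
    "+S" = unname(tab$p[tab$model == "+S"] <= level),
    "+MH" = unname(tab$p[tab$model == "+MH"] <= level),
    "Averaged" = res$p_averaged <= level,
    "Best" = unname(tab$p[tab$model == best] <= level)
  )
  pattern <- pattern[!is.na(pattern)]
  mh_tests <- if (all(c("+S", "+S+2H", "+S+MH") %in% tab$model)) {
    mh_rate_tests(res$fits[["+S"]], res$fits[["+S+2H"]],
                  res$fits[["+S+MH"]])
  } else NULL
  structure(list(
    table = tibble::as_tibble(tab), p_averaged = res$p_averaged,
    best_model = best, detection_pattern = pattern, level = level,
    mh_tests = mh_tests, fits = res$fits, nulls = res$nulls
  ), class = "busted_modeltest")
}

#' @export
print.busted_modeltest <- function(x, ...) {
  cat("<busted_modeltest:", nrow(x$table), "models | best:", x$best_model,
      "| model-averaged p =", format(x$p_averaged, digits = 4), ">\n")
  print(x$table[, c("model", "lnL", "k", "aicc", "weight", "lrt", "p")])
  cat("detection pattern (", paste(names(x$detection_pattern),
                                   collapse = ", "), "): ",
      paste(as.integer(x$detection_pattern), collapse = ""), "\n",
      sep = "")
  invisible(x)
}

#' Write a model-test report as JSON
#'
#' Serializes the per-model table, weights, model-averaged p-value, best
#' model, detection pattern and (if present) multiple-hit rate tests and
#' diagnostics summaries to a versioned JSON document.
#'
#' @param report A `busted_modeltest`.
#' @param path Output file.
#' @export
write_model_test_json <- function(report, path) {
  stopifnot(inherits(report, "busted_modeltest"))
  mles <- lapply(report$fits, function(f) {
    list(omega = f$mle$omega_grid$omegas,
         omega_weights = f$mle$omega_grid$weights,
         alpha = f$mle$alpha_grid$alphas,
         alpha_weights = f$mle$alpha_grid$weights,
         delta = f$mle$mh$delta, psi = f$mle$mh$psi,
         theta = as.numeric(f$mle$theta),
         tree_length = sum(f$mle$branch_lengths))
  })
  doc <- list(
    schema = "bustedmh-modeltest-1",
    models = report$table,
    p_averaged = report$p_averaged,
    best_model = report$best_model,
    detection_pattern = as.list(as.integer(report$detection_pattern)) |>
      setNames(names(report$detection_pattern)),
    level = report$level,
    mh_tests = report$mh_tests,
    mle = mles
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
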