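#' Tidy a fitted model into a parameter tibble
#'
#' @param x A `busted_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `block` (omega, alpha, mh, theta, branch_lengths).
#' @export
tidy.busted_fit <- function(x, ...) {
  og <- x$mle$omega_grid
  ag <- x$mle$alpha_grid
  K <- length(og$omegas)
  rows <- list(
    tibble::tibble(term = paste0("omega", seq_len(K)),
                   estimate = og$omegas, block = "omega"),
    tibble::tibble(term = paste0("p", seq_len(K)), estimate = og$weights,
                   block = "omega")
  )
  if (x$config$srv) {
    L <- length(ag$alphas)
    rows <- c(rows, list(
      tibble::tibble(term = paste0("alpha", seq_len(L)),
                     estimate = ag$alphas, block = "alpha"),
      tibble::tibble(term = paste0("f", seq_len(L)), estimate = ag$weights,
                     block = "alpha")))
  }
  if (x$config$mh_mode != "none") {
    mh <- tibble::tibble(term = c("delta", "psi"),
                         estimate = c(x$mle$mh$delta, x$mle$mh$psi),
                         block = "mh")
    if (x$config$mh_mode == "double") mh <- mh[1, ]
    rows <- c(rows, list(mh))
  }
  rows <- c(rows, list(
    tibble::tibble(term = paste0("theta_", c("AC", "AG", "AT", "CG",
                                             "CT", "GT")),
                   estimate = as.numeric(x$mle$theta), block = "theta"),
    tibble::tibble(term = "tree_length",
                   estimate = sum(x$mle$branch_lengths),
                   block = "branch_lengths")))
  dplyr::bind_rows(rows)
}

#' One-row model summary
#'
#' @param x A `busted_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `constrained`, `logLik`, `k`, `AICc`,
#'   `n_obs`, `tree_length`, `delta`, `psi`.
#' @export
glance.busted_fit <- function(x, ...) {
  tibble::tibble(
    model = x$config$name, constrained = x$constrained, logLik = x$lnL,
    k = x$k, AICc = x$aicc, n_obs = x$n_obs,
    tree_length = sum(x$mle$branch_lengths),
    delta = x$mle$mh$delta, psi = x$mle$mh$psi
  )
}

#' Tidy a model-test report
#'
#' @param x A `busted_modeltest`.
#' @param ... Unused.
#' @return The per-model table with weights and p-values.
#' @export
tidy.busted_modeltest <- function(x, ...) x$table

#' One-row summary of a model-test report
#'
#' @param x A `busted_modeltest`.
#' @param ... Unused.
#' @export
glance.busted_modeltest <- function(x, ...) {
  tibble::tibble(
    best_model = x$best_model, p_averaged = x$p_averaged,
    p_best = x$table$p[x$table$model == x$best_model],
    detection_pattern = paste(as.integer(x$detection_pattern),
                              collapse = ""),
    n_models = nrow(x$table)
  )
}

#' Plot a site-level LRT profile
#'
#' Bar chart of per-site contributions to the selection LRT.
#'
#' @param object A [lrt_site_profile()] result.
#' @param ... Unused.
#' @export
autoplot.site_profile <- function(object, ...) {
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = .data$site, y = .data$dlnl)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(x = "codon site",
                  y = "2 Δ log-likelihood (alt - null)",
                  title = sprintf(
                    "%d site(s) carry %.0f%% of the LRT (total = %.2f)",
                    object$n_sites_for_share, 100 * object$lrt_share,
                    object$total_lrt)) +
    ggplot2::theme_minimal()
}

#' Plot grid rejection rates
#'
#' Line plot of rejection rates per method across the scanned parameter
#' (delta, psi or omega3).
#'
#' @param object A tibble from [summarize_rejections()].
#' @param x_var Which cell variable to put on the x axis (default: the
#'   first of omega3, delta, psi, branch_scaling that varies).
#' @param ... Unused.
#' @export
plot_rejection_rates <- function(object, x_var = NULL, ...) {
  cands <- intersect(c("omega3", "delta", "psi", "branch_scaling"),
                     names(object))
  if (is.null(x_var)) {
    varying <- cands[vapply(cands, function(v) {
      length(unique(object[[v]])) > 1
    }, logical(1))]
    x_var <- if (length(varying)) varying[1] else cands[1]
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[x_var]], y = .data$rate,
                                       colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = x_var, y = "rejection rate at p ≤ 0.05") +
    ggplot2::theme_minimal()
}

#' Plot a tree colored by branch-level EBF ratio between two fits
#'
#' Colors each branch by the log ratio of its maximum empirical Bayes
#' factor under two models (values below one mean the first model has
#' less support for selection on that branch).  Values are plotted raw,
#' without clipping.
#'
#' @param ebf_a,ebf_b [branch_site_ebf()] results of the two fits.
#' @param tree The fitted tree ([ape::phylo]).
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot_ebf_tree <- function(ebf_a, ebf_b, tree, ...) {
  if (isTRUE(ebf_a$no_selective_class) ||
      isTRUE(ebf_b$no_selective_class)) {
    stop("both fits must have a positive selection class")
  }
  ratio <- apply(ebf_a$ebf, 1, max) / pmax(apply(ebf_b$ebf, 1, max),
                                           1e-300)
  lr <- log10(pmax(ratio, 1e-300))
  pal <- grDevices::colorRampPalette(c("blue", "grey70", "red"))(101)
  sc <- pmax(pmin(lr, 2), -2)
  cols <- pal[round(50 + 25 * sc) + 1]
  ape::plot.phylo(tree, edge.color = cols, ...)
  invisible(tibble::tibble(branch = names(ratio), ebf_ratio = ratio))
}
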