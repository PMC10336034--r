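#' Per-site evidence ratios between two fits
#'
#' The evidence ratio of site s is the ratio of its likelihoods under two
#' fitted models, `ER_s = P(D_s | fit_a) / P(D_s | fit_b)`; the log
#' evidence ratios sum to the total log-likelihood difference.  Evidence
#' ratios localize which sites drive the preference for one model over
#' another.
#'
#' @param fit_a,fit_b `busted_fit` objects on the same alignment and tree.
#' @return A tibble with `site`, `log_er`, `er`.
#' @export
site_evidence_ratios <- function(fit_a, fit_b) {
  sl_a <- .fit_site_lik(fit_a)
  sl_b <- .fit_site_lik(fit_b)
  if (length(sl_a$site_lnL) != length(sl_b$site_lnL)) {
    stop("fits were computed on different numbers of sites")
  }
  log_er <- sl_a$site_lnL - sl_b$site_lnL
  tibble::tibble(site = seq_along(log_er), log_er = log_er,
                 er = exp(log_er))
}

#' Branch-site empirical Bayes support for selection
#'
#' For every branch b and site s, the posterior probability that the pair
#' evolved under the selection category,
#' `P(omega_3 | D_s) = P(D_s | omega_3 at b) * p_3 / P(D_s)`, where the
#' conditional likelihood collapses the FOCAL branch's omega distribution
#' onto the selection category while all other branches keep the full
#' mixture, and `p_3` is the alignment-level mixture weight.  The
#' empirical Bayes factor is the posterior-to-prior odds ratio; it equals
#' one exactly when the data at the site are uninformative about the
#' branch.  With synonymous rate variation the site likelihoods
#' marginalize over the alpha categories with their fitted weights, in
#' both numerator and denominator.  These estimates are noisy and meant
#' for exploratory hot-spot finding, not formal site-level tests.
#'
#' @param fit An alternative-model `busted_fit` with positive selection
#'   weight `p_3 > 0`.
#' @return An object of class `branch_site_ebf`: `posterior` and `ebf`
#'   matrices (branches x sites, rows named by the child node of each
#'   branch), and `prior`.  If `p_3 = 0`, returns a marker object with
#'   `no_selective_class = TRUE`.
#' @export
branch_site_ebf <- function(fit) {
  stopifnot(inherits(fit, "busted_fit"))
  og <- fit$mle$omega_grid
  K <- length(og$omegas)
  prior <- og$weights[K]
  if (prior <= 0) {
    return(structure(list(no_selective_class = TRUE, prior = 0),
                     class = "branch_site_ebf"))
  }
  base <- .fit_site_lik(fit)
  E <- nrow(fit$prep$tp$edge)
  S <- fit$prep$n_sites
  post <- matrix(NA_real_, E, S)
  fw <- fit$mle$alpha_grid$weights
  for (e in seq_len(E)) {
    bp <- matrix(og$weights, E, K, byrow = TRUE)
    bp[e, ] <- c(rep(0, K - 1), 1)
    cond <- .fit_site_lik(fit, branch_p = bp)
    # P(D_s | omega_3 at b) * p3 / P(D_s), alpha marginalized in both
    lr <- exp(cond$pattern_lnL - base$pattern_lnL)
    post[e, ] <- (lr * prior)[base$site_to_pattern]
  }
  post <- pmin(pmax(post, 0), 1)
  ebf <- (post / pmax(1 - post, 1e-300)) / (prior / (1 - prior))
  tips <- fit$prep$tp$tree$tip.label
  ch <- fit$prep$tp$edge[, 2]
  rn <- ifelse(ch <= length(tips), tips[ch], paste0("node", ch))
  dimnames(post) <- dimnames(ebf) <- list(rn, NULL)
  structure(list(posterior = post, ebf = ebf, prior = prior),
            class = "branch_site_ebf")
}

#' @export
print.branch_site_ebf <- function(x, ...) {
  if (isTRUE(x$no_selective_class)) {
    cat("<branch_site_ebf: no selective class (p3 = 0)>\n")
  } else {
    cat("<branch_site_ebf:", nrow(x$ebf), "branches x", ncol(x$ebf),
        "sites | prior p3 =", format(x$prior, digits = 4), "|",
        sum(x$ebf > 100), "pairs with EBF > 100>\n")
  }
  invisible(x)
}

#' Site-level profile of the selection LRT
#'
#' Decomposes the alignment-wide selection LRT into per-site
#' contributions, `2 * (log P(D_s | alt) - log P(D_s | null))`, and
#' summarizes how concentrated the signal is: the smallest number of
#' sites whose positive contributions reach a share (default 80%) of the
#' total statistic, and the number of branch-site pairs with empirical
#' Bayes factors above a cutoff (default 100).  A handful of sites
#' carrying the bulk of the statistic is a red flag for alignment-error
#' driven detections.
#'
#' @param alt_fit,null_fit The alternative and omega3 = 1 fits of one
#'   model.
#' @param lrt_share Share of the total LRT for the site count.
#' @param ebf_cut EBF threshold for the pair count.
#' @param ebf Optional precomputed [branch_site_ebf()] of `alt_fit`.
#' @return An object of class `site_profile`: `sites` (tibble with
#'   `site`, `dlnl`, `contribution`), `total_lrt`, `n_sites_for_share`,
#'   `n_pairs_ebf_gt_cut`, `lrt_share`, `ebf_cut`.
#' @export
lrt_site_profile <- function(alt_fit, null_fit, lrt_share = 0.80,
                             ebf_cut = 100, ebf = NULL) {
  sl_a <- .fit_site_lik(alt_fit)
  sl_0 <- .fit_site_lik(null_fit)
  dlnl <- 2 * (sl_a$site_lnL - sl_0$site_lnL)
  total <- sum(dlnl)
  ord <- order(dlnl, decreasing = TRUE)
  n80 <- if (total <= 0) 0L else {
    cum <- cumsum(pmax(dlnl[ord], 0))
    as.integer(which(cum >= lrt_share * total)[1])
  }
  if (is.null(ebf)) ebf <- branch_site_ebf(alt_fit)
  n_pairs <- if (isTRUE(ebf$no_selective_class)) 0L else {
    sum(ebf$ebf > ebf_cut)
  }
  structure(list(
    sites = tibble::tibble(site = seq_along(dlnl), dlnl = dlnl,
                           contribution = if (total > 0) dlnl / total
                                          else rep(0, length(dlnl))),
    total_lrt = total, n_sites_for_share = n80,
    n_pairs_ebf_gt_cut = n_pairs,
    lrt_share = lrt_share, ebf_cut = ebf_cut
  ), class = "site_profile")
}

#' @export
print.site_profile <- function(x, ...) {
  cat("<site_profile: total LRT =", format(x$total_lrt, digits = 5), "|",
      x$n_sites_for_share, "site(s) carry", sprintf("%.0f%%",
                                                    100 * x$lrt_share),
      "of the statistic |", x$n_pairs_ebf_gt_cut, "branch-site pairs",
      "with EBF >", x$ebf_cut, ">\n")
  invisible(x)
}

#' Write a per-site diagnostic table
#'
#' Tab-separated table of per-site evidence ratios and LRT contributions.
#'
#' @param profile A [lrt_site_profile()].
#' @param ers Optional [site_evidence_ratios()] tibble to merge.
#' @param path Output file.
#' @export
write_site_table <- function(profile, path, ers = NULL) {
  tab <- profile$sites
  if (!is.null(ers)) tab <- dplyr::left_join(tab, ers, by = "site")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write branch-site EBF matrices as JSON
#'
#' @param ebf A [branch_site_ebf()].
#' @param path Output file.
#' @export
write_ebf_json <- function(ebf, path) {
  stopifnot(inherits(ebf, "branch_site_ebf"))
  doc <- if (isTRUE(ebf$no_selective_class)) {
    list(no_selective_class = TRUE)
  } else {
    list(prior = ebf$prior,
         ebf = setNames(lapply(seq_len(nrow(ebf$ebf)), function(i) {
           unname(ebf$ebf[i, ])
         }), rownames(ebf$ebf)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
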