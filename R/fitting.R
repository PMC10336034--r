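#' Free-parameter counts for the model hierarchy
#'
#' Parameters per model: `B` branch lengths, 5 nucleotide biases, 9
#' positional frequencies, `2K - 1` omega-mixture hyperparameters,
#' `2(L - 1)` alpha-mixture hyperparameters when synonymous rate variation
#' is modeled, and the multiple-hit rates (delta, and psi when triples are
#' allowed).  For the default configurations this reproduces the closed
#' forms `B + 13 + 2K` (BUSTED), `B + 11 + 2(K + L)` (+S), `B + 15 + 2K`
#' (+MH) and `B + 13 + 2(K + L)` (+S+MH); the intermediate +S+2H model has
#' one parameter more than +S.
#'
#' @param config A [model_config()].
#' @param n_branches Number of free branches `B` (see [n_free_branches()]).
#' @return Integer parameter count.
#' @export
count_parameters <- function(config, n_branches) {
  stopifnot(inherits(config, "model_config"))
  if (n_branches < 1) stop("n_branches must be >= 1")
  n_mh <- switch(config$mh_mode, none = 0L, double = 1L,
                 "double+triple" = 2L)
  n_srv <- if (config$srv) 2L * (config$L - 1L) else 0L
  as.integer(n_branches + 5L + 9L + (2L * config$K - 1L) + n_srv + n_mh)
}

# ---------------------------------------------------------------------------
# Parameter transforms.  The optimizer works on a boxed vector x; blocks:
#   omega:  s_1..s_{K-1} in [0,1] (cumulative products give the below-one
#           rates), u with omega_K = 1 + exp(u) (alternative only), and
#           K-1 stick-breaking weight fractions in [0,1].
#   alpha:  L-1 ratio fractions in [0,1] (rates relative to the top bin)
#           and L-1 stick fractions; the overall scale is solved from the
#           unit-mean constraint.
#   mh:     delta (and psi) boxed in [0, 15].
#   theta:  log-rates in [-8, 8] for AC, AT, CG, CT, GT.
#   branch: either one log tree-scale factor or per-branch log-lengths.
# ---------------------------------------------------------------------------

.sticks_to_weights <- function(q) {
  K <- length(q) + 1L
  p <- numeric(K)
  rem <- 1
  for (i in seq_along(q)) {
    p[i] <- rem * q[i]
    rem <- rem * (1 - q[i])
  }
  p[K] <- rem
  p
}

.weights_to_sticks <- function(p) {
  K <- length(p)
  p <- pmax(p, 1e-12) / sum(pmax(p, 1e-12))
  q <- numeric(K - 1L)
  rem <- 1
  for (i in seq_len(K - 1L)) {
    q[i] <- min(max(p[i] / rem, 1e-9), 1 - 1e-9)
    rem <- rem * (1 - q[i])
  }
  q
}

.omega_pack <- function(og, constrained) {
  K <- length(og$omegas)
  om <- og$omegas
  if (K == 1L) {
    par <- if (constrained) numeric(0) else log(max(om[1], 1e-8))
    return(list(par = par,
                lower = rep(-20, length(par)), upper = rep(12, length(par))))
  }
  s <- numeric(K - 1L)
  s[K - 1L] <- min(max(om[K - 1L], 0), 1)
  if (K > 2L) {
    for (j in seq_len(K - 2L)) {
      s[j] <- if (om[j + 1L] > 0) min(om[j] / om[j + 1L], 1) else 1
    }
  }
  q <- .weights_to_sticks(og$weights)
  if (constrained) {
    list(par = c(s, q), lower = rep(0, 2 * (K - 1L)),
         upper = rep(1, 2 * (K - 1L)))
  } else {
    u <- log(max(om[K] - 1, 1e-10))
    list(par = c(s, u, q),
         lower = c(rep(0, K - 1L), -25, rep(0, K - 1L)),
         upper = c(rep(1, K - 1L), 12, rep(1, K - 1L)))
  }
}

.omega_unpack <- function(x, K, constrained) {
  if (K == 1L) {
    om <- if (constrained) 1 else exp(x[1])
    return(omega_grid(om, 1))
  }
  s <- x[seq_len(K - 1L)]
  i <- K - 1L
  if (constrained) {
    omK <- 1
  } else {
    i <- i + 1L
    omK <- 1 + exp(x[i])
  }
  q <- x[i + seq_len(K - 1L)]
  om <- numeric(K)
  om[K] <- omK
  om[K - 1L] <- s[K - 1L]
  if (K > 2L) for (j in (K - 2L):1L) om[j] <- om[j + 1L] * s[j]
  omega_grid(om, .sticks_to_weights(q))
}

.alpha_pack <- function(ag) {
  L <- length(ag$alphas)
  if (L == 1L) return(list(par = numeric(0), lower = numeric(0),
                           upper = numeric(0)))
  a <- ag$alphas
  r <- a / max(a[L], 1e-12)
  g <- numeric(L - 1L)
  for (j in seq_len(L - 1L)) {
    g[j] <- if (r[j + 1L] > 0) min(max(r[j] / r[j + 1L], 0), 1) else 1
  }
  h <- .weights_to_sticks(ag$weights)
  list(par = c(g, h), lower = rep(0, 2 * (L - 1L)),
       upper = rep(1, 2 * (L - 1L)))
}

.alpha_unpack <- function(x, L) {
  if (L == 1L) return(alpha_grid(1, 1))
  g <- x[seq_len(L - 1L)]
  h <- x[L - 1L + seq_len(L - 1L)]
  r <- numeric(L)
  r[L] <- 1
  for (j in (L - 1L):1L) r[j] <- r[j + 1L] * g[j]
  alpha_grid(r, .sticks_to_weights(h))  # constructor rescales to mean one
}

# Active blocks: character subset of c("omega","alpha","mh","theta","branch")
.make_transform <- function(config, base, constrained, active,
                            branch_mode = c("scale", "full")) {
  branch_mode <- match.arg(branch_mode)
  K <- config$K
  L <- config$L
  par <- numeric(0); lower <- numeric(0); upper <- numeric(0)
  idx <- list()
  add <- function(name, block) {
    if (length(block$par)) {
      idx[[name]] <<- length(par) + seq_along(block$par)
      par <<- c(par, block$par)
      lower <<- c(lower, block$lower)
      upper <<- c(upper, block$upper)
    } else idx[[name]] <<- integer(0)
  }
  if ("omega" %in% active) add("omega", .omega_pack(base$params$omega_grid,
                                                   constrained))
  if ("alpha" %in% active && config$srv) {
    add("alpha", .alpha_pack(base$params$alpha_grid))
  }
  if ("mh" %in% active && config$mh_mode != "none") {
    n_mh <- if (config$mh_mode == "double") 1L else 2L
    mh0 <- c(base$params$mh$delta, base$params$mh$psi)[seq_len(n_mh)]
    add("mh", list(par = mh0, lower = rep(0, n_mh), upper = rep(15, n_mh)))
  }
  if ("theta" %in% active) {
    th <- as.numeric(base$params$theta)[c(1, 3, 4, 5, 6)]
    add("theta", list(par = log(pmax(th, 1e-8)), lower = rep(-8, 5),
                      upper = rep(8, 5)))
  }
  if ("branch" %in% active) {
    if (branch_mode == "scale") {
      add("branch", list(par = 0, lower = -6, upper = 6))
    } else {
      add("branch", list(par = log(pmax(base$t, 1e-7)),
                         lower = rep(log(1e-7), length(base$t)),
                         upper = rep(log(25), length(base$t))))
    }
  }
  unpack <- function(x) {
    p <- base$params
    t <- base$t
    if (length(idx$omega) || ("omega" %in% active && K == 1L)) {
      p$omega_grid <- .omega_unpack(x[idx$omega], K, constrained)
    }
    if (length(idx$alpha)) p$alpha_grid <- .alpha_unpack(x[idx$alpha], L)
    if (length(idx$mh)) {
      v <- x[idx$mh]
      p$mh <- mh_rates(v[1], if (length(v) > 1) v[2] else 0)
    }
    if (length(idx$theta)) {
      th <- exp(x[idx$theta])
      p$theta <- nucleotide_bias(th[1], th[2], th[3], th[4], th[5])
    }
    if (length(idx$branch)) {
      t <- if (branch_mode == "scale") base$t * exp(x[idx$branch])
           else exp(x[idx$branch])
    }
    list(params = p, t = t)
  }
  list(par = par, lower = lower, upper = upper, unpack = unpack, idx = idx)
}

# Nucleotide-level GTR initialization of branch lengths and biases.
.nuc_init <- function(aln, tree) {
  seqs <- alignment_sequences(aln)
  chm <- do.call(rbind, strsplit(seqs, ""))
  rownames(chm) <- names(seqs)
  pd <- phangorn::phyDat(chm, type = "DNA")
  tp <- .prep_tree(tree, aln)
  tr <- tp$tree
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  fit <- phangorn::pml(tr, pd, model = "GTR")
  fit <- suppressWarnings(phangorn::optim.pml(
    fit, optEdge = TRUE, optQ = TRUE, model = "GTR",
    control = phangorn::pml.control(trace = 0, epsilon = 1e-8, maxit = 12)
  ))
  qv <- fit$Q  # order: AC, AG, AT, CG, CT, GT
  th <- qv / qv[2]
  list(
    theta = nucleotide_bias(th[1], th[3], th[4], th[5], th[6]),
    t = pmax(fit$tree$edge.length, 1e-7),
    tree = fit$tree
  )
}

.default_start <- function(config, constrained) {
  K <- config$K
  om <- if (K == 1L) {
    omega_grid(if (constrained) 1 else 1.5, 1)
  } else {
    lows <- seq(0.2, 0.8, length.out = K - 1L)
    omega_grid(c(lows, if (constrained) 1 else 2), rep(1 / K, K))
  }
  ag <- if (config$srv && config$L > 1L) {
    alpha_grid(seq(0.5, 1.5, length.out = config$L), rep(1 / config$L,
                                                         config$L))
  } else alpha_grid(1, 1)
  mh <- if (config$mh_mode == "none") mh_rates(0, 0) else {
    mh_rates(0.05, if (config$mh_mode == "double+triple") 0.02 else 0)
  }
  list(omega_grid = om, alpha_grid = ag, mh = mh)
}

.neg_loglik_fn <- function(prep, config, transform, s_fixed = -1) {
  function(x) {
    st <- try(transform$unpack(x), silent = TRUE)
    if (inherits(st, "try-error")) return(1e10)
    res <- try(.core_call(prep, st$params, t = st$t, s_fixed = s_fixed),
               silent = TRUE)
    if (inherits(res, "try-error")) return(1e10)
    lsl <- res$log_site_lik
    fw <- st$params$alpha_grid$weights
    m <- apply(lsl, 1, max)
    if (any(!is.finite(m))) return(1e10)
    lnL <- sum(prep$weights * (m + log(as.vector(exp(lsl - m) %*% fw))))
    if (!is.finite(lnL)) return(1e10)
    -lnL
  }
}

#' Fit one model of the BUSTED hierarchy by maximum likelihood
#'
#' Maximum-likelihood estimation under a [model_config()].  Positional
#' frequencies are estimated once by [cf3x4()] and held fixed (they are
#' counted as parameters but not iterated, following standard practice for
#' frequency parameters).  Unseeded fits initialize branch lengths and
#' nucleotide biases from a nucleotide-level GTR fit; seeded fits start at
#' the nested model's optimum (guaranteeing the monotone-nesting property).
#' Optimization proceeds in stages: a quasi-Newton pass over the mixture
#' and multiple-hit parameters with a single tree-scale factor, then a
#' joint pass adding the nucleotide biases and (optionally) individual
#' branch lengths.
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] with branch lengths (substitutions per
#'   nucleotide site); used as the fixed topology and initial lengths.
#' @param config A [model_config()].
#' @param constrain_omega3 If `TRUE`, fit the null model with the selection
#'   category pinned at `omega_K = 1`.
#' @param seed_fit Optional `busted_fit` of a nested model used to seed the
#'   start values, or a list of candidate fits, in which case the start
#'   with the highest log-likelihood (after adaptation to this
#'   configuration) is used.
#' @param starts Number of optimization starts; starts beyond the first
#'   jitter the mixture hyperparameters (seeded RNG, restored on exit).
#' @param seed Integer seed controlling the jittered restarts.
#' @param branch_mode `"full"` optimizes every branch length; `"scale"`
#'   optimizes a single tree-scale factor (faster; used by the simulation
#'   harnesses).
#' @param control List of optimizer settings: `rel_tol`, `iter_max`,
#'   `eval_max`.
#' @return An object of class `busted_fit`: configuration, MLEs (`theta`,
#'   `pi`, `omega_grid`, `alpha_grid`, `mh`, branch lengths), `lnL`, `k`,
#'   `aicc`, `n_obs` and a `convergence` record.
#' @export
fit_model <- function(aln, tree, config, constrain_omega3 = FALSE,
                      seed_fit = NULL, starts = 3, seed = 1,
                      branch_mode = c("full", "scale"), control = list()) {
  stopifnot(inherits(aln, "codon_alignment"), inherits(config,
                                                       "model_config"))
  branch_mode <- match.arg(branch_mode)
  ctl <- utils::modifyList(list(rel_tol = 1e-6, iter_max = 250,
                                eval_max = 4000, restart_tol = 2e-3,
                                max_restarts = 2), control)
  prep <- .ll_prep(aln, tree)
  pi <- cf3x4(codon_counts(aln))

  build_base <- function(sf) {
    theta0 <- sf$mle$theta
    t0 <- sf$mle$branch_lengths
    if (length(t0) != nrow(prep$tp$edge)) {
      stop("seed fit was computed on a different topology")
    }
    s0 <- .default_start(config, constrain_omega3)
    og0 <- sf$mle$omega_grid
    if (length(og0$omegas) != config$K) og0 <- s0$omega_grid
    if (constrain_omega3) {
      og0 <- omega_grid(c(og0$omegas[-config$K],
                          if (config$K > 1) 1 else 1), og0$weights)
    }
    ag0 <- sf$mle$alpha_grid
    if (!config$srv) ag0 <- alpha_grid(1, 1)
    if (config$srv && length(ag0$alphas) != config$L) {
      # a seed without rate variation sits at the degenerate all-equal
      # point of the alpha mixture (zero gradient); start spread instead
      ag0 <- s0$alpha_grid
    }
    mh0 <- sf$mle$mh
    if (config$mh_mode == "none") mh0 <- mh_rates(0, 0)
    if (config$mh_mode == "double") mh0 <- mh_rates(mh0$delta, 0)
    list(params = list(theta = theta0, pi = pi, omega_grid = og0,
                       alpha_grid = ag0, mh = mh0,
                       strict_nonsyn_psi = config$strict_nonsyn_psi),
         t = t0)
  }
  # the true log-likelihood of a start point (scaling consistent with its
  # own parameters); used to choose among candidate seeds
  start_lnL <- function(base) {
    res <- try(.core_call(prep, base$params, t = base$t), silent = TRUE)
    if (inherits(res, "try-error")) return(-Inf)
    lsl <- res$log_site_lik
    m <- apply(lsl, 1, max)
    sum(prep$weights * (m + log(as.vector(exp(lsl - m) %*%
                                            base$params$alpha_grid$weights))))
  }

  if (!is.null(seed_fit)) {
    cands <- if (inherits(seed_fit, "busted_fit")) list(seed_fit)
             else seed_fit
    stopifnot(length(cands) >= 1,
              all(vapply(cands, inherits, logical(1), "busted_fit")))
    bases <- lapply(cands, build_base)
    base <- if (length(bases) == 1) bases[[1]] else {
      bases[[which.max(vapply(bases, start_lnL, numeric(1)))]]
    }
  } else {
    ni <- .nuc_init(aln, tree)
    s0 <- .default_start(config, constrain_omega3)
    base <- list(params = list(theta = ni$theta, pi = pi,
                               omega_grid = s0$omega_grid,
                               alpha_grid = s0$alpha_grid, mh = s0$mh,
                               strict_nonsyn_psi = config$strict_nonsyn_psi),
                 t = ni$t)
  }

  run_stages <- function(base) {
    iters <- 0L
    # freeze the generator scaling at the start values: the free tree-scale
    # parameter absorbs the reparameterization, so the optimum is unchanged;
    # branch lengths are converted back to substitutions/nucleotide at the
    # end.  Freezing keeps the transition-matrix caches hot during
    # finite-difference passes.
    s0 <- 3 / .flux_constant(base$params$theta, pi,
                             base$params$omega_grid, base$params$mh,
                             prep$code,
                             isTRUE(base$params$strict_nonsyn_psi))
    opt_pass <- function(cur, active, bm) {
      tr <- .make_transform(config, cur, constrain_omega3, active,
                            branch_mode = bm)
      o <- nlminb(tr$par, .neg_loglik_fn(prep, config, tr, s0),
                  lower = tr$lower, upper = tr$upper,
                  control = list(rel.tol = ctl$rel_tol,
                                 iter.max = ctl$iter_max,
                                 eval.max = ctl$eval_max))
      st <- tr$unpack(o$par)
      st$params$pi <- pi
      list(cur = st, obj = o$objective, iters = o$iterations,
           message = o$message, convergence = o$convergence)
    }
    # stage 1: distributions + MH rates + tree scale (restart until the
    # improvement stalls; restarting resets the trust region cheaply)
    p1 <- opt_pass(base, c("omega", "alpha", "mh", "branch"), "scale")
    iters <- iters + p1$iters
    for (r in seq_len(ctl$max_restarts)) {
      p1b <- opt_pass(p1$cur, c("omega", "alpha", "mh", "branch"),
                      "scale")
      iters <- iters + p1b$iters
      improved <- p1$obj - p1b$obj
      if (p1b$obj <= p1$obj) p1 <- p1b
      if (improved < ctl$restart_tol) break
    }
    cur <- p1$cur
    obj <- p1$obj
    msg <- p1$message
    conv <- p1$convergence
    if (branch_mode == "full") {
      # stage 2: joint pass adding nucleotide biases and branch lengths
      p2 <- opt_pass(cur, c("omega", "alpha", "mh", "theta", "branch"),
                     "full")
      if (p2$obj <= obj) {
        iters <- iters + p2$iters
        cur <- p2$cur
        obj <- p2$obj
        msg <- p2$message
        conv <- p2$convergence
      }
    }
    # convert branch lengths to substitutions/nucleotide under the MLEs
    s_mle <- 3 / .flux_constant(cur$params$theta, pi,
                                cur$params$omega_grid, cur$params$mh,
                                prep$code,
                                isTRUE(cur$params$strict_nonsyn_psi))
    cur$t <- cur$t * s0 / s_mle
    list(base = cur, obj = obj, iters = iters,
         message = msg, convergence = conv)
  }

  jitter_base <- function(base, amount = 0.25) {
    s0 <- .default_start(config, constrain_omega3)
    b <- base
    og <- b$params$omega_grid
    K <- length(og$omegas)
    om <- pmax(og$omegas * exp(runif(K, -amount, amount)), 0)
    om <- sort(om)
    if (K > 1) {
      om[seq_len(K - 1L)] <- pmin(om[seq_len(K - 1L)], 1)
      om[K] <- if (constrain_omega3) 1 else max(om[K], 1 + 1e-6)
    } else if (constrain_omega3) om <- 1
    w <- og$weights * exp(runif(K, -amount, amount))
    b$params$omega_grid <- omega_grid(om, w / sum(w))
    if (config$srv && config$L > 1L) {
      ag <- b$params$alpha_grid
      a <- pmax(ag$alphas * exp(runif(config$L, -amount, amount)), 1e-4)
      w <- ag$weights * exp(runif(config$L, -amount, amount))
      b$params$alpha_grid <- alpha_grid(sort(a), w / sum(w))
    }
    if (config$mh_mode != "none") {
      b$params$mh <- mh_rates(
        max(b$params$mh$delta, 0.02) * exp(runif(1, -amount, amount)),
        if (config$mh_mode == "double+triple") {
          max(b$params$mh$psi, 0.01) * exp(runif(1, -amount, amount))
        } else 0)
    }
    b
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed %% .Machine$integer.max)

  best <- run_stages(base)
  # guard the monotone-nesting property: if a spread start ended below the
  # seed's optimum, continue once from the exact nested expansion
  seed_best_lnL <- if (is.null(seed_fit)) -Inf else {
    max(vapply(if (inherits(seed_fit, "busted_fit")) list(seed_fit)
               else seed_fit, function(f) f$lnL, numeric(1)))
  }
  if (!is.null(seed_fit) && !constrain_omega3 &&
      -best$obj < seed_best_lnL - 1e-6) {
    base2 <- base
    if (config$srv) {
      base2$params$alpha_grid <- alpha_grid(rep(1, config$L),
                                            rep(1 / config$L, config$L))
    }
    cand <- try(run_stages(base2), silent = TRUE)
    if (!inherits(cand, "try-error") && cand$obj < best$obj) best <- cand
  }
  if (starts > 1) {
    for (st in seq_len(starts - 1L)) {
      cand <- try(run_stages(jitter_base(base)), silent = TRUE)
      if (!inherits(cand, "try-error") && cand$obj < best$obj - 1e-9) {
        best <- cand
      }
    }
  }

  lnL <- -best$obj
  B <- n_free_branches(prep$tp$tree)
  k <- count_parameters(config, B) - as.integer(constrain_omega3)
  n_obs <- prep$n_seq * prep$n_sites
  aicc <- -2 * lnL + 2 * k + 2 * k * (k + 1) / max(n_obs - k - 1, 1)

  mle <- best$base$params
  mle$branch_lengths <- best$base$t
  fit <- structure(list(
    config = config, constrained = constrain_omega3,
    mle = mle, lnL = lnL, k = k, aicc = aicc, n_obs = n_obs,
    tree = {
      tr <- prep$tp$tree
      tr$edge.length <- best$base$t
      tr
    },
    convergence = list(iterations = best$iters, status = best$message,
                       code = best$convergence),
    prep = prep
  ), class = "busted_fit")
  .warn_overfit(fit)
  fit
}

# Warn on signatures of an overparameterized mixture: near-identical
# adjacent rates or vanishing weights.
.warn_overfit <- function(fit) {
  check_grid <- function(vals, wts, label) {
    if (length(vals) < 2) return(invisible())
    rel <- abs(diff(vals)) / pmax(abs(vals[-1]), 1e-12)
    if (any(rel < 1e-3) || any(wts < 1e-4)) {
      warning("possible overfitting: ", label,
              " mixture has nearly identical rates or a vanishing weight",
              call. = FALSE)
    }
  }
  check_grid(fit$mle$omega_grid$omegas, fit$mle$omega_grid$weights, "omega")
  if (fit$config$srv) {
    check_grid(fit$mle$alpha_grid$alphas, fit$mle$alpha_grid$weights,
               "alpha")
  }
  invisible(fit)
}

#' @export
print.busted_fit <- function(x, ...) {
  cat("<busted_fit:", x$config$name,
      if (x$constrained) "(null, omega3 = 1)" else "(alternative)",
      "| lnL =", format(x$lnL, digits = 10), "| k =", x$k,
      "| AICc =", format(x$aicc, digits = 10), ">\n")
  og <- x$mle$omega_grid
  cat("  omega:", paste(sprintf("%.4g@%.1f%%", og$omegas,
                                100 * og$weights), collapse = ", "), "\n")
  if (x$config$srv) {
    ag <- x$mle$alpha_grid
    cat("  alpha:", paste(sprintf("%.4g@%.1f%%", ag$alphas,
                                  100 * ag$weights), collapse = ", "), "\n")
  }
  if (x$config$mh_mode != "none") {
    cat("  delta =", format(x$mle$mh$delta, digits = 4),
        " psi =", format(x$mle$mh$psi, digits = 4), "\n")
  }
  invisible(x)
}

# Site likelihood table at the fitted MLEs (patterns x alpha categories).
.fit_site_lik <- function(fit, branch_p = NULL) {
  res <- .core_call(fit$prep, fit$mle, branch_p = branch_p,
                    t = fit$mle$branch_lengths)
  .site_lik(res, fit$prep, fit$mle)
}

#' Recompute the log-likelihood of a fitted model
#'
#' Evaluates the likelihood at the stored MLEs (a fixed-point check and the
#' entry point for site-level diagnostics).
#'
#' @param fit A `busted_fit`.
#' @return A `site_lik` object (see [log_likelihood()]).
#' @export
fitted_site_likelihood <- function(fit) {
  stopifnot(inherits(fit, "busted_fit"))
  .fit_site_lik(fit)
}
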