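#' Sampler configuration for the Bayesian mixture model
#'
#' Settings for the Metropolis-Hastings sampler that infers mixture
#' coefficients over surrogate clusters. Defaults follow the published
#' algorithm: 200,000 iterations thinned every 1,000, 50 independent runs
#' combined by posterior weight, concentration parameters started at 0.5
#' under a Uniform(0, 10) hyperprior, a Normal(sd = 0.2) concentration
#' proposal, and a simplex proposal that perturbs ten entries by Y/5 with
#' Y ~ Uniform(0, 0.1).
#'
#' @param iterations Total MCMC iterations per run; must be a multiple of
#'   `thin`.
#' @param thin Thinning interval for retained states.
#' @param runs Number of independent runs to combine.
#' @param lambda_init Initial concentration value (broadcast over
#'   surrogates); also the Dirichlet parameter for the initial simplex draw.
#' @param lambda_bounds Support of the uniform hyperprior on each
#'   concentration parameter.
#' @param lambda_proposal_sd Standard deviation of the concentration
#'   random-walk proposal.
#' @param beta_proposal_scale Upper bound of the uniform step size Y.
#' @param moves_per_direction How many entries receive +Y/5 (and how many
#'   -Y/5) per proposal, sampled with replacement.
#' @param clamp_eps Numerical-stability clamp for perturbed simplex entries.
#' @param effective_total Pseudo-count total used to evaluate the
#'   multinomial likelihood on normalized copying fractions. `NULL` (the
#'   default) uses each recipient's own total copied length, rounded.
#' @param fix_lambda Optional fixed value for all concentration parameters;
#'   disables the concentration update entirely.
#' @param min_report Proportions below this threshold are zeroed and the
#'   remainder renormalized in the reported estimate (0 keeps everything).
#' @return A list of class `sourcefind_config`.
#' @export
sourcefind_config <- function(iterations = 200000L,
                              thin = 1000L,
                              runs = 50L,
                              lambda_init = 0.5,
                              lambda_bounds = c(0, 10),
                              lambda_proposal_sd = 0.2,
                              beta_proposal_scale = 0.1,
                              moves_per_direction = 5L,
                              clamp_eps = 1e-7,
                              effective_total = NULL,
                              fix_lambda = NULL,
                              min_report = 0) {
  stopifnot(iterations >= 1, thin >= 1, iterations %% thin == 0,
            runs >= 1, lambda_proposal_sd > 0, beta_proposal_scale > 0,
            moves_per_direction >= 1, clamp_eps > 0,
            length(lambda_bounds) == 2, lambda_bounds[1] < lambda_bounds[2],
            min_report >= 0, min_report < 1)
  if (!is.null(effective_total)) stopifnot(effective_total > 0)
  structure(list(iterations = as.integer(iterations), thin = as.integer(thin),
                 runs = as.integer(runs), lambda_init = lambda_init,
                 lambda_bounds = lambda_bounds,
                 lambda_proposal_sd = lambda_proposal_sd,
                 beta_proposal_scale = beta_proposal_scale,
                 moves_per_direction = as.integer(moves_per_direction),
                 clamp_eps = clamp_eps, effective_total = effective_total,
                 fix_lambda = fix_lambda, min_report = min_report),
            class = "sourcefind_config")
}

#' Mixture copying probabilities
#'
#' The donor-level probability vector implied by simplex weights over
#' surrogate profiles: `p_d = sum_s beta_s * f_d^s`.
#'
#' @param beta Simplex weight vector of length S.
#' @param profiles Surrogate profile tibble (see [surrogate_profiles()]) or
#'   an S x D numeric matrix of profile frequencies.
#' @return Numeric vector of length D summing to 1.
#' @export
mixture_probs <- function(beta, profiles) {
  f <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (length(beta) != nrow(f)) {
    abort(sprintf("beta has length %d but there are %d profiles",
                  length(beta), nrow(f)))
  }
  as.vector(beta %*% f)
}

#' Multinomial log-likelihood of a copying vector
#'
#' Evaluates the continuous (log-gamma) generalization of the multinomial
#' log-pmf for pseudo-counts `counts` under donor probabilities `p`:
#' `lgamma(N+1) - sum(lgamma(counts+1)) + sum(counts * log(p))`. Donor
#' probabilities are floored at 1e-300 so donors copied by the recipient but
#' absent from every surrogate incur a huge finite penalty rather than
#' `-Inf`. Reduces exactly to the multinomial log-pmf for integer counts.
#'
#' @param counts Non-negative pseudo-count vector (normalized copying
#'   fractions times an effective total).
#' @param p Donor probability vector, same length.
#' @return Log-likelihood (scalar).
#' @export
copying_loglik <- function(counts, p) {
  stopifnot(length(counts) == length(p), all(counts >= 0))
  p <- pmax(p, 1e-300)
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) + sum(counts * log(p))
}

#' Dirichlet log-density
#'
#' Log density of `Dirichlet(lambda)` at a simplex point; the prior on the
#' mixture coefficients.
#'
#' @param beta Interior simplex vector.
#' @param lambda Positive concentration vector of the same length.
#' @return Log density (scalar).
#' @export
dirichlet_logpdf <- function(beta, lambda) {
  stopifnot(length(beta) == length(lambda), all(lambda > 0))
  sum((lambda - 1) * log(beta)) + lgamma(sum(lambda)) - sum(lgamma(lambda))
}

#' Propose a new simplex state
#'
#' One Metropolis-Hastings proposal for the mixture coefficients: draw a
#' single step size `Y ~ Uniform(0, scale)`, add `Y/5` to each of
#' `moves` surrogates sampled with replacement, subtract `Y/5` from each of
#' `moves` surrogates sampled with replacement, clamp every touched entry
#' into `[eps, 1 - eps]`, and renormalize to sum 1. Uses R's global RNG.
#'
#' @param beta Current simplex vector.
#' @param scale Upper bound for Y.
#' @param moves Entries perturbed per direction.
#' @param eps Stability clamp.
#' @return Proposed simplex vector.
#' @export
propose_beta <- function(beta, scale = 0.1, moves = 5L, eps = 1e-7) {
  s <- length(beta)
  y <- runif(1, 0, scale)
  up <- sample.int(s, moves, replace = TRUE)
  dn <- sample.int(s, moves, replace = TRUE)
  step <- y / moves
  for (i in up) beta[i] <- min(beta[i] + step, 1 - eps)
  for (i in dn) beta[i] <- max(beta[i] - step, eps)
  beta / sum(beta)
}

#' Metropolis-Hastings acceptance decision
#'
#' Accepts with probability `min(exp(log_new - log_old), 1)`, computed in
#' log space.
#'
#' @param log_new,log_old Log posterior densities of the proposed and
#'   current states.
#' @return `TRUE` to accept.
#' @export
mh_accept <- function(log_new, log_old) {
  if (is.nan(log_new) || is.nan(log_old)) abort("NaN log posterior")
  log_new >= log_old || log(runif(1)) < (log_new - log_old)
}

#' Update concentration parameters
#'
#' One sweep of single-site Metropolis-Hastings updates of the Dirichlet
#' concentration vector: each entry receives a `Normal(sd)` random-walk
#' proposal, automatically rejected outside `bounds` (the uniform
#' hyperprior's support), otherwise accepted with probability
#' `min(Pr(beta | lambda') / Pr(beta | lambda), 1)`.
#'
#' @param lambda Current concentration vector.
#' @param beta Current simplex state.
#' @param sd Proposal standard deviation.
#' @param bounds Hyperprior support.
#' @return Updated concentration vector.
#' @export
update_lambda <- function(lambda, beta, sd = 0.2, bounds = c(0, 10)) {
  log_beta <- log(beta)
  lam_sum <- sum(lambda)
  for (s in seq_along(lambda)) {
    prop <- rnorm(1, lambda[s], sd)
    if (prop <= bounds[1] || prop > bounds[2]) next
    # density ratio changing only entry s
    log_r <- lgamma(lam_sum - lambda[s] + prop) - lgamma(lam_sum) -
      lgamma(prop) + lgamma(lambda[s]) +
      (prop - lambda[s]) * log_beta[s]
    if (log_r >= 0 || log(runif(1)) < log_r) {
      lam_sum <- lam_sum - lambda[s] + prop
      lambda[s] <- prop
    }
  }
  lambda
}

#' Run one MCMC chain for a single recipient
#'
#' Alternates the simplex proposal and the concentration sweep for
#' `config$iterations` iterations, starting from a
#' `Dirichlet(lambda_init, ..., lambda_init)` draw, and returns the thinned
#' states. Uses R's global RNG; seed it for reproducibility.
#'
#' @param fractions Recipient's normalized copying fractions (length D).
#' @param profiles Surrogate profile tibble or S x D matrix.
#' @param config A [sourcefind_config()].
#' @param effective_total Pseudo-count total; overrides the config value.
#' @return A list with `beta` (n_thin x S matrix), `lambda` (n_thin x S),
#'   `log_posterior` (length n_thin), and acceptance rates `accept_beta`,
#'   `accept_lambda`.
#' @export
run_chain <- function(fractions, profiles, config = sourcefind_config(),
                      effective_total = NULL) {
  f <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  s_n <- nrow(f)
  if (s_n < 1L) abort("need at least one surrogate profile")
  stopifnot(length(fractions) == ncol(f), all(fractions >= 0))
  fractions <- fractions / sum(fractions)
  n_tot <- effective_total %||% config$effective_total
  if (is.null(n_tot)) abort("effective_total must be set (config or argument)")
  counts <- fractions * n_tot
  ll_const <- lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))
  eps <- config$clamp_eps
  moves <- config$moves_per_direction
  scale <- config$beta_proposal_scale
  bounds <- config$lambda_bounds
  fixed <- !is.null(config$fix_lambda)

  loglik <- function(b) {
    p <- pmax(as.vector(b %*% f), 1e-300)
    ll_const + sum(counts * log(p))
  }

  lambda <- rep(if (fixed) config$fix_lambda else config$lambda_init, s_n)
  beta <- rgamma(s_n, shape = config$lambda_init)
  beta <- pmax(beta, eps)
  beta <- beta / sum(beta)
  cur_ll <- loglik(beta)
  cur_lp <- dirichlet_logpdf(beta, lambda)

  n_keep <- config$iterations %/% config$thin
  beta_out <- matrix(NA_real_, n_keep, s_n,
                     dimnames = list(NULL, rownames(f)))
  lambda_out <- matrix(NA_real_, n_keep, s_n)
  lp_out <- numeric(n_keep)
  acc_b <- 0L
  lam_before <- lambda
  lam_moves <- 0

  for (m in seq_len(config$iterations)) {
    prop <- propose_beta(beta, scale = scale, moves = moves, eps = eps)
    new_ll <- loglik(prop)
    new_lp <- dirichlet_logpdf(prop, lambda)
    if (mh_accept(new_ll + new_lp, cur_ll + cur_lp)) {
      beta <- prop; cur_ll <- new_ll; cur_lp <- new_lp
      acc_b <- acc_b + 1L
    }
    if (!fixed) {
      new_lam <- update_lambda(lambda, beta, sd = config$lambda_proposal_sd,
                               bounds = bounds)
      lam_moves <- lam_moves + sum(new_lam != lambda)
      if (any(new_lam != lambda)) {
        lambda <- new_lam
        cur_lp <- dirichlet_logpdf(beta, lambda)
      }
    }
    if (m %% config$thin == 0L) {
      k <- m %/% config$thin
      beta_out[k, ] <- beta
      lambda_out[k, ] <- lambda
      lp_out[k] <- cur_ll + cur_lp
    }
  }
  list(beta = beta_out, lambda = lambda_out, log_posterior = lp_out,
       accept_beta = acc_b / config$iterations,
       accept_lambda = if (fixed) NA_real_ else
         lam_moves / (config$iterations * s_n))
}

#' Combine independent runs by posterior weight
#'
#' Takes each run's highest-posterior thinned state and forms the
#' posterior-weighted average of their simplex vectors, with weights given
#' by the softmax of the per-run maximum log posteriors (log posteriors are
#' shifted by their maximum before exponentiating).
#'
#' @param betas Matrix with one row per run (each that run's
#'   maximum-posterior simplex state).
#' @param log_posteriors Per-run maximum log posteriors.
#' @return List with `proportions` (simplex vector) and `weights` (per-run
#'   softmax weights).
#' @export
combine_runs <- function(betas, log_posteriors) {
  if (is.null(dim(betas))) betas <- matrix(betas, nrow = 1)
  if (nrow(betas) == 0L) abort("no runs to combine")
  stopifnot(nrow(betas) == length(log_posteriors))
  w <- exp(log_posteriors - max(log_posteriors))
  w <- w / sum(w)
  prop <- as.vector(w %*% betas)
  prop <- prop / sum(prop)
  names(prop) <- colnames(betas)
  list(proportions = prop, weights = w)
}

#' Infer ancestry proportions from copying vectors
#'
#' Fits the Bayesian mixture model to each recipient in a chunklengths
#' table: each recipient's normalized copying vector is modelled as
#' multinomial around a weighted sum of surrogate profiles, with a Dirichlet
#' prior on the weights whose concentration parameters carry a bounded
#' uniform hyperprior. Runs `config$runs` independent chains per recipient
#' (seeded `seed + run index`) and combines them by posterior weight.
#'
#' @param x Chunklengths tibble (`recipient` + donor columns); see
#'   [read_chunklengths()].
#' @param profiles Surrogate profile tibble; see [surrogate_profiles()].
#' @param config A [sourcefind_config()].
#' @param seed Integer base seed; identical seeds give bit-identical
#'   estimates.
#' @return An object of class `sourcefind_fit` with elements `proportions`
#'   (tibble: `recipient` + one column per surrogate), `runs` (per-run
#'   provenance: max log posterior, combination weight, acceptance rates),
#'   `config`, and `seed`. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' prof <- simulate_profiles(3, 6, separation = 0.9, seed = 1)
#' cv <- simulate_recipients(tibble::tibble(recipient = "r1"),
#'                           beta = c(0.6, 0.3, 0.1), profiles = prof,
#'                           effective_total = 5000, seed = 2)
#' fit <- sourcefind(cv, prof,
#'                   config = sourcefind_config(iterations = 5000, thin = 50,
#'                                              runs = 2),
#'                   seed = 1)
#' tidy(fit)
#' @export
sourcefind <- function(x, profiles, config = sourcefind_config(), seed = 1L) {
  f <- profile_matrix(profiles)
  m <- copy_matrix(x)
  if (!identical(colnames(m), colnames(f))) {
    abort("donor columns of chunklengths and profiles must match (same order)")
  }
  recipients <- x$recipient
  res <- vector("list", length(recipients))
  run_rows <- vector("list", length(recipients))
  for (i in seq_along(recipients)) {
    lv <- m[i, ]
    tot <- sum(lv)
    if (tot <= 0) abort(paste0("zero copying vector for ", recipients[i]))
    n_tot <- config$effective_total %||% round(tot)
    best_beta <- matrix(NA_real_, config$runs, nrow(f),
                        dimnames = list(NULL, rownames(f)))
    best_lp <- numeric(config$runs)
    acc_b <- numeric(config$runs)
    acc_l <- numeric(config$runs)
    for (r in seq_len(config$runs)) {
      run_seed <- seed + (i - 1L) * config$runs + r
      set.seed(run_seed)
      ch <- run_chain(lv / tot, f, config, effective_total = n_tot)
      k <- which.max(ch$log_posterior)
      best_beta[r, ] <- ch$beta[k, ]
      best_lp[r] <- ch$log_posterior[k]
      acc_b[r] <- ch$accept_beta
      acc_l[r] <- ch$accept_lambda
    }
    comb <- combine_runs(best_beta, best_lp)
    prop <- comb$proportions
    if (config$min_report > 0) {
      prop[prop < config$min_report] <- 0
      if (sum(prop) == 0) abort("min_report removed every component")
      prop <- prop / sum(prop)
    }
    res[[i]] <- prop
    run_rows[[i]] <- tibble::tibble(
      recipient = recipients[i], run = seq_len(config$runs),
      log_posterior = best_lp, weight = comb$weights,
      accept_beta = acc_b, accept_lambda = acc_l)
  }
  props <- tibble::as_tibble(do.call(rbind, res))
  structure(list(
    proportions = dplyr::bind_cols(tibble::tibble(recipient = recipients),
                                   props),
    runs = dplyr::bind_rows(run_rows),
    config = config, seed = seed),
    class = "sourcefind_fit")
}

#' @export
print.sourcefind_fit <- function(x, ...) {
  cat("Bayesian copying-vector mixture fit\n")
  cat(sprintf("  %d recipient(s), %d surrogate cluster(s), %d run(s) of %d iterations\n",
              nrow(x$proportions), ncol(x$proportions) - 1L,
              x$config$runs, x$config$iterations))
  print(x$proportions, ...)
  invisible(x)
}

#' @rdname sourcefind
#' @param x A `sourcefind_fit`.
#' @param ... Unused.
#' @method tidy sourcefind_fit
#' @export
tidy.sourcefind_fit <- function(x, ...) {
  x$proportions |>
    tidyr::pivot_longer(-"recipient", names_to = "surrogate",
                        values_to = "proportion")
}

#' @rdname sourcefind
#' @method glance sourcefind_fit
#' @export
glance.sourcefind_fit <- function(x, ...) {
  x$runs |>
    dplyr::group_by(.data$recipient) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     max_log_posterior = max(.data$log_posterior),
                     mean_accept_beta = mean(.data$accept_beta),
                     .groups = "drop") |>
    dplyr::mutate(n_surrogates = ncol(x$proportions) - 1L,
                  iterations = x$config$iterations)
}

#' @rdname sourcefind
#' @param object A `sourcefind_fit`.
#' @method autoplot sourcefind_fit
#' @export
autoplot.sourcefind_fit <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$recipient, y = .data$proportion,
                                 fill = .data$surrogate)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "ancestry proportion",
                  fill = "surrogate cluster") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
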