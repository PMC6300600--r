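#' Simulate surrogate profiles with controlled distinctness
#'
#' Draws S Dirichlet profile rows over D donor columns and mixes each row
#' toward a distinct basis (one-hot) vector, so pairwise total-variation
#' distance between profiles grows with `separation`: 0 gives exchangeable
#' Dirichlet rows, 1 gives (near-)orthogonal basis-like profiles. Stands in
#' for reference panels when testing estimators against known truth.
#'
#' @param n_surrogates Number of surrogate profiles S.
#' @param n_donors Number of donor columns D (must be >= S).
#' @param separation Mixing weight toward the basis vectors, in `[0, 1]`.
#' @param alpha Dirichlet concentration of the random component.
#' @param seed Optional integer seed.
#' @return Profile tibble (`surrogate`, `n_ind`, donor columns), rows
#'   summing to 1.
#' @export
simulate_profiles <- function(n_surrogates, n_donors, separation = 0.8,
                              alpha = 1, seed = NULL) {
  stopifnot(n_donors >= n_surrogates, separation >= 0, separation <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(rgamma(n_surrogates * n_donors, shape = alpha),
              n_surrogates, n_donors)
  g <- g / rowSums(g)
  basis <- diag(n_donors)[seq_len(n_surrogates), , drop = FALSE]
  f <- (1 - separation) * g + separation * basis
  f <- f / rowSums(f)
  colnames(f) <- paste0("d", seq_len(n_donors))
  dplyr::bind_cols(
    tibble::tibble(surrogate = paste0("s", seq_len(n_surrogates)),
                   n_ind = 1L),
    tibble::as_tibble(as.data.frame(f)))
}

#' Simulate recipient copying vectors from known mixture proportions
#'
#' Draws each recipient's copying vector as
#' `Multinomial(effective_total, sum_s beta_s f^s)` — the generative
#' counterpart of the inference likelihood, so parameter recovery is tested
#' without model misspecification. An optional over-dispersion knob draws a
#' per-recipient probability vector from
#' `Dirichlet(p * overdispersion)` first (Dirichlet-multinomial), stressing
#' robustness to misspecification.
#'
#' @param n_recipients Number of recipients to simulate.
#' @param beta True simplex mixture proportions (length = rows of
#'   `profiles`).
#' @param profiles Surrogate profile tibble or matrix.
#' @param effective_total Multinomial total (plays the role of the total
#'   copied length C, in cM).
#' @param overdispersion `Inf` (default) for pure multinomial; finite
#'   positive values add Dirichlet-multinomial noise (smaller = noisier).
#' @param seed Optional integer seed.
#' @param ids Recipient identifiers.
#' @return Chunklengths tibble (`recipient` + donor columns); row sums equal
#'   `effective_total`.
#' @export
simulate_recipients <- function(n_recipients, beta, profiles,
                                effective_total, overdispersion = Inf,
                                seed = NULL,
                                ids = paste0("r", seq_len(n_recipients))) {
  f <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  stopifnot(length(beta) == nrow(f), abs(sum(beta) - 1) < 1e-9,
            all(beta >= 0), effective_total > 0)
  if (!is.null(seed)) set.seed(seed)
  p <- as.vector(beta %*% f)
  draws <- matrix(NA_real_, n_recipients, ncol(f))
  for (i in seq_len(n_recipients)) {
    pi <- p
    if (is.finite(overdispersion)) {
      g <- rgamma(length(p), shape = p * overdispersion)
      if (sum(g) == 0) g <- p
      pi <- g / sum(g)
    }
    draws[i, ] <- rmultinom(1, size = round(effective_total), prob = pi)
  }
  colnames(draws) <- colnames(f)
  dplyr::bind_cols(tibble::tibble(recipient = ids),
                   tibble::as_tibble(as.data.frame(draws)))
}

#' Drift a surrogate profile toward a private self-copy signature
#'
#' Moves probability mass of one surrogate's profile toward a single
#' dedicated donor column, emulating a heavily drifted reference cluster
#' whose members mostly copy from themselves. In the `drift_level -> Inf`
#' limit the profile is a point mass on the self column.
#'
#' @param profiles Profile tibble.
#' @param surrogate Which surrogate to drift.
#' @param self_donor Donor column receiving the drift mass.
#' @param drift_level Non-negative drift intensity; 0 returns the input
#'   unchanged.
#' @return Profile tibble with the drifted row renormalized.
#' @export
drift_profile <- function(profiles, surrogate, self_donor, drift_level) {
  stopifnot(drift_level >= 0, surrogate %in% profiles$surrogate,
            self_donor %in% names(profiles))
  i <- which(profiles$surrogate == surrogate)
  if (drift_level == 0) return(profiles)
  donors <- setdiff(names(profiles), c("surrogate", "n_ind"))
  row <- as.numeric(profiles[i, donors])
  names(row) <- donors
  if (is.infinite(drift_level)) {
    row[] <- 0
    row[self_donor] <- 1
  } else {
    row[self_donor] <- row[self_donor] + drift_level
    row <- row / sum(row)
  }
  profiles[i, donors] <- as.list(row)
  profiles
}

#' Parameter-recovery experiment
#'
#' Full simulate-estimate-compare loop: generates surrogate profiles,
#' simulates replicate recipients from known mixture proportions, estimates
#' the proportions with both the Bayesian sampler and the NNLS baseline,
#' and reports per-component bias, RMSE and the worst absolute error.
#' Deterministic under `seed`.
#'
#' @param true_beta True simplex proportions (length S).
#' @param n_donors Donor columns D.
#' @param separation Profile distinctness, as in [simulate_profiles()].
#' @param effective_total Multinomial total per recipient.
#' @param n_replicates Independent simulated datasets.
#' @param config Sampler configuration for the Bayesian estimates.
#' @param methods Which estimators to run.
#' @param seed Integer seed.
#' @return A tibble of class `copymix_recovery`: one row per method x
#'   surrogate with `true`, `bias`, `rmse`, `max_abs_error` (worst error for
#'   that component over replicates); per-replicate estimates in attribute
#'   `estimates`.
#' @export
recovery_experiment <- function(true_beta, n_donors = 2 * length(true_beta),
                                separation = 0.9, effective_total = 20000,
                                n_replicates = 20,
                                config = sourcefind_config(iterations = 20000,
                                                           thin = 200,
                                                           runs = 4),
                                methods = c("sourcefind", "nnls"),
                                seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  s_n <- length(true_beta)
  prof <- simulate_profiles(s_n, n_donors, separation = separation,
                            seed = seed)
  ests <- list()
  for (rep in seq_len(n_replicates)) {
    cv <- simulate_recipients(1, true_beta, prof, effective_total,
                              seed = seed + 1000L + rep,
                              ids = paste0("rep", rep))
    if ("sourcefind" %in% methods) {
      fit <- sourcefind(cv, prof, config = config,
                        seed = seed + 2000L + rep * config$runs)
      ests[[length(ests) + 1L]] <- tidy(fit) |>
        dplyr::mutate(method = "sourcefind", replicate = rep)
    }
    if ("nnls" %in% methods) {
      nn <- nnls_ancestry(cv, prof) |>
        tidyr::pivot_longer(-"recipient", names_to = "surrogate",
                            values_to = "proportion") |>
        dplyr::mutate(method = "nnls", replicate = rep)
      ests[[length(ests) + 1L]] <- nn
    }
  }
  est <- dplyr::bind_rows(ests)
  truth <- tibble::tibble(surrogate = prof$surrogate, true = true_beta)
  report <- est |>
    dplyr::left_join(truth, by = "surrogate") |>
    dplyr::group_by(.data$method, .data$surrogate) |>
    dplyr::summarise(true = .data$true[1],
                     bias = mean(.data$proportion - .data$true),
                     rmse = sqrt(mean((.data$proportion - .data$true)^2)),
                     max_abs_error = max(abs(.data$proportion - .data$true)),
                     .groups = "drop")
  attr(report, "estimates") <- est
  class(report) <- c("copymix_recovery", class(report))
  report
}

#' Plot a recovery experiment
#'
#' Scatter of per-replicate estimates against the true proportions.
#'
#' @param object A `copymix_recovery` report.
#' @param ... Unused.
#' @method autoplot copymix_recovery
#' @export
autoplot.copymix_recovery <- function(object, ...) {
  est <- attr(object, "estimates")
  truth <- dplyr::distinct(object, .data$surrogate, .data$true)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$surrogate,
                                    y = .data$proportion,
                                    colour = .data$method)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_point(data = truth, inherit.aes = FALSE,
                        mapping = ggplot2::aes(x = .data$surrogate,
                                               y = .data$true),
                        colour = "black", shape = 4, size = 3) +
    ggplot2::labs(y = "estimated proportion", x = "surrogate cluster") +
    ggplot2::theme_minimal()
}
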