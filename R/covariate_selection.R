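# Stepwise covariate search on the objective function value.
#
# Decision rules: a covariate is significant in the univariate screen or
# enters in a forward step when adding it lowers the OFV by more than
# 3.84 (chi-square, 1 df, P < 0.05); it survives backward elimination
# when removing it raises the OFV by at least 6.63 (P < 0.01). Ties in
# forward selection are broken by candidate order, and a candidate fit
# that fails to converge is treated as delta-OFV = 0 (conservative).

.step_row <- function(step, candidate, before, after, decision) {
  data.frame(step = step, candidate = candidate,
             ofv_before = before, ofv_after = after,
             delta_ofv = before - after, decision = decision,
             stringsAsFactors = FALSE)
}

# starting values carried over from a nested model: the candidate model
# reproduces it exactly at beta_new = 0, so the search can only improve
# the OFV and delta-OFV stays non-negative by construction
.warm_initial <- function(warm, covs) {
  if (is.null(warm)) return(NULL)
  beta <- setNames(rep(0, length(covs)), covs)
  for (nm in intersect(covs, names(warm$params$covariate_effects)))
    beta[nm] <- warm$params$covariate_effects[[nm]][["coef"]]
  list(theta_emax = warm$params$theta_emax,
       theta_et50 = warm$params$theta_et50,
       beta = beta,
       omega_emax = max(warm$params$omega_emax, 1e-3),
       omega_et50 = max(warm$params$omega_et50, 1e-3),
       sigma = warm$params$sigma)
}

.candidate_fit <- function(ds, covs, config, warm = NULL) {
  cfg <- config; cfg$hessian <- FALSE
  f1 <- tryCatch(fit_model(ds, covs, cfg), error = function(e) NULL)
  best <- if (!is.null(f1) && isTRUE(f1$converged) && is.finite(f1$ofv)) f1 else NULL
  wi <- .warm_initial(warm, covs)
  if (!is.null(wi)) {
    cfg$initial <- wi
    f2 <- tryCatch(fit_model(ds, covs, cfg), error = function(e) NULL)
    ok2 <- !is.null(f2) && isTRUE(f2$converged) && is.finite(f2$ofv)
    if (ok2 && (is.null(best) || f2$ofv < best$ofv)) best <- f2
  }
  best
}

#' Univariate covariate screen
#'
#' Adds each candidate alone to the base (no-covariate) model and flags
#' it significant when the OFV drops by more than `cut` (default 3.84,
#' chi-square with 1 df at P < 0.05).
#'
#' @param ds A prepared [meta_dataset()].
#' @param candidates Character vector of covariate names (on Emax).
#' @param config A [fit_config()] used for every fit.
#' @param cut Significance cutoff on the OFV drop.
#' @return A list with `log` (the step log data frame), `base_fit`, and
#'   `significant` (character vector).
#' @export
screen_univariate <- function(ds, candidates, config = fit_config(),
                              cut = 3.84) {
  stopifnot(inherits(ds, "meta_dataset"))
  candidates <- as.character(candidates)
  base_fit <- fit_model(ds, character(), config)
  if (!isTRUE(base_fit$converged))
    stop("base model did not converge; cannot screen covariates")
  rows <- list(); sig <- character()
  for (cand in candidates) {
    fit <- .candidate_fit(ds, cand, config, warm = base_fit)
    if (is.null(fit)) {
      warning("candidate '", cand, "' fit did not converge; recorded as not significant")
      rows[[cand]] <- .step_row("univariate", cand, base_fit$ofv, base_fit$ofv,
                                "not significant (non-convergent)")
      next
    }
    delta <- base_fit$ofv - fit$ofv
    dec <- if (delta > cut) "significant" else "not significant"
    if (delta > cut) sig <- c(sig, cand)
    rows[[cand]] <- .step_row("univariate", cand, base_fit$ofv, fit$ofv, dec)
  }
  log <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else .step_row(character(), character(), numeric(), numeric(), character())[0, ]
  list(log = log, base_fit = base_fit, significant = sig)
}

#' Forward-inclusion / backward-elimination covariate search
#'
#' Forward phase: repeatedly add the candidate with the largest OFV drop
#' among those exceeding `forward_cut` (3.84, P < 0.05). Backward phase:
#' repeatedly remove the included covariate whose removal raises the OFV
#' least, as long as that rise is below `backward_cut` (6.63, P < 0.01).
#' At termination every retained covariate's single-removal OFV rise is
#' at least `backward_cut`. The full search is replayable from the
#' returned log.
#'
#' @inheritParams screen_univariate
#' @param forward_cut OFV drop required to enter (default 3.84).
#' @param backward_cut OFV rise required to stay (default 6.63).
#' @return A list with `covariates` (the surviving specification), `log`
#'   (step log), `fit` (final fit) and `base_fit`.
#' @export
forward_backward <- function(ds, candidates, forward_cut = 3.84,
                             backward_cut = 6.63, config = fit_config()) {
  stopifnot(inherits(ds, "meta_dataset"))
  candidates <- as.character(candidates)
  base_fit <- fit_model(ds, character(), config)
  if (!isTRUE(base_fit$converged))
    stop("base model did not converge; cannot run covariate search")
  rows <- list(); k <- 0L
  current <- character()
  current_fit <- base_fit
  fit_cache <- list()
  cache_fit <- function(covs, warm = NULL) {
    key <- paste(sort(covs), collapse = "+")
    if (is.null(fit_cache[[key]]))
      fit_cache[[key]] <<- list(.candidate_fit(ds, covs, config, warm = warm))
    fit_cache[[key]][[1]]
  }

  # forward inclusion
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      fits[j] <- list(cache_fit(c(current, remaining[j]), warm = current_fit))
      deltas[j] <- if (is.null(fits[[j]])) 0 else current_fit$ofv - fits[[j]]$ofv
      k <- k + 1L
      rows[[k]] <- .step_row("forward", remaining[j], current_fit$ofv,
                             if (is.null(fits[[j]])) current_fit$ofv else fits[[j]]$ofv,
                             if (is.null(fits[[j]])) "skipped (non-convergent)"
                             else if (deltas[j] > forward_cut) "eligible" else "not eligible")
    }
    best <- which(deltas > forward_cut)
    if (!length(best)) break
    best <- best[which.max(deltas[best])]   # ties: first listed wins via which.max
    current <- c(current, remaining[best])
    current_fit <- fits[[best]]
    k <- k + 1L
    rows[[k]] <- .step_row("forward", remaining[best], base_fit$ofv,
                           current_fit$ofv, "included")
    remaining <- remaining[-best]
  }

  # backward elimination
  repeat {
    if (!length(current)) break
    rises <- rep(NA_real_, length(current))
    fits <- vector("list", length(current))
    for (j in seq_along(current)) {
      fits[j] <- list(if (length(current) == 1L) base_fit
                      else cache_fit(setdiff(current, current[j]),
                                     warm = current_fit))
      rises[j] <- if (is.null(fits[[j]])) Inf else fits[[j]]$ofv - current_fit$ofv
    }
    worst <- which.min(rises)
    if (!is.finite(rises[worst]) || rises[worst] >= backward_cut) {
      for (j in seq_along(current)) {
        k <- k + 1L
        rows[[k]] <- .step_row("backward", current[j], current_fit$ofv,
                               current_fit$ofv + rises[j], "retained")
      }
      break
    }
    k <- k + 1L
    rows[[k]] <- .step_row("backward", current[worst], current_fit$ofv,
                           fits[[worst]]$ofv, "removed")
    current_fit <- fits[[worst]]
    current <- setdiff(current, current[worst])
  }

  log <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else .step_row(character(), character(), numeric(), numeric(), character())[0, ]

  # the search ran without Hessians; refit the winning specification once
  # with the user's full config (warm-started, so this is a quick polish)
  if (length(current)) {
    cfg <- config; cfg$initial <- .warm_initial(current_fit, current)
    final <- tryCatch(fit_model(ds, current, cfg), error = function(e) NULL)
    if (!is.null(final) && isTRUE(final$converged) &&
        final$ofv <= current_fit$ofv + 1e-6)
      current_fit <- final
    else if (isTRUE(config$hessian))
      current_fit <- .add_covariance(current_fit, ds)
  }
  list(covariates = current, log = log, fit = current_fit, base_fit = base_fit)
}

#' Export a covariate-search step log as CSV
#'
#' @param log Step log from [screen_univariate()] or
#'   [forward_backward()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_step_log <- function(log, path) {
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}
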