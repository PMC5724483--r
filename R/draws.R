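# Realized draws from the hierarchical co-demographic model.

# Discrete uniform integer on {lo..hi} (endpoints included), O(1) memory.
rdunif <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L

#' Admissible times remaining after buffering existing events
#'
#' Computes the set of integer times in the prior range \{lo, hi\} that lie
#' outside every closed window \[t - beta, t + beta\] around already-placed
#' event times.  With `beta = 0` only the placed points themselves are
#' excluded.
#'
#' @param tau_prior Length-2 integer range \{lo, hi\}.
#' @param existing_times Numeric vector of already-placed event times.
#' @param beta Buffer in generations (>= 0).
#' @return A two-column matrix of closed integer intervals (start, end);
#'   zero rows when nothing remains admissible.
#' @examples
#' # one event at 100,000 with beta = 20,000 splits U{10000, 1e6} into
#' # U{10000, 79999} and U{120001, 1e6}
#' buffer_admissible(c(10000, 1e6), 100000, 20000)
#' @export
buffer_admissible <- function(tau_prior, existing_times, beta) {
  stopifnot(length(tau_prior) == 2L, beta >= 0)
  lo <- tau_prior[1]; hi <- tau_prior[2]
  if (length(existing_times) == 0L)
    return(matrix(c(lo, hi), 1L, dimnames = list(NULL, c("start", "end"))))
  ex <- cbind(pmax(lo, ceiling(existing_times - beta)),
              pmin(hi, floor(existing_times + beta)))
  ex <- ex[ex[, 1L] <= ex[, 2L], , drop = FALSE]
  if (nrow(ex)) {
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    merged <- list()
    cs <- ex[1L, 1L]; ce <- ex[1L, 2L]
    for (r in seq_len(nrow(ex))[-1L]) {
      if (ex[r, 1L] <= ce + 1) ce <- max(ce, ex[r, 2L])
      else { merged[[length(merged) + 1L]] <- c(cs, ce)
             cs <- ex[r, 1L]; ce <- ex[r, 2L] }
    }
    merged[[length(merged) + 1L]] <- c(cs, ce)
  } else merged <- list()
  gaps <- list(); prev <- lo
  for (m in merged) {
    if (m[1L] > prev) gaps[[length(gaps) + 1L]] <- c(prev, m[1L] - 1)
    prev <- m[2L] + 1
  }
  if (prev <= hi) gaps[[length(gaps) + 1L]] <- c(prev, hi)
  out <- if (length(gaps)) do.call(rbind, gaps) else
    matrix(numeric(0), 0L, 2L)
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

#' Draw one event time from the buffered prior
#'
#' Draws uniformly from the prior range minus the union of closed
#' \[t - beta, t + beta\] windows around existing event times (the prior is
#' sequentially modified by every subsequent draw).
#'
#' @inheritParams buffer_admissible
#' @return A single integer-valued time.
#' @export
apply_buffer <- function(tau_prior, existing_times, beta) {
  gaps <- buffer_admissible(tau_prior, existing_times, beta)
  widths <- gaps[, 2L] - gaps[, 1L] + 1
  total <- sum(widths)
  if (total < 1)
    stop(structure(class = c("codemo_buffer_error", "error", "condition"),
                   list(message = sprintf(
                     "buffer infeasibility: no admissible times remain after %d events",
                     length(existing_times)), call = NULL)))
  r <- if (total < .Machine$integer.max) sample.int(total, 1L) else
    floor(runif(1, 0, total)) + 1
  g <- which(r <= cumsum(widths))[1L]
  gaps[g, 1L] + (r - c(0, cumsum(widths))[g]) - 1
}

draw_buffered_times <- function(k, tau_prior, beta, existing = numeric(0)) {
  times <- numeric(k)
  for (j in seq_len(k)) {
    times[j] <- apply_buffer(tau_prior, existing, beta)
    existing <- c(existing, times[j])
  }
  times
}

#' Draw one realized co-demographic configuration
#'
#' Draws hyperparameters from a [hyperprior_spec()] and realizes buffered
#' event times: the pulse count psi, per-pulse taxon counts, idiosyncratic
#' count sigma = n - S_T, pulse times tau_s (ascending, so zeta_1 labels the
#' most recent pulse) and idiosyncratic times tau_i.  All event times are
#' pairwise more than beta apart (idiosyncratic times included unless the
#' spec disables it).
#'
#' @param spec A [hyperprior_spec()].
#' @param force_psi Optionally condition the draw on one psi value
#'   (enumeration schemes only); used for stratified reference tables.
#' @return An object of class `"codemo_draw"` with elements `psi`, `sigma`,
#'   `Psi`, `S_T`, `S`, `zeta_T`, `zeta_s`, `zeta`, `tau_s`, `tau_i`.
#' @export
draw_codemo <- function(spec, force_psi = NULL) {
  stopifnot(inherits(spec, "hyperprior_spec"))
  n <- spec$n_taxa
  if (spec$scheme == "dirichlet_process") {
    if (!is.null(force_psi))
      stop("force_psi is not supported under the dirichlet_process scheme")
    sizes <- dp_partition_sizes(n, spec$stirling)
    S <- sort(sizes[sizes >= 2L], decreasing = TRUE)
    psi <- length(S)
  } else {
    ev <- spec$events
    keep <- if (is.null(force_psi)) seq_len(nrow(ev$table)) else
      which(ev$table$psi == force_psi)
    if (!length(keep)) stop("no admissible configurations for psi = ",
                            force_psi)
    w <- ev$table$weight[keep]
    row <- keep[sample.int(length(keep), 1L, prob = w)]
    psi <- ev$table$psi[row]
    S <- ev$parts[[row]]
  }
  S_T <- sum(S)
  sigma <- n - S_T
  beta_eff <- beta_for_psi(spec, psi)
  # Sequential buffered placement can dead-end by bad luck even when a
  # mutually buffered arrangement exists; restart the whole placement a
  # bounded number of times before declaring infeasibility.
  times <- NULL
  for (attempt in seq_len(100L)) {
    times <- tryCatch({
      tau_s <- draw_buffered_times(psi, spec$tau_prior, beta_eff)
      existing <- if (spec$buffer_idiosyncratic) tau_s else numeric(0)
      beta_i <- if (spec$buffer_idiosyncratic) beta_eff else 0
      tau_i <- draw_buffered_times(sigma, spec$tau_prior, beta_i,
                                   existing = existing)
      list(tau_s = sort(tau_s), tau_i = sort(tau_i))
    }, codemo_buffer_error = function(e) NULL)
    if (!is.null(times)) break
  }
  if (is.null(times))
    stop("buffer infeasibility: could not place ", psi + sigma,
         " events pairwise more than beta = ", beta_eff,
         " generations apart within the tau prior range")
  tau_s <- times$tau_s
  tau_i <- times$tau_i
  # per-pulse proportions in random temporal order, aligned with tau_s
  zeta_s <- if (psi > 0) S[sample.int(psi)] / n else numeric(0)
  structure(list(
    psi = as.integer(psi), sigma = as.integer(sigma),
    Psi = as.integer(psi + sigma),
    S_T = as.integer(S_T), S = as.integer(round(zeta_s * n)),
    zeta_T = S_T / n, zeta_s = zeta_s,
    zeta = c(zeta_s, rep(1 / n, sigma)),
    tau_s = tau_s, tau_i = tau_i), class = "codemo_draw")
}

beta_for_psi <- function(spec, psi) {
  ov <- spec$beta_overrides
  if (!is.null(ov) && as.character(psi) %in% names(ov))
    ov[[as.character(psi)]] else spec$beta
}

# Uniform random set partition of n elements: block count k with probability
# proportional to the Stirling number S(n, k), then a uniform partition with
# exactly k blocks via the recursion S(m, j) = j S(m-1, j) + S(m-1, j-1).
dp_partition_sizes <- function(n, S) {
  w <- S[n + 1L, 2:(n + 1L)]
  k <- sample.int(n, 1L, prob = w)
  sizes <- integer(0)
  rec <- function(m, j) {
    if (j == m) return(rep(1L, m))
    if (j == 1L) return(m)
    if (runif(1) < S[m, j] / S[m + 1L, j + 1L]) c(rec(m - 1L, j - 1L), 1L)
    else { b <- rec(m - 1L, j); i <- sample.int(j, 1L); b[i] <- b[i] + 1L; b }
  }
  rec(n, k)
}

#' @export
print.codemo_draw <- function(x, ...) {
  cat(sprintf(
    "codemo_draw: Psi = %d (psi = %d pulses, sigma = %d idiosyncratic), zeta_T = %g\n",
    x$Psi, x$psi, x$sigma, x$zeta_T))
  if (x$psi > 0)
    cat("  pulses (most recent first): S =", paste(x$S, collapse = " "),
        "at tau_s =", paste(x$tau_s, collapse = " "), "\n")
  if (x$sigma > 0)
    cat("  idiosyncratic times:", paste(x$tau_i, collapse = " "), "\n")
  invisible(x)
}

#' Draw per-taxon demographic parameters for a realized configuration
#'
#' Randomly assigns the n taxa to the drawn events (taxa sharing a pulse copy
#' its time exactly), and draws each taxon's nuisance parameters
#' independently: epsilon from the expansion prior U(lo, hi) or the
#' contraction prior 1/U(a, b) according to the taxon's scenario, and N from
#' the discrete uniform size prior.
#'
#' @param draw A [draw_codemo()] result.
#' @param spec The [hyperprior_spec()] the draw came from.
#' @return An object of class `"taxon_params"`: list with numeric vectors
#'   `tau`, `epsilon`, `n_e` (length n) plus `pulse_id` labels and
#'   `scenario`.
#' @export
draw_taxon_params <- function(draw, spec) {
  stopifnot(inherits(draw, "codemo_draw"), inherits(spec, "hyperprior_spec"))
  n <- spec$n_taxa
  perm <- sample.int(n)
  tau <- numeric(n)
  pulse_id <- character(n)
  pos <- 1L
  for (j in seq_len(draw$psi)) {
    idx <- perm[pos:(pos + draw$S[j] - 1L)]
    tau[idx] <- draw$tau_s[j]
    pulse_id[idx] <- paste0("P", j)
    pos <- pos + draw$S[j]
  }
  for (j in seq_len(draw$sigma)) {
    idx <- perm[pos]
    tau[idx] <- draw$tau_i[j]
    pulse_id[idx] <- paste0("I", j)
    pos <- pos + 1L
  }
  expand <- spec$scenario == "expansion"
  epsilon <- numeric(n)
  epsilon[expand] <- runif(sum(expand), spec$epsilon_prior[1],
                           spec$epsilon_prior[2])
  if (any(!expand))
    epsilon[!expand] <- 1 / runif(sum(!expand),
                                  spec$contraction_epsilon_prior[1],
                                  spec$contraction_epsilon_prior[2])
  n_e <- rdunif(n, spec$n_prior[1], spec$n_prior[2])
  structure(list(tau = tau, epsilon = epsilon, n_e = as.numeric(n_e),
                 pulse_id = pulse_id, scenario = spec$scenario),
            class = "taxon_params")
}

#' Dispersion index and mean of the event times
#'
#' Computes the parameter summaries E(tau), the arithmetic mean of the
#' per-taxon change times, and Omega_tau = Var(tau)/E(tau), the dispersion
#' index of tau (sample variance, divisor n - 1).  Omega_tau is 0 exactly
#' when all taxa share one time (perfect synchrony).
#'
#' @param params A [draw_taxon_params()] result (or any list with a numeric
#'   `tau` of length >= 2).
#' @return List with `omega_tau` and `e_tau`.
#' @export
summarize_params <- function(params) {
  tau <- params$tau
  stopifnot(is.numeric(tau), length(tau) >= 2)
  m <- mean(tau)
  if (m == 0) stop("Omega_tau undefined: mean(tau) is zero")
  list(omega_tau = var(tau) / m, e_tau = m)
}
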