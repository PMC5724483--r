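# Hyperprior specification over pulse counts and taxon-assignment proportions.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer partitions of `total` into exactly `parts` parts, each >= 2,
# returned as non-increasing integer vectors (unordered multisets).
partitions_min2 <- function(total, parts, max_part = total) {
  if (parts == 0L)
    return(if (total == 0L) list(integer(0)) else list())
  hi <- min(max_part, total - 2L * (parts - 1L))
  if (hi < 2L) return(list())
  out <- list()
  for (p in hi:2L) {
    rest <- partitions_min2(total - p, parts - 1L, p)
    out <- c(out, lapply(rest, function(r) c(p, r)))
  }
  out
}

# Stirling numbers of the second kind, S[i+1, k+1] = S(i, k), as doubles.
stirling2_table <- function(n) {
  S <- matrix(0, n + 1L, n + 1L)
  S[1L, 1L] <- 1
  for (i in seq_len(n))
    for (k in seq_len(i))
      S[i + 1L, k + 1L] <- k * S[i, k + 1L] + S[i, k]
  S
}

#' Specify a hyperprior over co-demographic pulse configurations
#'
#' Builds the hyperprior governing how many size-change events occur across
#' `n_taxa` independent populations and how taxa are apportioned among them.
#' An event shared by >= 2 taxa is a synchronous pulse (psi counts these);
#' an event private to one taxon is idiosyncratic (sigma counts these);
#' Psi = psi + sigma.  zeta_T is the proportion of taxa in any pulse,
#' zeta_s the per-pulse proportions (each in \[2/n, 1\]).
#'
#' Schemes:
#' \describe{
#'   \item{`"psi_conditioned"`}{Discrete uniform over `psi_support`; within
#'     each psi, uniform over admissible zeta_T values; within each zeta_T,
#'     uniform over the admissible zeta_s multisets.  Idiosyncratic taxa fill
#'     the remainder (sigma = n - S_T).}
#'   \item{`"zeta_conditioned"`}{The psi in \{0, 1\} special case: complete
#'     idiosyncrasy, a single pulse of varying size, or full synchrony,
#'     with Psi = 1 + n - S_T when psi = 1 and sigma = n - S_T.  Implemented
#'     as `"psi_conditioned"` with `psi_support = c(0, 1)`.}
#'   \item{`"dirichlet_process"`}{Equal weight on every set partition of the
#'     n taxa (blocks of >= 2 are pulses, singletons idiosyncratic), the
#'     exchangeable random-partition prior of Chinese-restaurant type.}
#'   \item{`"custom"`}{`"psi_conditioned"` machinery plus min/max rules on
#'     zeta_T and the zeta_s elements.}
#' }
#'
#' @param n_taxa Number of taxa n (>= 2).
#' @param scheme Hyperparameterization scheme (see Details).
#' @param psi_support Integer vector of admissible psi values (subset of
#'   0..floor(n/2); ignored for `"dirichlet_process"`).
#' @param fixed_zeta Optional named list mapping a psi value (as character)
#'   to a fixed vector of per-pulse taxon counts S (each >= 2); when present
#'   for the drawn psi, zeta_s is fixed to that multiset (in random temporal
#'   order per draw) instead of varying.
#' @param zeta_T_min,zeta_T_max Bounds on zeta_T (custom rules).
#' @param zeta_min,zeta_max Optional bounds on each zeta_s element.
#' @param tau_prior Length-2 integer range \{lo, hi\} for event times in
#'   generations (discrete uniform, endpoints included).
#' @param epsilon_prior Length-2 range (lo, hi) for the expansion-scenario
#'   size-change ratio epsilon (continuous uniform).
#' @param n_prior Length-2 integer range \{lo, hi\} for current size N in
#'   gene copies (discrete uniform).
#' @param beta Pulse buffer in generations: all realized event times must be
#'   pairwise more than beta apart.
#' @param beta_overrides Optional named numeric vector of per-psi beta values
#'   (names are psi values), e.g. `c("0" = 10000)` to relax the buffer under
#'   complete idiosyncrasy.
#' @param scenario Character vector, length 1 or `n_taxa`, of per-taxon
#'   demographic scenarios: `"expansion"` or `"contraction"`.
#' @param contraction_epsilon_prior Length-2 range (a, b); contraction taxa
#'   draw epsilon = 1/U(a, b).  Defaults to `epsilon_prior`, i.e. the
#'   reciprocal of the expansion range.
#' @param buffer_idiosyncratic Buffer idiosyncratic event times against all
#'   other events (default) or only forbid exact duplicates.
#' @return An object of class `"hyperprior_spec"`.
#' @examples
#' hyperprior_spec(10, "psi_conditioned", psi_support = 0:5,
#'                 tau_prior = c(5000, 250000), epsilon_prior = c(0.01, 0.1),
#'                 n_prior = c(50000, 250000), beta = 30000)
#' @export
hyperprior_spec <- function(n_taxa,
                            scheme = c("psi_conditioned", "zeta_conditioned",
                                       "dirichlet_process", "custom"),
                            psi_support = NULL,
                            fixed_zeta = NULL,
                            zeta_T_min = 0, zeta_T_max = 1,
                            zeta_min = NULL, zeta_max = NULL,
                            tau_prior, epsilon_prior, n_prior,
                            beta = 0, beta_overrides = NULL,
                            scenario = "expansion",
                            contraction_epsilon_prior = NULL,
                            buffer_idiosyncratic = TRUE) {
  scheme <- match.arg(scheme)
  n_taxa <- as.integer(n_taxa)
  stopifnot(n_taxa >= 2,
            length(tau_prior) == 2L, tau_prior[1] < tau_prior[2],
            tau_prior[1] >= 0,
            length(epsilon_prior) == 2L, epsilon_prior[1] > 0,
            epsilon_prior[1] < epsilon_prior[2],
            length(n_prior) == 2L, n_prior[1] >= 2,
            n_prior[1] <= n_prior[2],
            beta >= 0)
  if (length(scenario) == 1L) scenario <- rep(scenario, n_taxa)
  stopifnot(length(scenario) == n_taxa,
            all(scenario %in% c("expansion", "contraction")))

  if (scheme == "zeta_conditioned") psi_support <- c(0L, 1L)
  if (scheme != "dirichlet_process") {
    psi_support <- sort(unique(as.integer(
      psi_support %||% 0:(n_taxa %/% 2L))))
    if (any(psi_support < 0L) || any(psi_support > n_taxa %/% 2L))
      stop("psi values must lie in 0..floor(n_taxa/2)")
  }
  if (!is.null(fixed_zeta)) {
    for (nm in names(fixed_zeta)) {
      sv <- fixed_zeta[[nm]]
      if (length(sv) != as.integer(nm) || any(sv < 2) || sum(sv) > n_taxa)
        stop("fixed_zeta[['", nm, "']] must hold ", nm,
             " taxon counts, each >= 2, summing to at most n_taxa")
    }
  }

  spec <- structure(list(
    n_taxa = n_taxa, scheme = scheme, psi_support = psi_support,
    fixed_zeta = fixed_zeta,
    zeta_T_min = zeta_T_min, zeta_T_max = zeta_T_max,
    zeta_min = zeta_min, zeta_max = zeta_max,
    tau_prior = as.numeric(tau_prior),
    epsilon_prior = as.numeric(epsilon_prior),
    n_prior = as.numeric(n_prior),
    beta = beta, beta_overrides = beta_overrides,
    scenario = scenario,
    contraction_epsilon_prior = contraction_epsilon_prior %||% epsilon_prior,
    buffer_idiosyncratic = isTRUE(buffer_idiosyncratic)),
    class = "hyperprior_spec")

  if (scheme == "dirichlet_process") {
    spec$stirling <- stirling2_table(n_taxa)
  } else {
    spec$events <- enumerate_events(spec)
    if (nrow(spec$events$table) == 0L)
      stop("empty admissible hyperprior set after constraints")
  }
  spec
}

# Enumerate (psi, S_T, partition) rows with hierarchical uniform weights:
# uniform over psi, then over admissible S_T within psi, then over admissible
# zeta_s multisets within S_T.
enumerate_events <- function(spec) {
  n <- spec$n_taxa
  rows <- list()
  parts_list <- list()
  for (psi in spec$psi_support) {
    branch <- list()
    if (psi == 0L) {
      if (spec$zeta_T_min <= 0)
        branch[["0"]] <- list(integer(0))
    } else {
      fixed <- spec$fixed_zeta[[as.character(psi)]]
      if (!is.null(fixed)) {
        sv <- sort(as.integer(fixed), decreasing = TRUE)
        branch[[as.character(sum(sv))]] <- list(sv)
      } else {
        for (S_T in seq.int(2L * psi, n)) {
          zt <- S_T / n
          if (zt < spec$zeta_T_min - 1e-9 || zt > spec$zeta_T_max + 1e-9)
            next
          pp <- partitions_min2(S_T, psi)
          if (!is.null(spec$zeta_min))
            pp <- Filter(function(p) all(p / n >= spec$zeta_min - 1e-9), pp)
          if (!is.null(spec$zeta_max))
            pp <- Filter(function(p) all(p / n <= spec$zeta_max + 1e-9), pp)
          if (length(pp)) branch[[as.character(S_T)]] <- pp
        }
      }
    }
    if (!length(branch)) next
    w_st <- 1 / (length(spec$psi_support) * length(branch))
    for (st in names(branch)) {
      pp <- branch[[st]]
      for (p in pp) {
        rows[[length(rows) + 1L]] <-
          c(psi = psi, S_T = as.integer(st), weight = w_st / length(pp))
        parts_list[[length(parts_list) + 1L]] <- p
      }
    }
  }
  tab <- if (length(rows)) as.data.frame(do.call(rbind, rows)) else
    data.frame(psi = integer(0), S_T = integer(0), weight = numeric(0))
  list(table = tab, parts = parts_list)
}

#' Enumerated hyperprior weights
#'
#' Returns the fully enumerated hyperprior as a data frame with one row per
#' admissible (psi, S_T, zeta_s-multiset) combination, its zeta_T, the
#' multiset of per-pulse taxon counts (as a string), and its probability.
#' For the Dirichlet-process scheme the enumeration is over the number of
#' events Psi, with P(Psi = k) proportional to the Stirling number S(n, k).
#'
#' @param spec A [hyperprior_spec()].
#' @return A data frame of weights summing to 1.
#' @export
hyperprior_weights <- function(spec) {
  stopifnot(inherits(spec, "hyperprior_spec"))
  if (spec$scheme == "dirichlet_process") {
    n <- spec$n_taxa
    w <- spec$stirling[n + 1L, 2:(n + 1L)]
    return(data.frame(Psi = seq_len(n), weight = w / sum(w)))
  }
  tab <- spec$events$table
  data.frame(psi = tab$psi, S_T = tab$S_T, zeta_T = tab$S_T / spec$n_taxa,
             parts = vapply(spec$events$parts,
                            function(p) paste(p, collapse = "+"), ""),
             weight = tab$weight)
}

#' @export
print.hyperprior_spec <- function(x, ...) {
  cat(sprintf("hyperprior_spec: %d taxa, scheme '%s'\n", x$n_taxa, x$scheme))
  if (x$scheme != "dirichlet_process")
    cat("  psi support:", paste(x$psi_support, collapse = " "), "\n")
  cat(sprintf("  tau ~ U{%g, %g}  epsilon ~ U(%g, %g)  N ~ U{%g, %g}\n",
              x$tau_prior[1], x$tau_prior[2], x$epsilon_prior[1],
              x$epsilon_prior[2], x$n_prior[1], x$n_prior[2]))
  cat(sprintf("  pulse buffer beta = %g generations%s\n", x$beta,
              if (!is.null(x$beta_overrides))
                paste0(" (overrides: ",
                       paste(names(x$beta_overrides), x$beta_overrides,
                             sep = "=", collapse = ", "), ")") else ""))
  invisible(x)
}
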