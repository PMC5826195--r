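#' Create a pipeline configuration
#'
#' All parameters have working defaults; see [GrmdaConfig-class] for their
#' meaning and units. Component counts \code{r}, \code{p}, \code{q} below 1
#' are fractions of the relevant axis dimension, resolved at scoring time by
#' [resolveDimensions()]; the defaults (0.47 of the smaller axis for the
#' association space, 0.45 of each axis for the similarity spaces)
#' reproduce the reference settings r = 180, p = 223, q = 172 on a
#' 495-miRNA by 383-disease corpus. Pass explicit integers to pin exact
#' counts.
#'
#' @param delta semantic contribution factor in (0, 1).
#' @param gammaD,gammaM Gaussian kernel bandwidth scalers (> 0).
#' @param r,p,q retained components (fraction < 1, or explicit count).
#' @param plsFraction fraction of PLS components to keep, in (0, 1].
#' @param plsMode "count" or "variance".
#' @param intercept propagate PLS intercepts into scores.
#' @param recomputeKernels rebuild Gaussian kernels inside each CV fold.
#' @param seed integer seed (NA leaves the RNG alone).
#' @return a validated [GrmdaConfig].
#' @export
#' @examples
#' grmdaConfig(seed = 7)
grmdaConfig <- function(delta = 0.5, gammaD = 1, gammaM = 1,
                        r = 0.47, p = 0.45, q = 0.45,
                        plsFraction = 0.9, plsMode = "count",
                        intercept = TRUE, recomputeKernels = TRUE,
                        seed = NA) {
  new("GrmdaConfig", delta = delta, gammaD = gammaD, gammaM = gammaM,
      r = r, p = p, q = q, plsFraction = plsFraction, plsMode = plsMode,
      intercept = intercept, recomputeKernels = recomputeKernels,
      seed = as.integer(seed))
}

#' Read a configuration from a YAML file
#'
#' Recognized keys (all optional): \code{delta}, \code{gamma_prime_d},
#' \code{gamma_prime_m}, \code{r}, \code{p}, \code{q}, \code{pls_fraction},
#' \code{pls_mode}, \code{no_intercept}, \code{recompute_kernels_per_fold},
#' \code{seed}. Unknown keys are an error. \code{overrides} (a named list in
#' the same vocabulary, e.g. from CLI flags) take precedence over file
#' values.
#'
#' @param path YAML file path (NULL = defaults only).
#' @param overrides named list of overriding values.
#' @return a [GrmdaConfig].
#' @export
readGrmdaConfig <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  known <- c("delta", "gamma_prime_d", "gamma_prime_m", "r", "p", "q",
             "pls_fraction", "pls_mode", "no_intercept",
             "recompute_kernels_per_fold", "seed")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pick <- function(key, default) if (is.null(vals[[key]])) default else vals[[key]]
  grmdaConfig(
    delta = pick("delta", 0.5),
    gammaD = pick("gamma_prime_d", 1),
    gammaM = pick("gamma_prime_m", 1),
    r = pick("r", 0.47), p = pick("p", 0.45), q = pick("q", 0.45),
    plsFraction = pick("pls_fraction", 0.9),
    plsMode = pick("pls_mode", "count"),
    intercept = !isTRUE(vals[["no_intercept"]]),
    recomputeKernels = pick("recompute_kernels_per_fold", TRUE),
    seed = pick("seed", NA))
}

#' Resolve retained-component counts against the data dimensions
#'
#' Fractional settings resolve as \code{p = round(frac_p * nm)},
#' \code{q = round(frac_q * nd)} and \code{r = round(frac_r * min(nm, nd))};
#' explicit integers pass through. Values exceeding the valid range are
#' clipped with a warning; a resolved value below 1 is an error. Also
#' returns the PLS component counts for the two regressions,
#' \code{max(1, floor(plsFraction * min(features, responses, samples - 1)))}
#' (used when \code{plsMode = "count"}).
#'
#' @param nm,nd numbers of miRNAs and diseases (both >= 2).
#' @param config a [GrmdaConfig].
#' @return list with elements \code{r}, \code{p}, \code{q},
#'   \code{ncompMirna}, \code{ncompDisease}.
#' @export
#' @examples
#' resolveDimensions(495, 383, grmdaConfig())
resolveDimensions <- function(nm, nd, config) {
  stopIfNot(nm >= 2 && nd >= 2, "need at least 2 miRNAs and 2 diseases")
  resolve <- function(v, dim, what) {
    k <- if (v < 1) round(v * dim) else as.integer(v)
    if (k < 1)
      stop("resolved ", what, " is below 1 (", v, " of ", dim, ")", call. = FALSE)
    if (k > dim) {
      warning(what, " = ", k, " exceeds its axis; clipped to ", dim,
              call. = FALSE)
      k <- dim
    }
    as.integer(k)
  }
  r <- resolve(config@r, min(nm, nd), "r")
  p <- resolve(config@p, nm, "p")
  q <- resolve(config@q, nd, "q")
  list(r = r, p = p, q = q,
       ncompMirna = max(1L, as.integer(floor(config@plsFraction * min(p, r, nm - 1)))),
       ncompDisease = max(1L, as.integer(floor(config@plsFraction * min(q, r, nd - 1)))))
}
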