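# Streitwieser limits for semiclassical C-Cl bond cleavage
STREITWIESER_LIMITS <- c(C = 1.057, Cl = 1.013)

#' Theoretical Streitwieser limit for C-Cl bond cleavage
#'
#' Maximum semiclassical kinetic isotope effect for cleavage of a
#' carbon-chlorine bond: 1.057 for carbon, 1.013 for chlorine. An AKIE
#' above the limit invalidates the mechanistic parameterization that
#' produced it.
#'
#' @param element `"C"` or `"Cl"`.
#' @return The dimensionless limit.
#' @export
streitwieser_limit <- function(element = c("C", "Cl")) {
  element <- match.arg(element)
  unname(STREITWIESER_LIMITS[element])
}

.registry_env <- new.env(parent = emptyenv())

position_registry <- function() {
  if (is.null(.registry_env$table)) {
    path <- system.file("extdata", "position_params.csv",
                        package = "dualcsia", mustWork = TRUE)
    tab <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    tab$n <- as.integer(tab$n)
    tab$x <- as.integer(tab$x)
    tab$z <- as.integer(tab$z)
    .registry_env$table <- tab
  }
  .registry_env$table
}

#' Construct a position-parameter set
#'
#' The (n, x, z) triple mapping a bulk enrichment factor to a
#' position-specific apparent kinetic isotope effect: `n` atoms of the
#' element per molecule, `x` of them at reactive positions, and `z`
#' indistinguishable reactive sites in intramolecular competition.
#'
#' @param compound compound label.
#' @param element `"C"` or `"Cl"`.
#' @param mechanism `"one_step"`, `"concerted"`, or `"stepwise"`.
#' @param n,x,z positive integers with `1 <= x <= n` and `z >= 1`.
#' @param provenance free-text origin note (defaults to `"user"`).
#' @return An object of class `position_params`.
#' @export
position_params <- function(compound, element = c("C", "Cl"),
                            mechanism = c("one_step", "concerted", "stepwise"),
                            n, x, z, provenance = "user") {
  element <- match.arg(element)
  mechanism <- match.arg(mechanism)
  n <- as.integer(n); x <- as.integer(x); z <- as.integer(z)
  if (is.na(n) || is.na(x) || is.na(z) || x < 1L || x > n || z < 1L) {
    stop("position parameters require integers with 1 <= x <= n and z >= 1",
         call. = FALSE)
  }
  structure(list(compound = compound, element = element,
                 mechanism = mechanism, n = n, x = x, z = z,
                 provenance = provenance),
            class = "position_params")
}

#' @export
print.position_params <- function(x, ...) {
  cat(sprintf("position_params: %s / %s / %s  n=%d x=%d z=%d  (%s)\n",
              x$compound, x$element, x$mechanism, x$n, x$x, x$z,
              x$provenance))
  invisible(x)
}

#' Look up published position parameters
#'
#' Returns the (n, x, z) registry entry for a compound/element/mechanism
#' combination. Chlorinated ethenes carry a single `"one_step"` entry;
#' 1,2-DCA carries separate `"concerted"` and `"stepwise"`
#' parameterizations of its dihaloelimination. The registry ships as a
#' human-editable CSV (`extdata/position_params.csv`); each entry carries a
#' provenance note, and user-constructed [position_params()] can be passed
#' anywhere a registry entry is accepted.
#'
#' @param compound one of PCE, cDCE, VC, 1,2-DCA.
#' @param element `"C"` or `"Cl"`.
#' @param mechanism defaults to `"one_step"`; must be `"concerted"` or
#'   `"stepwise"` for 1,2-DCA.
#' @return A [position_params()] object.
#' @examples
#' registry_lookup("cDCE", "C")
#' registry_lookup("1,2-DCA", "Cl", "concerted")
#' @export
registry_lookup <- function(compound, element = c("C", "Cl"),
                            mechanism = NULL) {
  element <- match.arg(element)
  reg <- position_registry()
  if (is.null(mechanism)) {
    mechanism <- if (identical(compound, "1,2-DCA")) NA_character_ else "one_step"
  }
  hit <- reg$compound == compound & reg$element == element &
    reg$mechanism == mechanism
  hit[is.na(hit)] <- FALSE
  if (sum(hit) != 1L) {
    keys <- sprintf("(%s, %s, %s)", reg$compound, reg$element, reg$mechanism)
    stop(sprintf(
      "no registry entry for (%s, %s, %s); valid combinations:\n  %s",
      compound, element, as.character(mechanism),
      paste(keys, collapse = "\n  ")), call. = FALSE)
  }
  row <- reg[hit, ]
  position_params(row$compound, row$element, row$mechanism,
                  row$n, row$x, row$z, provenance = row$provenance)
}

#' Apparent kinetic isotope effect from a bulk enrichment factor
#'
#' Converts a bulk enrichment factor to the position-specific apparent
#' kinetic isotope effect, correcting for non-reacting positions (n/x) and
#' intramolecular competition (z):
#' \deqn{AKIE = \frac{1}{1 + z\,(n/x)\,\varepsilon_{bulk}/1000}}
#' A negative epsilon (normal isotope effect) gives AKIE > 1. The map is
#' strictly decreasing in epsilon, so a confidence interval on epsilon
#' propagates by applying the formula to its endpoints and swapping them.
#' The computed AKIE is compared against the element's Streitwieser limit;
#' an exceedance flags the parameterization as mechanistically implausible.
#'
#' @param epsilon_bulk bulk enrichment factor in permil.
#' @param params a [position_params()] (typically from [registry_lookup()]).
#' @param epsilon_ci optional length-2 confidence interval on epsilon
#'   (permil), e.g. `fit$ci95` from [fit_rayleigh()].
#' @param factor_override optional numeric replacing the combinatorial
#'   factor `z * n / x` — an escape hatch for compounds whose published
#'   AKIEs are only consistent with an effective factor differing from the
#'   printed (n, x, z).
#' @return An object of class `akie_result`: `akie` (full precision),
#'   `akie_display` (rounded to 3 decimals), `ci95` (if requested),
#'   `params`, `epsilon_in`, `streitwieser_limit`, `exceeds_limit`,
#'   `mechanism_plausible`.
#' @examples
#' compute_akie(-27.5, registry_lookup("1,2-DCA", "C", "concerted"))
#' @export
compute_akie <- function(epsilon_bulk, params, epsilon_ci = NULL,
                         factor_override = NULL) {
  stopifnot(inherits(params, "position_params"),
            is.numeric(epsilon_bulk), length(epsilon_bulk) == 1L)
  fac <- if (is.null(factor_override)) {
    params$z * params$n / params$x
  } else {
    stopifnot(is.numeric(factor_override), factor_override > 0)
    factor_override
  }
  akie_of <- function(eps) {
    denom <- 1 + fac * eps / 1000
    if (any(denom <= 0)) {
      stop(sprintf(
        "epsilon = %g permil is out of domain for factor z*n/x = %g (1 + factor*eps <= 0)",
        eps, fac), call. = FALSE)
    }
    1 / denom
  }
  akie <- akie_of(epsilon_bulk)
  ci <- NULL
  if (!is.null(epsilon_ci)) {
    stopifnot(length(epsilon_ci) == 2L)
    # decreasing map: lower epsilon endpoint -> upper AKIE endpoint
    ci <- sort(vapply(epsilon_ci, akie_of, numeric(1)))
  }
  limit <- streitwieser_limit(params$element)
  structure(list(
    akie = akie,
    akie_display = round(akie, 3),
    ci95 = ci,
    params = params,
    epsilon_in = epsilon_bulk,
    factor = fac,
    streitwieser_limit = limit,
    exceeds_limit = akie > limit,
    mechanism_plausible = !(akie > limit)
  ), class = "akie_result")
}

#' @export
print.akie_result <- function(x, ...) {
  cat(sprintf("AKIE(%s, %s, %s) = %.3f from epsilon = %.1f permil\n",
              x$params$compound, x$params$element, x$params$mechanism,
              x$akie_display, x$epsilon_in))
  if (!is.null(x$ci95)) {
    cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci95[1], x$ci95[2]))
  }
  cat(sprintf("  Streitwieser limit %.3f: %s\n", x$streitwieser_limit,
              if (x$exceeds_limit) "EXCEEDED (parameterization implausible)"
              else "within limit"))
  invisible(x)
}

#' Invert the AKIE map back to a bulk enrichment factor
#'
#' Algebraic inverse of [compute_akie()]:
#' epsilon = 1000 (1/AKIE - 1) / (z n / x).
#'
#' @param akie dimensionless AKIE (> 0).
#' @param params a [position_params()].
#' @return Bulk enrichment factor in permil.
#' @export
invert_akie <- function(akie, params) {
  stopifnot(inherits(params, "position_params"), akie > 0)
  fac <- params$z * params$n / params$x
  1000 * (1 / akie - 1) / fac
}

#' Check an AKIE against the Streitwieser limit
#'
#' @param akie dimensionless AKIE (> 0).
#' @param element `"C"` or `"Cl"`.
#' @return A list with `element`, `limit`, `exceeds`, and `margin`
#'   (`akie - limit`; positive when the limit is exceeded).
#' @examples
#' streitwieser_check(1.129, "C")  # exceeds by 0.072
#' @export
streitwieser_check <- function(akie, element = c("C", "Cl")) {
  element <- match.arg(element)
  stopifnot(is.numeric(akie), akie > 0)
  limit <- streitwieser_limit(element)
  list(element = element, limit = limit,
       exceeds = akie > limit, margin = akie - limit)
}

#' Evaluate concerted vs stepwise mechanism scenarios
#'
#' For a compound with competing mechanistic parameterizations (by default
#' 1,2-DCA, whose dihaloelimination may remove both chlorines in one
#' rate-limiting step or sequentially), computes carbon and chlorine AKIEs
#' under each scenario and flags a scenario implausible when the AKIEs of
#' *all* its elements exceed their Streitwieser limits — the joint
#' criterion used to reject stepwise dihaloelimination in dual-element
#' studies. A single marginal exceedance (well within the uncertainty an
#' enrichment factor carries) does not by itself reject a scenario; the
#' per-element `exceeds_limit` flags are retained in the result so a
#' stricter reading remains available.
#'
#' @param eps_c,eps_cl bulk enrichment factors in permil.
#' @param compound compound with mechanism-specific registry entries
#'   (default `"1,2-DCA"`).
#' @param ci_c,ci_cl optional length-2 confidence intervals on the
#'   enrichment factors.
#' @param mechanisms scenarios to evaluate.
#' @return An object of class `mechanism_report`: per-scenario AKIE results,
#'   a logical `plausible` vector, and `surviving` (names of scenarios not
#'   excluded by a Streitwieser exceedance).
#' @examples
#' evaluate_mechanism_scenarios(-27.5, -5.3)
#' @export
evaluate_mechanism_scenarios <- function(eps_c, eps_cl,
                                         compound = "1,2-DCA",
                                         ci_c = NULL, ci_cl = NULL,
                                         mechanisms = c("concerted",
                                                        "stepwise")) {
  stopifnot(is.numeric(eps_c), is.numeric(eps_cl))
  scen <- lapply(mechanisms, function(mech) {
    list(
      mechanism = mech,
      akie_c = compute_akie(eps_c, registry_lookup(compound, "C", mech),
                            epsilon_ci = ci_c),
      akie_cl = compute_akie(eps_cl, registry_lookup(compound, "Cl", mech),
                             epsilon_ci = ci_cl)
    )
  })
  names(scen) <- mechanisms
  # implausible only when every element exceeds its limit
  plausible <- vapply(scen, function(s) {
    !(s$akie_c$exceeds_limit && s$akie_cl$exceeds_limit)
  }, logical(1))
  structure(list(
    compound = compound,
    scenarios = scen,
    plausible = plausible,
    surviving = names(plausible)[plausible]
  ), class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("Mechanism scenarios for %s:\n", x$compound))
  for (nm in names(x$scenarios)) {
    s <- x$scenarios[[nm]]
    cat(sprintf("  %-10s AKIE_C = %.3f%s  AKIE_Cl = %.3f%s  -> %s\n",
                nm,
                s$akie_c$akie_display,
                if (s$akie_c$exceeds_limit) "*" else " ",
                s$akie_cl$akie_display,
                if (s$akie_cl$exceeds_limit) "*" else " ",
                if (x$plausible[[nm]]) "plausible" else "implausible"))
  }
  cat("  (* exceeds the Streitwieser limit for that element)\n")
  invisible(x)
}

#' Classify a dual-element slope into fractionation patterns
#'
#' Labels a fitted Lambda as belonging to the low-Lambda pattern (weak
#' carbon relative to chlorine fractionation, as seen for PCE) or the
#' high-Lambda pattern (strong carbon relative to chlorine fractionation,
#' as for cDCE and VC). The decision boundary (default Lambda* = 6, placed
#' between the empirically observed clusters) is an operational
#' configuration value, not a physical constant; when the fit's 95%
#' confidence interval straddles the boundary the label is `"ambiguous"`.
#'
#' @param fit a `dual_element_fit`.
#' @param boundary decision boundary on Lambda (default 6).
#' @return A list with `label` (`"low_lambda_pattern"`,
#'   `"high_lambda_pattern"`, or `"ambiguous"`), `lambda`, `ci95`,
#'   `boundary`.
#' @export
classify_dual_pattern <- function(fit, boundary = 6) {
  stopifnot(inherits(fit, "dual_element_fit"), is.numeric(boundary))
  ci <- fit$ci95
  label <- if (!any(is.na(ci)) && ci[1] < boundary && ci[2] > boundary) {
    "ambiguous"
  } else if (fit$lambda < boundary) {
    "low_lambda_pattern"
  } else {
    "high_lambda_pattern"
  }
  list(label = label, lambda = fit$lambda, ci95 = ci, boundary = boundary)
}
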