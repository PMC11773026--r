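#' Define a polymerization reaction condition
#'
#' A reaction condition bundles the concentrations and affinities that
#' determine the profilin-actin equilibria of one polymerization reaction:
#' unlabeled and (Oregon Green) labeled actin monomer pools, the total
#' profilin concentration, and the dissociation constants of profilin for
#' each monomer species. Fluorescent labeling weakens profilin binding, so
#' the labeled-species Kd is typically ~10-fold larger.
#'
#' All concentrations are in micromolar (uM); no unit conversion is applied
#' anywhere in the package.
#'
#' @param actin_unlabeled Unlabeled actin monomer concentration (uM).
#' @param actin_labeled Labeled actin monomer concentration (uM).
#' @param profilin_total Total profilin concentration (uM).
#' @param kd_unlabeled Dissociation constant of profilin for unlabeled actin
#'   (uM). Must be positive.
#' @param kd_labeled Dissociation constant of profilin for labeled actin (uM).
#'   Must be positive.
#' @param profilin_isoform Free-text label for the profilin used, e.g. `"Sc"`
#'   (budding yeast) or `"Hs"` (human profilin-1).
#' @param formin_construct Free-text label for the formin construct, e.g.
#'   `"FH1FH2"`, `"PCPD-FH2"`, `"FH1FH2-C"`.
#' @return An object of class `reaction_condition`.
#' @examples
#' sc_condition(profilin_total = 5)
#' reaction_condition(0.5, 0.25, 5, 2.9, 29)
#' @seealso [solve_shared_profilin()], [sc_condition()], [hs_condition()]
#' @export
reaction_condition <- function(actin_unlabeled, actin_labeled, profilin_total,
                               kd_unlabeled, kd_labeled,
                               profilin_isoform = "Sc",
                               formin_construct = "FH1FH2") {
  conc <- c(actin_unlabeled = actin_unlabeled, actin_labeled = actin_labeled,
            profilin_total = profilin_total)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0")
  kd <- c(kd_unlabeled = kd_unlabeled, kd_labeled = kd_labeled)
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("dissociation constants must be finite and > 0")
  structure(
    list(actin_unlabeled = actin_unlabeled, actin_labeled = actin_labeled,
         profilin_total = profilin_total, kd_unlabeled = kd_unlabeled,
         kd_labeled = kd_labeled, profilin_isoform = profilin_isoform,
         formin_construct = formin_construct),
    class = "reaction_condition"
  )
}

#' @export
print.reaction_condition <- function(x, ...) {
  cat(sprintf(
    "Reaction condition (%s profilin, %s):\n  actin %g uM unlabeled + %g uM labeled; profilin %g uM\n  Kd %g uM (unlabeled), %g uM (labeled)\n",
    x$profilin_isoform, x$formin_construct, x$actin_unlabeled,
    x$actin_labeled, x$profilin_total, x$kd_unlabeled, x$kd_labeled))
  invisible(x)
}

#' Preset reaction conditions
#'
#' Convenience constructors for the two standard condition families.
#' `sc_condition()` uses budding-yeast (Sc) profilin affinities, Kd 2.9 uM
#' for unlabeled and 29 uM for labeled actin monomers. `hs_condition()` uses
#' human profilin-1 affinities, Kd 0.1 uM (unlabeled) and 1.0 uM (labeled).
#' The actin split follows the standard 33%-labeled mixtures:
#' 0.75 uM total = 0.5 unlabeled + 0.25 labeled; 1 uM total =
#' 0.67 unlabeled + 0.33 labeled.
#'
#' @param profilin_total Total profilin concentration (uM).
#' @param actin_total Total actin concentration, one of 0.75 or 1 (uM).
#' @param formin_construct Formin construct label.
#' @return A `reaction_condition`.
#' @export
sc_condition <- function(profilin_total, actin_total = 0.75,
                         formin_construct = "FH1FH2") {
  split <- actin_split(actin_total)
  reaction_condition(split[1], split[2], profilin_total,
                     kd_unlabeled = 2.9, kd_labeled = 29,
                     profilin_isoform = "Sc",
                     formin_construct = formin_construct)
}

#' @rdname sc_condition
#' @export
hs_condition <- function(profilin_total, actin_total = 0.75,
                         formin_construct = "FH1FH2") {
  split <- actin_split(actin_total)
  reaction_condition(split[1], split[2], profilin_total,
                     kd_unlabeled = 0.1, kd_labeled = 1.0,
                     profilin_isoform = "Hs",
                     formin_construct = formin_construct)
}

# 33%-labeled actin mixtures; the two standard totals use the printed splits
actin_split <- function(actin_total) {
  if (isTRUE(all.equal(actin_total, 0.75))) return(c(0.5, 0.25))
  if (isTRUE(all.equal(actin_total, 1))) return(c(0.67, 0.33))
  c(actin_total * 2 / 3, actin_total / 3)
}

#' Profilin-actin concentration in the weak-binding limit
#'
#' Langmuir isotherm for the concentration of profilin-actin complex when
#' binding is weak relative to the monomer pool, so actin depletion of the
#' free profilin pool is handled by the caller (via `profilin_free`):
#' `PA = actin * P_free / (kd + P_free)`.
#'
#' @param actin Actin monomer concentration (uM).
#' @param profilin_free Free profilin concentration (uM).
#' @param kd Dissociation constant (uM, > 0).
#' @return Profilin-actin complex concentration (uM), in `[0, actin)`.
#' @examples
#' pa_weak_binding(0.5, 2.9, 2.9)  # half-saturation: 0.25
#' @export
pa_weak_binding <- function(actin, profilin_free, kd) {
  stopifnot(is.numeric(actin), is.numeric(profilin_free), is.numeric(kd))
  if (any(actin < 0) || any(profilin_free < 0))
    stop("actin and profilin_free must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  actin * profilin_free / (kd + profilin_free)
}

#' Profilin-actin concentration from the binding quadratic
#'
#' Exact two-species equilibrium for one actin pool and one profilin pool,
#' appropriate when the dissociation constant is tighter than the reactant
#' concentrations (e.g. human profilin-1). Returns the smaller root of
#' `PA^2 - (A + P + Kd) PA + A P = 0`, computed in the numerically stable
#' form `2 A P / (b + sqrt(b^2 - 4 A P))`.
#'
#' @param actin Actin monomer concentration (uM).
#' @param profilin_total Total profilin concentration (uM).
#' @param kd Dissociation constant (uM, > 0).
#' @return Complex concentration (uM), `0 <= PA <= min(actin, profilin_total)`.
#' @examples
#' pa_quadratic(0.5, 1.0, 0.1)
#' @export
pa_quadratic <- function(actin, profilin_total, kd) {
  stopifnot(is.numeric(actin), is.numeric(profilin_total), is.numeric(kd))
  if (any(actin < 0) || any(profilin_total < 0))
    stop("actin and profilin_total must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  b <- actin + profilin_total + kd
  disc <- b^2 - 4 * actin * profilin_total
  if (any(disc < 0))
    stop("internal error: negative discriminant in binding quadratic")
  2 * actin * profilin_total / (b + sqrt(disc))
}

#' Solve the shared-profilin-pool equilibrium
#'
#' Labeled and unlabeled actin monomers compete for the same profilin pool.
#' At equilibrium each complex obeys mass action with the common free
#' profilin concentration,
#' `PA_i = A_i * P_free / (Kd_i + P_free)`,
#' and profilin is conserved:
#' `P_free + PA_unlabeled + PA_labeled = P_total`.
#' The conservation residual is strictly increasing in `P_free`, so the root
#' on `[0, P_total]` is unique; it is located by bracketed root finding to
#' an absolute tolerance of 1e-12 uM.
#'
#' `profilin_free = "total"` replaces the solve with the approximation
#' `P_free = P_total` (each species evaluated by the isotherm at the full
#' pool). This mode intentionally ignores profilin depletion by bound actin
#' and is provided for comparison with analyses that treat each species
#' independently; its output violates profilin conservation when complexes
#' are an appreciable share of the pool.
#'
#' @param condition A [reaction_condition()].
#' @param profilin_free `"solve"` (default) for the exact conservation root,
#'   or `"total"` for the `P_free = P_total` approximation.
#' @return An object of class `equilibrium_state`: a list with
#'   `pa_unlabeled`, `pa_labeled`, `pa_total`, `profilin_free` (all uM).
#' @examples
#' solve_shared_profilin(sc_condition(profilin_total = 5))
#' @export
solve_shared_profilin <- function(condition,
                                  profilin_free = c("solve", "total")) {
  stopifnot(inherits(condition, "reaction_condition"))
  profilin_free <- match.arg(profilin_free)
  au <- condition$actin_unlabeled; al <- condition$actin_labeled
  pt <- condition$profilin_total
  ku <- condition$kd_unlabeled; kl <- condition$kd_labeled

  if (pt == 0) return(equilibrium_state(0, 0, 0))

  if (profilin_free == "total") {
    pf <- pt
  } else {
    residual <- function(pf) {
      pf + au * pf / (ku + pf) + al * pf / (kl + pf) - pt
    }
    root <- stats::uniroot(residual, lower = 0, upper = pt, tol = 1e-12,
                           check.conv = TRUE)
    pf <- root$root
  }
  equilibrium_state(pa_weak_binding(au, pf, ku),
                    pa_weak_binding(al, pf, kl), pf)
}

equilibrium_state <- function(pa_unlabeled, pa_labeled, profilin_free) {
  structure(
    list(pa_unlabeled = pa_unlabeled, pa_labeled = pa_labeled,
         pa_total = pa_unlabeled + pa_labeled, profilin_free = profilin_free),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "Profilin-actin equilibrium (uM):\n  PA unlabeled %.6g, PA labeled %.6g, PA total %.6g\n  free profilin %.6g\n",
    x$pa_unlabeled, x$pa_labeled, x$pa_total, x$profilin_free))
  invisible(x)
}

#' Per-species equilibrium, ignoring competition for profilin
#'
#' Computes profilin-actin for each monomer species independently, with the
#' full profilin pool available to each: the weak-binding isotherm at
#' `P_free = P_total` (suitable for weak binders such as Sc profilin) or the
#' exact binding quadratic per species (suitable for tight binders such as
#' human profilin-1). Because both species draw on the full pool, the summed
#' complexes can overcount profilin at high actin; [solve_shared_profilin()]
#' is the self-consistent alternative.
#'
#' @param condition A [reaction_condition()].
#' @param binding `"isotherm"` or `"quadratic"`; `"auto"` (default) selects
#'   the quadratic when the tighter Kd is below the total actin
#'   concentration.
#' @return An `equilibrium_state`; its `profilin_free` is
#'   `P_total - PA_total`, floored at 0.
#' @export
solve_independent_species <- function(condition,
                                      binding = c("auto", "isotherm",
                                                  "quadratic")) {
  stopifnot(inherits(condition, "reaction_condition"))
  binding <- match.arg(binding)
  if (binding == "auto") {
    tight <- min(condition$kd_unlabeled, condition$kd_labeled) <
      (condition$actin_unlabeled + condition$actin_labeled)
    binding <- if (tight) "quadratic" else "isotherm"
  }
  pt <- condition$profilin_total
  if (binding == "isotherm") {
    pu <- pa_weak_binding(condition$actin_unlabeled, pt,
                          condition$kd_unlabeled)
    pl <- pa_weak_binding(condition$actin_labeled, pt, condition$kd_labeled)
  } else {
    pu <- pa_quadratic(condition$actin_unlabeled, pt, condition$kd_unlabeled)
    pl <- pa_quadratic(condition$actin_labeled, pt, condition$kd_labeled)
  }
  equilibrium_state(pu, pl, max(pt - pu - pl, 0))
}

#' Labeled/unlabeled ratio of profilin-bound actin
#'
#' The ratio `PA_labeled / PA_unlabeled` used to convert the unlabeled
#' FH1-delivered fraction into the labeled one: the two complexes are
#' delivered in proportion to their concentrations.
#'
#' @param state An `equilibrium_state`.
#' @return Dimensionless ratio.
#' @export
pa_label_ratio <- function(state) {
  stopifnot(inherits(state, "equilibrium_state"))
  if (state$pa_unlabeled <= 0)
    stop("pa_label_ratio undefined: no profilin-bound unlabeled actin ",
         "(pa_unlabeled = 0)")
  state$pa_labeled / state$pa_unlabeled
}
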